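# Synthetic tubular airway phantoms with analytic ground truth.
#
# A phantom is an air-filled tube (HU = hu_air) with elliptical
# cross-section embedded in soft tissue (HU = hu_tissue), following a
# parametric centerline in the midsagittal plane. The lateral (LR)
# semi-axis is a(s), the anterior-posterior semi-axis b(s), both linear in
# arc length. The volume is Gaussian-blurred (partial-volume emulation) and
# Gaussian noise is added. Landmarks are planted at prescribed arc-length
# positions so the whole measurement pipeline has closed-form truth.

#' Specify a tubular airway phantom
#'
#' @param curve list describing the centerline: `list(type = "line",
#'   direction =, length =)`, `list(type = "arc", radius =, angle =)` (a
#'   planar sagittal arc starting vertically and bowing anteriorly), or
#'   `list(type = "cubic", coef =, length =)` with `y = f(z)` cubic
#'   coefficients.
#' @param a,b length-2: lateral / anterior-posterior semi-axes (mm) at the
#'   superior and inferior ends (linear taper).
#' @param hu_air,hu_tissue HU of lumen and surrounding tissue.
#' @param noise_sd Gaussian noise SD, HU.
#' @param blur_sigma Gaussian blur SD, mm (partial-volume emulation).
#' @param voxel_size isotropic voxel size, mm.
#' @param boundary_s arc-length positions (mm) of the four landmark-derived
#'   boundaries `c(s_a, s_b, s_c, s_d)`; the fifth boundary is the tube
#'   end. Default: fractions 0.08/0.35/0.60/0.78 of tube length.
#' @param margin tissue margin around the tube, mm.
#' @param seed RNG seed for the noise.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(curve = list(type = "arc", radius = 30,
                                      angle = pi / 3),
                         a = c(5, 3), b = c(5, 3),
                         hu_air = -1000, hu_tissue = 100,
                         noise_sd = 20, blur_sigma = 0.3, voxel_size = 0.5,
                         boundary_s = NULL, margin = 6, seed = 1) {
  stopifnot(hu_air < hu_tissue, voxel_size > 0, length(a) == 2,
            length(b) == 2)
  if (any(c(a, b) <= 2 * voxel_size))
    stop("semi-axes must exceed 2 voxel sizes everywhere")
  cv <- make_curve(curve)
  if (is.null(boundary_s))
    boundary_s <- cv$length * c(0.08, 0.35, 0.60, 0.78)
  if (is.unsorted(boundary_s) || boundary_s[1] < 0 ||
      boundary_s[4] >= cv$length)
    stop("boundary_s must be sorted inside [0, tube length)")
  structure(list(curve = curve, cv = cv, a = a, b = b, hu_air = hu_air,
                 hu_tissue = hu_tissue, noise_sd = noise_sd,
                 blur_sigma = blur_sigma, voxel_size = voxel_size,
                 boundary_s = boundary_s, margin = margin, seed = seed),
            class = "phantom_spec")
}

# Arc-length parameterized curve evaluators: point(s), tangent(s) (unit),
# all curves in the x = 0 sagittal plane, superior -> inferior.
make_curve <- function(curve) {
  type <- match.arg(curve$type, c("line", "arc", "cubic"))
  if (type == "line") {
    dir <- normalize3(curve$direction %||% c(0, 0, -1))
    L <- curve$length
    list(length = L,
         point = function(s) t(vapply(s, function(si) si * dir, numeric(3))),
         tangent = function(s) matrix(dir, nrow = length(s), ncol = 3,
                                      byrow = TRUE))
  } else if (type == "arc") {
    # sagittal arc: tilted anteriorly at the superior end (nasopharyngeal
    # bend), vertical at the inferior (tracheal) end
    R <- curve$radius
    L <- R * curve$angle
    if (curve$angle > pi / 2 + 1e-9)
      stop("arc angle must not exceed 90 degrees (z must stay monotone)")
    list(length = L,
         point = function(s) {
           phi <- (L - s) / R
           cbind(0, R * (cos(phi) - cos(L / R)),
                 R * (sin(phi) - sin(L / R)))
         },
         tangent = function(s) {
           phi <- (L - s) / R
           cbind(0, sin(phi), -cos(phi))
         })
  } else {
    cf <- curve$coef  # y = cf[1] + cf[2] z + cf[3] z^2 + cf[4] z^3
    zlen <- curve$length
    zs <- seq(0, -zlen, length.out = 4000)
    ys <- cf[1] + cf[2] * zs + cf[3] * zs^2 + cf[4] * zs^3
    pts <- cbind(0, ys - ys[1], zs)
    sl <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
    L <- sl[length(sl)]
    list(length = L,
         point = function(s) {
           z <- stats::approx(sl, zs, xout = pmin(pmax(s, 0), L))$y
           cbind(0, cf[1] + cf[2] * z + cf[3] * z^2 + cf[4] * z^3 - ys[1], z)
         },
         tangent = function(s) {
           z <- stats::approx(sl, zs, xout = pmin(pmax(s, 0), L))$y
           dy <- cf[2] + 2 * cf[3] * z + 3 * cf[4] * z^2
           t(apply(cbind(0, -dy, -1), 1, normalize3))
         })
  }
}

phantom_semiaxes <- function(spec, s) {
  f <- s / spec$cv$length
  list(a = spec$a[1] + (spec$a[2] - spec$a[1]) * f,
       b = spec$b[1] + (spec$b[2] - spec$b[1]) * f)
}

# in-plane anterior unit vector: AP = tangent x LR with LR = +x
phantom_ap <- function(tan) cbind(0, -tan[, 3], tan[, 2])

#' Generate a phantom CT volume, landmarks and ground truth
#'
#' Voxelizes the tube (lumen `hu_air`, surroundings `hu_tissue`), applies
#' Gaussian blur and seeded Gaussian noise, plants the 26 landmarks
#' consistently with their anatomic roles at the planned arc-length
#' positions, and computes analytic ground truth for all 30 measurement
#' variables by quadrature of the tube integrals.
#'
#' @param spec a [phantom_spec].
#' @param scan_id identifier attached to the volume.
#' @return list with `volume` ([ct_volume]), `landmarks` (raw name ->
#'   point mapping, mm), `truth` (named list; see details), `seed_voxel`
#'   (an in-lumen voxel index), `roi_superior`, `roi_inferior` (mm).
#' @export
generate_phantom <- function(spec, scan_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  cv <- spec$cv
  L <- cv$length
  h <- spec$voxel_size

  ds <- h / 2
  ssamp <- seq(ds / 2, L - ds / 2 + 1e-9, by = ds)
  Ps <- cv$point(ssamp)
  Ts <- cv$tangent(ssamp)
  ax <- phantom_semiaxes(spec, ssamp)

  rmax <- max(spec$a, spec$b)
  lo <- apply(Ps, 2, min) - rmax - spec$margin
  hi <- apply(Ps, 2, max) + rmax + spec$margin
  origin <- lo
  dims <- ceiling((hi - lo) / h) + 1L
  if (any(dims > 1024L)) stop("tube exits a practical volume bound")
  xs <- origin[1] + (seq_len(dims[1]) - 1) * h
  ys <- origin[2] + (seq_len(dims[2]) - 1) * h
  zs <- origin[3] + (seq_len(dims[3]) - 1) * h

  # fractional lumen occupancy: 3x3x3 supersampling with per-subsample
  # partial coverage (a linear ramp on the signed radial distance to the
  # tube wall over one subsample width), so the voxel HU tracks the air
  # fraction the way a scanner's partial-volume averaging does, with no
  # grid-phase quantization
  frac <- array(0, dims)
  hw <- 0.6 * ds  # slab half-thickness with a small overlap guard
  ss <- h / 3
  subo <- c(-ss, 0, ss)
  for (ox in subo) for (oy in subo) for (oz in subo) {
    air <- array(0, dims)
    xs_o <- xs + ox; ys_o <- ys + oy; zs_o <- zs + oz
    for (k in seq_along(ssamp)) {
      P <- Ps[k, ]; tn <- Ts[k, ]
      ak <- ax$a[k]; bk <- ax$b[k]
      r <- max(ak, bk) + h
      ix <- which(xs_o >= P[1] - r & xs_o <= P[1] + r)
      iy <- which(ys_o >= P[2] - r & ys_o <= P[2] + r)
      iz <- which(zs_o >= P[3] - r & zs_o <= P[3] + r)
      if (!length(ix) || !length(iy) || !length(iz)) next
      dx <- xs_o[ix] - P[1]; dy <- ys_o[iy] - P[2]; dz <- zs_o[iz] - P[3]
      nx_ <- length(ix); ny_ <- length(iy); nz_ <- length(iz)
      # LR = +x; AP = (0, -tz, ty); axial w = d . tangent (tangent x = 0)
      v <- outer(dy * (-tn[3]), dz * tn[2], "+")
      w <- outer(dy * tn[2], dz * tn[3], "+")
      sk <- ssamp[k]
      in_w <- abs(w) <= hw
      # signed distance to the elliptical wall along the radial ray
      rho2 <- array(outer((dx / ak)^2, (v / bk)^2, "+"), c(nx_, ny_, nz_))
      rp <- sqrt(array(outer(dx^2, v^2, "+"), c(nx_, ny_, nz_)))
      dist <- rp * (1 - 1 / pmax(sqrt(rho2), 1e-9))
      dist[rho2 < 1e-18] <- -min(ak, bk)
      cov <- pmin(pmax(0.5 - dist / ss, 0), 1)
      # axial coverage ramps at the two tube ends
      wabs <- sk + w
      cov_ax <- pmin(pmax(0.5 + wabs / ss, 0), 1) *
        pmin(pmax(0.5 + (L - wabs) / ss, 0), 1)
      cov <- cov * aperm(array(in_w * cov_ax, c(ny_, nz_, nx_)), c(3, 1, 2))
      air[ix, iy, iz] <- pmax(air[ix, iy, iz], cov)
    }
    frac <- frac + air
  }
  frac <- frac / 27

  vox <- spec$hu_tissue + frac * (spec$hu_air - spec$hu_tissue)
  if (spec$blur_sigma > 0)
    vox <- gaussian_blur_3d(vox, spec$blur_sigma / h)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    vox <- vox + array(stats::rnorm(prod(dims), 0, spec$noise_sd), dims)
  }
  volume <- ct_volume(vox, spacing = rep(h, 3), origin = origin,
                      kernel = "standard", scan_id = scan_id)

  lms <- plant_landmarks(spec)
  truth <- phantom_truth(spec, lms)

  mid <- cv$point(L / 2)[1, ]
  seed_voxel <- pmax(1L, pmin(dims, round((mid - origin) / h) + 1L))
  # ROI bounds clear the (possibly oblique) end faces entirely, so the
  # axial clip never truncates the tube the ground truth describes
  list(volume = volume, landmarks = lms, truth = truth,
       seed_voxel = seed_voxel,
       roi_superior = cv$point(0)[1, 3] + rmax + 1,
       roi_inferior = cv$point(L)[1, 3] - rmax - 1)
}

# separable Gaussian blur, sigma in voxels, replicated edges
gaussian_blur_3d <- function(arr, sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  kk <- stats::dnorm(-r:r, sd = sigma_vox)
  kk <- kk / sum(kk)
  d <- dim(arr)
  for (axis in 1:3) {
    out <- array(0, d)
    n <- d[axis]
    for (off in -r:r) {
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      sl <- switch(axis,
                   arr[idx, , , drop = FALSE],
                   arr[, idx, , drop = FALSE],
                   arr[, , idx, drop = FALSE])
      out <- out + kk[off + r + 1] * sl
    }
    arr <- out
  }
  arr
}

# Plant the 26 landmarks consistently with their anatomic roles.
plant_landmarks <- function(spec) {
  cv <- spec$cv
  bs <- spec$boundary_s
  pt <- function(s) cv$point(s)[1, ]
  tn <- function(s) cv$tangent(s)[1, ]
  ap <- function(s) phantom_ap(cv$tangent(s))[1, ]
  lr <- c(1, 0, 0)
  P_a <- pt(bs[1]); P_b <- pt(bs[2]); P_c <- pt(bs[3]); P_d <- pt(bs[4])
  b_d <- phantom_semiaxes(spec, bs[4])$b
  pns <- c(0, P_a[2] + 25, P_a[3])
  ans <- c(0, P_a[2] + 45, P_a[3])
  veend <- P_b
  epmid <- pt((bs[2] + bs[3]) / 2)
  list(
    ga = P_d + b_d * ap(bs[4]), gp = P_d - b_d * ap(bs[4]),
    epS = epmid + 5 * ap((bs[2] + bs[3]) / 2) + c(0, -2, 4),
    epBse = epmid + 5 * ap((bs[2] + bs[3]) / 2),
    epBsePo = epmid - 6 * ap((bs[2] + bs[3]) / 2),
    PSInL = P_c + 4 * lr + 8 * tn(bs[3]),
    PSInR = P_c - 4 * lr + 8 * tn(bs[3]),
    PSSuL = P_c + 4 * lr, PSSuR = P_c - 4 * lr,
    VaInL = epmid + 3 * lr + c(0, 1, -1),
    VaInR = epmid - 3 * lr + c(0, 1, -1),
    VeAn = P_b + 9 * ap(bs[2]), VePo = P_b - 9 * ap(bs[2]),
    VeBa = (pns + veend) / 2 + c(0, -3, 2),
    VeEnd = veend,
    NpxAn = P_a + 8 * ap(bs[1]), NpxPo = P_a - 8 * ap(bs[1]),
    NasalS = pt(0) + c(0, 8, 4),
    ANS = ans, PNS = pns,
    ABI = pns + c(0, 38, -6),
    PIC = pns + c(0, 30, 0), PALS = pns + c(0, 10, 0))
}

# Closed-form / quadrature ground truth for the 30 variables.
phantom_truth <- function(spec, lms) {
  cv <- spec$cv
  L <- cv$length
  bs <- c(spec$boundary_s, L)
  csa <- function(s) {
    ax <- phantom_semiaxes(spec, s)
    pi * ax$a * ax$b
  }
  vol <- function(s0, s1) {
    if (s1 <= s0) return(0)
    stats::integrate(csa, s0, s1, rel.tol = 1e-10)$value
  }
  at <- function(s) {
    ax <- phantom_semiaxes(spec, s)
    list(area = pi * ax$a * ax$b, ap = 2 * ax$b, width = 2 * ax$a)
  }
  ba <- lapply(bs, at)
  vols <- c(vol(bs[1], bs[2]), vol(bs[2], bs[3]), vol(bs[3], bs[4]),
            vol(bs[4], bs[5]))
  lens <- diff(bs)

  mmax <- (lms$PIC + lms$PALS) / 2
  P_a <- cv$point(bs[1])[1, ]
  vtl <- sqrt(sum((lms$ABI - mmax)^2)) + sqrt(sum((mmax - lms$PNS)^2)) +
    sqrt(sum((lms$PNS - P_a)^2)) + (bs[4] - bs[1])

  # velum truth: dense polyline length of the quadratic Bezier
  p0 <- lms$PNS; p1 <- lms$VeBa; p2 <- lms$VeEnd
  uu <- seq(0, 1, length.out = 20001)
  curve_pts <- outer((1 - uu)^2, p0) + outer(2 * uu * (1 - uu), p1) +
    outer(uu^2, p2)
  velum <- sum(sqrt(rowSums(diff(curve_pts)^2)))

  psl <- sqrt(sum((lms$PSSuL - lms$PSInL)^2))
  psr <- sqrt(sum((lms$PSSuR - lms$PSInR)^2))

  list(
    Nasopharynx = vols[1], NasopharynxL = lens[1],
    NasopharynxArea = ba[[1]]$area, NasopharynxAPDist = ba[[1]]$ap,
    NasopharynxWidth = ba[[1]]$width,
    Oropharynx = vols[2], OropharynxL = lens[2],
    OropharynxArea = ba[[2]]$area, OropharynxAPDist = ba[[2]]$ap,
    OropharynxWidth = ba[[2]]$width,
    Laryngopharynx = vols[3], LaryngopharynxL = lens[3],
    LaryngopharynxArea = ba[[3]]$area, LaryngopharynxAPDist = ba[[3]]$ap,
    LaryngopharynxWidth = ba[[3]]$width,
    PharynxVolume = sum(vols[1:3]), PharynxLength = sum(lens[1:3]),
    GlottisArea = ba[[4]]$area, GlottisAPDist = ba[[4]]$ap,
    GlottisWidth = ba[[4]]$width,
    Subglottal = vols[4], SubglottalL = lens[4],
    TracheaArea = ba[[5]]$area, TracheaAPDist = ba[[5]]$ap,
    TracheaWidth = ba[[5]]$width,
    VTLength_i = vtl, VelumLength = velum,
    PSLengthLeft = psl, PSLengthRight = psr,
    AveragePSLength = (psl + psr) / 2,
    threshold_expected = (spec$hu_air + spec$hu_tissue) / 2,
    tube_length = L)
}

#' Run the full measurement pipeline on a volume
#'
#' Convenience wrapper chaining threshold -> segmentation -> surface ->
#' fairing -> centerline -> sections -> landmark resolution -> measurement.
#'
#' @param volume a [ct_volume].
#' @param landmarks raw landmark mapping (see [resolve_landmarks()]).
#' @param seed_voxel in-lumen voxel index for segmentation.
#' @param roi_superior,roi_inferior axial bounds, mm.
#' @param threshold optional HU threshold; computed from the histogram when
#'   omitted.
#' @param lambda_dt,fair_iterations fairing parameters.
#' @param contour_spacing,resample_step centerline parameters, mm.
#' @return list with all intermediate artifacts and the
#'   `measurement_record` (`$record`).
#' @export
run_pipeline <- function(volume, landmarks, seed_voxel, roi_superior,
                         roi_inferior, threshold = NULL, lambda_dt = 0.5,
                         fair_iterations = 3, contour_spacing = 2,
                         resample_step = 1) {
  if (volume$kernel != "standard") volume <- harmonize_kernel(volume)
  thr <- if (is.null(threshold)) compute_airway_threshold(volume)
         else list(upper_threshold = threshold)
  mask <- segment_airway(volume, thr$upper_threshold, seed_voxel,
                         roi_superior, roi_inferior)
  mesh <- extract_surface(mask)
  mesh <- fair_mesh(mesh, lambda_dt = lambda_dt,
                    iterations = fair_iterations)
  mesh <- refine_surface(mesh, volume, thr$upper_threshold)
  cl <- extract_centerline(mesh, contour_spacing = contour_spacing,
                           resample_step = resample_step)
  sections <- slice_orthogonal(mesh, cl)
  lmset <- resolve_landmarks(landmarks)
  record <- measure_all(volume, mask, mesh, cl, sections, lmset)
  list(threshold = thr, mask = mask, mesh = mesh, centerline = cl,
       sections = sections, landmarks = lmset, record = record)
}

#' Compare measured values against phantom ground truth
#'
#' @param truth ground-truth list from [generate_phantom()].
#' @param measured a `measurement_record` (or named list).
#' @param tolerance per-variable relative-error tolerance (default 0.05,
#'   the 5% reliability bar used for inter-rater agreement).
#' @return A `pipeline_report`: data.frame of per-variable errors plus
#'   attributes `are` (overall average relative error) and `pass`.
#' @export
evaluate_pipeline <- function(truth, measured, tolerance = 0.05) {
  mv <- as_measure_vector(measured)
  shared <- intersect(names(mv), names(truth))
  tv <- unlist(truth[shared])
  mv <- mv[shared]
  ok <- !is.na(mv) & !is.na(tv)
  tv <- tv[ok]; mv <- mv[ok]
  rel <- abs(mv - tv) / abs(tv)
  df <- data.frame(variable = names(tv), truth = unname(tv),
                   measured = unname(mv), rel_error = unname(rel),
                   pass = unname(rel <= tolerance),
                   stringsAsFactors = FALSE)
  are <- mean(abs(mv - tv) / ((abs(mv) + abs(tv)) / 2))
  structure(df, are = are, pass = all(df$pass), tolerance = tolerance,
            class = c("pipeline_report", "data.frame"))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> ARE %.3f%%, %d/%d variables within %.0f%%\n",
              100 * attr(x, "are"), sum(x$pass), nrow(x),
              100 * attr(x, "tolerance")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Simulate a longitudinal growth dataset
#'
#' Draws log-scale responses from the random-intercept growth model
#' `y = b0 + b1 Sex + b2 Adult + b3 Sex*Adult + b4 PediatricAge +
#' b5 Sex*PediatricAge + alpha_i + eps`, with `Sex` coded male = 1,
#' `Adult` a dummy for adult subjects and `PediatricAge` the age in years
#' for children (0 for adults). Repeat scans of a subject share the
#' subject's random intercept.
#'
#' @param n_subjects total number of subjects.
#' @param scans_per_subject scans per subject (recycled). The default mixes
#'   single and repeat scans, as longitudinal imaging databases do; at
#'   least some repeats are needed to separate the subject variance from
#'   the residual.
#' @param betas numeric length 6: `b0..b5`.
#' @param sigma_subject random-intercept SD (log scale).
#' @param sigma_resid residual SD (log scale).
#' @param age_range pediatric age range, years.
#' @param sex_ratio proportion of males.
#' @param prop_adult proportion of adult subjects.
#' @param seed RNG seed.
#' @param variable variable name tag for the output rows.
#' @return data.frame (subject_id, scan_id, sex, adult, pediatric_age,
#'   variable, value, log_value) with the true parameters as attributes.
#' @export
simulate_growth_data <- function(n_subjects = 72,
                                 scans_per_subject = c(1, 1, 2),
                                 betas = c(7.3, 0.05, 2.6, 0.15, 0.22,
                                           0.02),
                                 sigma_subject = 0.25, sigma_resid = 0.2,
                                 age_range = c(0, 5), sex_ratio = 0.5,
                                 prop_adult = 16 / 72, seed = 1,
                                 variable = "PharynxVolume") {
  stopifnot(length(betas) == 6, sigma_subject >= 0, sigma_resid >= 0)
  set.seed(seed)
  n_male <- round(n_subjects * sex_ratio)
  sex <- c(rep(1L, n_male), rep(0L, n_subjects - n_male))
  if (min(table(factor(sex, levels = 0:1))) < 2)
    stop("degenerate design: need at least 2 subjects per sex")
  n_adult <- round(n_subjects * prop_adult)
  adult <- integer(n_subjects)
  adult[sample.int(n_subjects, n_adult)] <- 1L
  if (all(adult == 1L) || all(adult == 0L))
    stop("degenerate design: need both pediatric and adult subjects")
  age <- ifelse(adult == 1L, 0,
                stats::runif(n_subjects, age_range[1], age_range[2]))
  alpha <- stats::rnorm(n_subjects, 0, sigma_subject)
  nscan <- rep_len(scans_per_subject, n_subjects)
  rows <- rep(seq_len(n_subjects), nscan)
  lp <- betas[1] + betas[2] * sex[rows] + betas[3] * adult[rows] +
    betas[4] * sex[rows] * adult[rows] + betas[5] * age[rows] +
    betas[6] * sex[rows] * age[rows]
  y <- lp + alpha[rows] + stats::rnorm(length(rows), 0, sigma_resid)
  out <- data.frame(
    subject_id = sprintf("S%03d", rows),
    scan_id = sprintf("S%03d_%d", rows, sequence(nscan)),
    sex = sex[rows], adult = adult[rows],
    pediatric_age = age[rows] * (1 - adult[rows]),
    variable = variable, value = exp(y), log_value = y,
    stringsAsFactors = FALSE)
  attr(out, "betas") <- betas
  attr(out, "sigma_subject") <- sigma_subject
  attr(out, "sigma_resid") <- sigma_resid
  out
}
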