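# Anatomic landmarks, region partition and the 30-variable measurement
# record. Landmark abbreviations follow the field's naming (glottis
# anterior/posterior, epiglottis, piriform sinuses, valleculae, velum,
# nasopharynx, nasal spines, maxilla).

#' The 26-landmark registry
#'
#' Names, roles and parents of the landmark schema used throughout the
#' package. Three landmarks are derived midpoints (computed, never
#' supplied); the inferior piriform-sinus pair may be missing unilaterally.
#'
#' @return data.frame with columns `name`, `role`
#'   (`required`/`derived`/`optional`) and `parents`.
#' @export
landmark_registry <- function() {
  data.frame(
    name = c("ga", "gp", "epS", "epBse", "epBsePo", "PSInL", "PSInR",
             "PSSuL", "PSSuR", "VaInL", "VaInR", "VeAn", "VePo", "MidVe",
             "VeBa", "VeEnd", "NpxAn", "NpxPo", "NpxMid", "NasalS",
             "ANS", "PNS", "ABI", "PIC", "PALS", "MMax"),
    role = c("required", "required", "required", "required", "required",
             "optional", "optional", "required", "required", "required",
             "required", "required", "required", "derived", "required",
             "required", "required", "required", "derived", "required",
             "required", "required", "required", "required", "required",
             "derived"),
    parents = c(rep("", 13), "VeAn,VePo", "", "", "", "", "NpxAn,NpxPo",
                "", "", "", "", "", "", "PIC,PALS"),
    stringsAsFactors = FALSE)
}

#' Validate and resolve a landmark set
#'
#' Checks the supplied name -> point mapping against the registry, computes
#' the three derived midpoints (`MidVe`, `NpxMid`, `MMax`) from their
#' parents — overwriting any supplied values — and validates the schema
#' (ANS must be anterior to PNS).
#'
#' @param raw named list of length-3 numeric points, or a 3-column matrix /
#'   data.frame with row names (mm, RAS).
#' @return A `landmark_set`: 26 x 3 coordinate matrix (rows named by
#'   abbreviation; missing optional landmarks are NA rows).
#' @export
resolve_landmarks <- function(raw) {
  reg <- landmark_registry()
  if (is.data.frame(raw) && all(c("name", "x", "y", "z") %in% names(raw))) {
    m <- as.matrix(raw[, c("x", "y", "z")])
    rownames(m) <- raw$name
    raw <- m
  }
  if (is.list(raw) && !is.data.frame(raw))
    raw <- do.call(rbind, raw)
  raw <- as.matrix(raw)
  if (is.null(rownames(raw))) stop("landmarks must be named")
  unknown <- setdiff(rownames(raw), reg$name)
  if (length(unknown))
    stop("unknown landmark name: ", paste(unknown, collapse = ", "))
  coords <- matrix(NA_real_, nrow = nrow(reg), ncol = 3,
                   dimnames = list(reg$name, c("x", "y", "z")))
  coords[rownames(raw), ] <- raw
  required <- reg$name[reg$role == "required"]
  miss <- required[!required %in% rownames(raw) |
                     rowSums(is.na(coords[required, , drop = FALSE])) > 0]
  if (length(miss))
    stop("missing required landmark: ", paste(miss, collapse = ", "))
  for (d in which(reg$role == "derived")) {
    par <- strsplit(reg$parents[d], ",")[[1]]
    coords[reg$name[d], ] <- colMeans(coords[par, , drop = FALSE])
  }
  if (!(coords["ANS", "y"] > coords["PNS", "y"]))
    stop("ANS must be anterior to PNS (ANS_y > PNS_y)")
  structure(coords, class = c("landmark_set", "matrix"))
}

#' @export
print.landmark_set <- function(x, ...) {
  defined <- sum(stats::complete.cases(unclass(x)))
  cat(sprintf("<landmark_set> %d/%d landmarks defined\n", defined, nrow(x)))
  invisible(x)
}

lm_pt <- function(landmarks, name) {
  p <- unclass(landmarks)[name, ]
  if (any(is.na(p))) stop("landmark ", name, " is missing")
  p
}

#' Partition the centerline into the four airway regions
#'
#' Locates the five boundary positions along the centerline: (a) the
#' crossing of the palatal plane (through the ANS-PNS line, zero lateral
#' tilt), (b) the point nearest the velum tip `VeEnd`, (c) nearest the
#' midpoint of the aryepiglottic-fold landmarks `PSSuL`/`PSSuR`, (d)
#' nearest the glottis midpoint (`ga`/`gp`), and (e) the centerline end
#' (the mask was clipped at the first tracheal ring). The four regions are
#' nasopharynx (a to b), oropharynx (b to c), laryngopharynx (c to d) and
#' subglottal (d to e).
#'
#' @param centerline a `centerline` (superior to inferior).
#' @param landmarks a `landmark_set`.
#' @return A `region_partition`: named numeric of arc-length boundaries
#'   `s_a` to `s_e` (mm) plus region bounds.
#' @export
partition_regions <- function(centerline, landmarks) {
  P <- centerline$points
  s <- centerline$arc_length
  ans <- lm_pt(landmarks, "ANS"); pns <- lm_pt(landmarks, "PNS")
  nrm <- normalize3(cross3(pns - ans, c(1, 0, 0)))
  d <- as.numeric(sweep(P, 2, ans) %*% nrm)
  flips <- which(d[-1] * d[-length(d)] < 0)
  if (length(flips) == 0 && !any(d == 0))
    stop("centerline does not cross the palatal plane")
  if (any(d == 0)) {
    s_a <- s[which(d == 0)[1]]
  } else {
    i <- flips[1]
    f <- d[i] / (d[i] - d[i + 1])
    s_a <- s[i] + f * (s[i + 1] - s[i])
  }
  nearest_s <- function(target) {
    # continuous projection onto the polyline: nearest point on any segment
    A <- P[-nrow(P), , drop = FALSE]
    B <- P[-1, , drop = FALSE]
    AB <- B - A
    len2 <- rowSums(AB^2)
    tproj <- pmin(pmax(rowSums(sweep(A, 2, target, "-") * -AB) / len2, 0), 1)
    Q <- A + AB * tproj
    d2 <- rowSums(sweep(Q, 2, target)^2)
    i <- which.min(d2)  # ties break toward the superior point
    s[i] + tproj[i] * (s[i + 1] - s[i])
  }
  s_b <- nearest_s(lm_pt(landmarks, "VeEnd"))
  s_c <- nearest_s((lm_pt(landmarks, "PSSuL") + lm_pt(landmarks, "PSSuR")) / 2)
  s_d <- nearest_s((lm_pt(landmarks, "ga") + lm_pt(landmarks, "gp")) / 2)
  s_e <- s[length(s)]
  b <- c(s_a = s_a, s_b = s_b, s_c = s_c, s_d = s_d, s_e = s_e)
  if (is.unsorted(b))
    stop("boundaries out of order: ",
         paste(sprintf("%s=%.2f", names(b), b), collapse = ", "))
  structure(list(boundaries = b,
                 regions = list(nasopharynx = c(s_a, s_b),
                                oropharynx = c(s_b, s_c),
                                laryngopharynx = c(s_c, s_d),
                                subglottal = c(s_d, s_e))),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat("<region_partition> boundaries (mm along centerline):\n  ")
  cat(paste(sprintf("%s=%.2f", names(x$boundaries), x$boundaries),
            collapse = ", "), "\n")
  invisible(x)
}

# Section at an arbitrary arc-length position (plane recomputed, never
# interpolated from neighbouring sections).
section_at <- function(mesh, centerline, s) {
  loc <- centerline_at(centerline, s)
  make_section(mesh, loc$point, loc$tangent, near_point = loc$point)
}

#' Region measurements from sections and partition
#'
#' Computes the 25 region variables: per-region orthogonal volume
#' (trapezoidal integral of section area over arc length), centerline
#' length, and boundary cross-section area / anterior-posterior distance /
#' width at the superior boundary of each supraglottal region, at the
#' glottis, and at the tracheal end; plus the pharynx totals (sums of the
#' three supraglottal regions).
#'
#' @param mesh a watertight `airway_mesh`.
#' @param centerline a `centerline`.
#' @param sections list from [slice_orthogonal()] (aligned with the
#'   centerline points).
#' @param partition a `region_partition`.
#' @param end_standoff distance (mm) by which the tracheal-end boundary
#'   section is pulled back from the mesh end cap. The fairing step rounds
#'   the rim where the segmentation was clipped, so a section cut exactly
#'   at the end under-reads; the standoff samples the last position where
#'   the surface still represents the lumen wall. Region lengths and
#'   volumes are unaffected.
#' @return named list of 25 values (mm^3, mm, mm^2).
#' @export
measure_partition <- function(mesh, centerline, sections, partition,
                              end_standoff = 0.5) {
  s <- centerline$arc_length
  areas <- vapply(sections, function(x) x$area %||% NA_real_, numeric(1))
  b <- partition$boundaries
  b_sec_pos <- b
  b_sec_pos["s_e"] <- max(b["s_d"], b["s_e"] - end_standoff)
  bsec <- lapply(b_sec_pos, function(si) section_at(mesh, centerline, si))
  bad <- vapply(bsec, function(x) isTRUE(x$empty), logical(1))
  if (any(bad))
    stop("empty cross-section at boundary ",
         paste(names(b)[bad], collapse = ", "))
  barea <- vapply(bsec, `[[`, numeric(1), "area")

  region_volume <- function(s0, s1, a0, a1) {
    if (s1 - s0 <= 0) return(0)
    inner <- which(s > s0 & s < s1 & !is.na(areas))
    sg <- c(s0, s[inner], s1)
    ag <- c(a0, areas[inner], a1)
    sum(diff(sg) * (ag[-1] + ag[-length(ag)]) / 2)
  }
  vols <- c(
    nasopharynx = region_volume(b["s_a"], b["s_b"], barea[1], barea[2]),
    oropharynx = region_volume(b["s_b"], b["s_c"], barea[2], barea[3]),
    laryngopharynx = region_volume(b["s_c"], b["s_d"], barea[3], barea[4]),
    subglottal = region_volume(b["s_d"], b["s_e"], barea[4], barea[5]))
  lens <- c(diff(b))  # s_b-s_a, s_c-s_b, s_d-s_c, s_e-s_d

  list(
    Nasopharynx = unname(vols["nasopharynx"]),
    NasopharynxL = unname(lens[1]),
    NasopharynxArea = bsec$s_a$area,
    NasopharynxAPDist = bsec$s_a$ap_dist,
    NasopharynxWidth = bsec$s_a$width,
    Oropharynx = unname(vols["oropharynx"]),
    OropharynxL = unname(lens[2]),
    OropharynxArea = bsec$s_b$area,
    OropharynxAPDist = bsec$s_b$ap_dist,
    OropharynxWidth = bsec$s_b$width,
    Laryngopharynx = unname(vols["laryngopharynx"]),
    LaryngopharynxL = unname(lens[3]),
    LaryngopharynxArea = bsec$s_c$area,
    LaryngopharynxAPDist = bsec$s_c$ap_dist,
    LaryngopharynxWidth = bsec$s_c$width,
    PharynxVolume = unname(vols[[1]] + vols[[2]] + vols[[3]]),
    PharynxLength = unname(lens[[1]] + lens[[2]] + lens[[3]]),
    GlottisArea = bsec$s_d$area,
    GlottisAPDist = bsec$s_d$ap_dist,
    GlottisWidth = bsec$s_d$width,
    Subglottal = unname(vols["subglottal"]),
    SubglottalL = unname(lens[4]),
    TracheaArea = bsec$s_e$area,
    TracheaAPDist = bsec$s_e$ap_dist,
    TracheaWidth = bsec$s_e$width)
}

#' Vocal tract length from the incisor
#'
#' Curvilinear distance from the posterior aspect of the maxillary incisors
#' (ABI) to the glottis: the oral polyline ABI -> MMax -> PNS -> centerline
#' entry at the palatal-plane crossing, plus the centerline arc length from
#' there to the glottal boundary.
#'
#' @param centerline a `centerline`.
#' @param partition a `region_partition`.
#' @param landmarks a `landmark_set`.
#' @return length in mm.
#' @export
vtl_incisor <- function(centerline, partition, landmarks) {
  abi <- lm_pt(landmarks, "ABI")
  mmax <- lm_pt(landmarks, "MMax")
  pns <- lm_pt(landmarks, "PNS")
  b <- partition$boundaries
  entry <- centerline_at(centerline, b["s_a"])$point
  oral <- sqrt(sum((abi - mmax)^2)) + sqrt(sum((mmax - pns)^2)) +
    sqrt(sum((pns - entry)^2))
  oral + (b[["s_d"]] - b[["s_a"]])
}

#' Curvilinear velum length
#'
#' Length of the quadratic curve from PNS to the velum tip (VeEnd) shaped
#' by the velum-back landmark (VeBa) as the middle control point (a
#' quadratic Bezier), computed by numeric quadrature. The curve stays in
#' the convex hull of the three landmarks, so the length always lies
#' between the straight PNS-VeEnd distance and the PNS-VeBa-VeEnd
#' polyline; collinear landmarks reduce to the straight distance.
#'
#' @param landmarks a `landmark_set`.
#' @return length in mm.
#' @export
velum_length <- function(landmarks) {
  p0 <- lm_pt(landmarks, "PNS")
  p1 <- lm_pt(landmarks, "VeBa")
  p2 <- lm_pt(landmarks, "VeEnd")
  speed <- function(u)
    vapply(seq_along(u), function(i) {
      d <- 2 * (1 - u[i]) * (p1 - p0) + 2 * u[i] * (p2 - p1)
      sqrt(sum(d^2))
    }, numeric(1))
  stats::integrate(speed, 0, 1, rel.tol = 1e-9)$value
}

#' Piriform sinus lengths
#'
#' 3D distances from the aryepiglottic-fold midpoints (PSSuL/R) to the most
#' inferior piriform-sinus points (PSInL/R). The average uses both sides
#' when both exist, or the single available side.
#'
#' @param landmarks a `landmark_set`.
#' @return list with `left`, `right` (mm or NA) and `average` (mm).
#' @export
piriform_lengths <- function(landmarks) {
  m <- unclass(landmarks)
  side <- function(su, inf) {
    if (any(is.na(m[su, ])) || any(is.na(m[inf, ]))) return(NA_real_)
    sqrt(sum((m[su, ] - m[inf, ])^2))
  }
  left <- side("PSSuL", "PSInL")
  right <- side("PSSuR", "PSInR")
  if (is.na(left) && is.na(right))
    stop("both piriform sinus landmark pairs are incomplete")
  list(left = left, right = right,
       average = mean(c(left, right), na.rm = TRUE))
}

#' Average relative error between two measurement records
#'
#' Mean over the shared non-missing variables of `|a - b| / mean(a, b)`;
#' symmetric in its arguments.
#'
#' @param a,b `measurement_record`s (or named numeric vectors).
#' @return fraction (0 = identical).
#' @export
average_relative_error <- function(a, b) {
  va <- as_measure_vector(a)
  vb <- as_measure_vector(b)
  shared <- intersect(names(va), names(vb))
  if (length(shared) == 0) stop("records share no variables")
  va <- va[shared]; vb <- vb[shared]
  ok <- !is.na(va) & !is.na(vb)
  va <- va[ok]; vb <- vb[ok]
  denom <- (va + vb) / 2
  if (any(denom == 0)) stop("zero denominator in relative error")
  mean(abs(va - vb) / denom)
}

as_measure_vector <- function(x) {
  if (inherits(x, "measurement_record")) return(unlist(x$values))
  unlist(x)
}
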