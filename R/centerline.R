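# Centerline extraction and orthogonal cross-sections.
#
# The centerline is obtained in three stages: (1) level contours of the mesh
# along a patient axis, keeping one contour per level and recording its area
# centroid; (2) a smoothing cubic B-spline (de Boor basis) through the
# centroid sequence; (3) one refinement pass that re-slices the mesh
# orthogonally to the current tangents and refits. The result is resampled
# at a fixed arc-length step and extended to the mesh end caps by ray
# casting so the subglottal (inferior) boundary coincides with the clipped
# mesh end.

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Intersection of a watertight mesh with a plane.
# Returns a list of closed contours, each a list(points = k x 3 matrix in
# traversal order, area = mm^2, centroid = mm).
mesh_plane_section <- function(mesh, point, normal) {
  normal <- normalize3(normal)
  V <- mesh$vertices
  F <- mesh$faces
  d <- (V[, 1] - point[1]) * normal[1] + (V[, 2] - point[2]) * normal[2] +
    (V[, 3] - point[3]) * normal[3]
  d[abs(d) < 1e-9] <- 1e-9  # nudge vertices off the plane
  s1 <- d[F[, 1]] > 0; s2 <- d[F[, 2]] > 0; s3 <- d[F[, 3]] > 0
  crossing <- !(s1 == s2 & s2 == s3)
  if (!any(crossing)) return(list())
  Fc <- F[crossing, , drop = FALSE]

  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  # the two crossing edges of each face
  e12 <- (d[Fc[, 1]] > 0) != (d[Fc[, 2]] > 0)
  e23 <- (d[Fc[, 2]] > 0) != (d[Fc[, 3]] > 0)
  e31 <- (d[Fc[, 3]] > 0) != (d[Fc[, 1]] > 0)
  keys <- cbind(ifelse(e12, edge_key(Fc[, 1], Fc[, 2]), NA),
                ifelse(e23, edge_key(Fc[, 2], Fc[, 3]), NA),
                ifelse(e31, edge_key(Fc[, 3], Fc[, 1]), NA))
  seg <- t(apply(keys, 1, function(r) r[!is.na(r)]))
  if (ncol(seg) != 2) stop("degenerate plane-mesh intersection")

  ukeys <- unique(as.vector(seg))
  # crossing point for each unique edge
  parts <- do.call(rbind, strsplit(ukeys, " "))
  ia <- as.integer(parts[, 1]); ib <- as.integer(parts[, 2])
  tt <- d[ia] / (d[ia] - d[ib])
  P <- V[ia, , drop = FALSE] +
    tt * (V[ib, , drop = FALSE] - V[ia, , drop = FALSE])

  a1 <- match(seg[, 1], ukeys)
  a2 <- match(seg[, 2], ukeys)
  # adjacency: each crossing edge is shared by exactly two crossing faces
  nbr <- vector("list", length(ukeys))
  for (i in seq_along(a1)) {
    nbr[[a1[i]]] <- c(nbr[[a1[i]]], a2[i])
    nbr[[a2[i]]] <- c(nbr[[a2[i]]], a1[i])
  }
  visited <- logical(length(ukeys))
  contours <- list()
  for (start in seq_along(ukeys)) {
    if (visited[start]) next
    loop <- integer(0)
    cur <- start
    prev <- 0L
    repeat {
      visited[cur] <- TRUE
      loop <- c(loop, cur)
      nx <- setdiff(nbr[[cur]], prev)
      nx <- nx[!visited[nx]]
      if (length(nx) == 0) break
      prev <- cur
      cur <- nx[1]
    }
    if (length(loop) >= 3) contours[[length(contours) + 1]] <- loop
  }

  basis <- plane_basis(normal)
  lapply(contours, function(loop) {
    pts <- P[loop, , drop = FALSE]
    rel <- sweep(pts, 2, point)
    u <- rel %*% basis$e1
    v <- rel %*% basis$e2
    n <- length(u)
    nxt <- c(2:n, 1)
    crossp <- u * v[nxt] - u[nxt] * v
    a2x <- sum(crossp)
    area <- abs(a2x) / 2
    if (area > 1e-9) {
      cu <- sum((u + u[nxt]) * crossp) / (3 * a2x)
      cv <- sum((v + v[nxt]) * crossp) / (3 * a2x)
    } else {
      cu <- mean(u); cv <- mean(v)
    }
    centroid <- point + cu * basis$e1 + cv * basis$e2
    list(points = pts, area = area, centroid = centroid)
  })
}

# Orthonormal in-plane basis: e1 ~ projected patient Anterior axis when
# possible, e2 = normal x e1 (~ projected Right/lateral axis).
plane_basis <- function(normal) {
  normal <- normalize3(normal)
  ap <- c(0, 1, 0) - sum(c(0, 1, 0) * normal) * normal
  if (sqrt(sum(ap^2)) < 1e-6) {
    lr <- c(1, 0, 0) - sum(c(1, 0, 0) * normal) * normal
    e2 <- normalize3(lr)
    e1 <- normalize3(cross3(e2, normal))
    return(list(e1 = e1, e2 = e2, ap_defined = FALSE))
  }
  e1 <- normalize3(ap)
  e2 <- normalize3(cross3(normal, e1))
  list(e1 = e1, e2 = e2, ap_defined = TRUE)
}

# Smoothing cubic B-spline through a point sequence. Knots are uniform in
# chord length; the number of interior knots grows until the RMS residual
# drops to `target_rms` (mm). Basis functions are evaluated with the de Boor
# recursion (splines::splineDesign). Returns eval/deriv closures on [0, 1].
fit_bspline_curve <- function(points, target_rms) {
  n <- nrow(points)
  if (n < 4) stop("fewer than 4 centroids; spline underdetermined")
  chord <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  t <- chord / chord[n]
  max_inner <- max(0L, n - 4L)
  for (k in 0:max_inner) {
    inner <- if (k > 0) seq(0, 1, length.out = k + 2)[2:(k + 1)] else numeric(0)
    knots <- c(rep(0, 4), inner, rep(1, 4))
    B <- splines::splineDesign(knots, t, ord = 4)
    coef <- qr.coef(qr(B), points)
    fit <- B %*% coef
    rms <- sqrt(mean(rowSums((fit - points)^2)))
    if (rms <= target_rms || k == max_inner) break
  }
  list(
    eval = function(tt) {
      tt <- pmin(pmax(tt, 0), 1)
      splines::splineDesign(knots, tt, ord = 4) %*% coef
    },
    deriv = function(tt) {
      tt <- pmin(pmax(tt, 0), 1)
      splines::splineDesign(knots, tt, ord = 4, derivs = rep(1L, length(tt))) %*%
        coef
    },
    rms = rms, inner_knots = length(knots) - 8L)
}

# Robust spline fit: fit, drop centroids whose residual marks them as
# outliers (cap-contaminated contours near obliquely clipped ends), refit.
robust_fit_bspline <- function(points, target_rms, max_trim = 3L) {
  for (i in seq_len(max_trim + 1L)) {
    sp <- fit_bspline_curve(points, target_rms)
    chord <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
    tt <- chord / chord[length(chord)]
    res <- sqrt(rowSums((sp$eval(tt) - points)^2))
    cut <- max(3 * sqrt(mean(res^2)), 2 * target_rms)
    bad <- res > cut
    if (!any(bad) || sum(!bad) < 4 || i > max_trim) return(sp)
    points <- points[!bad, , drop = FALSE]
  }
  sp
}

# First positive ray-mesh intersection distance (Moller-Trumbore), or NA.
ray_mesh_distance <- function(mesh, origin, dir) {
  dir <- normalize3(dir)
  V <- mesh$vertices; F <- mesh$faces
  v0 <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - v0
  e2 <- V[F[, 3], , drop = FALSE] - v0
  h <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
             dir[3] * e2[, 1] - dir[1] * e2[, 3],
             dir[1] * e2[, 2] - dir[2] * e2[, 1])
  a <- rowSums(e1 * h)
  ok <- abs(a) > 1e-12
  s <- sweep(v0, 2, origin, "-") * -1
  u <- rowSums(s * h) / a
  q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
             s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
             s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
  v <- (q[, 1] * dir[1] + q[, 2] * dir[2] + q[, 3] * dir[3]) / a
  t <- rowSums(e2 * q) / a
  hit <- ok & u >= 0 & v >= 0 & (u + v) <= 1 & t > 1e-9
  if (!any(hit)) return(NA_real_)
  min(t[hit])
}

#' Extract the lumen centerline
#'
#' Level-contour centroid extraction along `axis_hint`, smoothed with a
#' cubic B-spline, refined by one orthogonal re-slicing pass, resampled at
#' `resample_step` and extended to the mesh end caps. Points are ordered
#' superior to inferior.
#'
#' @param mesh a watertight `airway_mesh`.
#' @param axis_hint initial slicing axis: `"z"` (superior, default), `"y"`
#'   or `"x"`.
#' @param contour_spacing level spacing for centroid extraction, mm.
#' @param spline_smoothing target RMS deviation of the spline from the
#'   centroids, mm; defaults to `contour_spacing / 4`.
#' @param resample_step arc-length step of the returned polyline, mm.
#' @param refine_passes number of orthogonal re-slicing passes (default 2).
#' @return A `centerline`: list with `points` (n x 3, mm), `arc_length`
#'   (cumulative, mm) and `tangents` (unit, per segment; last repeated).
#' @export
extract_centerline <- function(mesh, axis_hint = "z", contour_spacing = 2,
                               spline_smoothing = contour_spacing / 4,
                               resample_step = 1, refine_passes = 2) {
  stopifnot(inherits(mesh, "airway_mesh"))
  ax <- match(match.arg(axis_hint, c("x", "y", "z")), c("x", "y", "z"))
  rng <- range(mesh$vertices[, ax])
  if (diff(rng) < 3 * contour_spacing)
    stop("mesh extent along the hint axis is below 3 contour spacings")
  margin <- min(contour_spacing / 2, 0.5)
  levels <- seq(rng[2] - margin, rng[1] + margin, by = -contour_spacing)
  nrm <- c(0, 0, 0); nrm[ax] <- 1

  centroids <- list()
  careas <- numeric(0)
  for (lev in levels) {
    p <- c(0, 0, 0); p[ax] <- lev
    cs <- mesh_plane_section(mesh, p, nrm)
    if (length(cs) == 0) next  # mesh not intersected at this level; skip
    areas <- vapply(cs, `[[`, numeric(1), "area")
    centroids[[length(centroids) + 1]] <- cs[[which.max(areas)]]$centroid
    careas <- c(careas, max(areas))
  }
  C0 <- do.call(rbind, centroids)
  sp <- fit_bspline_curve(C0, spline_smoothing)

  # refinement stays clear of the clipped ends: planes cut orthogonally to
  # the lumen can strike an obliquely clipped end cap within roughly one
  # lumen radius of it, so samples are inset by the end-contour radius and
  # the tips are recovered afterwards by tangential extension
  # end-contour radii estimated robustly over the nearest few levels: at an
  # obliquely clipped end the first level cuts only a sliver of the cap
  nl <- length(careas)
  inset_top <- max(sqrt(careas[seq_len(min(4L, nl))] / pi))
  inset_bot <- max(sqrt(careas[seq(max(1L, nl - 3L), nl)] / pi))

  # refinement: re-slice orthogonally to the current tangents and refit.
  # Axial level contours near an obliquely clipped end are skewed by the
  # end cap; each orthogonal re-slicing pass contracts that bias, and a
  # small fixed number of passes is enough in practice.
  n_ref <- max(nrow(C0), 8L)
  for (pass in seq_len(refine_passes)) {
    tg <- seq(0, 1, length.out = 20L * n_ref)
    Pg <- sp$eval(tg)
    sg <- c(0, cumsum(sqrt(rowSums(diff(Pg)^2))))
    Lg <- sg[length(sg)]
    # the inset is taken once, in the first pass; later passes already span
    # the clipped domain
    lo <- if (pass == 1L) min(inset_top, 0.25 * Lg) else 0
    hi <- Lg - if (pass == 1L) min(inset_bot, 0.25 * Lg) else 0
    tt <- stats::approx(sg, tg, xout = seq(lo, hi, length.out = n_ref),
                        ties = "ordered")$y
    pts <- sp$eval(tt)
    tans <- sp$deriv(tt)
    centroids <- list()
    for (i in seq_along(tt)) {
      tan_i <- normalize3(tans[i, ])
      cs <- mesh_plane_section(mesh, pts[i, ], tan_i)
      if (length(cs) == 0) next
      d2 <- vapply(cs, function(ct) sum((ct$centroid - pts[i, ])^2),
                   numeric(1))
      centroids[[length(centroids) + 1]] <- cs[[which.min(d2)]]$centroid
    }
    C1 <- do.call(rbind, centroids)
    # the refined (inset) centroids carry little noise, so the final fit
    # tracks them tightly; earlier fits stay stiff for robustness against
    # cap-contaminated centroids
    target <- if (pass == refine_passes) spline_smoothing / 5
              else spline_smoothing
    sp <- robust_fit_bspline(C1, target)
  }

  # resample the refined interior at fixed arc-length steps
  tf <- seq(0, 1, length.out = 40L * nrow(C1))
  Pf <- sp$eval(tf)
  sg <- c(0, cumsum(sqrt(rowSums(diff(Pf)^2))))
  total <- sg[length(sg)]
  starget <- seq(0, total, by = resample_step)
  if (total - starget[length(starget)] > resample_step / 2)
    starget <- c(starget, total)
  tpar <- stats::approx(sg, tf, xout = starget, ties = "ordered")$y
  P <- sp$eval(tpar)

  # recover the tips by marching: step along the tangent, re-slice
  # orthogonally, re-center on the contour centroid; stop just inside the
  # end cap located by ray casting
  delta <- min(0.1, resample_step / 4)
  n <- nrow(P)
  top_ext <- march_end(mesh, P[1, ], normalize3(P[1, ] - P[2, ]),
                       resample_step, delta)
  bot_ext <- march_end(mesh, P[n, ], normalize3(P[n, ] - P[n - 1, ]),
                       resample_step, delta)
  if (!is.null(top_ext)) P <- rbind(top_ext[rev(seq_len(nrow(top_ext))), ,
                                            drop = FALSE], P)
  if (!is.null(bot_ext)) P <- rbind(P, bot_ext)

  # drop any consecutive duplicates
  keep <- c(TRUE, rowSums(diff(P)^2) > 1e-16)
  P <- P[keep, , drop = FALSE]
  new_centerline(P)
}

# Predictor-corrector tube march from an end point along a tangent: each
# step predicts pt + h * tangent, cuts the mesh orthogonally there, and
# corrects onto the area centroid of the nearest contour. Stops when the
# section vanishes or collapses (end cap) and finishes with a straight
# extension to just inside the cap.
march_end <- function(mesh, start, tangent, h, delta, max_steps = 500L) {
  cur <- start
  tan <- tangent
  out <- vector("list", 0L)
  prev_area <- NA_real_
  for (i in seq_len(max_steps)) {
    texit <- ray_mesh_distance(mesh, cur, tan)
    if (!is.na(texit) && texit <= h + delta) break
    nxt <- cur + h * tan
    cs <- mesh_plane_section(mesh, nxt, tan)
    if (length(cs) == 0) break
    d2 <- vapply(cs, function(ct) sum((ct$centroid - nxt)^2), numeric(1))
    ct <- cs[[which.min(d2)]]
    # a clean orthogonal cut re-centers by far less than a step; a large
    # correction means the plane is striking the end cap
    if (sqrt(min(d2)) > 0.3 * h) break
    if (!is.na(prev_area) && ct$area < 0.4 * prev_area) break  # cap hit
    newpt <- ct$centroid
    tan <- normalize3(0.5 * tan + 0.5 * normalize3(newpt - cur))
    prev_area <- ct$area
    out[[length(out) + 1]] <- newpt
    cur <- newpt
  }
  # finish with a straight extension to just inside the end cap; the march
  # stops within about one step of the cap, so a long ray exit means the
  # ray is running obliquely along the cap and is clamped
  texit <- ray_mesh_distance(mesh, cur, tan)
  if (!is.na(texit) && texit > delta + 1e-6)
    out[[length(out) + 1]] <- cur + (min(texit, 1.5 * h) - delta) * tan
  if (length(out) == 0) NULL else do.call(rbind, out)
}

# Construct a centerline object from ordered points.
new_centerline <- function(P) {
  n <- nrow(P)
  seg <- diff(P)
  lens <- sqrt(rowSums(seg^2))
  tangents <- seg / lens
  tangents <- rbind(tangents, tangents[n - 1, ])
  structure(list(points = P, arc_length = c(0, cumsum(lens)),
                 tangents = tangents),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, arc length %.2f mm\n",
              nrow(x$points), max(x$arc_length)))
  invisible(x)
}

# Interpolated point + unit tangent at arc-length position s.
centerline_at <- function(centerline, s) {
  sl <- centerline$arc_length
  s <- min(max(s, sl[1]), sl[length(sl)])
  i <- findInterval(s, sl, rightmost.closed = TRUE)
  i <- min(i, length(sl) - 1L)
  f <- (s - sl[i]) / (sl[i + 1] - sl[i])
  pt <- centerline$points[i, ] * (1 - f) + centerline$points[i + 1, ] * f
  list(point = pt, tangent = centerline$tangents[i, ])
}

# Build a cross_section object from a plane cut of the mesh; picks the
# contour whose centroid is nearest `near_point` (piriform-sinus exclusion
# rule: side cavities cut by the same plane are discarded).
make_section <- function(mesh, point, normal, near_point = point,
                         index = NA_integer_) {
  normal <- normalize3(normal)
  cs <- mesh_plane_section(mesh, point, normal)
  basis <- plane_basis(normal)
  if (length(cs) == 0) {
    return(structure(list(centerline_index = index, plane_point = point,
                          plane_normal = normal, boundary = NULL,
                          area = NA_real_, ap_dist = NA_real_,
                          width = NA_real_, empty = TRUE),
                     class = "cross_section"))
  }
  d2 <- vapply(cs, function(ct) sum((ct$centroid - near_point)^2), numeric(1))
  ct <- cs[[which.min(d2)]]
  ext <- if (basis$ap_defined)
    section_extents_points(ct$points, basis$e1, basis$e2)
  else list(ap_dist = NA_real_, width = NA_real_)
  structure(list(centerline_index = index, plane_point = point,
                 plane_normal = normal, boundary = ct$points,
                 centroid = ct$centroid, area = ct$area,
                 ap_dist = ext$ap_dist, width = ext$width,
                 ap_axis = basis$e1, lr_axis = basis$e2, empty = FALSE),
            class = "cross_section")
}

section_extents_points <- function(points, ap_axis, lr_axis) {
  pu <- points %*% ap_axis
  pv <- points %*% lr_axis
  list(ap_dist = max(pu) - min(pu), width = max(pv) - min(pv))
}

#' Cross-sections orthogonal to the centerline
#'
#' One section per centerline point, cut in the plane orthogonal to the
#' local tangent (the last point reuses the preceding segment's tangent).
#' When a plane cuts the mesh in several closed contours the contour whose
#' centroid is nearest the centerline point is kept. Planes that miss the
#' mesh give sections flagged `empty`.
#'
#' @param mesh a watertight `airway_mesh`.
#' @param centerline a `centerline`.
#' @return list of `cross_section` objects (fields: `plane_point`,
#'   `plane_normal`, `boundary`, `area` mm^2, `ap_dist` mm, `width` mm,
#'   `empty`).
#' @export
slice_orthogonal <- function(mesh, centerline) {
  n <- nrow(centerline$points)
  lapply(seq_len(n), function(i)
    make_section(mesh, centerline$points[i, ], centerline$tangents[i, ],
                 near_point = centerline$points[i, ], index = i))
}

#' In-plane anterior-posterior and lateral extents of a section
#'
#' @param section a `cross_section` with non-empty boundary.
#' @param ap_axis,lr_axis in-plane orthonormal unit vectors (default: the
#'   section's own projected patient A and R axes).
#' @return list with `ap_dist` and `width`, mm.
#' @export
section_extents <- function(section, ap_axis = section$ap_axis,
                            lr_axis = section$lr_axis) {
  if (isTRUE(section$empty) || is.null(section$boundary))
    stop("section has an empty boundary")
  if (abs(sum(ap_axis * lr_axis)) > 1e-6 ||
      abs(sum(ap_axis^2) - 1) > 1e-6 || abs(sum(lr_axis^2) - 1) > 1e-6)
    stop("orientation vectors must be orthonormal")
  section_extents_points(section$boundary, ap_axis, lr_axis)
}
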