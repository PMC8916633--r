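# Shared phantom fixtures, built once per test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# straight cylinder, r = 5 mm, L = 40 mm, 0.5 mm voxels, noiseless
cyl_spec <- function(voxel = 0.5, noise = 0, blur = 0) {
  phantom_spec(curve = list(type = "line", length = 40),
               a = c(5, 5), b = c(5, 5), noise_sd = noise,
               blur_sigma = blur, voxel_size = voxel,
               boundary_s = c(5, 15, 25, 32), seed = 11)
}

cyl_phantom <- function() fixture("cyl", function() generate_phantom(cyl_spec()))

cyl_segmented <- function() fixture("cyl_seg", function() {
  ph <- cyl_phantom()
  thr <- compute_airway_threshold(ph$volume)
  mask <- segment_airway(ph$volume, thr$upper_threshold, ph$seed_voxel,
                         ph$roi_superior, ph$roi_inferior)
  list(phantom = ph, threshold = thr, mask = mask)
})

cyl_mesh <- function() fixture("cyl_mesh", function() {
  extract_surface(cyl_segmented()$mask)
})

cyl_pipeline <- function() fixture("cyl_pipe", function() {
  ph <- cyl_phantom()
  run_pipeline(ph$volume, ph$landmarks, ph$seed_voxel,
               ph$roi_superior, ph$roi_inferior)
})

# 30-degree tilted cylinder (same radius/length)
tilt_spec <- function(voxel = 0.5) {
  phantom_spec(curve = list(type = "line",
                            direction = c(0, sin(pi / 6), -cos(pi / 6)),
                            length = 40),
               a = c(5, 5), b = c(5, 5), noise_sd = 0, blur_sigma = 0,
               voxel_size = voxel, boundary_s = c(5, 15, 25, 32), seed = 12)
}

tilt_mesh <- function() fixture("tilt_mesh", function() {
  ph <- generate_phantom(tilt_spec())
  thr <- compute_airway_threshold(ph$volume)
  mask <- segment_airway(ph$volume, thr$upper_threshold, ph$seed_voxel,
                         ph$roi_superior, ph$roi_inferior)
  mesh <- fair_mesh(extract_surface(mask))
  list(phantom = ph, mesh = refine_surface(mesh, ph$volume,
                                           thr$upper_threshold))
})

# default arc phantom (the study-condition tube) through the full pipeline
arc_pipeline <- function() fixture("arc_pipe", function() {
  ph <- generate_phantom(phantom_spec())
  c(list(phantom = ph),
    run_pipeline(ph$volume, ph$landmarks, ph$seed_voxel,
                 ph$roi_superior, ph$roi_inferior))
})

# independent flood fill oracle (6/26 connectivity), plain R
flood_fill_oracle <- function(mask, seed, connectivity = 26) {
  d <- dim(mask)
  vis <- array(FALSE, d)
  stopifnot(mask[seed[1], seed[2], seed[3]])
  queue <- list(seed)
  vis[seed[1], seed[2], seed[3]] <- TRUE
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (r in seq_len(nrow(offs))) {
      nb <- cur + offs[r, ]
      if (any(nb < 1) || any(nb > d)) next
      if (!vis[nb[1], nb[2], nb[3]] && mask[nb[1], nb[2], nb[3]]) {
        vis[nb[1], nb[2], nb[3]] <- TRUE
        queue[[length(queue) + 1]] <- nb
      }
    }
  }
  vis
}

# brute-force 2D convolution with reflective padding (filter oracle)
conv2_reflect_oracle <- function(mat, kernel) {
  k <- nrow(kernel); r <- (k - 1) %/% 2
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(0, nr, nc)
  refl <- function(i, n) {
    i[i < 1] <- 2 - i[i < 1]
    i[i > n] <- 2 * n - i[i > n]
    i
  }
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r)
      acc <- acc + kernel[di + r + 1, dj + r + 1] *
        mat[refl(i + di, nr), refl(j + dj, nc)]
    out[i, j] <- acc
  }
  out
}

# point-in-mesh test by ray-crossing parity along +x
point_in_mesh_oracle <- function(mesh, p) {
  V <- mesh$vertices; F <- mesh$faces
  dir <- c(1, 0, 0)
  v0 <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - v0
  e2 <- V[F[, 3], , drop = FALSE] - v0
  h <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
             dir[3] * e2[, 1] - dir[1] * e2[, 3],
             dir[1] * e2[, 2] - dir[2] * e2[, 1])
  a <- rowSums(e1 * h)
  s <- -sweep(v0, 2, p, "-")
  u <- rowSums(s * h) / a
  q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
             s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
             s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
  v <- (q %*% dir) / a
  t <- rowSums(e2 * q) / a
  hit <- abs(a) > 1e-12 & u >= 0 & v >= 0 & (u + v) <= 1 & t > 0
  sum(hit, na.rm = TRUE) %% 2 == 1
}
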