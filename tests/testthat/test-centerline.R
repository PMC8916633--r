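test_that("cylinder centerline recovers the true axis and length", {
  res <- cyl_pipeline()
  cl <- res$centerline
  # true axis: x = y = 0, z in [-40, 0]
  axdev <- sqrt(rowSums(cl$points[, 1:2]^2))
  expect_lt(max(axdev), 0.5)
  expect_lt(abs(max(cl$arc_length) - 40) / 40, 0.02)
})

test_that("quarter-circle arc length is recovered within 3 percent", {
  cl <- fixture("quarter_arc_cl", function() {
    ph <- generate_phantom(phantom_spec(curve = list(type = "arc",
                                                     radius = 30,
                                                     angle = pi / 2)))
    thr <- compute_airway_threshold(ph$volume)
    mask <- segment_airway(ph$volume, thr$upper_threshold, ph$seed_voxel,
                           ph$roi_superior, ph$roi_inferior)
    mesh <- refine_surface(fair_mesh(extract_surface(mask)), ph$volume,
                           thr$upper_threshold)
    extract_centerline(mesh)
  })
  expect_lt(abs(max(cl$arc_length) - pi * 15) / (pi * 15), 0.03)
})

test_that("a tilted cylinder's centerline stays within one voxel of truth", {
  tm <- tilt_mesh()
  cl <- fixture("tilt_cl", function() extract_centerline(tm$mesh))
  sp <- tilt_spec()
  ss <- seq(0, 40, by = 0.02)
  tru <- sp$cv$point(ss)
  dev <- apply(cl$points, 1, function(p) min(sqrt(colSums((t(tru) - p)^2))))
  expect_lt(max(dev), 0.5)
})

test_that("orthogonal sections of a cylinder have disc area, axial do not", {
  tm <- tilt_mesh()
  cl <- fixture("tilt_cl", function() extract_centerline(tm$mesh))
  secs <- slice_orthogonal(tm$mesh, cl)
  n <- length(secs)
  interior <- secs[seq(ceiling(n / 4), floor(3 * n / 4))]
  areas <- vapply(interior, `[[`, numeric(1), "area")
  expect_true(all(abs(areas - pi * 25) / (pi * 25) < 0.03))
  # axial cut of the same tube is broader by 1/cos(30 deg)
  mid <- interior[[round(length(interior) / 2)]]
  ax <- airwaymorph:::mesh_plane_section(
    tm$mesh, mid$plane_point, c(0, 0, 1))
  ax_area <- max(vapply(ax, `[[`, numeric(1), "area"))
  expect_gt(ax_area / mid$area, 1.10)
  expect_lt(abs(ax_area - pi * 25 / cos(pi / 6)) / (pi * 25 / cos(pi / 6)),
            0.03)
})

test_that("sections are orthogonal, ordered and mostly inside the mesh", {
  res <- cyl_pipeline()
  cl <- res$centerline
  secs <- res$sections
  dots <- vapply(seq_along(secs), function(i)
    abs(sum(secs[[i]]$plane_normal * cl$tangents[i, ])), numeric(1))
  expect_true(all(abs(dots - 1) < 1e-9))
  expect_true(all(diff(cl$arc_length) > 0))
  steps <- diff(cl$arc_length)
  inner_steps <- steps[2:(length(steps) - 1)]
  expect_true(all(abs(inner_steps - 1) <= 0.1 + 1e-9))
  inside <- vapply(seq_len(nrow(cl$points)), function(i)
    point_in_mesh_oracle(res$mesh, cl$points[i, ]), logical(1))
  expect_gte(sum(inside), nrow(cl$points) - 2)
})

test_that("section accuracy improves with finer voxels", {
  area_err <- function(voxel) {
    ph <- generate_phantom(cyl_spec(voxel = voxel))
    res <- run_pipeline(ph$volume, ph$landmarks, ph$seed_voxel,
                        ph$roi_superior, ph$roi_inferior)
    secs <- res$sections
    n <- length(secs)
    areas <- vapply(secs[seq(ceiling(n / 4), floor(3 * n / 4))], `[[`,
                    numeric(1), "area")
    mean(abs(areas - pi * 25) / (pi * 25))
  }
  coarse <- fixture("area_err_coarse", function() area_err(1.0))
  fine <- mean(abs(vapply(
    cyl_pipeline()$sections[15:25], `[[`, numeric(1), "area") - pi * 25) /
      (pi * 25))
  expect_lt(fine, coarse)
})

test_that("a plane tangent to the end cap yields an empty flagged section", {
  m <- cyl_mesh()
  zmin <- min(m$vertices[, 3])
  sec <- airwaymorph:::make_section(m, c(0, 0, zmin - 1), c(0, 0, 1))
  expect_true(sec$empty)
  expect_true(is.na(sec$area))
  expect_error(section_extents(sec), "empty")
})

test_that("section extents project onto the in-plane axes correctly", {
  # planar ellipse boundary, AP semi-axis 5, LR semi-axis 10, z-normal plane
  th <- seq(0, 2 * pi, length.out = 481)[-481]
  ell <- cbind(10 * cos(th), 5 * sin(th), 0)
  sec <- structure(list(boundary = ell, ap_axis = c(0, 1, 0),
                        lr_axis = c(1, 0, 0), empty = FALSE),
                   class = "cross_section")
  ext <- section_extents(sec)
  expect_equal(ext$ap_dist, 10, tolerance = 1e-3)
  expect_equal(ext$width, 20, tolerance = 1e-3)

  circ <- sec; circ$boundary <- cbind(7 * cos(th), 7 * sin(th), 0)
  ext2 <- section_extents(circ)
  expect_equal(ext2$ap_dist, ext2$width, tolerance = 1e-6)

  # rotating the ellipse 90 degrees in-plane swaps the extents;
  # brute-force projection over the polygon vertices as the oracle
  rot <- sec; rot$boundary <- cbind(-ell[, 2], ell[, 1], 0)
  ext3 <- section_extents(rot)
  expect_equal(ext3$ap_dist, max(rot$boundary[, 2]) - min(rot$boundary[, 2]))
  expect_equal(ext3$width, max(rot$boundary[, 1]) - min(rot$boundary[, 1]))
  expect_equal(ext3$ap_dist, ext$width)
  expect_equal(ext3$width, ext$ap_dist)

  expect_error(section_extents(sec, ap_axis = c(0, 1, 0),
                               lr_axis = c(0, 1, 0)), "orthonormal")
})

test_that("multi-contour planes keep the contour nearest the centerline", {
  # two parallel tubes; plane cuts both; selection must pick the near one
  vox <- array(100, c(30, 11, 16))
  vox[4:10, 4:8, ] <- -1000
  vox[20:26, 4:8, ] <- -1000
  vol <- ct_volume(vox, rep(1, 3))
  mask <- structure(list(voxels = vol$voxels <= -450, spacing = rep(1, 3),
                         origin = c(0, 0, 0), scan_id = "t"),
                    class = "airway_mask")
  mesh <- extract_surface(mask)
  near <- c(6, 5, 8)
  sec <- airwaymorph:::make_section(mesh, near, c(0, 0, 1))
  expect_true(all(sec$boundary[, 1] < 15))
})
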