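# landmark plumbing on a simple synthetic set
toy_landmarks <- function() {
  ph <- cyl_phantom()
  ph$landmarks
}

test_that("landmark resolution validates and derives the schema", {
  reg <- landmark_registry()
  expect_identical(nrow(reg), 26L)
  lm <- resolve_landmarks(toy_landmarks())
  expect_identical(nrow(lm), 26L)
  expect_identical(sum(stats::complete.cases(unclass(lm))), 26L)

  # derived midpoints overwrite anything supplied
  raw <- toy_landmarks()
  raw$MidVe <- c(99, 99, 99)
  lm2 <- resolve_landmarks(raw)
  expect_equal(unclass(lm2)["MidVe", ],
               (raw$VeAn + raw$VePo) / 2, ignore_attr = TRUE)
  expect_equal(unclass(lm2)["NpxMid", ], (raw$NpxAn + raw$NpxPo) / 2,
               ignore_attr = TRUE)
  expect_equal(unclass(lm2)["MMax", ], (raw$PIC + raw$PALS) / 2,
               ignore_attr = TRUE)

  miss <- toy_landmarks(); miss$PNS <- NULL
  expect_error(resolve_landmarks(miss), "missing required landmark: PNS")
  bad <- toy_landmarks(); bad$Nonsense <- c(0, 0, 0)
  expect_error(resolve_landmarks(bad), "unknown landmark")
  flip <- toy_landmarks()
  flip$ANS <- flip$PNS + c(0, -5, 0)
  expect_error(resolve_landmarks(flip), "anterior")
})

test_that("optional piriform landmarks may be absent unilaterally", {
  raw <- toy_landmarks()
  raw$PSInR <- NULL
  lm <- resolve_landmarks(raw)
  expect_true(all(is.na(unclass(lm)["PSInR", ])))
  ps <- piriform_lengths(lm)
  expect_true(is.na(ps$right))
  expect_equal(ps$average, ps$left)
})

test_that("landmark-derived boundaries land at their planted positions", {
  res <- cyl_pipeline()
  pa <- partition_regions(res$centerline, res$landmarks)
  planted <- c(5, 15, 25, 32)
  expect_true(all(abs(pa$boundaries[1:4] - planted) < 1))
  expect_true(!is.unsorted(pa$boundaries))
  # VeEnd placed exactly on a centerline point pins s_b to that point
  cl <- res$centerline
  lm <- unclass(res$landmarks)
  lm["VeEnd", ] <- cl$points[12, ]
  pa2 <- partition_regions(cl, structure(lm, class = c("landmark_set",
                                                       "matrix")))
  expect_equal(unname(pa2$boundaries["s_b"]), cl$arc_length[12],
               tolerance = 1e-9)
})

test_that("misordered landmarks are reported as out of order", {
  res <- cyl_pipeline()
  lm <- unclass(res$landmarks)
  # put the aryepiglottic midpoint below the glottis midpoint
  shift <- lm["ga", 3] - 10 - lm["PSSuL", 3]
  lm["PSSuL", 3] <- lm["PSSuL", 3] + shift
  lm["PSSuR", 3] <- lm["PSSuR", 3] + shift
  expect_error(partition_regions(res$centerline,
                                 structure(lm, class = c("landmark_set",
                                                         "matrix"))),
               "out of order")
})

test_that("region measurements match the analytic cylinder", {
  res <- cyl_pipeline()
  ph <- cyl_phantom()
  rec <- res$record
  v <- unlist(rec$values)
  # lengths of the planted regions: 10, 10, 7, ~8
  expect_lt(abs(v["NasopharynxL"] - 10) / 10, 0.02)
  expect_lt(abs(v["OropharynxL"] - 10) / 10, 0.02)
  expect_lt(abs(v["LaryngopharynxL"] - 7) / 7, 0.03)
  # volumes within 3% of pi r^2 L
  expect_lt(abs(v["Nasopharynx"] - pi * 250) / (pi * 250), 0.03)
  expect_lt(abs(v["Oropharynx"] - pi * 250) / (pi * 250), 0.03)
  # boundary CSAs within 3% of the disc
  for (nm in c("NasopharynxArea", "OropharynxArea", "LaryngopharynxArea",
               "GlottisArea"))
    expect_lt(abs(v[nm] - pi * 25) / (pi * 25), 0.03)
})

test_that("pharynx totals are exact sums of their subregions", {
  v <- unlist(cyl_pipeline()$record$values)
  expect_identical(unname(v["PharynxVolume"]),
                   unname(v["Nasopharynx"] + v["Oropharynx"] +
                            v["Laryngopharynx"]))
  expect_identical(unname(v["PharynxLength"]),
                   unname(v["NasopharynxL"] + v["OropharynxL"] +
                            v["LaryngopharynxL"]))
})

test_that("a zero-length region has zero volume and length", {
  res <- cyl_pipeline()
  pa <- partition_regions(res$centerline, res$landmarks)
  pa$boundaries["s_c"] <- pa$boundaries["s_b"]
  out <- measure_partition(res$mesh, res$centerline, res$sections, pa)
  expect_identical(out$OropharynxL, 0)
  expect_identical(out$Oropharynx, 0)
})

test_that("volume by section integration agrees with the mesh volume", {
  res <- cyl_pipeline()
  pa <- res$record$partition
  v <- unlist(res$record$values)
  total_sections <- v["Nasopharynx"] + v["Oropharynx"] +
    v["Laryngopharynx"] + v["Subglottal"]
  # mesh volume between s_a and the end, via the full mesh minus the part
  # above the palatal crossing: approximate with analytic truth instead
  analytic <- pi * 25 * (max(res$centerline$arc_length) -
                           pa$boundaries["s_a"])
  expect_lt(abs(total_sections - analytic) / analytic, 0.02)
})

test_that("vocal tract length assembles oral polyline plus pharyngeal arc", {
  res <- cyl_pipeline()
  ph <- cyl_phantom()
  pa <- res$record$partition
  v <- unlist(res$record$values)
  expect_lt(abs(v["VTLength_i"] - ph$truth$VTLength_i), 1)

  # degenerate glottis at the palatal crossing: oral polyline only
  pa2 <- pa
  pa2$boundaries["s_d"] <- pa$boundaries["s_a"]
  lm <- res$landmarks
  oral_only <- vtl_incisor(res$centerline, pa2, lm)
  m <- unclass(lm)
  entry <- airwaymorph:::centerline_at(res$centerline,
                                       pa$boundaries["s_a"])$point
  expect_equal(oral_only,
               sqrt(sum((m["ABI", ] - m["MMax", ])^2)) +
                 sqrt(sum((m["MMax", ] - m["PNS", ])^2)) +
                 sqrt(sum((m["PNS", ] - entry)^2)),
               tolerance = 1e-9)
})

test_that("collinear oral landmarks give the straight-line distance", {
  # straight centerline down z through origin, collinear ABI/MMax/PNS on it
  P <- cbind(0, 0, seq(0, -50, by = -1))
  cl <- airwaymorph:::new_centerline(P)
  lm <- toy_landmarks()
  lm$ABI <- c(0, 0, 10); lm$PIC <- c(0, 0, 8); lm$PALS <- c(0, 0, 4)
  lm$PNS <- c(0, 0, 2); lm$ANS <- c(0, 1e-6, 12)  # ANS barely anterior
  lms <- resolve_landmarks(lm)
  part <- list(boundaries = c(s_a = 0, s_b = 10, s_c = 20, s_d = 30,
                              s_e = 50))
  expect_equal(vtl_incisor(cl, part, lms), 40, tolerance = 1e-6)
})

test_that("velum length follows the quadratic curve shaped by its landmarks", {
  mk <- function(pns, veba, veend) {
    lm <- toy_landmarks()
    lm$PNS <- pns; lm$VeBa <- veba; lm$VeEnd <- veend
    lm$ANS <- pns + c(0, 10, 0)
    resolve_landmarks(lm)
  }
  expect_equal(velum_length(mk(c(0, 0, 0), c(0, 10, 0), c(0, 20, 0))), 20,
               tolerance = 1e-6)
  # right angle: between the chord and the polyline
  va <- velum_length(mk(c(0, 0, 0), c(0, 10, 0), c(10, 10, 0)))
  expect_gt(va, sqrt(200))
  expect_lt(va, 20)
  # quadrature oracle: dense polyline of the same quadratic curve
  p0 <- c(0, 0, 0); p1 <- c(0, 10, 0); p2 <- c(10, 10, 0)
  uu <- seq(0, 1, length.out = 200001)
  pts <- outer((1 - uu)^2, p0) + outer(2 * uu * (1 - uu), p1) +
    outer(uu^2, p2)
  expect_equal(va, sum(sqrt(rowSums(diff(pts)^2))), tolerance = 1e-5)
  # midpoint collinear degenerates to the straight distance
  expect_equal(velum_length(mk(c(0, 0, 0), c(5, 5, 0), c(10, 10, 0))),
               sqrt(200), tolerance = 1e-6)
})

test_that("piriform lengths and their average follow the one-sided rule", {
  lm <- toy_landmarks()
  lm$PSSuL <- c(0, 0, 10); lm$PSInL <- c(0, 0, 0)
  lm$PSSuR <- c(5, 0, 10); lm$PSInR <- c(5, 0, 0)
  ps <- piriform_lengths(resolve_landmarks(lm))
  expect_equal(ps$left, 10); expect_equal(ps$right, 10)
  expect_equal(ps$average, 10)

  lm$PSInL <- c(0, 0, 4); lm$PSInR <- c(5, 0, 0)
  ps2 <- piriform_lengths(resolve_landmarks(lm))
  expect_equal(ps2$average, 8)  # mean of 6 and 10

  lm$PSInR <- NULL
  lm$PSInL <- c(0, 0, 2)
  ps3 <- piriform_lengths(resolve_landmarks(lm))
  expect_equal(ps3$average, 8)  # the single available side

  lm$PSInL <- NULL
  expect_error(piriform_lengths(resolve_landmarks(lm)), "incomplete")
})

test_that("average relative error is symmetric with the mean denominator", {
  a <- c(Nasopharynx = 100, OropharynxL = 10)
  expect_identical(average_relative_error(a, a), 0)
  one <- average_relative_error(c(x = 100), c(x = 110))
  expect_equal(one, 10 / 105, tolerance = 1e-12)
  b <- c(Nasopharynx = 104, OropharynxL = 9.5)
  expect_identical(average_relative_error(a, b),
                   average_relative_error(b, a))
  expect_error(average_relative_error(c(x = 1), c(y = 1)), "share no")
})

test_that("the assembled record has exactly 30 variables with units", {
  rec <- cyl_pipeline()$record
  expect_identical(length(rec$values), 30L)
  expect_identical(names(rec$values), measurement_variables())
  expect_true(all(unlist(rec$values) > 0))
  df <- as.data.frame(rec)
  expect_identical(nrow(df), 30L)
  expect_setequal(unique(df$units), c("mm3", "mm", "mm2"))
})

test_that("an absent piriform side yields 29 numbers and a present average", {
  res <- cyl_pipeline()
  ph <- cyl_phantom()
  raw <- ph$landmarks
  raw$PSInR <- NULL
  rec <- measure_all(mesh = res$mesh, centerline = res$centerline,
                     sections = res$sections,
                     landmarks = resolve_landmarks(raw))
  v <- unlist(rec$values)
  expect_identical(sum(is.na(v)), 1L)
  expect_true(is.na(v["PSLengthRight"]))
  expect_false(is.na(v["AveragePSLength"]))
})

test_that("inconsistent scan provenance is refused", {
  res <- cyl_pipeline()
  seg <- cyl_segmented()
  vol2 <- seg$phantom$volume
  vol2$scan_id <- "other_scan"
  expect_error(
    measure_all(vol2, seg$mask, res$mesh, res$centerline, res$sections,
                res$landmarks),
    "inconsistent provenance")
})
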