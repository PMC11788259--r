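geom1 <- acquisition_geometry(h1 = 40, h2 = 60, d = 1, pixel_pitch = 1e-3)

test_that("geometry constructor enforces its invariants", {
  expect_error(acquisition_geometry(40, 40, 1, 1e-3), "must differ")
  expect_error(acquisition_geometry(-40, 60, 1, 1e-3), "positive")
  expect_error(acquisition_geometry(40, 60, 0, 1e-3), "positive")
  expect_error(acquisition_geometry(100, 60, 1, 1e-3), "below the SSD")
})

test_that("forward projection follows N = D d / (h + z)", {
  expect_equal(project_point(c(5, 0, 0), 40, geom1), c(0.125, 0))
  expect_equal(project_point(c(0, 0, 7), 40, geom1), c(0, 0))
  g2 <- acquisition_geometry(h1 = 50, h2 = 60, d = 2, pixel_pitch = 1e-3)
  expect_equal(project_point(c(3, -4, 10), 50, g2), c(0.1, -0.4 / 3),
               tolerance = 1e-12)
  expect_error(project_point(c(1, 1, -45), 40, geom1), "degenerate")
})

test_that("reconstruction inverts the forward projection", {
  # frozen hand-verified case: (5, 0, 0) seen at h1 = 40 and h2 = 60
  pair <- c(0.125, 0, 5 / 60, 0)
  p <- reconstruct_point(pair, geom1)
  expect_equal(as.numeric(p), c(5, 0, 0), tolerance = 1e-12)

  set.seed(42)
  for (i in 1:500) {
    pt <- c(stats::runif(1, -12, 12), stats::runif(1, -12, 12),
            stats::runif(1, -8, 8))
    if (abs(pt[1]) < 1e-3 && abs(pt[2]) < 1e-3) next
    pair <- c(project_point(pt, geom1$h1, geom1),
              project_point(pt, geom1$h2, geom1))
    rec <- reconstruct_point(pair, geom1)
    expect_equal(as.numeric(rec), pt, tolerance = 1e-9)
  }
})

test_that("single-axis degeneracy falls back to the informative axis", {
  # point on the y axis: x disparity is zero, z must come from y
  pt <- c(0, 4, 2)
  pair <- c(project_point(pt, 40, geom1), project_point(pt, 60, geom1))
  rec <- reconstruct_point(pair, geom1)
  expect_equal(as.numeric(rec), pt, tolerance = 1e-9)
  expect_false(attr(rec, "degenerate"))

  # on-axis point: both disparities vanish, flagged for interpolation
  rec0 <- reconstruct_point(c(0, 0, 0, 0), geom1)
  expect_true(attr(rec0, "degenerate"))
})

test_that("height-ratio relation N1/N2 = (h2+z)/(h1+z) holds on synthetic pairs", {
  set.seed(7)
  for (i in 1:50) {
    pt <- c(stats::runif(1, 0.5, 10), stats::runif(1, 0.5, 10),
            stats::runif(1, -5, 5))
    n1 <- project_point(pt, geom1$h1, geom1)
    n2 <- project_point(pt, geom1$h2, geom1)
    expect_equal(n1[1] / n2[1], (geom1$h2 + pt[3]) / (geom1$h1 + pt[3]),
                 tolerance = 1e-12)
  }
})

test_that("nearer camera sees the larger projection", {
  set.seed(11)
  for (i in 1:20) {
    pt <- c(stats::runif(1, 0.5, 10), 0, stats::runif(1, -30, 20))
    x1 <- project_point(pt, geom1$h1, geom1)[1]
    x2 <- project_point(pt, geom1$h2, geom1)[1]
    expect_gt(abs(x1), abs(x2))  # h1 < h2: camera 1 is nearer the skin
  }
})

test_that("cutout projection applies per-point magnification b/(SSD+z)", {
  expect_equal(project_to_cutout(c(10, 0, 0), geom1), c(9.5, 0))
  expect_equal(project_to_cutout(c(10, 10, 5), geom1),
               c(10 * 95 / 105, 10 * 95 / 105), tolerance = 1e-12)
  expect_equal(project_to_cutout(c(0, 0, 3), geom1), c(0, 0))
  expect_error(project_to_cutout(c(1, 1, -101), geom1), "degenerate")

  # magnification strictly decreases with depth
  mags <- sapply(seq(-5, 5, by = 1),
                 function(z) project_to_cutout(c(10, 0, z), geom1)[1])
  expect_true(all(diff(mags) < 0))
})

test_that("contour reconstruction maps a flat circle to a 0.95-scaled circle", {
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  pairs <- t(sapply(th, function(a) {
    pt <- c(5 * cos(a), 5 * sin(a), 0)
    c(project_point(pt, geom1$h1, geom1), project_point(pt, geom1$h2, geom1))
  }))
  cut <- reconstruct_contour(pairs, geom1)
  r <- sqrt(cut[, 1]^2 + cut[, 2]^2)
  expect_equal(r, rep(4.75, 72), tolerance = 1e-9)
  # angular order of the input pairs is preserved in the output polygon
  ang <- atan2(cut[, 2], cut[, 1]) %% (2 * pi)
  expect_equal(ang, th, tolerance = 1e-9)
  expect_error(reconstruct_contour(pairs[1:2, ], geom1), "at least 3")
})

test_that("varying-depth contours get per-point magnification (tilted plane)", {
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  pts <- cbind(4 * cos(th), 4 * sin(th))
  pts <- cbind(pts, 0.3 * pts[, 1] - 0.2 * pts[, 2])  # z varies linearly
  pairs <- t(apply(pts, 1, function(p)
    c(project_point(p, geom1$h1, geom1), project_point(p, geom1$h2, geom1))))
  cut <- reconstruct_contour(pairs, geom1)
  truth <- t(apply(pts, 1, project_to_cutout, geom = geom1))
  expect_lt(max(abs(unclass(cut)[, 1:2] - truth)), 1e-6)
})

test_that("degenerate on-axis pairs are interpolated from angular neighbors", {
  th <- seq(0, 2 * pi, length.out = 37)[-37]
  pairs <- t(sapply(th, function(a) {
    pt <- c(5 * cos(a), 5 * sin(a), 0)
    c(project_point(pt, geom1$h1, geom1), project_point(pt, geom1$h2, geom1))
  }))
  pairs[10, ] <- 0  # force an on-axis sample
  cut <- reconstruct_contour(pairs, geom1)
  expect_equal(attr(cut, "n_degenerate"), 1L)
  expected <- (unclass(cut)[9, 1:2] + unclass(cut)[11, 1:2]) / 2
  expect_equal(unname(unclass(cut)[10, 1:2]), unname(expected),
               tolerance = 1e-9)

  pairs[, ] <- 0
  expect_error(reconstruct_contour(pairs, geom1), "reconstruction failure")
})

test_that("averaged scaling reproduces its closed-form examples and calibration", {
  expect_equal(averaged_scaling(c(1, 0, 1, 0), 40, 60, 100), c(1, 0))
  expect_equal(averaged_scaling(c(0, 0, 0, 0), 40, 60, 100), c(0, 0))
  expect_error(averaged_scaling(c(1, 0, 1, 0), 40, 60, -1), "positive")

  # with d_sc = d (h1+h2)^2 / (2 h1 h2) * (SSD/b) the mean-scaling output
  # equals the exact cutout coordinate for flat (z = 0) contours
  d_sc <- averaged_scaling_constant(geom1)
  expect_equal(d_sc, 1 * 100^2 / (2 * 40 * 60) * (100 / 95), tolerance = 1e-12)
  pt <- c(5, -2, 0)
  pair <- c(project_point(pt, 40, geom1), project_point(pt, 60, geom1))
  expect_equal(averaged_scaling(pair, 40, 60, d_sc),
               project_to_cutout(pt, geom1), tolerance = 1e-12)
})

test_that("radial distortion hook round-trips and defaults to off", {
  gk <- acquisition_geometry(40, 60, 1, 1e-3, k1 = 0.05)
  pt <- c(4, -3, 1)
  pair <- c(project_point(pt, 40, gk), project_point(pt, 60, gk))
  distorted <- oact:::distort_pair(pair, gk)
  expect_false(isTRUE(all.equal(distorted, pair)))
  rec <- reconstruct_point(distorted, gk)
  expect_equal(as.numeric(rec), pt, tolerance = 1e-8)
  # k1 = 0 leaves coordinates untouched
  expect_identical(oact:::undistort_pair(pair, geom1), pair)
})
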