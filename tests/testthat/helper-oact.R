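# fixtures built in code: rasters with known analytic curves, random
# star-convex polygons, and printed-table inputs reused across tests

# dark ring of given radial profile rho(theta_deg) (px) on a light raster;
# ring half-width w/2 px, measured along the ray from the center
draw_ring <- function(H, W, cx, cy, rho, width = 3, fg = 0, bg = 1) {
  xs <- matrix(rep(seq_len(W), each = H), H, W) - cx
  ys <- cy - matrix(rep(seq_len(H), W), H, W)   # y up
  r <- sqrt(xs^2 + ys^2)
  th <- (atan2(ys, xs) * 180 / pi) %% 360
  target <- if (is.function(rho)) rho(th) else rho
  img <- matrix(bg, H, W)
  img[abs(r - target) <= width / 2] <- fg
  img
}

ellipse_rho <- function(a, b) function(th_deg) {
  th <- th_deg * pi / 180
  a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
}

# random star-convex polygon about the origin (smooth radial perturbation)
random_star_polygon <- function(n = 50, r0 = 2) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- r0 * (1 + 0.2 * cos(2 * th + stats::runif(1, 0, 2 * pi)) +
               0.1 * cos(5 * th + stats::runif(1, 0, 2 * pi)))
  cbind(r * cos(th), r * sin(th))
}

# independent area oracle: fan triangulation from an interior point,
# valid for star-convex polygons
fan_triangulation_area <- function(m, about = c(0, 0)) {
  x <- m[, 1] - about[1]; y <- m[, 2] - about[2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(abs(x * yn - xn * y)) / 2
}

# independent radial resampling oracle: dense boundary sampling + linear
# interpolation of radius over angle about the area centroid
brute_radial_resample <- function(m, angles_deg, n_dense = 20000) {
  cen <- oact::polygon_centroid(m)
  n <- nrow(m)
  pts <- matrix(NA_real_, 0, 2)
  per_edge <- ceiling(n_dense / n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- seq(0, 1, length.out = per_edge + 1)[-(per_edge + 1)]
    pts <- rbind(pts, cbind(m[i, 1] + s * (m[j, 1] - m[i, 1]),
                            m[i, 2] + s * (m[j, 2] - m[i, 2])))
  }
  dx <- pts[, 1] - cen[1]; dy <- pts[, 2] - cen[2]
  th <- (atan2(dy, dx) * 180 / pi) %% 360
  r <- sqrt(dx^2 + dy^2)
  o <- order(th)
  th <- th[o]; r <- r[o]
  stats::approx(c(th - 360, th, th + 360), rep(r, 3), xout = angles_deg)$y
}

# printed monitor-unit and index tables used by the worked-example tests
mu_hand <- c(100.73, 101.61, 100.88)
mu_ct   <- c(100.60, 101.29, 100.90)
mu_oact <- c(101.03,  99.69, 100.46)
ari_hand <- c(1.159, 0.964, 0.930, 1.023, 0.903, 0.924, 1.053)
ari_ct   <- c(0.990, 0.939, 0.954, 0.944, 1.042, 1.052, 0.953)
ari_oact <- c(1.004, 0.997, 1.001, 0.990, 1.012, 0.984, 0.984)
cmi_hand <- c(0.916, 0.908, 0.969, 0.931, 0.941, 0.901, 0.924)
cmi_ct   <- c(0.859, 0.909, 0.937, 0.875, 0.956, 0.937, 0.950)
cmi_oact <- c(0.956, 0.931, 0.996, 0.955, 0.974, 0.957, 0.977)

# run the installed CLI in a child Rscript with the test library visible
run_cli <- function(args) {
  cli <- system.file("cli", "oact.R", package = "oact")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(shQuote(cli), args), stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", shQuote(paste(.libPaths(), collapse = .Platform$path.sep)))))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
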