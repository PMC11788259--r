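#' Default synthetic acquisition geometry
#'
#' Camera heights 40 and 60 cm above the isocenter plane, focal distance
#' 0.368 cm and pixel pitch 2.268e-4 cm/px (a 1/2.3-inch 5 MP sensor, 6.17
#' mm across 2720 pixels, with an ~80-degree field of view), SSD 100 cm and
#' source-to-cutout distance 95 cm.
#'
#' @return An \code{\link{acquisition_geometry}}.
#' @export
default_geometry <- function() {
  acquisition_geometry(h1 = 40, h2 = 60, d = 0.368,
                       pixel_pitch = 0.617 / 2720, ssd = 100, b = 95)
}

#' Rendering specification for synthetic contour photographs
#'
#' @param image_dim \code{c(width, height)} in pixels (default the 5 MP
#'   camera frame, 2720 x 2040).
#' @param line_width_px Stroke width of the drawn contour in pixels (>= 1).
#' @param fg,bg Stroke and background intensities in [0, 1].
#' @param noise_sd Additive Gaussian noise standard deviation (intensity
#'   units).
#' @param seed Random seed controlling the noise; fixed for reproducibility.
#' @return A list of class \code{"oact_renderspec"}.
#' @export
render_spec <- function(image_dim = c(2720, 2040), line_width_px = 3,
                        fg = 0.1, bg = 0.95, noise_sd = 0.02, seed = 1L) {
  if (line_width_px < 1) stop("line width must be >= 1 px", call. = FALSE)
  structure(list(image_dim = image_dim, line_width_px = line_width_px,
                 fg = fg, bg = bg, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "oact_renderspec")
}

#' Generate a ground-truth scene contour
#'
#' Builds a closed, star-convex planar curve (circle, ellipse, or a smooth
#' Fourier blob standing in for irregular clinical shapes) and drapes it on
#' a surface model: flat at a constant depth, a tilted plane, or a spherical
#' cap. The depth coordinate z is the signed offset from the isocenter
#' plane, positive away from the source.
#'
#' @param family \code{"circle"}, \code{"ellipse"}, or \code{"blob"}.
#' @param params List of family parameters: circle \code{r0}; ellipse
#'   \code{a}, \code{b}; blob \code{r0}, optional \code{n_harmonics}
#'   (default 4, max 6) and \code{amp} (total relative amplitude bound,
#'   default 0.15).
#' @param surface \code{"flat"} (depth \code{z0}), \code{"tilted"} (plane
#'   \code{z = z0 + gx x + gy y}), or \code{"cap"} (spherical cap of radius
#'   \code{R}, apex depth \code{z0}).
#' @param z0,gx,gy,R Surface parameters, cm (see \code{surface}).
#' @param center Planar centroid offset \code{c(x, y)}, cm.
#' @param seed Seed for the blob harmonics.
#' @return An object of class \code{"oact_scene"} with a vectorized
#'   evaluator \code{point(t)} returning an n x 3 matrix of curve points for
#'   t in [0, 1).
#' @export
make_shape <- function(family = c("circle", "ellipse", "blob"),
                       params = list(r0 = 3), surface = c("flat", "tilted", "cap"),
                       z0 = 0, gx = 0, gy = 0, R = 10, center = c(0, 0),
                       seed = 1L) {
  family <- match.arg(family)
  surface <- match.arg(surface)
  rfun <- switch(family,
    circle = {
      r0 <- params$r0
      if (is.null(r0) || r0 <= 0) stop("circle needs r0 > 0", call. = FALSE)
      function(th) rep(r0, length(th))
    },
    ellipse = {
      a <- params$a; b <- params$b
      if (is.null(a) || is.null(b) || a <= 0 || b <= 0)
        stop("ellipse needs semi-axes a, b > 0", call. = FALSE)
      function(th) a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
    },
    blob = {
      r0 <- params$r0
      if (is.null(r0) || r0 <= 0) stop("blob needs r0 > 0", call. = FALSE)
      nh <- min(params$n_harmonics %||% 4L, 6L)
      amp <- params$amp %||% 0.15
      set.seed(seed)
      ks <- 2:(1 + nh)
      ak <- stats::runif(nh, -1, 1)
      ak <- ak / sum(abs(ak)) * amp
      ph <- stats::runif(nh, 0, 2 * pi)
      f <- function(th) {
        r <- rep(1, length(th))
        for (j in seq_along(ks)) r <- r + ak[j] * cos(ks[j] * th + ph[j])
        r0 * r
      }
      if (min(f(seq(0, 2 * pi, length.out = 2048))) <= 0)
        stop("blob parameters violate star-convexity (radius <= 0)",
             call. = FALSE)
      f
    })
  zfun <- switch(surface,
    flat = function(x, y) rep(z0, length(x)),
    tilted = function(x, y) z0 + gx * x + gy * y,
    cap = function(x, y) {
      rho2 <- (x - center[1])^2 + (y - center[2])^2
      if (any(rho2 > R^2)) stop("contour exceeds spherical cap radius",
                                call. = FALSE)
      z0 + R - sqrt(R^2 - rho2)
    })
  point <- function(t) {
    th <- 2 * pi * t
    r <- rfun(th)
    x <- center[1] + r * cos(th)
    y <- center[2] + r * sin(th)
    cbind(x, y, zfun(x, y))
  }
  structure(list(family = family, surface = surface, point = point,
                 rfun = rfun, center = center, seed = seed),
            class = "oact_scene")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render the two-height photograph pair for a scene
#'
#' Projects the scene curve through the pinhole model at each camera height,
#' rasterizes it as an anti-aliased dark stroke on a light background
#' (sub-pixel curve sampling at 4x the pixel Nyquist rate), and adds
#' seeded Gaussian noise. The exact analytic projections and the analytic
#' cutout-plane ground truth are returned alongside for oracle tests.
#'
#' @param scene An \code{\link{make_shape}} scene.
#' @param geom An \code{\link{acquisition_geometry}}.
#' @param spec A \code{\link{render_spec}}.
#' @param n_curve Number of parameter samples used for the analytic ground
#'   truth polygons (default 720).
#' @return List with grayscale rasters \code{img1}, \code{img2} (matrices,
#'   [row = y, col = x]), analytic image-plane projections \code{proj1},
#'   \code{proj2} (cm), and \code{truth_cutout} (analytic per-point
#'   magnified \code{\link{cutout_contour}}).
#' @export
render_pair <- function(scene, geom, spec = render_spec(), n_curve = 720) {
  ts <- seq(0, 1, length.out = n_curve + 1)[-(n_curve + 1)]
  pts <- scene$point(ts)
  proj <- function(h) cbind(pts[, 1] * geom$d / (h + pts[, 3]),
                            pts[, 2] * geom$d / (h + pts[, 3]))
  proj1 <- proj(geom$h1)
  proj2 <- proj(geom$h2)
  tc <- cbind(pts[, 1] * geom$b / (geom$ssd + pts[, 3]),
              pts[, 2] * geom$b / (geom$ssd + pts[, 3]))
  set.seed(spec$seed)
  img1 <- rasterize_curve(scene, geom, geom$h1, spec, "h1")
  img2 <- rasterize_curve(scene, geom, geom$h2, spec, "h2")
  list(img1 = img1, img2 = img2, proj1 = proj1, proj2 = proj2,
       truth_cutout = cutout_contour(tc[, 1], tc[, 2], z = pts[, 3]))
}

# project and rasterize the scene curve at one camera height; draws an
# anti-aliased stroke from the min distance to a dense polyline sampling
rasterize_curve <- function(scene, geom, h, spec, label) {
  W <- spec$image_dim[1]; H <- spec$image_dim[2]
  # pilot pass to estimate curve length in pixels, then resample at 4 per px
  pilot <- scene$point(seq(0, 1, length.out = 1025)[-1025])
  pp <- cbind(pilot[, 1] * geom$d / (h + pilot[, 3]),
              pilot[, 2] * geom$d / (h + pilot[, 3])) / geom$pixel_pitch
  seg <- sqrt(diff(c(pp[, 1], pp[1, 1]))^2 + diff(c(pp[, 2], pp[1, 2]))^2)
  n <- max(2048L, as.integer(ceiling(4 * sum(seg))))
  ts <- seq(0, 1, length.out = n + 1)[-(n + 1)]
  pts <- scene$point(ts)
  xs <- pts[, 1] * geom$d / (h + pts[, 3]) / geom$pixel_pitch
  ys <- pts[, 2] * geom$d / (h + pts[, 3]) / geom$pixel_pitch
  # image-plane cm (y up) -> pixel coordinates (row down), principal point
  # at the frame center
  px <- xs + (W + 1) / 2
  py <- (H + 1) / 2 - ys
  half <- spec$line_width_px / 2
  win <- as.integer(ceiling(half + 1.5))
  if (any(px < 1 + win) || any(px > W - win) ||
      any(py < 1 + win) || any(py > H - win))
    stop(sprintf("contour exits the frame at camera height %s", label),
         call. = FALSE)
  ix0 <- round(px); iy0 <- round(py)
  offs <- expand.grid(dy = -win:win, dx = -win:win)
  stride <- H + 2L * win
  dist <- rep(Inf, stride * (W + 2L * win))
  lin_all <- integer(0); dd_all <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    iy <- iy0 + offs$dy[k] + win
    ix <- ix0 + offs$dx[k] + win
    dd <- sqrt((iy - win - py)^2 + (ix - win - px)^2)
    lin_all <- c(lin_all, as.integer(iy + (ix - 1L) * stride))
    dd_all <- c(dd_all, dd)
  }
  # smallest distance per pixel must win: write in decreasing order so the
  # last assignment is the minimum
  o <- order(dd_all, decreasing = TRUE)
  dist[lin_all[o]] <- dd_all[o]
  dim(dist) <- c(stride, W + 2L * win)
  dist <- dist[(win + 1):(win + H), (win + 1):(win + W)]
  cov <- pmin(pmax(half + 0.5 - dist, 0), 1)
  img <- spec$bg - (spec$bg - spec$fg) * cov
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(H * W, sd = spec$noise_sd), H, W)
  img[img < 0] <- 0; img[img > 1] <- 1
  img
}

#' Run the full pipeline on a synthetic scene and score it
#'
#' Renders the two-height image pair, runs the imaging stages (crop around
#' the projected contour, Gaussian smoothing, binarization,
#' skeletonization, radial sampling), reconstructs the cutout contour
#' through the geometry module, and scores it against the analytic ground
#' truth with ARI and CMI.
#'
#' @param scene,geom,spec See \code{\link{render_pair}}.
#' @param interval_deg Radial sampling step in degrees (default 5).
#' @param sigma Gaussian smoothing sigma in pixels (default 2).
#' @param crop_margin_px Margin added around the projected contour when
#'   cropping (default 40).
#' @return List with \code{truth} (analytic \code{\link{cutout_contour}}),
#'   \code{pipeline} (reconstructed \code{\link{cutout_contour}}), and
#'   \code{report} (an \code{\link{oact_compare}} metric report).
#' @export
end_to_end_case <- function(scene, geom, spec = render_spec(),
                            interval_deg = 5, sigma = 2,
                            crop_margin_px = 40) {
  rp <- render_pair(scene, geom, spec)
  contour_of <- function(img, proj) {
    W <- ncol(img); H <- nrow(img)
    px <- proj[, 1] / geom$pixel_pitch + (W + 1) / 2
    py <- (H + 1) / 2 - proj[, 2] / geom$pixel_pitch
    x0 <- max(1, floor(min(px)) - crop_margin_px)
    y0 <- max(1, floor(min(py)) - crop_margin_px)
    x1 <- min(W, ceiling(max(px)) + crop_margin_px)
    y1 <- min(H, ceiling(max(py)) + crop_margin_px)
    roi <- preprocess(img, crop = c(x0, y0, x1 - x0 + 1, y1 - y0 + 1),
                      sigma = sigma, pixel_pitch = geom$pixel_pitch)
    sk <- binarize_and_skeletonize(roi)
    radial_sample(sk, interval_deg = interval_deg,
                  pixel_pitch = geom$pixel_pitch)
  }
  c1 <- contour_of(rp$img1, rp$proj1)
  c2 <- contour_of(rp$img2, rp$proj2)
  pairs <- pair_contours(c1, c2)
  cut <- reconstruct_contour(pairs, geom)
  report <- oact_compare(unclass(cut), unclass(rp$truth_cutout),
                         interval_deg = interval_deg)
  list(truth = rp$truth_cutout, pipeline = cut, report = report,
       radial1 = c1, radial2 = c2)
}
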