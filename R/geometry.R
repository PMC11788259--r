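#' Acquisition geometry for bi-planar contour photography
#'
#' Describes the fixed imaging configuration: a pinhole camera placed
#' successively at two heights \code{h1} and \code{h2} above the isocenter
#' plane (the SSD = 100 cm reference plane), looking straight down along the
#' beam central axis. A point on the skin at signed depth offset \code{z}
#' below the isocenter plane (positive away from the source) projects onto
#' the imaging plane, a distance \code{d} behind the optic origin, at
#' \code{N = D * d / (h + z)} for each transverse coordinate \code{D}.
#'
#' @param h1,h2 Camera heights above the isocenter plane, cm. Must differ.
#' @param d Distance from the camera optic origin to the imaging plane, cm.
#' @param pixel_pitch Physical size of one sensor pixel, cm/pixel.
#' @param ssd Source-to-surface reference distance, cm (default 100).
#' @param b Source-to-cutout distance, cm (default 95).
#' @param k1 Optional single-coefficient radial distortion correction applied
#'   to normalized image coordinates before reconstruction (default 0 = off).
#' @return An object of class \code{"oact_geometry"}.
#' @examples
#' geom <- acquisition_geometry(h1 = 40, h2 = 60, d = 1, pixel_pitch = 1e-3)
#' project_point(c(5, 0, 0), h = 40, geom = geom)
#' @export
acquisition_geometry <- function(h1, h2, d, pixel_pitch,
                                 ssd = 100, b = 95, k1 = 0) {
  vals <- c(h1 = h1, h2 = h2, d = d, pixel_pitch = pixel_pitch,
            ssd = ssd, b = b)
  if (!all(is.finite(vals)) || !is.finite(k1))
    stop("acquisition geometry values must be finite", call. = FALSE)
  if (any(vals <= 0))
    stop("h1, h2, d, pixel_pitch, ssd and b must be strictly positive",
         call. = FALSE)
  if (h1 == h2)
    stop("camera heights h1 and h2 must differ", call. = FALSE)
  if (h1 >= ssd || h2 >= ssd)
    stop("camera heights must be below the SSD reference plane", call. = FALSE)
  structure(list(h1 = h1, h2 = h2, d = d, pixel_pitch = pixel_pitch,
                 ssd = ssd, b = b, k1 = k1),
            class = "oact_geometry")
}

#' @export
print.oact_geometry <- function(x, ...) {
  cat("Bi-planar acquisition geometry\n")
  cat(sprintf("  camera heights : h1 = %g cm, h2 = %g cm\n", x$h1, x$h2))
  cat(sprintf("  focal distance : d = %g cm (pixel pitch %g cm/px)\n",
              x$d, x$pixel_pitch))
  cat(sprintf("  SSD = %g cm, source-to-cutout b = %g cm\n", x$ssd, x$b))
  if (x$k1 != 0) cat(sprintf("  radial correction k1 = %g\n", x$k1))
  invisible(x)
}

# tolerance below which a projection disparity |x2 - x1| is treated as
# on-axis for that coordinate (cm); far below one pixel pitch
DEGENERACY_TOL <- 1e-6

#' Forward pinhole projection of a 3D point
#'
#' Projects a room-frame point \code{(x, y, z)} onto the imaging plane of a
#' camera at height \code{h} above the isocenter plane. Serves as the oracle
#' for reconstruction round trips.
#'
#' @param p Numeric length-3 vector \code{c(x, y, z)}, cm; \code{z} is the
#'   signed offset from the isocenter plane, positive away from the source.
#' @param h Camera height above the isocenter plane, cm.
#' @param geom An \code{\link{acquisition_geometry}}.
#' @return Numeric length-2 image-plane coordinates (cm), origin at the
#'   principal point.
#' @export
project_point <- function(p, h, geom) {
  stopifnot(length(p) == 3, is.finite(p))
  range <- h + p[3]
  if (range <= 0)
    stop("degenerate geometry: point at or behind the camera plane (h + z <= 0)",
         call. = FALSE)
  c(p[1], p[2]) * geom$d / range
}

#' Reconstruct a 3D point from its two image-plane projections
#'
#' Inverts the forward model using the closed-form bi-planar relations
#' \code{x = x1 x2 (h1 - h2) / (d (x2 - x1))} and
#' \code{z = (x1 h1 - x2 h2) / (x2 - x1)} (and the y analogues). Because
#' pixel noise makes the x- and y-derived depth estimates disagree, \code{z}
#' is taken as the disparity-weighted average of the two axis estimates
#' (weights \code{|x2 - x1|} and \code{|y2 - y1|}); when one axis is
#' degenerate (disparity below tolerance, i.e. the point lies on that axis)
#' the informative axis alone supplies \code{z} and the degenerate
#' coordinate is recovered from \code{N (h + z) / d}.
#'
#' @param pair Numeric length-4 vector \code{c(x1, y1, x2, y2)}: image-plane
#'   coordinates (cm) at heights \code{h1} and \code{h2}.
#' @param geom An \code{\link{acquisition_geometry}}.
#' @return Numeric length-3 \code{c(x, y, z)} (cm), with attribute
#'   \code{"degenerate"} set to \code{TRUE} when both axes were below the
#'   disparity tolerance (on-axis point; caller should interpolate from
#'   angular neighbors).
#' @export
reconstruct_point <- function(pair, geom) {
  stopifnot(length(pair) == 4, is.finite(pair))
  pair <- undistort_pair(pair, geom)
  x1 <- pair[1]; y1 <- pair[2]; x2 <- pair[3]; y2 <- pair[4]
  h1 <- geom$h1; h2 <- geom$h2; d <- geom$d

  wx <- abs(x2 - x1); wy <- abs(y2 - y1)
  okx <- wx >= DEGENERACY_TOL
  oky <- wy >= DEGENERACY_TOL
  if (!okx && !oky) {
    out <- c(0, 0, 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  zx <- if (okx) (x1 * h1 - x2 * h2) / (x2 - x1) else 0
  zy <- if (oky) (y1 * h1 - y2 * h2) / (y2 - y1) else 0
  z <- (wx * (if (okx) zx else 0) + wy * (if (oky) zy else 0)) /
    ((if (okx) wx else 0) + (if (oky) wy else 0))
  # transverse coordinates from the averaged depth; both views agree exactly
  # on noiseless input, averaging splits the difference under noise
  x <- (x1 * (h1 + z) + x2 * (h2 + z)) / (2 * d)
  y <- (y1 * (h1 + z) + y2 * (h2 + z)) / (2 * d)
  out <- c(x, y, z)
  attr(out, "degenerate") <- FALSE
  out
}

# single-coefficient radial correction on normalized coordinates (x/d, y/d);
# identity when k1 = 0
undistort_pair <- function(pair, geom) {
  if (geom$k1 == 0) return(pair)
  fix <- function(xy) {
    n <- xy / geom$d
    n <- n * (1 + geom$k1 * sum(n^2))
    n * geom$d
  }
  c(fix(pair[1:2]), fix(pair[3:4]))
}

# forward model of the distortion hook, used to synthesize distorted test
# input; inverse of undistort to first order only, exact when k1 = 0
distort_pair <- function(pair, geom) {
  if (geom$k1 == 0) return(pair)
  fix <- function(xy) {
    n <- xy / geom$d
    # invert n_u = n_d (1 + k1 r_d^2) by fixed-point iteration
    nd <- n
    for (i in 1:25) nd <- n / (1 + geom$k1 * sum(nd^2))
    nd * geom$d
  }
  c(fix(pair[1:2]), fix(pair[3:4]))
}

#' Project a reconstructed 3D point to the cutout plane
#'
#' Applies the per-point magnification \code{b / (SSD + z)} that maps a skin
#' point at depth offset \code{z} to the cutout plane at distance \code{b}
#' from the source: \code{xB = x b / (SSD + z)}, \code{yB = y b / (SSD + z)}.
#' Points on the isocenter plane (\code{z = 0}) scale by exactly
#' \code{b / SSD}.
#'
#' @param p Numeric length-3 \code{c(x, y, z)}, cm.
#' @param geom An \code{\link{acquisition_geometry}}.
#' @return Numeric length-2 \code{c(xB, yB)} cutout-plane coordinates (cm).
#' @export
project_to_cutout <- function(p, geom) {
  stopifnot(length(p) == 3, is.finite(p))
  denom <- geom$ssd + p[3]
  if (denom <= 0)
    stop("degenerate geometry: SSD + z <= 0", call. = FALSE)
  c(p[1], p[2]) * geom$b / denom
}

#' Reconstruct a full cutout contour from angle-matched point pairs
#'
#' Runs \code{\link{reconstruct_point}} then \code{\link{project_to_cutout}}
#' on every pair. Pairs flagged degenerate (both projection disparities below
#' tolerance, which happens for points on the optical axis) are filled in by
#' linear interpolation of \code{(xB, yB)} over angle index from the nearest
#' non-degenerate neighbors, wrapping around the closed contour.
#'
#' @param pairs Numeric matrix with one row per angular sample and columns
#'   \code{x1, y1, x2, y2} (cm), ordered by increasing angle.
#' @param geom An \code{\link{acquisition_geometry}}.
#' @return A \code{\link{cutout_contour}}: closed polygon ordered like the
#'   input, with attributes \code{z} (per-vertex reconstructed depth, cm) and
#'   \code{n_degenerate}.
#' @export
reconstruct_contour <- function(pairs, geom) {
  pairs <- as.matrix(pairs)
  n <- nrow(pairs)
  if (n < 3)
    stop("at least 3 angle-matched pairs are required", call. = FALSE)
  pts <- matrix(NA_real_, n, 2)
  zs <- rep(NA_real_, n)
  bad <- logical(n)
  for (i in seq_len(n)) {
    p <- reconstruct_point(pairs[i, ], geom)
    if (isTRUE(attr(p, "degenerate"))) {
      bad[i] <- TRUE
    } else {
      pts[i, ] <- project_to_cutout(p, geom)
      zs[i] <- p[3]
    }
  }
  if (sum(bad) > 0.25 * n)
    stop(sprintf("reconstruction failure: %d of %d points degenerate (> 25%%)",
                 sum(bad), n), call. = FALSE)
  if (any(bad)) {
    pts[, 1] <- interp_circular(pts[, 1], bad)
    pts[, 2] <- interp_circular(pts[, 2], bad)
    zs <- interp_circular(zs, bad)
  }
  cutout_contour(pts[, 1], pts[, 2], z = zs, n_degenerate = sum(bad))
}

# linear interpolation over circular index for entries flagged bad
interp_circular <- function(v, bad) {
  n <- length(v)
  good <- which(!bad)
  if (length(good) == 0) stop("no valid points to interpolate from")
  idx <- seq_len(n)
  # unwrap by replicating good points one period either side
  xs <- c(good - n, good, good + n)
  ys <- rep(v[good], 3)
  v[bad] <- stats::approx(xs, ys, xout = idx[bad])$y
  v
}

#' Simplified mean-scaling contour coordinate
#'
#' The averaged-scaling mode computes
#' \code{x_new = ((h1 + h2) / d_sc) * ((x1 + x2) / 2)} (and the y analogue)
#' from the two image-plane coordinates and a scaling constant \code{d_sc}.
#' This is an approximation: it agrees with the exact reconstruction +
#' cutout projection only for flat contours (\code{z = 0}) and only when
#' \code{d_sc = d (h1 + h2)^2 / (2 h1 h2) * (SSD / b)}; see
#' \code{\link{averaged_scaling_constant}}. The exact route
#' (\code{\link{reconstruct_point}} + \code{\link{project_to_cutout}}) is the
#' package default; this mode is provided for comparison.
#'
#' @param pair Numeric length-4 \code{c(x1, y1, x2, y2)} (cm).
#' @param h1,h2 Camera heights, cm.
#' @param d_sc Scaling constant, cm; must be positive.
#' @return Numeric length-2 \code{c(x_new, y_new)}.
#' @export
averaged_scaling <- function(pair, h1, h2, d_sc) {
  if (!is.finite(d_sc) || d_sc <= 0)
    stop("scaling constant d_sc must be positive", call. = FALSE)
  stopifnot(length(pair) == 4, is.finite(pair))
  s <- (h1 + h2) / d_sc
  c(s * (pair[1] + pair[3]) / 2, s * (pair[2] + pair[4]) / 2)
}

#' Calibration constant making averaged scaling exact for flat contours
#'
#' For a contour lying entirely on the isocenter plane the mean-scaling
#' formula reproduces the exact cutout coordinates when
#' \code{d_sc = d (h1 + h2)^2 / (2 h1 h2) * (SSD / b)}.
#'
#' @param geom An \code{\link{acquisition_geometry}}.
#' @return The calibrated \code{d_sc} (cm).
#' @export
averaged_scaling_constant <- function(geom) {
  geom$d * (geom$h1 + geom$h2)^2 / (2 * geom$h1 * geom$h2) *
    (geom$ssd / geom$b)
}

#' Ordered polygon in the cutout plane
#'
#' @param x,y Vertex coordinates, cm, in the cutout plane (distance \code{b}
#'   from the source), ordered along the contour; the first vertex is not
#'   repeated.
#' @param z Optional per-vertex reconstructed skin depth (cm).
#' @param n_degenerate Number of vertices that were interpolated.
#' @return An object of class \code{"oact_cutout"}: a two-column matrix.
#' @export
cutout_contour <- function(x, y, z = NULL, n_degenerate = 0L) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3)
    stop("a cutout contour needs at least 3 vertices", call. = FALSE)
  m <- cbind(x = as.numeric(x), y = as.numeric(y))
  structure(m, z = z, n_degenerate = n_degenerate,
            class = c("oact_cutout", class(m)))
}

#' @export
print.oact_cutout <- function(x, ...) {
  cat(sprintf("Cutout contour: %d vertices, area %.3f cm^2\n",
              nrow(x), shoelace_area(x)))
  if (!is.null(attr(x, "z")))
    cat(sprintf("  reconstructed depth z in [%.2f, %.2f] cm\n",
                min(attr(x, "z")), max(attr(x, "z"))))
  nd <- attr(x, "n_degenerate")
  if (!is.null(nd) && nd > 0)
    cat(sprintf("  %d degenerate vertices interpolated\n", nd))
  invisible(x)
}
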