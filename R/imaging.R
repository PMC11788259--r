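#' Read a contour photograph into a grayscale raster
#'
#' Reads a PNG or JPEG (8- or 16-bit; EXIF orientation is honored by the
#' underlying reader) and converts it to a luminance-weighted grayscale
#' matrix in [0, 1].
#'
#' @param path Image file path.
#' @return Numeric matrix, rows = image rows (y, top down), cols = x.
#' @export
read_contour_image <- function(path) {
  img <- EBImage::readImage(path)
  if (EBImage::colorMode(img) == EBImage::Color)
    img <- EBImage::channel(img, "luminance")
  # EBImage stores [x, y]; internal rasters are [row = y, col = x]
  t(as.array(img))
}

#' Crop, smooth and normalize a region of interest
#'
#' Crops the square region enclosing the drawn contour from the full frame,
#' converts to grayscale if needed, applies a Gaussian filter of standard
#' deviation \code{sigma} pixels, and clamps intensities to [0, 1].
#'
#' @param image Grayscale matrix in [0, 1] (see
#'   \code{\link{read_contour_image}}), or a file path.
#' @param crop Crop box \code{c(x0, y0, w, h)} in pixels, 1-based top-left
#'   corner, or \code{NULL} for the full frame.
#' @param sigma Gaussian standard deviation in pixels (>= 0; 0 = no
#'   smoothing).
#' @param pixel_pitch Physical pixel size, cm/pixel, carried along for the
#'   downstream pixel-to-cm conversion.
#' @return An object of class \code{"oact_roi"}: list with \code{raster},
#'   \code{offset} (0-based pixel offset of the crop in the frame),
#'   \code{frame_dim} \code{c(width, height)}, \code{pixel_pitch}.
#' @export
preprocess <- function(image, crop = NULL, sigma = 2, pixel_pitch = NA_real_) {
  if (is.character(image)) image <- read_contour_image(image)
  stopifnot(is.matrix(image))
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  H <- nrow(image); W <- ncol(image)
  if (is.null(crop)) crop <- c(1, 1, W, H)
  x0 <- crop[1]; y0 <- crop[2]; w <- crop[3]; h <- crop[4]
  if (w < 1 || h < 1) stop("empty crop box", call. = FALSE)
  if (x0 < 1 || y0 < 1 || x0 + w - 1 > W || y0 + h - 1 > H)
    stop("crop box extends outside the frame", call. = FALSE)
  roi <- image[y0:(y0 + h - 1), x0:(x0 + w - 1), drop = FALSE]
  if (sigma > 0) {
    img <- EBImage::Image(t(roi))
    img <- EBImage::gblur(img, sigma = sigma)
    roi <- t(as.array(img))
  }
  roi[roi < 0] <- 0; roi[roi > 1] <- 1
  structure(list(raster = roi, offset = c(x0 - 1, y0 - 1),
                 frame_dim = c(W, H), pixel_pitch = pixel_pitch),
            class = "oact_roi")
}

#' Binarize and skeletonize a contour region of interest
#'
#' Thresholds the smoothed ROI with Otsu's method (foreground = dark stroke
#' on a light background), keeps the largest connected component if several
#' are present (with a warning), and thins the stroke to a one-pixel-wide
#' 8-connected centerline by Zhang-Suen thinning; spurs shorter than 5
#' pixels are pruned.
#'
#' @param roi An \code{"oact_roi"} from \code{\link{preprocess}}, or a
#'   grayscale matrix.
#' @return Logical skeleton matrix (same shape as the ROI raster), with the
#'   ROI metadata attached as attributes \code{offset}, \code{frame_dim},
#'   \code{pixel_pitch}.
#' @export
binarize_and_skeletonize <- function(roi) {
  meta <- list(offset = c(0, 0), frame_dim = NULL, pixel_pitch = NA_real_)
  if (inherits(roi, "oact_roi")) {
    meta <- roi[c("offset", "frame_dim", "pixel_pitch")]
    roi <- roi$raster
  }
  stopifnot(is.matrix(roi))
  rng <- range(roi)
  if (diff(rng) < 1e-6)
    stop("empty contour: image has no dark/light separation", call. = FALSE)
  thr <- EBImage::otsu(EBImage::Image(t(roi)), range = rng)
  fg <- roi < thr
  if (!any(fg))
    stop("empty contour: nothing below the binarization threshold",
         call. = FALSE)
  fg <- keep_largest_component(fg)
  sk <- zhang_suen_thin(fg)
  sk <- prune_spurs(sk, max_len = 5L)
  attributes(sk) <- c(attributes(sk), meta)
  sk
}

# keep the largest 8-connected foreground component; warn when several
# non-trivial components compete (e.g. two separate drawn shapes)
keep_largest_component <- function(fg) {
  lab <- EBImage::bwlabel(EBImage::Image(t(fg)))
  lab <- t(as.array(lab))
  if (max(lab) <= 1) return(fg)
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  if (sum(sizes >= 0.1 * sizes[big]) > 1)
    warning("multiple contour components found; keeping the largest",
            call. = FALSE)
  lab == big
}

# Zhang-Suen thinning, vectorized over the whole raster. Foreground TRUE.
zhang_suen_thin <- function(img) {
  img <- img * 1L
  H <- nrow(img); W <- ncol(img)
  pad <- matrix(0L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- img
  shift <- function(m, dy, dx) m[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)]
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p <- pad[2:(H + 1), 2:(W + 1)]
      # neighbors clockwise from north: p2..p9
      p2 <- shift(pad, -1, 0); p3 <- shift(pad, -1, 1); p4 <- shift(pad, 0, 1)
      p5 <- shift(pad, 1, 1); p6 <- shift(pad, 1, 0); p7 <- shift(pad, 1, -1)
      p8 <- shift(pad, 0, -1); p9 <- shift(pad, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (pass == 1) {
        cond <- p == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- p == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        p[cond] <- 0L
        pad[2:(H + 1), 2:(W + 1)] <- p
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pad[2:(H + 1), 2:(W + 1)] == 1L
}

# iteratively strip endpoint pixels (exactly one 8-neighbor) up to max_len
# times; a closed cycle has no endpoints and is untouched
prune_spurs <- function(sk, max_len = 5L) {
  H <- nrow(sk); W <- ncol(sk)
  for (i in seq_len(max_len)) {
    pad <- matrix(FALSE, H + 2, W + 2)
    pad[2:(H + 1), 2:(W + 1)] <- sk
    nb <- matrix(0L, H, W)
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      nb <- nb + pad[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)]
    }
    ends <- sk & nb <= 1
    if (!any(ends)) break
    sk[ends] <- FALSE
  }
  sk
}

#' Geometric center of a skeletonized contour
#'
#' Mean position of the skeleton (foreground) pixels.
#'
#' @param skeleton Logical matrix from
#'   \code{\link{binarize_and_skeletonize}}.
#' @return Numeric length-2 \code{c(x, y)} in pixel coordinates of the
#'   skeleton raster (x = column, y = row, 1-based).
#' @export
contour_center <- function(skeleton) {
  idx <- which(skeleton, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty skeleton", call. = FALSE)
  c(mean(idx[, 2]), mean(idx[, 1]))
}

#' Radial contour container
#'
#' A closed contour represented by N equally spaced polar samples about a
#' center point.
#'
#' @param angle_deg Strictly increasing angles covering [0, 360), degrees,
#'   measured counterclockwise from +x with y up (beam's-eye view).
#' @param radius_cm Positive radii, cm.
#' @param center Center \code{c(x, y)} in image-plane cm (origin at the
#'   principal point) where known, else \code{c(0, 0)}.
#' @param interval_deg Angular step, degrees.
#' @return An object of class \code{"oact_radial"}.
#' @export
radial_contour <- function(angle_deg, radius_cm, center = c(0, 0),
                           interval_deg = diff(angle_deg[1:2])) {
  n <- length(angle_deg)
  if (length(radius_cm) != n)
    stop("angles and radii differ in length", call. = FALSE)
  if (abs(n * interval_deg - 360) > 1e-9)
    stop("N * interval_deg must equal 360", call. = FALSE)
  if (any(diff(angle_deg) <= 0))
    stop("angles must be strictly increasing", call. = FALSE)
  if (any(!is.finite(radius_cm)) || any(radius_cm <= 0))
    stop("radii must be positive and finite", call. = FALSE)
  structure(list(angle_deg = as.numeric(angle_deg),
                 radius_cm = as.numeric(radius_cm),
                 center = center, interval_deg = interval_deg),
            class = "oact_radial")
}

#' @export
print.oact_radial <- function(x, ...) {
  cat(sprintf("Radial contour: N = %d samples every %g degrees, r in [%.3f, %.3f] cm\n",
              length(x$radius_cm), x$interval_deg,
              min(x$radius_cm), max(x$radius_cm)))
  invisible(x)
}

#' Sample a skeleton into a radial contour
#'
#' Divides the skeleton into \code{360 / interval_deg} equal angular bins
#' about the center and records, per bin, the median center-to-pixel
#' distance converted to cm. Bin k covers angles
#' \code{[k*interval - interval/2, k*interval + interval/2)} measured
#' counterclockwise from +x with y up. Empty bins are filled by linear
#' interpolation over angle from the nearest non-empty neighbors. When a bin
#' contains pixels at widely separated radii (range > 20% of the bin
#' median), the shape violates the star-convex assumption of the radial
#' parameterization; the median is kept and a warning is raised.
#'
#' @param skeleton Logical skeleton matrix.
#' @param center Center \code{c(x, y)} in skeleton pixel coordinates
#'   (default \code{\link{contour_center}}).
#' @param interval_deg Angular step (must divide 360; default 5).
#' @param pixel_pitch cm per pixel; taken from the skeleton's metadata if
#'   omitted.
#' @return A \code{\link{radial_contour}}. Its center is expressed in
#'   image-plane cm relative to the full-frame principal point (frame
#'   center) when the skeleton carries crop metadata.
#' @export
radial_sample <- function(skeleton, center = contour_center(skeleton),
                          interval_deg = 5,
                          pixel_pitch = attr(skeleton, "pixel_pitch")) {
  if (is.null(pixel_pitch) || is.na(pixel_pitch)) pixel_pitch <- 1
  n <- 360 / interval_deg
  if (abs(n - round(n)) > 1e-9)
    stop("interval_deg must divide 360", call. = FALSE)
  n <- as.integer(round(n))
  idx <- which(skeleton, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty skeleton", call. = FALSE)
  dx <- idx[, 2] - center[1]
  dy <- center[2] - idx[, 1]          # image rows grow downward; flip to y-up
  th <- atan2(dy, dx) * 180 / pi
  th <- th %% 360
  r <- sqrt(dx^2 + dy^2)
  bin <- floor(((th + interval_deg / 2) %% 360) / interval_deg) + 1L
  radii <- rep(NA_real_, n)
  warn_bins <- integer(0)
  for (k in seq_len(n)) {
    rk <- r[bin == k]
    rk <- rk[rk > 0]
    if (length(rk) == 0) next
    med <- stats::median(rk)
    if (diff(range(rk)) > 0.2 * med) warn_bins <- c(warn_bins, k)
    radii[k] <- med
  }
  empty <- is.na(radii)
  if (sum(empty) > n / 2)
    stop(sprintf("radial sampling failure: %d of %d angular bins empty",
                 sum(empty), n), call. = FALSE)
  if (any(empty)) radii <- interp_circular(radii, empty)
  if (length(warn_bins))
    warning(sprintf("star-convexity violation in %d angular bin(s); using bin medians",
                    length(warn_bins)), call. = FALSE)
  center_cm <- c(0, 0)
  off <- attr(skeleton, "offset"); fd <- attr(skeleton, "frame_dim")
  if (!is.null(off) && !is.null(fd)) {
    # principal point at the full-frame center, y flipped to beam's-eye view
    cx_frame <- off[1] + center[1]
    cy_frame <- off[2] + center[2]
    center_cm <- c((cx_frame - (fd[1] + 1) / 2) * pixel_pitch,
                   ((fd[2] + 1) / 2 - cy_frame) * pixel_pitch)
  }
  radial_contour(seq(0, 360 - interval_deg, by = interval_deg),
                 radii * pixel_pitch, center = center_cm,
                 interval_deg = interval_deg)
}

#' Pair two radial contours into angle-matched image-plane point pairs
#'
#' Corresponding points are matched by angular index: pair k holds
#' \code{(r1_k cos th_k, r1_k sin th_k)} from the first image and
#' \code{(r2_k cos th_k, r2_k sin th_k)} from the second, in image-plane cm
#' with each image's contour center mapped to the principal point.
#'
#' @param c1,c2 \code{\link{radial_contour}} objects with identical angular
#'   grids (c1 from the camera at h1, c2 from the camera at h2).
#' @return Numeric matrix with columns \code{x1, y1, x2, y2}, one row per
#'   angle, suitable for \code{\link{reconstruct_contour}}.
#' @export
pair_contours <- function(c1, c2) {
  stopifnot(inherits(c1, "oact_radial"), inherits(c2, "oact_radial"))
  if (length(c1$radius_cm) != length(c2$radius_cm) ||
      c1$interval_deg != c2$interval_deg)
    stop("contours are sampled on different angular grids", call. = FALSE)
  th <- c1$angle_deg * pi / 180
  cbind(x1 = c1$radius_cm * cos(th), y1 = c1$radius_cm * sin(th),
        x2 = c2$radius_cm * cos(th), y2 = c2$radius_cm * sin(th))
}
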