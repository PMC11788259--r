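#' Trace an electron cutout contour from a two-height photograph pair
#'
#' The end-to-end tracing pipeline: each photograph is cropped to the region
#' of interest, converted to grayscale, Gaussian-filtered, binarized
#' (Otsu) and skeletonized; the skeleton is sampled radially about its
#' geometric center at \code{interval_deg} steps; the two radial contours
#' are paired by angle and each pair of image-plane points is inverted
#' through the bi-planar pinhole model to a 3D skin point, which is then
#' projected to the cutout plane with its own magnification
#' \code{b / (SSD + z)}.
#'
#' @param image1,image2 Photograph taken at height \code{h1} resp.
#'   \code{h2}: file path (PNG/JPEG) or grayscale matrix.
#' @param geom An \code{\link{acquisition_geometry}} or path to a config
#'   file for \code{\link{read_geometry_config}}.
#' @param crop1,crop2 Crop boxes \code{c(x0, y0, w, h)} in pixels for each
#'   image (\code{NULL} = full frame).
#' @param interval_deg Radial sampling step in degrees (default 5; use 1
#'   for N = 360 sampling of intricate shapes).
#' @param sigma Gaussian smoothing sigma in pixels (default 2).
#' @param mode \code{"exact"} (default) uses the full per-point 3D
#'   reconstruction; \code{"averaged"} uses the simplified mean-scaling
#'   formula with the calibration constant of
#'   \code{\link{averaged_scaling_constant}}, exact only for flat contours.
#' @return An object of class \code{"oact_trace"}: list with \code{cutout}
#'   (a \code{\link{cutout_contour}}), the per-image \code{radial1},
#'   \code{radial2}, \code{roi1}, \code{roi2}, \code{skeleton1},
#'   \code{skeleton2}, centers, collected \code{warnings}, the geometry and
#'   run metadata.
#' @export
oact_trace <- function(image1, image2, geom, crop1 = NULL, crop2 = NULL,
                       interval_deg = 5, sigma = 2,
                       mode = c("exact", "averaged")) {
  mode <- match.arg(mode)
  if (is.character(geom)) geom <- read_geometry_config(geom)
  stopifnot(inherits(geom, "oact_geometry"))
  warnings <- character(0)
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  t0 <- proc.time()[3]
  stage <- function(img, crop) {
    roi <- preprocess(img, crop = crop, sigma = sigma,
                      pixel_pitch = geom$pixel_pitch)
    sk <- collect(binarize_and_skeletonize(roi))
    cen <- contour_center(sk)
    rc <- collect(radial_sample(sk, center = cen,
                                interval_deg = interval_deg,
                                pixel_pitch = geom$pixel_pitch))
    list(roi = roi, skeleton = sk, center = cen, radial = rc)
  }
  s1 <- stage(image1, crop1)
  t1 <- proc.time()[3]
  s2 <- stage(image2, crop2)
  t2 <- proc.time()[3]
  dims1 <- dim(s1$roi$raster); dims2 <- dim(s2$roi$raster)
  if (!is.null(s1$roi$frame_dim) && !is.null(s2$roi$frame_dim) &&
      !identical(s1$roi$frame_dim, s2$roi$frame_dim)) {
    warnings <- c(warnings, "image frame sizes differ; images processed independently")
    warning("image frame sizes differ; images processed independently",
            call. = FALSE)
  }
  pairs <- pair_contours(s1$radial, s2$radial)
  cut <- if (mode == "exact") {
    reconstruct_contour(pairs, geom)
  } else {
    d_sc <- averaged_scaling_constant(geom)
    pts <- t(apply(pairs, 1, averaged_scaling,
                   h1 = geom$h1, h2 = geom$h2, d_sc = d_sc))
    cutout_contour(pts[, 1], pts[, 2])
  }
  t3 <- proc.time()[3]
  structure(list(cutout = cut,
                 radial1 = s1$radial, radial2 = s2$radial,
                 roi1 = s1$roi, roi2 = s2$roi,
                 skeleton1 = s1$skeleton, skeleton2 = s2$skeleton,
                 center1 = s1$center, center2 = s2$center,
                 geometry = geom, interval_deg = interval_deg,
                 sigma = sigma, mode = mode, warnings = warnings,
                 timings = c(image1 = t1 - t0, image2 = t2 - t1,
                             reconstruction = t3 - t2)),
            class = "oact_trace")
}

#' @export
print.oact_trace <- function(x, ...) {
  cat(sprintf("Cutout trace (%s mode): N = %d angular samples every %g degrees\n",
              x$mode, nrow(x$cutout), x$interval_deg))
  cat(sprintf("  cutout area %.3f cm^2 at b = %g cm from the source\n",
              shoelace_area(x$cutout), x$geometry$b))
  if (length(x$warnings))
    cat("  warnings:\n", paste0("   - ", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
summary.oact_trace <- function(object, ...) {
  z <- attr(object$cutout, "z")
  cat("Bi-planar cutout trace\n")
  print(object$geometry)
  cat(sprintf("  cutout vertices : %d (every %g degrees)\n",
              nrow(object$cutout), object$interval_deg))
  cat(sprintf("  cutout area     : %.3f cm^2\n", shoelace_area(object$cutout)))
  if (!is.null(z) && !all(is.na(z)))
    cat(sprintf("  skin depth z    : %.2f to %.2f cm about the isocenter plane\n",
                min(z, na.rm = TRUE), max(z, na.rm = TRUE)))
  nd <- attr(object$cutout, "n_degenerate")
  if (!is.null(nd) && nd > 0)
    cat(sprintf("  interpolated degenerate vertices: %d\n", nd))
  if (length(object$warnings))
    cat("  warnings:\n", paste0("   - ", object$warnings, collapse = "\n"), "\n")
  cat(sprintf("  stage timings (s): %s\n",
              paste(sprintf("%s %.2f", names(object$timings), object$timings),
                    collapse = ", ")))
  invisible(object)
}

#' @export
plot.oact_trace <- function(x, ...) {
  m <- as_vertex_matrix(x$cutout)
  graphics::plot(rbind(m, m[1, ]), type = "l", lwd = 2, asp = 1,
                 xlab = "x (cm)", ylab = "y (cm)",
                 main = sprintf("Cutout contour, area %.2f cm^2",
                                shoelace_area(x$cutout)), ...)
  graphics::points(polygon_centroid(m)[1], polygon_centroid(m)[2], pch = 3)
  invisible(x)
}

#' Write all tracing outputs to a directory
#'
#' Writes the cutout polygon CSV, a 1:1-scale SVG print template, per-image
#' radial contour CSVs and QC overlay PNGs, and a JSON run manifest listing
#' inputs, geometry, warnings, timings, and every output file.
#'
#' @param trace An \code{"oact_trace"} from \code{\link{oact_trace}}.
#' @param out_dir Output directory (created if needed).
#' @param inputs Optional character vector of input image paths echoed into
#'   the manifest.
#' @return Path of the manifest JSON, invisibly.
#' @export
write_trace_outputs <- function(trace, out_dir, inputs = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  outputs <- c(cutout_csv = p("cutout.csv"),
               cutout_svg = p("cutout_template.svg"),
               radial1_csv = p("radial_h1.csv"),
               radial2_csv = p("radial_h2.csv"),
               qc1_png = p("qc_h1.png"),
               qc2_png = p("qc_h2.png"))
  write_contour_csv(trace$cutout, outputs["cutout_csv"])
  write_contour_svg(trace$cutout, outputs["cutout_svg"])
  write_contour_csv(trace$radial1, outputs["radial1_csv"])
  write_contour_csv(trace$radial2, outputs["radial2_csv"])
  write_qc_overlay(trace$roi1, trace$skeleton1, trace$center1,
                   trace$radial1, outputs["qc1_png"])
  write_qc_overlay(trace$roi2, trace$skeleton2, trace$center2,
                   trace$radial2, outputs["qc2_png"])
  g <- trace$geometry
  manifest <- list(
    software = paste("oact", as.character(utils::packageVersion("oact"))),
    inputs = as.list(inputs %||% character(0)),
    geometry = list(h1_cm = g$h1, h2_cm = g$h2, d_cm = g$d,
                    pixel_pitch_cm = g$pixel_pitch, ssd_cm = g$ssd,
                    b_cm = g$b, k1 = g$k1),
    interval_deg = trace$interval_deg, sigma = trace$sigma,
    mode = trace$mode,
    cutout_area_cm2 = shoelace_area(trace$cutout),
    warnings = as.list(trace$warnings),
    timings_s = as.list(trace$timings),
    outputs = as.list(outputs))
  mp <- p("manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  stopifnot(all(file.exists(outputs)))
  invisible(mp)
}

#' Write a synthetic scene as a simulated acquisition
#'
#' Renders the two-height image pair for a scene and writes the PNGs, the
#' ground-truth contour CSVs (analytic image-plane projections and the
#' analytic cutout), a geometry config, and a manifest JSON.
#'
#' @param scene A \code{\link{make_shape}} scene.
#' @param geom An \code{\link{acquisition_geometry}}.
#' @param spec A \code{\link{render_spec}}.
#' @param out_dir Output directory.
#' @return Path of the manifest JSON, invisibly. The rendered pair and
#'   ground truth are attached as attribute \code{"render"}.
#' @export
write_simulation <- function(scene, geom, spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  rp <- render_pair(scene, geom, spec)
  EBImage::writeImage(EBImage::Image(t(rp$img1)), p("image_h1.png"))
  EBImage::writeImage(EBImage::Image(t(rp$img2)), p("image_h2.png"))
  write_contour_csv(rp$truth_cutout, p("truth_cutout.csv"))
  write_contour_csv(polygon_contour(rp$proj1), p("truth_projection_h1.csv"))
  write_contour_csv(polygon_contour(rp$proj2), p("truth_projection_h2.csv"))
  write_geometry_config(geom, p("geometry.cfg"))
  manifest <- list(
    software = paste("oact", as.character(utils::packageVersion("oact"))),
    scene = list(family = scene$family, surface = scene$surface,
                 seed = scene$seed),
    render = list(image_dim = spec$image_dim,
                  line_width_px = spec$line_width_px,
                  fg = spec$fg, bg = spec$bg,
                  noise_sd = spec$noise_sd, seed = spec$seed),
    geometry = p("geometry.cfg"),
    outputs = list(image_h1 = p("image_h1.png"), image_h2 = p("image_h2.png"),
                   truth_cutout = p("truth_cutout.csv")))
  mp <- p("manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  out <- mp
  attr(out, "render") <- rp
  invisible(out)
}
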