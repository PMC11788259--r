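#' Read a contour CSV
#'
#' Accepts either of the two interchange layouts: \code{x_cm,y_cm} (ordered
#' polygon vertices, counterclockwise, first vertex not repeated) or
#' \code{angle_deg,radius_cm} (radial samples about an implicit center at
#' the origin).
#'
#' @param path CSV file path.
#' @return List with \code{polygon} (two-column vertex matrix, cm) and,
#'   when the file was radial, \code{radial} (a
#'   \code{\link{radial_contour}}).
#' @export
read_contour_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path, strip.white = TRUE),
                 error = function(e)
                   stop(sprintf("cannot parse contour CSV '%s': %s",
                                path, conditionMessage(e)), call. = FALSE))
  bad <- which(!stats::complete.cases(df) |
                 !apply(df, 1, function(r) all(is.finite(suppressWarnings(as.numeric(r))))))
  if (length(bad))
    stop(sprintf("malformed contour CSV '%s': non-numeric value at line %d",
                 path, bad[1] + 1L), call. = FALSE)
  nm <- tolower(names(df))
  if (all(c("x_cm", "y_cm") %in% nm)) {
    poly <- polygon_contour(df[[which(nm == "x_cm")]], df[[which(nm == "y_cm")]])
    list(polygon = poly, radial = NULL)
  } else if (all(c("angle_deg", "radius_cm") %in% nm)) {
    ang <- df[[which(nm == "angle_deg")]]
    rad <- df[[which(nm == "radius_cm")]]
    rc <- radial_contour(ang, rad)
    list(polygon = polygon_contour(radial_to_xy(rc)), radial = rc)
  } else {
    stop(sprintf("contour CSV '%s' must have header x_cm,y_cm or angle_deg,radius_cm",
                 path), call. = FALSE)
  }
}

#' Write a contour CSV
#'
#' @param contour A polygon (two-column vertex matrix; written as
#'   \code{x_cm,y_cm}) or a \code{\link{radial_contour}} (written as
#'   \code{angle_deg,radius_cm}).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_contour_csv <- function(contour, path) {
  if (inherits(contour, "oact_radial")) {
    df <- data.frame(angle_deg = contour$angle_deg,
                     radius_cm = contour$radius_cm)
  } else {
    m <- as_vertex_matrix(contour)
    df <- data.frame(x_cm = m[, 1], y_cm = m[, 2])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flat key-value geometry configuration
#'
#' Parses an INI/TOML-style flat file of \code{key = value} lines (comments
#' start with \code{#}). Required keys: \code{h1_cm}, \code{h2_cm},
#' \code{d_cm}, \code{pixel_pitch_cm}. Optional: \code{ssd_cm} (default
#' 100), \code{b_cm} (default 95), \code{k1} (default 0).
#'
#' @param path Config file path.
#' @return An \code{\link{acquisition_geometry}}.
#' @export
read_geometry_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("geometry config '%s' not found", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.+)$", lines))
  vals <- list()
  for (m in kv) {
    if (length(m) == 3) vals[[m[2]]] <- suppressWarnings(as.numeric(m[3]))
  }
  need <- c("h1_cm", "h2_cm", "d_cm", "pixel_pitch_cm")
  missing <- setdiff(need, names(vals))
  if (length(missing))
    stop(sprintf("geometry config '%s' is missing required key(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  bad <- names(vals)[vapply(vals, function(v) !is.finite(v), logical(1))]
  if (length(bad))
    stop(sprintf("geometry config '%s': non-numeric value for key(s): %s",
                 path, paste(bad, collapse = ", ")), call. = FALSE)
  acquisition_geometry(h1 = vals$h1_cm, h2 = vals$h2_cm, d = vals$d_cm,
                       pixel_pitch = vals$pixel_pitch_cm,
                       ssd = vals$ssd_cm %||% 100,
                       b = vals$b_cm %||% 95,
                       k1 = vals$k1 %||% 0)
}

#' Write a geometry configuration file
#'
#' @param geom An \code{\link{acquisition_geometry}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_geometry_config <- function(geom, path) {
  writeLines(c(
    "# bi-planar acquisition geometry (cm)",
    sprintf("h1_cm = %.10g", geom$h1),
    sprintf("h2_cm = %.10g", geom$h2),
    sprintf("d_cm = %.10g", geom$d),
    sprintf("pixel_pitch_cm = %.10g", geom$pixel_pitch),
    sprintf("ssd_cm = %.10g", geom$ssd),
    sprintf("b_cm = %.10g", geom$b),
    sprintf("k1 = %.10g", geom$k1)), path)
  invisible(path)
}

#' Export a cutout contour as a 1:1 physical-scale SVG template
#'
#' Writes the polygon with explicit millimetre units so the template prints
#' at true size at the cutout plane. A centre cross and a 10 mm scale bar
#' are included for print verification.
#'
#' @param contour Polygon (two-column vertex matrix, cm).
#' @param path Output .svg path.
#' @param margin_mm White margin around the contour, mm.
#' @return \code{path}, invisibly.
#' @export
write_contour_svg <- function(contour, path, margin_mm = 15) {
  m <- as_vertex_matrix(contour) * 10  # cm -> mm
  # SVG y grows downward; flip so the template prints in beam's-eye view
  m[, 2] <- -m[, 2]
  xr <- range(m[, 1]); yr <- range(m[, 2])
  w <- diff(xr) + 2 * margin_mm
  h <- diff(yr) + 2 * margin_mm
  ox <- margin_mm - xr[1]; oy <- margin_mm - yr[1]
  pts <- paste(sprintf("%.3f,%.3f", m[, 1] + ox, m[, 2] + oy), collapse = " ")
  cx <- ox; cy <- oy
  svg <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%.3fmm" height="%.3fmm" viewBox="0 0 %.3f %.3f">',
            w, h, w, h),
    sprintf('  <polygon points="%s" fill="none" stroke="black" stroke-width="0.35"/>', pts),
    sprintf('  <line x1="%.3f" y1="%.3f" x2="%.3f" y2="%.3f" stroke="black" stroke-width="0.2"/>',
            cx - 4, cy, cx + 4, cy),
    sprintf('  <line x1="%.3f" y1="%.3f" x2="%.3f" y2="%.3f" stroke="black" stroke-width="0.2"/>',
            cx, cy - 4, cx, cy + 4),
    sprintf('  <line x1="%.3f" y1="%.3f" x2="%.3f" y2="%.3f" stroke="black" stroke-width="0.5"/>',
            margin_mm / 4, h - margin_mm / 4, margin_mm / 4 + 10, h - margin_mm / 4),
    sprintf('  <text x="%.3f" y="%.3f" font-size="3">10 mm</text>',
            margin_mm / 4, h - margin_mm / 4 - 1.5),
    '</svg>')
  writeLines(svg, path)
  invisible(path)
}

#' Write a metric report as JSON
#'
#' @param report An \code{"oact_metrics"} object from
#'   \code{\link{oact_compare}}.
#' @param path Output .json path.
#' @return \code{path}, invisibly.
#' @export
write_metric_report <- function(report, path) {
  out <- list(area_reference = report$area_reference,
              area_test = report$area_test,
              ari = report$ari,
              cmi = report$cmi,
              n_intervals = report$n_intervals,
              angle_deg = report$angles_deg,
              deviation_cm = report$deviation_cm)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a QC overlay PNG for one processed image
#'
#' Renders the smoothed ROI with the extracted skeleton, the contour
#' center, and the sampled radial points marked, for visual verification of
#' the tracing.
#'
#' @param roi An \code{"oact_roi"} from \code{\link{preprocess}}.
#' @param skeleton Logical skeleton matrix from
#'   \code{\link{binarize_and_skeletonize}}.
#' @param center Center in skeleton pixel coordinates.
#' @param radial A \code{\link{radial_contour}} sampled from the skeleton.
#' @param path Output .png path.
#' @return \code{path}, invisibly.
#' @export
write_qc_overlay <- function(roi, skeleton, center, radial, path) {
  base <- roi$raster
  r <- base; g <- base; b <- base
  r[skeleton] <- 1; g[skeleton] <- 0; b[skeleton] <- 0
  pitch <- if (is.na(roi$pixel_pitch)) 1 else roi$pixel_pitch
  th <- radial$angle_deg * pi / 180
  sx <- round(center[1] + radial$radius_cm / pitch * cos(th))
  sy <- round(center[2] - radial$radius_cm / pitch * sin(th))
  ok <- sx >= 1 & sx <= ncol(base) & sy >= 1 & sy <= nrow(base)
  idx <- cbind(sy[ok], sx[ok])
  r[idx] <- 0; g[idx] <- 0.8; b[idx] <- 0
  cx <- round(center[1]); cy <- round(center[2])
  cross <- cbind(c(rep(cy, 9), (cy - 4):(cy + 4)),
                 c((cx - 4):(cx + 4), rep(cx, 9)))
  cross <- cross[cross[, 1] >= 1 & cross[, 1] <= nrow(base) &
                   cross[, 2] >= 1 & cross[, 2] <= ncol(base), , drop = FALSE]
  r[cross] <- 0; g[cross] <- 0.2; b[cross] <- 1
  img <- EBImage::rgbImage(red = t(r), green = t(g), blue = t(b))
  EBImage::writeImage(img, path)
  invisible(path)
}
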