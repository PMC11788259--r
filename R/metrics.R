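#' Closed polygon contour
#'
#' @param x,y Ordered vertex coordinates (cm); the polygon is implicitly
#'   closed and the first vertex must not be repeated.
#' @return A two-column matrix of class \code{"oact_polygon"}.
#' @export
polygon_contour <- function(x, y = NULL) {
  if (is.null(y)) {
    m <- as.matrix(x)
    if (ncol(m) != 2) stop("expected two columns (x, y)", call. = FALSE)
  } else {
    stopifnot(length(x) == length(y))
    m <- cbind(x, y)
  }
  if (nrow(m) >= 2 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  if (nrow(m) < 3)
    stop("a polygon contour needs at least 3 distinct vertices", call. = FALSE)
  if (!all(is.finite(m))) stop("polygon vertices must be finite", call. = FALSE)
  colnames(m) <- c("x", "y")
  structure(m, class = c("oact_polygon", class(m)))
}

#' Polygon area by the shoelace formula
#'
#' Computes the enclosed area of a simple closed polygon from its ordered
#' vertices: \code{A = |sum(x_i y_(i+1) - x_(i+1) y_i)| / 2}. The result is
#' independent of vertex orientation and of the starting vertex. For a
#' self-intersecting polygon the absolute signed area is returned with a
#' warning.
#'
#' @param p A polygon: two-column matrix of ordered vertices, or an
#'   \code{\link{polygon_contour}} / \code{\link{cutout_contour}}.
#' @return Area in the square of the vertex units (cm^2 for cm input).
#' @examples
#' shoelace_area(cbind(c(0, 4, 0), c(0, 0, 3)))  # 6
#' @export
shoelace_area <- function(p) {
  m <- as_vertex_matrix(p)
  if (is_self_intersecting(m))
    warning("polygon self-intersects; returning absolute signed area",
            call. = FALSE)
  abs(signed_area(m))
}

signed_area <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

as_vertex_matrix <- function(p) {
  m <- unclass(p)
  m <- as.matrix(m)
  if (ncol(m) != 2) stop("expected a two-column vertex matrix", call. = FALSE)
  if (nrow(m) >= 2 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  if (nrow(m) < 3) stop("polygon needs at least 3 vertices", call. = FALSE)
  m
}

# O(n^2) proper-crossing test between non-adjacent edges; n is small (<= a
# few hundred vertices) for every contour this package produces
is_self_intersecting <- function(m) {
  n <- nrow(m)
  a <- m; b <- m[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]
    if (!length(js)) next
    if (any(segments_cross(a[i, ], b[i, ], a[js, , drop = FALSE],
                           b[js, , drop = FALSE]))) return(TRUE)
  }
  FALSE
}

segments_cross <- function(p1, p2, q1, q2) {
  q1 <- matrix(q1, ncol = 2); q2 <- matrix(q2, ncol = 2)
  d1 <- cross2(p2 - p1, t(t(q1) - p1))
  d2 <- cross2(p2 - p1, t(t(q2) - p1))
  d3 <- cross2v(q2 - q1, t(p1 - t(q1)))
  d4 <- cross2v(q2 - q1, t(p2 - t(q1)))
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

cross2 <- function(u, vmat) u[1] * vmat[, 2] - u[2] * vmat[, 1]
cross2v <- function(umat, vmat) umat[, 1] * vmat[, 2] - umat[, 2] * vmat[, 1]

#' Area ratio index (ARI)
#'
#' Ratio of the digitized (test) contour area to the reference contour area,
#' both computed with \code{\link{shoelace_area}}. A value of 1 indicates
#' perfect area conformity, but over- and under-coverage in different parts
#' of the contour can cancel; see \code{\link{cmi}} for a metric without
#' that directional tradeoff.
#'
#' @param test,reference Polygons (see \code{\link{shoelace_area}}).
#' @return The dimensionless area ratio.
#' @export
ari <- function(test, reference) {
  area_ratio(shoelace_area(test), shoelace_area(reference))
}

#' Area ratio from two pre-computed areas
#'
#' @param area_test,area_reference Areas in cm^2.
#' @return \code{area_test / area_reference}.
#' @export
area_ratio <- function(area_test, area_reference) {
  if (any(area_reference == 0))
    stop("reference area is zero", call. = FALSE)
  area_test / area_reference
}

#' Contour matching index (CMI)
#'
#' For two contours sampled at the same N angles about aligned centers,
#' \code{CMI = 1 - (1/N) * sum(|r_test,i - r_ref,i| / r_ref,i)}. CMI is 1 if
#' and only if the contours are identical at every sampled angle, and unlike
#' the ARI it cannot be inflated by compensating over- and under-coverage.
#'
#' @param test,reference \code{\link{radial_contour}} objects (or plain
#'   numeric radius vectors of equal length) sampled on the same angle grid.
#' @return A score in (-Inf, 1].
#' @export
cmi <- function(test, reference) {
  rt <- radial_radii(test); rr <- radial_radii(reference)
  if (length(rt) != length(rr))
    stop("contours are sampled at different numbers of angles", call. = FALSE)
  if (any(rr == 0))
    stop("reference radius of zero at a sampled angle", call. = FALSE)
  1 - mean(abs(rt - rr) / rr)
}

radial_radii <- function(x) {
  if (inherits(x, "oact_radial")) x$radius_cm else as.numeric(x)
}

#' Resample two polygons onto a shared radial grid for CMI
#'
#' Each polygon is translated so its area centroid sits at the origin, then
#' resampled at \code{360 / interval_deg} equally spaced angles by exact
#' ray-polygon intersection on the polygon edges (no rasterization).
#' Alignment is centroid-to-centroid translation only: no rotation or scale
#' registration, since the clinical comparison lives in a fixed
#' beam's-eye-view frame.
#'
#' @param test,reference Polygons (two-column vertex matrices).
#' @param interval_deg Angular step in degrees (default 5, i.e. N = 72).
#' @return List with \code{test} and \code{reference}
#'   \code{\link{radial_contour}} objects on the shared grid.
#' @export
align_for_cmi <- function(test, reference, interval_deg = 5) {
  angles <- radial_angle_grid(interval_deg)
  list(test = polygon_to_radial(test, angles, interval_deg),
       reference = polygon_to_radial(reference, angles, interval_deg))
}

radial_angle_grid <- function(interval_deg) {
  n <- 360 / interval_deg
  if (abs(n - round(n)) > 1e-9)
    stop("interval_deg must divide 360", call. = FALSE)
  seq(0, 360 - interval_deg, by = interval_deg)
}

polygon_to_radial <- function(p, angles_deg, interval_deg) {
  m <- as_vertex_matrix(p)
  cen <- polygon_centroid(m)
  m <- cbind(m[, 1] - cen[1], m[, 2] - cen[2])
  r <- vapply(angles_deg * pi / 180, function(th) {
    hits <- ray_polygon_hits(m, th)
    if (length(hits) == 0)
      stop(sprintf("polygon is not star-convex about its centroid: no boundary at %g degrees",
                   th * 180 / pi), call. = FALSE)
    if (diff(range(hits)) > 1e-9 * max(hits)) return(NA_real_)
    hits[1]
  }, numeric(1))
  if (anyNA(r)) {
    bad <- angles_deg[is.na(r)]
    stop(sprintf("polygon is not star-convex about its centroid at angles: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  radial_contour(angles_deg, r, center = cen, interval_deg = interval_deg)
}

# all positive ray parameters t where the ray (cos th, sin th) * t, t > 0,
# crosses the polygon boundary; coincident hits at shared vertices collapse
ray_polygon_hits <- function(m, th) {
  u <- c(cos(th), sin(th))
  n <- nrow(m)
  p <- m; q <- m[c(2:n, 1), , drop = FALSE]
  e <- q - p
  denom <- u[1] * e[, 2] - u[2] * e[, 1]
  tnum <- p[, 1] * e[, 2] - p[, 2] * e[, 1]
  snum <- p[, 1] * u[2] - p[, 2] * u[1]
  ok <- abs(denom) > 1e-300
  t <- tnum[ok] / denom[ok]
  s <- snum[ok] / denom[ok]
  # closed edge interval with roundoff slack: a ray through a shared vertex
  # registers on both adjacent edges and the duplicates collapse below
  hits <- t[s >= -1e-9 & s <= 1 + 1e-9 & t > 1e-12]
  if (length(hits) <= 1) return(hits)
  hits <- sort(hits)
  hits[c(TRUE, diff(hits) > 1e-9 * max(hits))]
}

#' Area centroid of a simple polygon
#'
#' @param p A polygon (two-column vertex matrix).
#' @return Numeric length-2 centroid.
#' @export
polygon_centroid <- function(p) {
  m <- as_vertex_matrix(p)
  x <- m[, 1]; y <- m[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-300) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Mean and population standard deviation
#'
#' Summary convention used for tabulated index values: arithmetic mean and
#' the population SD (divisor N, not N - 1).
#'
#' @param values Non-empty numeric vector.
#' @return List with elements \code{mean} and \code{sd}.
#' @export
summarize_values <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty value list", call. = FALSE)
  m <- mean(values)
  list(mean = m, sd = sqrt(mean((values - m)^2)))
}

#' Mean percentage difference between two matched series
#'
#' Computes \code{mean(100 * (a_i - b_i) / b_i)} with \code{b} the
#' comparison baseline (second-named method), plus its population SD.
#' Used e.g. to compare monitor-unit series between cutout methods.
#'
#' @param a,b Equal-length numeric vectors; \code{b} must be nonzero.
#' @return List with \code{mean} and \code{sd} of the per-pair percentage
#'   differences.
#' @export
percent_diff_series <- function(a, b) {
  if (length(a) != length(b))
    stop("series lengths differ", call. = FALSE)
  if (length(a) == 0) stop("empty series", call. = FALSE)
  if (any(b == 0)) stop("baseline series contains zero", call. = FALSE)
  summarize_values(100 * (a - b) / b)
}

#' Full agreement report between a test and a reference contour
#'
#' Computes areas, ARI, and (for star-convex contours) the CMI with
#' per-angle radial deviations on a shared angular grid.
#'
#' @param test,reference Polygons (two-column vertex matrices, cm), or paths
#'   to contour CSV files readable by \code{\link{read_contour_csv}}.
#' @param interval_deg Angular step for the CMI grid (default 5).
#' @return An object of class \code{"oact_metrics"}: list with
#'   \code{area_test}, \code{area_reference}, \code{ari}, \code{cmi},
#'   \code{n_intervals}, \code{angles_deg}, \code{deviation_cm} (absolute
#'   radial deviations), and the two aligned radial contours.
#' @examples
#' sq <- polygon_contour(c(0, 2, 2, 0), c(0, 0, 2, 2))
#' oact_compare(0.95 * unclass(sq), sq)
#' @export
oact_compare <- function(test, reference, interval_deg = 5) {
  if (is.character(test)) test <- read_contour_csv(test)$polygon
  if (is.character(reference)) reference <- read_contour_csv(reference)$polygon
  at <- shoelace_area(test)
  ar <- shoelace_area(reference)
  al <- align_for_cmi(test, reference, interval_deg)
  dev <- abs(al$test$radius_cm - al$reference$radius_cm)
  structure(list(area_test = at, area_reference = ar,
                 ari = area_ratio(at, ar),
                 cmi = cmi(al$test, al$reference),
                 n_intervals = length(dev),
                 angles_deg = al$test$angle_deg,
                 deviation_cm = dev,
                 test = al$test, reference = al$reference),
            class = "oact_metrics")
}

#' @export
print.oact_metrics <- function(x, digits = 3, ...) {
  cat("Contour agreement report\n")
  cat(sprintf("  reference area : %.*f cm^2\n", digits, x$area_reference))
  cat(sprintf("  test area      : %.*f cm^2\n", digits, x$area_test))
  cat(sprintf("  ARI            : %.*f\n", digits, x$ari))
  cat(sprintf("  CMI (N = %d)   : %.*f\n", x$n_intervals, digits, x$cmi))
  cat(sprintf("  mean |dr|      : %.*f cm (max %.*f cm)\n",
              digits, mean(x$deviation_cm), digits, max(x$deviation_cm)))
  invisible(x)
}

#' @export
plot.oact_metrics <- function(x, ...) {
  pr <- radial_to_xy(x$reference)
  pt <- radial_to_xy(x$test)
  lim <- range(pr, pt)
  graphics::plot(rbind(pr, pr[1, ]), type = "l", col = "blue", lwd = 2,
                 xlim = lim, ylim = lim, asp = 1,
                 xlab = "x (cm)", ylab = "y (cm)",
                 main = sprintf("ARI %.3f, CMI %.3f", x$ari, x$cmi), ...)
  graphics::lines(rbind(pt, pt[1, ]), col = "red", lwd = 1.5)
  graphics::segments(pr[, 1], pr[, 2], pt[, 1], pt[, 2], col = "grey50")
  graphics::legend("topright", legend = c("reference", "test"),
                   col = c("blue", "red"), lwd = c(2, 1.5), bty = "n")
  invisible(x)
}

radial_to_xy <- function(rc) {
  th <- rc$angle_deg * pi / 180
  cbind(rc$radius_cm * cos(th), rc$radius_cm * sin(th))
}
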