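# Echo-derived left-atrial indices.
#
# Atrial volumes use the single-plane method of disks (Simpson's rule): the
# traced atrial contour is cut into strips perpendicular to the
# supero-inferior long axis; each strip's chord is taken as the diameter of
# a circular disk, so a strip of chord d and thickness h contributes
# pi * (d/2)^2 * h. Emptying fraction, appendage midline length and duct
# fractional shortening are plain ratio/polyline formulas.

# Chord length of a simple polygon cut by the line {t = a} where t is the
# coordinate along unit vector u from origin A; extent measured along the
# perpendicular v, intervals paired by the even-odd rule.
polygon_chord <- function(poly, A, u, a) {
  v <- c(-u[2], u[1])
  t_ <- (poly[, 1] - A[1]) * u[1] + (poly[, 2] - A[2]) * u[2]
  s_ <- (poly[, 1] - A[1]) * v[1] + (poly[, 2] - A[2]) * v[2]
  n <- length(t_)
  nxt <- c(2:n, 1L)
  lo <- pmin(t_, t_[nxt]); hi <- pmax(t_, t_[nxt])
  cross <- which(lo <= a & a < hi)     # half-open: robust at vertices
  if (length(cross) < 2L) return(0)
  frac <- (a - t_[cross]) / (t_[nxt][cross] - t_[cross])
  sv <- sort(s_[cross] + frac * (s_[nxt][cross] - s_[cross]))
  sum(sv[seq(2, length(sv), by = 2)] - sv[seq(1, length(sv) - 1, by = 2)])
}

check_simple_polygon <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) stop("polygon needs at least 3 vertices")
  seg <- cbind(poly, poly[c(2:n, 1L), , drop = FALSE])
  ccw <- function(ax, ay, bx, by, cx, cy)
    (by - ay) * (cx - ax) - (bx - ax) * (cy - ay)
  for (i in seq_len(n - 2L)) for (j in (i + 2L):n) {
    if (i == 1L && j == n) next      # adjacent through the closure
    a <- seg[i, 1:2]; b <- seg[i, 3:4]; c_ <- seg[j, 1:2]; d <- seg[j, 3:4]
    if (ccw(a[1], a[2], b[1], b[2], c_[1], c_[2]) *
        ccw(a[1], a[2], b[1], b[2], d[1], d[2]) < 0 &&
        ccw(c_[1], c_[2], d[1], d[2], a[1], a[2]) *
        ccw(c_[1], c_[2], d[1], d[2], b[1], b[2]) < 0)
      stop("polygon is self-intersecting")
  }
  invisible(poly)
}

#' Single-plane Simpson's-rule (method of disks) volume of a traced chamber
#'
#' @param polygon two-column matrix of contour vertices in mm (closed
#'   implicitly; a repeated closing vertex is tolerated).
#' @param long_axis 2 x 2 matrix: endpoints of the long axis (rows), mm.
#'   Only the direction is used; the stack of disks spans the polygon's
#'   extent along it.
#' @param n_disks number of disks (default 20).
#' @param check validate that the polygon is simple (default `TRUE`; O(n^2)).
#' @return volume in microliters (mm^3).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 401)[-401]
#' circ <- cbind(cos(th), sin(th))
#' simpson_volume(circ, rbind(c(0, -1), c(0, 1)), n_disks = 200)  # ~ 4/3*pi
#' @export
simpson_volume <- function(polygon, long_axis, n_disks = 20L, check = TRUE) {
  poly <- as.matrix(polygon)
  if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), ]
  if (check) check_simple_polygon(poly)
  A <- as.numeric(long_axis[1, ]); B <- as.numeric(long_axis[2, ])
  L <- sqrt(sum((B - A)^2))
  if (L == 0) stop("degenerate long axis (zero length)")
  u <- (B - A) / L
  t_ <- (poly[, 1] - A[1]) * u[1] + (poly[, 2] - A[2]) * u[2]
  t0 <- min(t_); t1 <- max(t_)
  h <- (t1 - t0) / n_disks
  stations <- t0 + (seq_len(n_disks) - 0.5) * h
  d <- vapply(stations, function(a) polygon_chord(poly, A, u, a), numeric(1))
  sum(pi * (d / 2)^2 * h)
}

#' Left-atrial emptying fraction
#' @param vmin,vmax minimum and maximum atrial volumes (same units).
#' @return `100 * (vmax - vmin) / vmax`, percent.
#' @export
la_ef <- function(vmin, vmax) {
  if (any(vmax <= 0)) stop("vmax must be positive")
  if (any(vmin > vmax)) stop("vmin exceeds vmax")
  100 * (vmax - vmin) / vmax
}

#' Appendage duct fractional shortening
#' @param d_max,d_min maximum and minimum duct diameters (mm).
#' @return `100 * (d_max - d_min) / d_max`, percent.
#' @export
laa_duct_fs <- function(d_max, d_min) {
  if (any(d_max <= 0)) stop("d_max must be positive")
  if (any(d_min > d_max)) stop("d_min exceeds d_max")
  100 * (d_max - d_min) / d_max
}

#' Length of the appendage midline polyline
#' @param midline two-column matrix of vertices (mm), >= 2 rows.
#' @return total polyline length in mm.
#' @export
laa_length <- function(midline) {
  m <- as.matrix(midline)
  if (nrow(m) < 2L) stop("midline needs at least 2 vertices")
  sum(sqrt(rowSums(diff(m)^2)))
}

#' All atrial indices from one subject's traces
#'
#' @param trace list with `la_polygon_min`, `la_polygon_max` (contours, mm),
#'   `long_axis` (2 x 2 endpoints), `laa_midline` (polyline), `duct_d_min`,
#'   `duct_d_max` (mm).
#' @param n_disks disks for [simpson_volume()].
#' @return data frame row: `la_vmin_ul`, `la_vmax_ul`, `la_ef_pct`,
#'   `laa_length_mm`, `laa_duct_fs_pct`.
#' @export
atrial_indices <- function(trace, n_disks = 20L) {
  vmin <- simpson_volume(trace$la_polygon_min, trace$long_axis, n_disks)
  vmax <- simpson_volume(trace$la_polygon_max, trace$long_axis, n_disks)
  data.frame(la_vmin_ul = vmin, la_vmax_ul = vmax,
             la_ef_pct = la_ef(min(vmin, vmax), max(vmin, vmax)),
             laa_length_mm = laa_length(trace$laa_midline),
             laa_duct_fs_pct = laa_duct_fs(trace$duct_d_max,
                                           trace$duct_d_min))
}
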