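# Internal helpers shared across modules.

#' Evaluate an expression with a temporarily fixed RNG seed
#'
#' Saves and restores the global `.Random.seed`, so generator calls are
#' reproducible without disturbing the caller's RNG stream.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}

#' Cubic spline interpolation with not-a-knot or natural end conditions
#'
#' Interpolating cubic spline through `(x, y)` evaluated at `xout`.
#' `"notaknot"` makes the third derivative continuous across the second and
#' penultimate knots (exact on polynomials of degree <= 3); `"natural"` sets
#' the second derivative to zero at both ends.
#'
#' @param x,y knots; `x` strictly increasing, length >= 2.
#' @param xout evaluation points.
#' @param method `"notaknot"` (default) or `"natural"`.
#' @return numeric vector of interpolated values at `xout`.
#' @examples
#' cubic_spline(0:5, (0:5)^3, xout = 2.5)   # exactly 15.625
#' @export
cubic_spline <- function(x, y, xout, method = c("notaknot", "natural")) {
  method <- match.arg(method)
  n <- length(x)
  stopifnot(length(y) == n, n >= 2L, all(diff(x) > 0))
  if (n == 2L) return(stats::approx(x, y, xout = xout, rule = 2)$y)
  if (n == 3L && method == "notaknot") {
    # single interior knot: not-a-knot degenerates to the parabola through
    # the three points
    co <- solve(cbind(1, x, x^2), y)
    return(co[1] + co[2] * xout + co[3] * xout^2)
  }
  h <- diff(x)
  dy <- diff(y) / h
  # unknowns: second derivatives M_i at the knots
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1] / 6
    A[i, i]     <- (h[i - 1] + h[i]) / 3
    A[i, i + 1] <- h[i] / 6
    b[i] <- dy[i] - dy[i - 1]
  }
  if (method == "natural") {
    A[1, 1] <- 1
    A[n, n] <- 1
  } else {
    # third-derivative continuity at x_2 and x_{n-1}
    A[1, 1:3] <- c(h[2], -(h[1] + h[2]), h[1])
    A[n, (n - 2):n] <- c(h[n - 1], -(h[n - 2] + h[n - 1]), h[n - 2])
  }
  M <- solve(A, b)
  idx <- pmin(pmax(findInterval(xout, x), 1L), n - 1L)
  x0 <- x[idx]; x1 <- x[idx + 1L]
  hi <- h[idx]
  t0 <- (x1 - xout) / hi; t1 <- (xout - x0) / hi
  M[idx] * (t0^3 - t0) * hi^2 / 6 + M[idx + 1L] * (t1^3 - t1) * hi^2 / 6 +
    y[idx] * t0 + y[idx + 1L] * t1
}

#' Rasterize a closed polygon onto a pixel grid
#'
#' Scanline fill with the even-odd rule sampled at 0-based pixel centers;
#' vertical spans and horizontal fills are half-open so that abutting
#' polygons tile without double-counting and an axis-aligned w x h rectangle
#' covers exactly w*h pixels.
#'
#' @param xy two-column matrix of vertices (pixel units, 0-based centers).
#' @param nx,ny grid dimensions in pixels.
#' @return logical matrix `nx` x `ny` (x = row index - 1, y = col index - 1).
#' @keywords internal
rasterize_polygon <- function(xy, nx, ny) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2L, nrow(xy) >= 3L)
  # drop duplicated closing vertex if present
  if (all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
  m <- matrix(FALSE, nx, ny)
  vx <- xy[, 1]; vy <- xy[, 2]
  nxv <- length(vx)
  j <- c(2:nxv, 1L)
  for (row in 0:(ny - 1L)) {
    # edges crossing the scanline y = row (half-open in y)
    lo <- pmin(vy, vy[j]); hi <- pmax(vy, vy[j])
    cross <- which(lo <= row & row < hi)
    if (!length(cross)) next
    xc <- vx[cross] + (row - vy[cross]) * (vx[j][cross] - vx[cross]) /
      (vy[j][cross] - vy[cross])
    xc <- sort(xc)
    for (k in seq(1L, length(xc) - 1L, by = 2L)) {
      xs <- ceiling(xc[k])
      xe <- ceiling(xc[k + 1L]) - 1L  # half-open [xc_k, xc_{k+1})
      xs <- max(xs, 0L); xe <- min(xe, nx - 1L)
      if (xs <= xe) m[(xs:xe) + 1L, row + 1L] <- TRUE
    }
  }
  m
}

#' Polar angle of image points under the sector convention
#'
#' Angle in degrees in `[0, 360)`: 0 at image "up" (-y), increasing clockwise
#' in image coordinates (x right, y down).
#'
#' @param dx,dy offsets from the rotation center.
#' @keywords internal
image_angle_deg <- function(dx, dy) {
  (atan2(dx, -dy) * 180 / pi) %% 360
}
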