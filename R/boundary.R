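#' Generate a star-convex nuclear boundary polygon
#'
#' Builds a closed, counter-clockwise polygon with radial profile
#' `r(theta) = radius_px * (1 + roughness * z(theta))`, where `z` is a
#' zero-mean sum of random Fourier harmonics rescaled so `max(abs(z)) = 1`.
#' The radial deviation from the base circle is therefore bounded by
#' `roughness * radius_px` exactly, and the polygon stays star-convex about
#' the origin for any `roughness < 1`.
#'
#' @param radius_px base radius in pixels, >= 3.
#' @param roughness fractional perturbation amplitude, >= 0.
#' @param n_harmonics number of Fourier harmonics (wavenumbers 2..n+1); the
#'   k = 0, 1 terms are excluded so the perturbation neither rescales nor
#'   translates the nucleus.
#' @param n_vertices number of polygon vertices; default scales with the
#'   circumference so the chord length stays below one pixel.
#' @param seed optional RNG seed for the harmonic coefficients.
#' @return a `n x 2` matrix of (x, y) vertices, counter-clockwise, centred
#'   on the origin, with attribute `radial_fun` (the radius at each theta).
#' @examples
#' b <- make_boundary(10, 0.2, seed = 1)
#' range(sqrt(rowSums(b^2)))
#' @export
make_boundary <- function(radius_px, roughness, n_harmonics = 8,
                          n_vertices = NULL, seed = NULL) {
  stopifnot_finite(radius_px, "radius_px")
  stopifnot_finite(roughness, "roughness")
  if (radius_px < 3) stop("radius_px must be >= 3", call. = FALSE)
  if (roughness < 0) stop("roughness must be >= 0", call. = FALSE)
  if (is.null(n_vertices)) {
    n_vertices <- max(64L, ceiling(4 * pi * radius_px))
  }
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  z <- rep(0, n_vertices)
  if (roughness > 0 && n_harmonics > 0) {
    co <- with_seed(seed, {
      k <- 2:(n_harmonics + 1L)
      # 1/k amplitude decay: large-scale lobes dominate, fine wiggles persist
      list(k = k, a = stats::rnorm(length(k)) / k, b = stats::rnorm(length(k)) / k)
    })
    for (i in seq_along(co$k)) {
      z <- z + co$a[i] * cos(co$k[i] * theta) + co$b[i] * sin(co$k[i] * theta)
    }
    m <- max(abs(z))
    if (m > 0) z <- z / m
  }
  r <- radius_px * (1 + roughness * z)
  poly <- cbind(x = r * cos(theta), y = r * sin(theta))
  attr(poly, "radial") <- r
  attr(poly, "theta") <- theta
  poly
}

# Shoelace signed area of a closed polygon (positive = counter-clockwise).
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Total edge length of a closed polygon.
polygon_perimeter <- function(poly) {
  d <- diff(rbind(poly, poly[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

# Rasterize a star-convex boundary centred at (cx, cy) onto pixel centres:
# a pixel belongs to the nucleus iff its distance from the centre is at most
# the (circularly interpolated) boundary radius at its polar angle.
rasterize_boundary <- function(poly, cx, cy, nrow_img, ncol_img) {
  r <- attr(poly, "radial")
  th <- attr(poly, "theta")
  rmax <- max(r)
  r0 <- max(1L, floor(cy - rmax)); r1 <- min(nrow_img, ceiling(cy + rmax))
  c0 <- max(1L, floor(cx - rmax)); c1 <- min(ncol_img, ceiling(cx + rmax))
  rows <- r0:r1; cols <- c0:c1
  dy <- rep(rows - cy, times = length(cols))
  dx <- rep(cols - cx, each = length(rows))
  ang <- atan2(dy, dx) %% (2 * pi)
  # periodic linear interpolation of the radial profile
  rad <- stats::approx(c(th, 2 * pi), c(r, r[1]), xout = ang, rule = 2)$y
  inside <- (dx * dx + dy * dy) <= rad * rad
  list(rows = rows, cols = cols,
       mask = matrix(inside, nrow = length(rows), ncol = length(cols)))
}
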