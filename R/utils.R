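#' Round half away from zero
#'
#' Fixed-point rounding with ties going up (0.5 -> 1), unlike [base::round()]
#' which rounds half to even. Used everywhere a reported quantity is rounded
#' (volume ratios, segregation percentages).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Derive a child seed from a master seed
#'
#' All stochastic generators take a single integer seed; multi-part
#' simulations derive per-part seeds with this splitter so that every source
#' of randomness flows from one master seed.
#'
#' @param seed master seed (integer).
#' @param i child index (integer >= 0).
#' @return an integer seed in [1, 2^31 - 2].
#' @export
childSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 2654435) %% 2147483646 + 1)
}

# pixel-centre coordinate grids for an image of dim = c(nrow, ncol);
# x runs along columns, y along rows, both in pixel units (centre of pixel
# [1,1] is at (0.5, 0.5)); row-major raster convention
.pixelGrid <- function(dim) {
  nr <- dim[1]; nc <- dim[2]
  list(
    x = matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc),
    y = matrix(rep(seq_len(nr) - 0.5, times = nc), nr, nc)
  )
}

# logical mask of an ellipse (centre cx,cy; semi-axes a,b; rotation theta)
.ellipseMask <- function(dim, cx, cy, a, b, theta = 0) {
  g <- .pixelGrid(dim)
  u <- (g$x - cx) * cos(theta) + (g$y - cy) * sin(theta)
  v <- -(g$x - cx) * sin(theta) + (g$y - cy) * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# normalized anteroposterior coordinate in [0, 1] for every pixel:
# projection onto the AP axis, 0 = anterior pole, 1 = posterior pole
.apCoordinate <- function(dim, cx, cy, a, theta = 0) {
  g <- .pixelGrid(dim)
  s <- (g$x - cx) * cos(theta) + (g$y - cy) * sin(theta)
  (s + a) / (2 * a)
}

.assertScalarNum <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (strict && x <= min) stop(sprintf("'%s' must be > %g", name, min), call. = FALSE)
  if (!strict && x < min) stop(sprintf("'%s' must be >= %g", name, min), call. = FALSE)
  invisible(x)
}
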