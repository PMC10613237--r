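#' Lateral sampling grid for fields and matrices
#'
#' A `field_grid` fixes the coordinate contract every field and matrix in the
#' package shares: an `n` x `n` lattice with pixel pitch `pitch` (micrometres),
#' centred physical coordinates (0 at the grid centre), an optical wavelength
#' and the numerical aperture of the collection/illumination cone. The derived
#' quantities `k0 = 2*pi/wavelength` and the field-of-view side `L0 = n*pitch`
#' are exposed as list elements.
#'
#' The pitch must satisfy the half-wavelength sampling bound
#' `pitch <= wavelength/2`, so that the full `NA = 1` angular passband is
#' represented without aliasing.
#'
#' @param n integer, points per side (>= 2).
#' @param pitch pixel pitch in micrometres.
#' @param wavelength wavelength in micrometres.
#' @param na numerical aperture, in (0, 1].
#' @return An object of class `field_grid`: a list with elements `n`, `pitch`,
#'   `wavelength`, `na`, `k0`, `extent` (= `L0`), `x` (centred coordinates),
#'   and precomputed spatial-frequency machinery (`kx`, fft-ordered; `pupil`,
#'   logical passband mask).
#' @examples
#' g <- make_grid(64, 0.45, 0.9, 1.0)
#' g$extent  # 28.8 um
#' @export
make_grid <- function(n, pitch, wavelength, na = 1.0) {
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n))
    stop("make_grid: 'n' must be a single integer >= 2")
  if (!is.numeric(pitch) || length(pitch) != 1 || pitch <= 0)
    stop("make_grid: 'pitch' must be a positive length")
  if (!is.numeric(wavelength) || length(wavelength) != 1 || wavelength <= 0)
    stop("make_grid: 'wavelength' must be a positive length")
  if (!is.numeric(na) || length(na) != 1 || na <= 0 || na > 1)
    stop("make_grid: 'na' must lie in (0, 1]")
  if (pitch > wavelength / 2 + 1e-12)
    stop("make_grid: 'pitch' must not exceed wavelength/2 (half-wavelength sampling)")
  n <- as.integer(n)
  k0 <- 2 * pi / wavelength
  # centred coordinates: index i (1-based) -> (i - 1 - n/2) * pitch; for even n
  # the origin sits at index n/2 + 1
  x <- (seq_len(n) - 1 - floor(n / 2)) * pitch
  # fft-ordered spatial frequencies (rad / um)
  f <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1) / (n * pitch)
  kx <- 2 * pi * f
  kr2 <- outer(kx^2, kx^2, `+`)
  kcut <- min(na, 1) * k0
  pupil <- kr2 <= kcut^2 + 1e-12
  structure(list(
    n = n, pitch = pitch, wavelength = wavelength, na = na,
    k0 = k0, extent = n * pitch, x = x, kx = kx, kr2 = kr2, pupil = pupil
  ), class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf(
    "<field_grid> %d x %d, pitch %.4g um (L0 = %.4g um), lambda %.4g um, NA %.3g\n",
    x$n, x$n, x$pitch, x$extent, x$wavelength, x$na))
  invisible(x)
}

is_field_grid <- function(x) inherits(x, "field_grid")

same_grid <- function(a, b) {
  is_field_grid(a) && is_field_grid(b) && a$n == b$n &&
    isTRUE(all.equal(a$pitch, b$pitch)) &&
    isTRUE(all.equal(a$wavelength, b$wavelength)) &&
    isTRUE(all.equal(a$na, b$na))
}

#' Complex scalar field on a grid
#'
#' Wraps an `n` x `n` complex matrix together with its [make_grid()] grid.
#'
#' @param grid a `field_grid`.
#' @param values an `n` x `n` numeric or complex matrix; finite values only.
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(grid, values) {
  stopifnot(is_field_grid(grid))
  values <- as_complex_matrix(values)
  if (!all(dim(values) == c(grid$n, grid$n)))
    stop("complex_field: 'values' must be ", grid$n, " x ", grid$n)
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values))))
    stop("complex_field: non-finite values")
  structure(list(grid = grid, values = values), class = "complex_field")
}

as_complex_matrix <- function(v) {
  if (!is.matrix(v)) stop("expected a matrix")
  if (!is.complex(v)) storage.mode(v) <- "complex"
  v
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %d x %d on L0 = %.4g um; energy %.4g\n",
              x$grid$n, x$grid$n, x$grid$extent, field_energy(x)))
  invisible(x)
}

#' Total energy (squared 2-norm) of a field
#' @param field a `complex_field`.
#' @return numeric scalar `sum(|E|^2)`.
#' @export
field_energy <- function(field) {
  sum(Mod(field$values)^2)
}

# --- internal FFT helpers (unshifted order, unitary scaling) ----------------

fft2 <- function(m) stats::fft(m) / sqrt(length(m))
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / sqrt(length(m))

fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((floor(n1 / 2) + 1):n1, 1:floor(n1 / 2)),
    c((floor(n2 / 2) + 1):n2, 1:floor(n2 / 2))]
}

ifftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((n1 - floor(n1 / 2) + 1):n1, 1:(n1 - floor(n1 / 2))),
    c((n2 - floor(n2 / 2) + 1):n2, 1:(n2 - floor(n2 / 2)))]
}

# index (1-based) of the physical origin pixel
grid_origin_index <- function(grid) floor(grid$n / 2) + 1L

# linear (vectorised, column-major) index of a lateral position given in um,
# snapped to the nearest lattice point
grid_linear_index <- function(grid, pos) {
  i <- round(pos[1] / grid$pitch) + grid_origin_index(grid)
  j <- round(pos[2] / grid$pitch) + grid_origin_index(grid)
  if (i < 1 || i > grid$n || j < 1 || j > grid$n)
    stop("position off grid")
  (j - 1L) * grid$n + i
}
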