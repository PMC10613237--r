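#' @useDynLib mstrace, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Free-space angular-spectrum transfer function over axial distance `dist`
# (um), unshifted FFT order.  kz = sqrt(k0^2 - k_par^2) on the propagating
# band; non-propagating (evanescent / corner) modes acquire zero phase
# advance, so the transfer is unit-modulus everywhere and the operator is
# exactly unitary, symmetric and invertible — the property the structural
# inversion of the forward model relies on.  The NA pupil is a property of
# the measurement (grid$pupil), not of free space, and is applied separately
# where a physical aperture acts.
prop_transfer <- function(grid, dist) {
  kz <- sqrt(pmax(grid$k0^2 - grid$kr2, 0))
  exp(1i * kz * dist)
}

# Project a field (or fft-ordered spectrum) onto the propagating passband.
passband_project <- function(grid, values) {
  sp <- fft2(values)
  sp[!grid$pupil] <- 0
  ifft2(sp)
}

#' Angular-spectrum free-space propagation
#'
#' Advances a monochromatic scalar field by a distance `distance` along the
#' optical axis using the exact angular-spectrum transfer function
#' `exp(i k_z d)` with `k_z = sqrt(k0^2 - k_par^2)` on the propagating band.
#' Non-propagating (evanescent) components acquire zero phase advance, so the
#' transfer is unit-modulus everywhere: the operator is exactly unitary,
#' reciprocal and invertible, and `propagate(d)` followed by `propagate(-d)`
#' restores any field to numerical precision. The objective's circular pupil
#' `|k_par| <= NA*k0` (`grid$pupil`) is a property of the measurement, applied
#' separately where an aperture physically acts, never inside free space.
#'
#' With `pad = TRUE` the field is embedded in a grid enlarged by a factor
#' `pad_factor` before transforming and cropped afterwards, which suppresses
#' periodic wrap-around for strongly spreading fields at the cost of exact
#' passband unitarity (energy genuinely leaves the region of interest). The
#' periodic (`pad = FALSE`) operator is the package's canonical, exactly
#' unitary and reciprocal representation used by the matrix pipeline.
#'
#' @param field a [complex_field()].
#' @param distance propagation distance in micrometres (signed).
#' @param pad logical; zero-pad to control wrap-around (default `FALSE`).
#' @param pad_factor integer enlargement factor when `pad = TRUE`.
#' @return a `complex_field` at the new plane.
#' @export
angular_spectrum_propagate <- function(field, distance, pad = FALSE,
                                       pad_factor = 2L) {
  stopifnot(inherits(field, "complex_field"))
  if (!is.numeric(distance) || length(distance) != 1 || !is.finite(distance))
    stop("angular_spectrum_propagate: 'distance' must be a finite number")
  v <- field$values
  if (!all(is.finite(Re(v))) || !all(is.finite(Im(v))))
    stop("angular_spectrum_propagate: non-finite field values")
  g <- field$grid
  if (!pad) {
    out <- ifft2(fft2(v) * prop_transfer(g, distance))
    return(complex_field(g, out))
  }
  np <- as.integer(pad_factor) * g$n
  big <- make_grid(np, g$pitch, g$wavelength, g$na)
  vb <- matrix(0 + 0i, np, np)
  o <- (np - g$n) %/% 2
  vb[o + seq_len(g$n), o + seq_len(g$n)] <- v
  ob <- ifft2(fft2(vb) * prop_transfer(big, distance))
  complex_field(g, ob[o + seq_len(g$n), o + seq_len(g$n)])
}

#' Dense free-space propagation operator
#'
#' Builds the `n^2` x `n^2` dense matrix whose action on a vectorised field
#' equals [angular_spectrum_propagate()] over the (signed) distance
#' `z_to - z_from`. On the periodic grid the operator is circulant, so it is
#' assembled from one propagated point response by lateral shifts; in the
#' space basis it equals its own transpose (reciprocity of free-space
#' propagation).
#'
#' @param grid a `field_grid`.
#' @param z_from,z_to axial coordinates (um) of the input and output planes.
#' @return a list of class `propagation_operator` with elements `values`
#'   (dense complex matrix), `grid`, `z_from`, `z_to`.
#' @export
propagation_matrix <- function(grid, z_from, z_to) {
  stopifnot(is_field_grid(grid))
  # the transfer phase advances by the path length travelled, regardless of
  # direction along z
  dist <- abs(z_to - z_from)
  g0 <- propagated_delta(grid, dist)
  structure(list(values = circulant_from_kernel(grid, g0),
                 grid = grid, z_from = z_from, z_to = z_to),
            class = "propagation_operator")
}

# band-limited point response: delta at the origin pixel, propagated `dist`
propagated_delta <- function(grid, dist) {
  n <- grid$n
  v <- matrix(0 + 0i, n, n)
  v[grid_origin_index(grid), grid_origin_index(grid)] <- 1 + 0i
  ifft2(fft2(v) * prop_transfer(grid, dist))
}

# dense circulant operator whose column j is the kernel field circularly
# shifted to be centred on lattice point j
circulant_from_kernel <- function(grid, kernel) {
  n <- grid$n
  o <- grid_origin_index(grid)
  sh <- outer(0:(n - 1), 0:(n - 1), function(a, b) (a - b) %% n)
  # column index j = (j2-1)*n + j1 corresponds to lattice point (j1, j2);
  # kernel is centred at (o, o): entry (i, j) = kernel[(i1-j1+o) mod, (i2-j2+o) mod]
  d1 <- outer(seq_len(n) - 1L, seq_len(n) - 1L,
              function(a, b) ((a - b + o - 1L) %% n) + 1L)
  idx <- kronecker((d1 - 1L) * n, matrix(1L, n, n)) +
    kronecker(matrix(1L, n, n), d1)
  matrix(kernel[idx], n * n, n * n)
}

#' Band-limited free-space Green's function reference
#'
#' The spherical-wave reference field used to normalise reflection-matrix
#' columns: a unit point source at lateral position `source_point` propagated
#' over the axial separation `dz` with the same band limit and pupil as all
#' other propagation in the package, so that dividing an unscattered
#' point-source column by this reference leaves a flat phase.
#'
#' @param grid a `field_grid`.
#' @param source_point lateral position `c(x, y)` in um (snapped to lattice).
#' @param dz axial separation in um; must be non-zero.
#' @return a `complex_field`.
#' @export
greens_reference <- function(grid, source_point = c(0, 0), dz) {
  stopifnot(is_field_grid(grid))
  if (dz == 0) stop("greens_reference: 'dz' must be non-zero (normalization undefined)")
  n <- grid$n
  v <- matrix(0 + 0i, n, n)
  v[grid_linear_index(grid, source_point)] <- 1 + 0i
  complex_field(grid, ifft2(fft2(v) * prop_transfer(grid, abs(dz))))
}

# --- batch application of frequency-diagonal operators to dense matrices ----

# Apply transfer H (n x n, fft order) to every column-field of matrix M.
apply_spectral_cols <- function(M, grid, H) {
  col_spectral_apply(M, H, grid$n)
}

# Apply to the column (input) index: right-multiplication by the symmetric
# circulant operator equals applying it to every row-field.
apply_spectral_rows <- function(M, grid, H) {
  t(col_spectral_apply(t(M), H, grid$n))
}
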