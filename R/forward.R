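# Multi-slice forward model: transmission/reflection matrices of a plate
# stack over a reflective object, and scan-frame matrix assembly.

# Apply the medium operator (surface z_N -> object z_0) to every column-field
# of M.  `phases` optionally overrides/offsets the plate phases (list of n x n
# maps, one per plate, subtracted when `negate = TRUE`, used alone when
# `use_only = TRUE`).
stack_apply_cols <- function(M, medium, correction = NULL) {
  g <- medium$grid
  plates <- medium$plates
  N <- length(plates)
  z <- c(0, medium$depths)               # z_0, z_1, ..., z_N
  if (N == 0) return(M)
  for (k in N:1) {
    ph <- plates[[k]]$phase
    if (!is.null(correction)) ph <- ph - correction[[k]]
    M <- row_mult_field(M, exp(1i * ph), g)
    M <- apply_spectral_cols(M, g, prop_transfer(g, z[k + 1] - z[k]))
  }
  M
}

# Apply the structural inverse of the stack (object z_0 -> surface z_N):
# reversed product of conjugated factors.
stack_apply_cols_inverse <- function(M, medium, correction = NULL) {
  g <- medium$grid
  plates <- medium$plates
  N <- length(plates)
  z <- c(0, medium$depths)
  if (N == 0) return(M)
  for (k in 1:N) {
    M <- apply_spectral_cols(M, g, Conj(prop_transfer(g, z[k + 1] - z[k])))
    ph <- plates[[k]]$phase
    if (!is.null(correction)) ph <- ph - correction[[k]]
    M <- row_mult_field(M, exp(-1i * ph), g)
  }
  M
}

# multiply every column-field elementwise by the n x n map `f`
row_mult_field <- function(M, f, grid) {
  row_scale(M, as.vector(f))
}

#' Transmission matrix of a single layer
#'
#' The operator `T_k = P * Phi_k`: the diagonal unit-modulus phase factor
#' `exp(i phi_k)` of the plate followed by free-space propagation to the
#' adjacent plane described by `propagation`.
#'
#' @param plate a [random_phase_plate()] (or any `phase_plate`).
#' @param propagation a [propagation_matrix()] operator on the same grid.
#' @return a [transmission_matrix()] from the plate plane to the operator's
#'   output plane.
#' @export
layer_transmission <- function(plate, propagation) {
  stopifnot(inherits(plate, "phase_plate"),
            inherits(propagation, "propagation_operator"))
  g <- propagation$grid
  if (!all(dim(plate$phase) == c(g$n, g$n)))
    stop("layer_transmission: plate and propagation grids differ")
  vals <- col_scale(propagation$values, exp(1i * as.vector(plate$phase)))
  transmission_matrix(vals, g, input_plane = plate$depth,
                      output_plane = propagation$z_to)
}

#' Transmission matrix of a plate stack
#'
#' Dense one-way operator `T = T_1 T_2 ... T_N` from the medium surface
#' (plane of the deepest plate, `z_N`) to the object plane `z_0 = 0`,
#' including the final free-space propagation to the object plane. An empty
#' medium yields pure propagation over the total distance (the identity at
#' distance 0).
#'
#' @param medium a [medium_model()].
#' @return a [transmission_matrix()] with `provenance = "ground_truth"`.
#' @export
medium_transmission <- function(medium) {
  stopifnot(inherits(medium, "medium_model"))
  g <- medium$grid
  d <- g$n^2
  M <- diag(1 + 0i, d)
  M <- stack_apply_cols(M, medium)
  transmission_matrix(M, g, input_plane = medium$surface_z, output_plane = 0)
}

#' Reflection matrix of a medium + object
#'
#' Builds the roundtrip operator `R = T^T O T` of the multi-slice forward
#' model, with `O` the diagonal amplitude-reflectance of the object at the
#' object plane. With `reference_plane = "z0"` both indices are referenced to
#' the object plane (virtual illumination/detection foci at `z_0`, the form a
#' scanned time-gated measurement delivers); with `"zN"` they stay at the
#' medium surface. The result is symmetric (`R = t(R)`) by reciprocity.
#'
#' With `aperture = "none"` the matrix is the bare model `T^T O T`, for
#' which structural correction with the ground-truth stack is an exact
#' inverse. With `aperture = "pupil"` the objective's circular passband is
#' applied to the illumination and detection sides (`Pi R Pi`), emulating
#' what a finite-NA measurement actually records; non-propagating content
#' of a focused probe — which free space leaves in place — is then removed
#' the way a physical objective removes it.
#'
#' @param medium a [medium_model()].
#' @param object an [make_target_object()] map on the same grid.
#' @param reference_plane `"z0"` (default) or `"zN"`.
#' @param aperture `"none"` (bare model) or `"pupil"` (measurement
#'   emulation).
#' @return a [reflection_matrix()].
#' @export
reflection_from_medium <- function(medium, object,
                                   reference_plane = c("z0", "zN"),
                                   aperture = c("none", "pupil")) {
  stopifnot(inherits(medium, "medium_model"), inherits(object, "object_map"))
  reference_plane <- match.arg(reference_plane)
  aperture <- match.arg(aperture)
  g <- medium$grid
  if (!same_grid(g, object$grid))
    stop("reflection_from_medium: medium and object grids differ")
  d <- g$n^2
  A <- diag(1 + 0i, d)
  if (reference_plane == "z0" && medium$surface_z > 0) {
    # virtual focus at the object plane: back-propagate to the surface first
    A <- apply_spectral_cols(A, g, Conj(prop_transfer(g, medium$surface_z)))
  }
  A <- stack_apply_cols(A, medium)
  o <- as.vector(object$reflectance)
  Rv <- crossprod(A, o * A)   # t(A) %*% diag(o) %*% A, no conjugation
  plane <- if (reference_plane == "z0") 0 else medium$surface_z
  R <- reflection_matrix(Rv, g, input_plane = plane, output_plane = plane)
  if (aperture == "pupil") apply_aperture(R) else R
}

#' Apply the objective's pupil to both sides of a matrix
#'
#' Projects the illumination (column) and detection (row) indices of a
#' space-basis matrix onto the circular passband `|k_par| <= NA*k0`,
#' emulating the angular coverage of the objective.
#'
#' @param R a [reflection_matrix()] (space basis).
#' @return the band-limited `reflection_matrix`.
#' @export
apply_aperture <- function(R) {
  stopifnot(inherits(R, "reflection_matrix"))
  if (R$basis != "space") stop("apply_aperture: R must be in the space basis")
  g <- R$grid
  H <- matrix(as.numeric(g$pupil) + 0i, g$n, g$n)
  R$values <- apply_spectral_rows(apply_spectral_cols(R$values, g, H), g, H)
  R
}

#' Object-uncorrelated background scattering
#'
#' Adds a seeded random clutter matrix emulating multiple scattering that
#' never interacts with the object: complex Gaussian noise correlated over
#' `correlation_length` along both field indices, symmetrised for
#' reciprocity, and scaled so its total power is `relative_power` times the
#' power of `R`.
#'
#' @param R a [reflection_matrix()].
#' @param relative_power clutter-to-signal total power ratio (>= 0).
#' @param correlation_length lateral correlation length in um.
#' @param seed integer seed.
#' @return a `reflection_matrix` with clutter added.
#' @export
add_background_scattering <- function(R, relative_power, correlation_length,
                                      seed) {
  stopifnot(inherits(R, "reflection_matrix"))
  if (relative_power < 0)
    stop("add_background_scattering: 'relative_power' must be >= 0")
  if (relative_power == 0) return(R)
  g <- R$grid
  d <- g$n^2
  C <- with_seed(seed, matrix(complex(real = stats::rnorm(d * d),
                                      imaginary = stats::rnorm(d * d)), d, d))
  filt <- exp(-(g$kr2) * correlation_length^2 / 8)
  filt[!g$pupil] <- 0
  C <- apply_spectral_cols(C, g, filt)
  C <- apply_spectral_rows(C, g, filt)
  C <- (C + t(C)) / 2
  C <- C * sqrt(relative_power * sum(Mod(R$values)^2) / sum(Mod(C)^2))
  R$values <- R$values + C
  R
}

#' Scan stack of complex field images
#'
#' Container for per-scan-position 2D complex field images (descanned frame)
#' with their scan positions on the grid lattice; the raw material a scanned
#' reflection-matrix measurement delivers.
#'
#' @param grid a `field_grid`.
#' @param fields `n^2`-column matrix whose column `j` is the vectorised field
#'   image for scan position `j`, or an `n` x `n` x `n^2` array.
#' @param positions `n^2` x 2 matrix of scan positions in um on the pitch
#'   lattice, covering the region of interest exactly once.
#' @return object of class `scan_stack`.
#' @export
scan_stack <- function(grid, fields, positions) {
  stopifnot(is_field_grid(grid))
  d <- grid$n^2
  if (is.array(fields) && length(dim(fields)) == 3) {
    stopifnot(all(dim(fields) == c(grid$n, grid$n, d)))
    dim(fields) <- c(d, d)
  }
  fields <- as_complex_matrix(fields)
  if (!all(dim(fields) == c(d, d)))
    stop("scan_stack: need ", d, " field images of ", d, " pixels")
  positions <- as.matrix(positions)
  if (!all(dim(positions) == c(d, 2)))
    stop("scan_stack: need ", d, " scan positions")
  ij <- positions / grid$pitch
  if (max(abs(ij - round(ij))) > 1e-6)
    stop("scan_stack: positions are off the pitch lattice")
  key <- paste(round(ij[, 1]), round(ij[, 2]))
  if (anyDuplicated(key))
    stop("scan_stack: scan positions must cover the ROI exactly once")
  structure(list(grid = grid, fields = fields, positions = positions),
            class = "scan_stack")
}

# canonical raster scan positions (column-major over the centred lattice)
raster_positions <- function(grid) {
  x <- grid$x
  cbind(rep(x, times = grid$n), rep(x, each = grid$n))
}

#' Assemble a reflection matrix from a scan stack
#'
#' Shifts every descanned field image into the laboratory frame by its scan
#' position (circular shift on the periodic lattice), vectorises it and
#' places it as the column of the reflection matrix corresponding to that
#' input position, reproducing the scanned-measurement construction.
#'
#' @param stack a [scan_stack()].
#' @return a [reflection_matrix()] at the object plane.
#' @export
assemble_from_scan <- function(stack) {
  stopifnot(inherits(stack, "scan_stack"))
  g <- stack$grid
  n <- g$n
  d <- n^2
  Rv <- matrix(0 + 0i, d, d)
  for (j in seq_len(d)) {
    si <- as.integer(round(stack$positions[j, ] / g$pitch))
    f <- matrix(stack$fields[, j], n, n)
    f <- circshift2(f, si[1], si[2])
    col <- grid_linear_index(g, stack$positions[j, ])
    Rv[, col] <- as.vector(f)
  }
  reflection_matrix(Rv, g, input_plane = 0, output_plane = 0)
}

#' Synthesize a scan stack from a reflection matrix
#'
#' Inverse of [assemble_from_scan()]: produces the descanned per-position
#' field images a scanned measurement of `R` would record, in canonical
#' raster order. `assemble_from_scan(synthesize_scan(R))` reproduces `R`
#' exactly.
#'
#' @param R a [reflection_matrix()] at the object plane, space basis.
#' @return a [scan_stack()].
#' @export
synthesize_scan <- function(R) {
  stopifnot(inherits(R, "reflection_matrix"))
  if (R$basis != "space" || R$input_plane != 0 || R$output_plane != 0)
    stop("synthesize_scan: R must be at the object plane in the space basis")
  g <- R$grid
  n <- g$n
  d <- n^2
  pos <- raster_positions(g)
  F <- matrix(0 + 0i, d, d)
  for (j in seq_len(d)) {
    col <- grid_linear_index(g, pos[j, ])
    f <- matrix(R$values[, col], n, n)
    si <- as.integer(round(pos[j, ] / g$pitch))
    F[, j] <- as.vector(circshift2(f, -si[1], -si[2]))
  }
  scan_stack(g, F, pos)
}

circshift2 <- function(m, s1, s2) {
  n1 <- nrow(m); n2 <- ncol(m)
  i <- ((seq_len(n1) - 1 - s1) %% n1) + 1
  j <- ((seq_len(n2) - 1 - s2) %% n2) + 1
  m[i, j, drop = FALSE]
}

#' Confocal image from a reflection matrix
#'
#' Reshapes the squared magnitude of the diagonal of an object-plane,
#' space-basis reflection matrix into the region-of-interest image — the
#' time-gated confocal reflectance image (co-located illumination and
#' detection).
#'
#' @param R a [reflection_matrix()] at the object plane, space basis.
#' @param intensity if `TRUE` (default) return `|diag|^2`, else the complex
#'   amplitude map.
#' @return an `n` x `n` numeric (or complex) matrix.
#' @export
confocal_image <- function(R, intensity = TRUE) {
  stopifnot(inherits(R, "reflection_matrix"))
  if (R$basis != "space")
    stop("confocal_image: R must be in the space basis")
  if (R$input_plane != R$output_plane)
    stop("confocal_image: R must have co-located planes")
  dg <- diag(R$values)
  n <- R$grid$n
  if (intensity) matrix(Mod(dg)^2, n, n) else matrix(dg, n, n)
}

# --- probe-based ballistic-fraction estimate for a medium -------------------

# Deterministic strided subset of frequency modes (fft-order linear indices)
# covering the full basis, so the probe estimate is an unbiased subsample of
# the ballistic-fraction ratio over all modes.
probe_mode_indices <- function(grid, n_probe) {
  d <- grid$n^2
  if (n_probe >= d) return(seq_len(d))
  unique(round(seq(1, d, length.out = n_probe)))
}

#' Probe-based ballistic fraction of a plate stack
#'
#' Estimates `eta_T` of a medium without building the dense transmission
#' matrix: a deterministic strided subset of `n_probe` plane-wave modes is
#' propagated through the stack and the diagonal-to-total power ratio of the
#' corresponding frequency-basis columns is accumulated. Converges to
#' [ballistic_fraction()] of [medium_transmission()] as `n_probe` approaches
#' the full mode count; the subsample ratio keeps large-grid calibration and
#' per-cycle traces affordable.
#'
#' @param medium a [medium_model()] (for identified stacks see
#'   [identified_stack()]).
#' @param n_probe number of probe modes.
#' @param correction optional list of per-plate phase maps subtracted from
#'   the plate phases before probing (residual-stack measurements).
#' @return estimated `eta_T` in (0, 1].
#' @export
ballistic_fraction_probe <- function(medium, n_probe = 1024,
                                     correction = NULL) {
  stopifnot(inherits(medium, "medium_model"))
  eta_T_probe(medium, n_probe = n_probe, correction = correction)
}

# eta_T of the stack measured by probing a strided subset of plane-wave
# modes: ratio of diagonal to total power over the probed columns of the
# frequency-basis transmission matrix.  `correction` as in stack_apply_cols.
eta_T_probe <- function(medium, n_probe = 256, correction = NULL) {
  g <- medium$grid
  n <- g$n
  d <- n^2
  idx <- probe_mode_indices(g, n_probe)
  # unitary plane-wave columns for the probed modes
  E <- matrix(0 + 0i, d, length(idx))
  for (j in seq_along(idx)) {
    sp <- matrix(0 + 0i, n, n)
    sp[idx[j]] <- 1
    E[, j] <- as.vector(ifft2(sp))
  }
  Tx <- stack_apply_cols(E, medium, correction = correction)
  num <- 0; den <- 0
  for (j in seq_along(idx)) {
    sp <- fft2(matrix(Tx[, j], n, n))
    num <- num + Mod(sp[idx[j]])^2
    den <- den + sum(Mod(sp)^2)
  }
  if (den == 0) stop("eta_T_probe: zero matrix")
  num / den
}
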