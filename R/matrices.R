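#' Reflection-matrix container
#'
#' A dense `n^2` x `n^2` complex operator mapping every illumination field to
#' the backscattered field at a fixed time gate. Columns index input
#' (illumination) points, rows index output (detection) points. The container
#' carries the grid, the axial planes the two indices refer to, the basis
#' (`"space"` or `"frequency"`) and a `time_gated` metadata flag (the time
#' gate is a modelling assumption — no intra-medium back-reflections — not a
#' temporal simulation).
#'
#' @param values dense complex matrix, `n^2` x `n^2`.
#' @param grid a [make_grid()] grid.
#' @param input_plane,output_plane axial coordinates (um) of the planes the
#'   column and row indices refer to (object plane is `z = 0`).
#' @param basis `"space"` or `"frequency"`.
#' @param time_gated logical flag.
#' @return an object of class `reflection_matrix`.
#' @export
reflection_matrix <- function(values, grid, input_plane = 0, output_plane = 0,
                              basis = c("space", "frequency"),
                              time_gated = TRUE) {
  stopifnot(is_field_grid(grid))
  basis <- match.arg(basis)
  values <- as_complex_matrix(values)
  d <- grid$n^2
  if (!all(dim(values) == c(d, d)))
    stop("reflection_matrix: 'values' must be ", d, " x ", d)
  structure(list(values = values, grid = grid,
                 input_plane = input_plane, output_plane = output_plane,
                 basis = basis, time_gated = time_gated),
            class = "reflection_matrix")
}

#' Transmission-matrix container
#'
#' One-way propagation operator through the plate stack, by convention from
#' the medium surface (input plane `z_N`) to the object plane (output plane
#' `z_0 = 0`). `provenance` records whether the matrix is the simulated
#' ground truth or the stack identified by the reconstruction.
#'
#' @param values dense complex matrix, `n^2` x `n^2`.
#' @param grid a [make_grid()] grid.
#' @param input_plane,output_plane axial coordinates (um).
#' @param basis `"space"` or `"frequency"`.
#' @param provenance `"ground_truth"` or `"identified"`.
#' @return an object of class `transmission_matrix`.
#' @export
transmission_matrix <- function(values, grid, input_plane, output_plane = 0,
                                basis = c("space", "frequency"),
                                provenance = c("ground_truth", "identified")) {
  stopifnot(is_field_grid(grid))
  basis <- match.arg(basis)
  provenance <- match.arg(provenance)
  values <- as_complex_matrix(values)
  d <- grid$n^2
  if (!all(dim(values) == c(d, d)))
    stop("transmission_matrix: 'values' must be ", d, " x ", d)
  structure(list(values = values, grid = grid,
                 input_plane = input_plane, output_plane = output_plane,
                 basis = basis, provenance = provenance),
            class = "transmission_matrix")
}

#' @export
print.reflection_matrix <- function(x, ...) {
  cat(sprintf("<reflection_matrix> %d x %d, %s basis, planes (out %g um, in %g um)\n",
              nrow(x$values), ncol(x$values), x$basis,
              x$output_plane, x$input_plane))
  invisible(x)
}

#' @export
print.transmission_matrix <- function(x, ...) {
  cat(sprintf("<transmission_matrix> %d x %d, %s basis, %s, %g um -> %g um\n",
              nrow(x$values), ncol(x$values), x$basis, x$provenance,
              x$input_plane, x$output_plane))
  invisible(x)
}

is_operator_matrix <- function(x)
  inherits(x, "reflection_matrix") || inherits(x, "transmission_matrix")

# unitary 2D DFT of both matrix indices, centred frequency ordering:
# M~ = Fc M Fc^H with Fc the fftshift-reordered unitary DFT
freq_transform_values <- function(M, grid, inverse = FALSE) {
  n <- grid$n
  if (!inverse) {
    # left factor: transform every column-field, then centre the row index
    A <- col_fft2(M, n, FALSE)
    A <- A[shift_perm(n), , drop = FALSE]
    # right factor F^H: (M F^H)^T = conj(F) M^T = Conj(F %*% Conj(M^T))
    A <- t(Conj(col_fft2(Conj(t(A)), n, FALSE)))
    A[, shift_perm(n), drop = FALSE]
  } else {
    A <- M[, invshift_perm(n), drop = FALSE]
    A <- t(Conj(col_fft2(Conj(t(A)), n, TRUE)))
    A <- A[invshift_perm(n), , drop = FALSE]
    col_fft2(A, n, TRUE)
  }
}

# permutation mapping fft-order linear indices to centred order
shift_perm <- function(n) {
  p1 <- c((floor(n / 2) + 1):n, 1:floor(n / 2))
  as.vector(outer(p1, (p1 - 1L) * n, `+`))
}

invshift_perm <- function(n) order(shift_perm(n))

#' Change the basis of a matrix to spatial frequency
#'
#' Transforms both indices of a space-basis reflection or transmission matrix
#' to the spatial-frequency basis with the unitary, centred discrete Fourier
#' convention, so that total power is preserved exactly and the round trip
#' through [to_space_basis()] reproduces the input to numerical precision.
#'
#' @param matrix a `reflection_matrix` or `transmission_matrix` in the space
#'   basis.
#' @return the same kind of object with `basis = "frequency"`.
#' @export
to_frequency_basis <- function(matrix) {
  stopifnot(is_operator_matrix(matrix))
  if (matrix$basis == "frequency")
    stop("to_frequency_basis: matrix is already in the frequency basis")
  matrix$values <- freq_transform_values(matrix$values, matrix$grid)
  matrix$basis <- "frequency"
  matrix
}

#' Change the basis of a matrix back to space
#'
#' Inverse of [to_frequency_basis()].
#' @param matrix a matrix container in the frequency basis.
#' @return the same kind of object with `basis = "space"`.
#' @export
to_space_basis <- function(matrix) {
  stopifnot(is_operator_matrix(matrix))
  if (matrix$basis == "space")
    stop("to_space_basis: matrix is already in the space basis")
  matrix$values <- freq_transform_values(matrix$values, matrix$grid,
                                         inverse = TRUE)
  matrix$basis <- "space"
  matrix
}
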