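# Quantitative diagnostics: ballistic fractions and enhancements, optical
# thickness, angular spread functions, correlation scoring.

#' Ballistic power fraction of a transmission matrix
#'
#' The fraction of transmitted power that preserves its propagation
#' direction: `eta_T = sum_i |T~_ii|^2 / sum_ij |T~_ij|^2`, with `T~` the
#' matrix in the spatial-frequency basis. Space-basis input is transformed
#' internally.
#'
#' @param T_mat a [transmission_matrix()].
#' @return `eta_T` in (0, 1].
#' @export
ballistic_fraction <- function(T_mat) {
  stopifnot(inherits(T_mat, "transmission_matrix"))
  Tf <- if (T_mat$basis == "space") to_frequency_basis(T_mat) else T_mat
  tot <- sum(Mod(Tf$values)^2)
  if (tot == 0) stop("ballistic_fraction: zero matrix")
  sum(Mod(diag(Tf$values))^2) / tot
}

#' Roundtrip ballistic enhancement `xi1`
#'
#' The roundtrip enhancement of the ballistic signal delivered by rectifying
#' the identified stack: `xi1 = eta_T^{-2}`.
#'
#' @param T_c a [transmission_matrix()] (typically the identified stack).
#' @return `xi1 >= 1` for any physical stack.
#' @export
xi1 <- function(T_c) ballistic_fraction(T_c)^-2

#' One-way optical thickness of a transmission matrix
#'
#' `-log(eta_T)`, the optical thickness in units of the scattering mean free
#' path, estimated from the intensity ratio between the diagonal and the
#' total in the spatial-frequency basis. Additive over independently
#' scattering stacked plates within sampling error.
#'
#' @param T_mat a [transmission_matrix()].
#' @return optical thickness (dimensionless, `l_s` units).
#' @export
optical_thickness <- function(T_mat) -log(ballistic_fraction(T_mat))

#' Confocal enhancement `eta_c`
#'
#' Ratio of summed squared diagonal magnitudes of the corrected over the
#' uncorrected object-plane reflection matrix:
#' `eta_c = sum_i |R^c_ii|^2 / sum_i |R_ii|^2`.
#'
#' @param R,R_c uncorrected and corrected [reflection_matrix()] objects at
#'   `(z0, z0)`, space basis.
#' @return `eta_c > 0`.
#' @export
confocal_enhancement <- function(R, R_c) {
  stopifnot(inherits(R, "reflection_matrix"), inherits(R_c, "reflection_matrix"))
  for (m in list(R, R_c))
    if (m$basis != "space" || m$input_plane != m$output_plane)
      stop("confocal_enhancement: matrices must be co-located in the space basis")
  den <- sum(Mod(diag(R$values))^2)
  if (den == 0) stop("confocal_enhancement: zero uncorrected diagonal")
  sum(Mod(diag(R_c$values))^2) / den
}

#' Ballistic contribution `alpha` of the uncorrected confocal signal
#'
#' Estimates the fraction of the uncorrected confocal power attributable to
#' ballistic (direction-preserving) light. The reference transmission matrix
#' is restricted to its frequency-diagonal (ballistic) component `T_b`, the
#' ballistic confocal diagonal is predicted as `diag(T_b^T O T_b)`, and
#' `alpha = sum_i |diag_b,i|^2 / sum_i |R_ii|^2`. In synthetic studies
#' `T_ref` is the ground-truth matrix and `object` the true map; with
#' measured data the identified stack and the reconstructed object stand in
#' (the estimator is then approximate, which is why `xi2 = eta_c / alpha`
#' carries a wider tolerance than `xi1`).
#'
#' @param R uncorrected [reflection_matrix()] at `(z0, z0)`, space basis.
#' @param T_ref reference [transmission_matrix()] (ground truth or
#'   identified), space or frequency basis. Must be referenced like the
#'   forward model (surface to object) on `R`'s grid.
#' @param object an `object_map` (the reflector driving the diagonal).
#' @return `alpha` in [0, 1] up to estimator noise.
#' @export
ballistic_contribution_alpha <- function(R, T_ref, object) {
  stopifnot(inherits(R, "reflection_matrix"),
            inherits(T_ref, "transmission_matrix"),
            inherits(object, "object_map"))
  if (R$basis != "space" || R$input_plane != 0 || R$output_plane != 0)
    stop("ballistic_contribution_alpha: R must be at (z0, z0), space basis")
  g <- R$grid
  Tf <- if (T_ref$basis == "space") to_frequency_basis(T_ref) else T_ref
  dq <- diag(Tf$values)
  # T_b = F^H diag(dq) F is circulant: one kernel field, shifted columns.
  # dq is in centred frequency order; restore fft order before inverting.
  n <- g$n
  dq_fft <- matrix(dq, n, n)[invshift_perm_1d(n), invshift_perm_1d(n)]
  delta <- matrix(0 + 0i, n, n)
  delta[grid_origin_index(g), grid_origin_index(g)] <- 1 + 0i
  kernel <- ifft2(fft2(delta) * dq_fft)
  Tb <- matrix(kernel[circulant_index(g)], n^2, n^2)
  o <- as.vector(object$reflectance)
  # diag(T_b^T O T_b)_j = sum_i Tb[i,j]^2 o[i]
  db <- colSums(Tb * (o * Tb))
  den <- sum(Mod(diag(R$values))^2)
  if (den == 0) stop("ballistic_contribution_alpha: zero confocal diagonal")
  sum(Mod(db)^2) / den
}

invshift_perm_1d <- function(n) {
  p1 <- c((floor(n / 2) + 1):n, 1:floor(n / 2))
  order(p1)
}

#' Ballistic enhancement `xi2` from the image analysis
#'
#' `xi2 = eta_c / alpha`: the confocal enhancement rescaled by the ballistic
#' contribution to the uncorrected diagonal, giving the enhancement of the
#' ballistic signal as seen in the reconstructed image.
#'
#' @param eta_c a [confocal_enhancement()] value.
#' @param alpha a [ballistic_contribution_alpha()] value.
#' @return `xi2`.
#' @export
xi2 <- function(eta_c, alpha) eta_c / alpha

#' Angular spread function through the stack
#'
#' Propagates a normally incident unit plane wave from the medium surface
#' down to `depth` (immediately below any plate located at that depth) and
#' returns its intensity distribution over spatial frequency (centred
#' ordering; the central pixel is the ballistic component). With
#' `corrected_by`, the identified phases are subtracted at each plate,
#' showing how much of the broadening the rectification removes.
#'
#' @param medium a [medium_model()].
#' @param depth target depth in um, `0 <= depth <= z_N`.
#' @param corrected_by optional list of `n` x `n` phase maps (one per plate,
#'   e.g. `phase_c` from [mst_iterate()] estimates).
#' @return list with `intensity` (`n` x `n`, centred spatial frequency),
#'   `ballistic` (central-pixel intensity), `depth`.
#' @export
angular_spread_function <- function(medium, depth, corrected_by = NULL) {
  stopifnot(inherits(medium, "medium_model"))
  g <- medium$grid
  if (depth < 0 || depth > max(c(medium$depths, 0)))
    stop("angular_spread_function: 'depth' outside the modeled axial range")
  n <- g$n
  field <- matrix(1 + 0i, n, n)
  N <- length(medium$plates)
  cur <- if (N > 0) medium$depths[N] else depth
  if (N > 0) {
    for (k in N:1) {
      zk <- medium$depths[k]
      if (zk < depth) break
      field <- ifft2(fft2(field) * prop_transfer(g, cur - zk))
      cur <- zk
      ph <- medium$plates[[k]]$phase
      if (!is.null(corrected_by)) ph <- ph - corrected_by[[k]]
      field <- field * exp(1i * ph)
    }
  }
  field <- ifft2(fft2(field) * prop_transfer(g, cur - depth))
  sp <- fftshift2(fft2(field))
  intensity <- Mod(sp)^2
  o <- grid_origin_index(g)
  list(intensity = intensity, ballistic = intensity[o, o], depth = depth)
}

#' Pearson correlation score between two maps
#'
#' `mode = "intensity"` correlates two real-valued maps with the ordinary
#' Pearson coefficient. `mode = "complex_phase"` correlates the unit phasors
#' `exp(i phi)` of two phase maps and reports the magnitude of the
#' normalised complex covariance, which removes the best-fit global piston
#' automatically (a constant phase offset multiplies the covariance by a
#' unit phasor and leaves its magnitude unchanged).
#'
#' @param estimate,truth numeric (or phase, radians) matrices of equal size.
#' @param mode `"intensity"` or `"complex_phase"`.
#' @param mask optional logical matrix restricting the comparison.
#' @return correlation in `[-1, 1]` (`[0, 1]` for `complex_phase`).
#' @export
pearson_score <- function(estimate, truth,
                          mode = c("intensity", "complex_phase"),
                          mask = NULL) {
  mode <- match.arg(mode)
  if (!all(dim(estimate) == dim(truth)))
    stop("pearson_score: shapes differ")
  sel <- if (is.null(mask)) rep(TRUE, length(estimate)) else as.vector(mask)
  a <- as.vector(estimate)[sel]
  b <- as.vector(truth)[sel]
  if (mode == "intensity") {
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      stop("pearson_score: constant input (correlation undefined)")
    return(stats::cor(a, b))
  }
  x <- exp(1i * a)
  y <- exp(1i * b)
  xc <- x - mean(x)
  yc <- y - mean(y)
  nx <- sqrt(sum(Mod(xc)^2)); ny <- sqrt(sum(Mod(yc)^2))
  if (nx == 0 || ny == 0)
    stop("pearson_score: constant input (correlation undefined)")
  Mod(sum(xc * Conj(yc))) / (nx * ny)
}

#' Number of traced scattering events
#'
#' A roundtrip through `N` identified plates plus the reflection at the
#' object traces `2N + 1` scattering events (N inward, one at the object,
#' N outward).
#'
#' @param n_plates number of phase plates.
#' @return integer event count.
#' @export
traced_scattering_events <- function(n_plates) 2L * as.integer(n_plates) + 1L

#' Assemble a metrics report
#'
#' Computes the full set of ballistic-enhancement diagnostics for a
#' reconstruction: `eta_T` and `xi1` of the identified stack, `eta_c`,
#' `alpha` and `xi2 = eta_c/alpha` when a ground-truth reference is
#' available, the one-way optical thickness before and after rectification,
#' and named Pearson correlations. Definitional identities
#' (`xi1 = eta_T^-2`, `OD = -log(eta_T)`, `xi2 = eta_c/alpha`) hold to
#' machine precision by construction.
#'
#' @param R uncorrected reflection matrix at `(z0, z0)`.
#' @param R_c corrected reflection matrix at `(z0, z0)`.
#' @param T_identified identified dense [transmission_matrix()].
#' @param T_truth optional ground-truth transmission matrix.
#' @param object optional ground-truth `object_map`.
#' @param residual_od optional residual optical thickness after subtracting
#'   the identified phases (computed by the caller from the residual stack).
#' @return object of class `mst_metrics` (a named list).
#' @export
metrics_report <- function(R, R_c, T_identified, T_truth = NULL,
                           object = NULL, residual_od = NULL) {
  eta_T <- ballistic_fraction(T_identified)
  out <- list(eta_T = eta_T, xi1 = eta_T^-2,
              optical_thickness_identified = -log(eta_T),
              eta_c = confocal_enhancement(R, R_c))
  if (!is.null(T_truth))
    out$optical_thickness_truth <- optical_thickness(T_truth)
  if (!is.null(T_truth) && !is.null(object)) {
    out$alpha <- ballistic_contribution_alpha(R, T_truth, object)
    out$xi2 <- out$eta_c / out$alpha
  }
  if (!is.null(residual_od)) out$residual_od <- residual_od
  if (!is.null(object)) {
    mst_img <- matrix(Mod(diag(R_c$values))^2, R$grid$n, R$grid$n)
    conf_img <- confocal_image(R)
    truth_img <- Mod(object$reflectance)^2
    out$correlations <- c(
      mst_image = pearson_score(mst_img, truth_img),
      confocal_image = pearson_score(conf_img, truth_img))
  }
  structure(out, class = "mst_metrics")
}

#' @export
print.mst_metrics <- function(x, ...) {
  cat("<mst_metrics>\n")
  cat(sprintf("  eta_T = %.4g  (xi1 = %.4g, OD = %.3g l_s)\n",
              x$eta_T, x$xi1, x$optical_thickness_identified))
  cat(sprintf("  eta_c = %.4g", x$eta_c))
  if (!is.null(x$xi2)) cat(sprintf("  alpha = %.3g  xi2 = %.4g", x$alpha, x$xi2))
  cat("\n")
  if (!is.null(x$correlations))
    cat(sprintf("  image correlations: MST %.3f, confocal %.3f\n",
                x$correlations[["mst_image"]], x$correlations[["confocal_image"]]))
  invisible(x)
}
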