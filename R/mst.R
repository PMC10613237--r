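# Multiple scattering tracing: plane transforms, Green's-normalized
# correlation matrices, per-layer phase estimation by power iteration, the
# multi-cycle correction loop, and object reconstruction.

.mstrace_cache <- new.env(parent = emptyenv())

# cached circulant index matrix for a grid size (maps a centred kernel field
# to the dense (rho_i - rho_j) matrix)
circulant_index <- function(grid) {
  key <- paste0("cidx", grid$n)
  if (!is.null(.mstrace_cache[[key]])) return(.mstrace_cache[[key]])
  n <- grid$n
  o <- grid_origin_index(grid)
  d1 <- outer(seq_len(n) - 1L, seq_len(n) - 1L,
              function(a, b) ((a - b + o - 1L) %% n) + 1L)
  idx <- kronecker((d1 - 1L) * n, matrix(1L, n, n)) +
    kronecker(matrix(1L, n, n), d1)
  .mstrace_cache[[key]] <- idx
  idx
}

#' MST reconstruction configuration
#'
#' Loop controls for [mst_iterate()]. Defaults: power iteration starts from
#' the all-ones vector with at most 30 steps and a relative-change tolerance
#' of `1e-6`; the cycle loop stops when the RMS phase increment of every
#' layer falls below 0.01 rad or after `max_cycles` cycles; layers are
#' visited from nearest-to-object outward on the input path, then the output
#' path is processed through the matrix transpose.
#'
#' @param layer_depths plate depths `z_k` in um, strictly increasing.
#' @param max_cycles maximum number of correction cycles (>= 1).
#' @param phase_increment_tolerance RMS increment (radians) below which the
#'   loop stops.
#' @param power_iteration_max_steps,power_iteration_tolerance power-iteration
#'   controls.
#' @param reference_point lateral position (um) whose phase is pinned to zero
#'   (piston convention); falls back to the strongest column when unusable.
#' @param fov_masking confine estimates to the circular field of view of
#'   diameter [plate_fov_diameter()] at each depth (clipped to the grid)?
#' @param layer_order `"near_to_far"` (default) or `"far_to_near"`.
#' @param na_eff effective cone aperture used for the FOV diameters.
#' @param normalization Green's normalisation mode, `"phase_only"`
#'   (default; see [normalize_by_greens()]) or `"amplitude"`.
#' @param greens_regularization in `"amplitude"` mode, Green's amplitudes
#'   below this multiple of the median `|G|` are masked out of the
#'   normalisation instead of divided (noise blow-up control at the
#'   band-limit nulls).
#' @param trace_n_probe probe modes for the per-cycle `xi1` trace estimate.
#' @param alpha ballistic contribution of the uncorrected confocal diagonal
#'   (see [ballistic_contribution_alpha()]); used for the `xi2` trace.
#'   `NA` when no ground-truth reference is available.
#' @param keep_corrected keep the full corrected matrix in the result?
#' @param verbose print per-cycle progress?
#' @return an object of class `mst_config`.
#' @export
mst_config <- function(layer_depths,
                       max_cycles = 20L,
                       phase_increment_tolerance = 0.01,
                       power_iteration_max_steps = 30L,
                       power_iteration_tolerance = 1e-6,
                       reference_point = c(0, 0),
                       fov_masking = TRUE,
                       layer_order = c("near_to_far", "far_to_near"),
                       na_eff = sin(atan(0.6)),
                       normalization = c("phase_only", "amplitude"),
                       greens_regularization = 0.5,
                       trace_n_probe = 192L,
                       alpha = NA_real_,
                       keep_corrected = FALSE,
                       verbose = FALSE) {
  if (length(layer_depths) < 1 || any(layer_depths <= 0) ||
      any(diff(layer_depths) <= 0))
    stop("mst_config: 'layer_depths' must be positive and strictly increasing")
  if (max_cycles < 1) stop("mst_config: 'max_cycles' must be >= 1")
  if (phase_increment_tolerance <= 0 || power_iteration_tolerance <= 0)
    stop("mst_config: tolerances must be positive")
  structure(list(layer_depths = layer_depths,
                 max_cycles = as.integer(max_cycles),
                 phase_increment_tolerance = phase_increment_tolerance,
                 power_iteration_max_steps = as.integer(power_iteration_max_steps),
                 power_iteration_tolerance = power_iteration_tolerance,
                 reference_point = reference_point,
                 fov_masking = fov_masking,
                 layer_order = match.arg(layer_order),
                 na_eff = na_eff,
                 normalization = match.arg(normalization),
                 greens_regularization = greens_regularization,
                 trace_n_probe = as.integer(trace_n_probe),
                 alpha = alpha,
                 keep_corrected = keep_corrected,
                 verbose = verbose),
            class = "mst_config")
}

#' Transform a reflection matrix between axial planes
#'
#' Re-references the input (column) and output (row) indices of a reflection
#' matrix to new axial planes by multiplying free-space (back-)propagation
#' operators on the corresponding sides. Transforming to a plane and back
#' restores the matrix on the passband to numerical precision, and the
#' composition of two partial transforms equals the direct transform.
#'
#' @param R a [reflection_matrix()] in the space basis.
#' @param input_plane,output_plane target planes in um (default: keep).
#' @return a `reflection_matrix` referenced to the new planes.
#' @export
transform_to_layer <- function(R, input_plane = R$input_plane,
                               output_plane = R$output_plane) {
  stopifnot(inherits(R, "reflection_matrix"))
  if (R$basis != "space")
    stop("transform_to_layer: R must be in the space basis")
  g <- R$grid
  M <- R$values
  if (output_plane != R$output_plane)
    M <- apply_spectral_cols(M, g, prop_transfer(g, output_plane - R$output_plane))
  if (input_plane != R$input_plane)
    M <- apply_spectral_rows(M, g, prop_transfer(g, input_plane - R$input_plane))
  reflection_matrix(M, g, input_plane = input_plane,
                    output_plane = output_plane, time_gated = R$time_gated)
}

#' Green's-function normalized matrix
#'
#' Removes the spherical-wave curvature of a layer-referenced reflection
#' matrix `R[(rho, z0), (rho', z_k)]` using the band-limited free-space
#' Green's function `G(rho - rho'; z_k)`, so that, for a noiseless
#' single-plate medium, the result carries the rank-1 phase structure
#' `exp(i phi_k(rho'))` along its columns. Two normalisations are provided:
#'
#' * `"phase_only"` (default): multiply by `conj(G)/|G|`, cancelling the
#'   curvature while keeping the `|G|` amplitude in place. Because the
#'   unmodelled multiple-scattering term has roughly uniform variance per
#'   entry, leaving `|G|` as a weight is the matched filter: entries near
#'   the nulls of `G` are down-weighted instead of amplified, and the phase
#'   of the dominant singular vector remains unbiased.
#' * `"amplitude"`: the literal entrywise division by `G` (exactly rank-1
#'   for a noiseless single plate). Entries where `|G|` falls below
#'   `regularization` times its median amplitude are masked (flagged, not
#'   divided) to avoid noise blow-up at the band-limit nulls.
#'
#' @param R_layer a `reflection_matrix` with `output_plane = 0` and
#'   `input_plane = z_k > 0`, space basis.
#' @param regularization threshold relative to the median `|G|`
#'   (`"amplitude"` mode).
#' @param normalization `"phase_only"` or `"amplitude"`.
#' @return object of class `normalized_matrix`: list with `values` (masked
#'   entries zeroed), `mask` (logical matrix of masked entries, or `NULL`),
#'   `layer_depth`, `normalization`, `grid`.
#' @export
normalize_by_greens <- function(R_layer, regularization = 0.5,
                                normalization = c("phase_only", "amplitude")) {
  stopifnot(inherits(R_layer, "reflection_matrix"))
  normalization <- match.arg(normalization)
  if (R_layer$output_plane != 0 || R_layer$input_plane <= 0)
    stop("normalize_by_greens: R must be referenced to (z0, z_k) with z_k > 0")
  g <- R_layer$grid
  g0 <- propagated_delta(g, R_layer$input_plane)
  G <- matrix(g0[circulant_index(g)], g$n^2, g$n^2)
  if (normalization == "phase_only") {
    a <- Mod(G)
    fac <- Conj(G) / a
    fac[a == 0] <- 0 + 0i
    S <- R_layer$values * fac
    mask <- NULL
  } else {
    small <- Mod(G) < regularization * stats::median(Mod(g0))
    S <- R_layer$values / G
    if (any(small)) S[small] <- 0 + 0i
    mask <- if (any(small)) small else NULL
  }
  structure(list(values = S, mask = mask,
                 layer_depth = R_layer$input_plane,
                 normalization = normalization, grid = g),
            class = "normalized_matrix")
}

#' Per-layer phase estimate by power iteration
#'
#' Solves the rank-1 phase factorisation of a Green's-normalized matrix —
#' `argmin_phi || S - tau * o %o% exp(i phi) ||_F` — by power iteration for
#' the dominant right singular vector, keeping only its phase angle
#' (phase-only projection) and pinning the designated reference point to
#' zero. Columns outside the field-of-view mask, fully masked columns and
#' zero columns receive a zero increment.
#'
#' @param S a [normalize_by_greens()] result.
#' @param config an [mst_config()] (power-iteration controls, reference
#'   point).
#' @param fov_mask optional logical `n` x `n` mask over input positions.
#' @return list with `increment` (`n` x `n` radians, zero outside the active
#'   set), `active` (logical map), `rms` (RMS increment over active
#'   positions), `steps`, `converged`.
#' @export
estimate_phase <- function(S, config, fov_mask = NULL) {
  stopifnot(inherits(S, "normalized_matrix"))
  g <- S$grid
  d <- g$n^2
  M <- S$values
  active <- rep(TRUE, d)
  if (!is.null(fov_mask)) active <- active & as.vector(fov_mask)
  cn <- colSums(Mod(M)^2)
  active <- active & cn > 0
  if (!any(active)) stop("estimate_phase: no active (unmasked) columns")
  if (!is.null(fov_mask) && !all(active)) {
    M <- col_scale(M, as.complex(active))
  }
  v <- complex(real = rep(1 / sqrt(d), d))
  steps <- 0L
  converged <- FALSE
  for (it in seq_len(config$power_iteration_max_steps)) {
    u <- M %*% v
    vn <- Conj(crossprod(M, Conj(u)))
    nv <- sqrt(sum(Mod(vn)^2))
    if (nv == 0) stop("estimate_phase: power iteration collapsed to zero")
    vn <- vn / nv
    # relative change up to global phase
    ph <- sum(Conj(vn) * v)
    delta <- sqrt(sum(Mod(vn * (ph / Mod(ph)) - v)^2))
    v <- vn
    steps <- it
    if (is.finite(delta) && delta < config$power_iteration_tolerance) {
      converged <- TRUE
      break
    }
  }
  w <- Conj(as.vector(v))        # direction of exp(i phi)
  ref <- grid_linear_index(g, config$reference_point)
  if (!active[ref] || Mod(w[ref]) < 1e-3 * max(Mod(w[active]))) {
    ref <- which(active)[which.max(Mod(w[active]))]
  }
  phi <- Arg(w) - Arg(w[ref])
  phi <- atan2(sin(phi), cos(phi))   # wrap to (-pi, pi]
  phi[!active] <- 0
  list(increment = matrix(phi, g$n, g$n),
       active = matrix(active, g$n, g$n),
       rms = sqrt(mean(phi[active]^2)),
       steps = steps, converged = converged)
}

#' Apply a phase correction to one side of a reflection matrix
#'
#' Multiplies the conjugate phase diagonal `exp(-i phi)` on the input
#' (column) or output (row) side of a layer-referenced matrix. Applying an
#' estimate and then its negation restores the matrix exactly.
#'
#' @param R a `reflection_matrix` referenced to the layer on the stated side.
#' @param increment `n` x `n` phase increment in radians.
#' @param side `"input"` or `"output"`.
#' @return the corrected `reflection_matrix`.
#' @export
apply_phase_correction <- function(R, increment, side = c("input", "output")) {
  stopifnot(inherits(R, "reflection_matrix"))
  side <- match.arg(side)
  g <- R$grid
  if (!all(dim(increment) == c(g$n, g$n)))
    stop("apply_phase_correction: increment/grid mismatch")
  ph <- exp(-1i * as.vector(increment))
  R$values <- if (side == "input") col_scale(R$values, ph)
              else row_scale(R$values, ph)
  R
}

# circular FOV mask of diameter L_k centred on the origin, clipped to grid
fov_mask_for_depth <- function(grid, z_k, na_eff) {
  L <- plate_fov_diameter(z_k, grid$extent, na_eff)
  xx <- matrix(grid$x, grid$n, grid$n)
  yy <- t(xx)
  sqrt(xx^2 + yy^2) <= L / 2
}

#' Run the multiple-scattering-tracing loop
#'
#' The full reconstruction: per cycle, layers are visited along the input
#' path (the matrix is re-referenced to each plate plane, Green's-normalized,
#' the phase increment estimated by power iteration and compensated), then
#' the output path is processed identically through the matrix transpose.
#' Increments are accumulated per layer and side; the loop stops when every
#' increment's RMS falls below the configured tolerance, or after
#' `max_cycles`. Ballistic-enhancement traces (`eta_c`, `xi1`, and `xi2` when
#' an `alpha` reference is supplied) are recorded once per cycle after the
#' transpose pass.
#'
#' @param R a [reflection_matrix()] at the object plane (`(z0, z0)`), space
#'   basis.
#' @param config an [mst_config()].
#' @return object of class `mst_result`: list with `estimates` (per layer:
#'   `depth`, `phase_in`, `phase_out`, accumulated `phase_c`, `fov_mask`),
#'   `traces` (data.frame with one row per completed cycle), `converged`,
#'   `cycles_run`, `image` (MST intensity image), `object_estimate`
#'   (complex), `config`, and optionally `corrected` (the corrected matrix).
#' @export
mst_iterate <- function(R, config) {
  stopifnot(inherits(R, "reflection_matrix"), inherits(config, "mst_config"))
  if (R$basis != "space" || R$input_plane != 0 || R$output_plane != 0)
    stop("mst_iterate: R must be referenced to (z0, z0) in the space basis")
  g <- R$grid
  n <- g$n
  d <- n^2
  depths <- config$layer_depths
  N <- length(depths)
  order_k <- if (config$layer_order == "near_to_far") seq_len(N) else rev(seq_len(N))

  fov <- lapply(depths, function(z)
    if (config$fov_masking) fov_mask_for_depth(g, z, config$na_eff)
    else matrix(TRUE, n, n))
  cidx <- circulant_index(g)
  # per-layer normalisation factor: multiply (never divide) so masked/null
  # entries are simply zero
  Gfac <- lapply(depths, function(z) {
    g0 <- propagated_delta(g, z)
    G <- matrix(g0[cidx], d, d)
    a <- Mod(G)
    if (config$normalization == "phase_only") {
      fac <- Conj(G) / a
      fac[a == 0] <- 0 + 0i
    } else {
      fac <- 1 / G
      fac[a < config$greens_regularization * stats::median(Mod(g0))] <- 0 + 0i
    }
    fac
  })

  Rw <- R$values
  diag0 <- sum(Mod(diag(Rw))^2)
  acc_in <- replicate(N, matrix(0, n, n), simplify = FALSE)
  acc_out <- replicate(N, matrix(0, n, n), simplify = FALSE)

  traces <- list()
  converged <- FALSE
  cycles <- 0L

  for (cyc in seq_len(config$max_cycles)) {
    max_rms <- 0
    for (pass in c("in", "out")) {
      if (pass == "out") Rw <- t(Rw)
      cur <- 0
      for (k in order_k) {
        Rw <- apply_spectral_rows(Rw, g, prop_transfer(g, depths[k] - cur))
        cur <- depths[k]
        if (!all(is.finite(Re(Rw))))
          stop("mst_iterate: non-finite values at layer ", k,
               " (cycle ", cyc, ")")
        Sv <- Rw * Gfac[[k]]
        S <- structure(list(values = Sv, mask = NULL, layer_depth = depths[k],
                            normalization = config$normalization, grid = g),
                       class = "normalized_matrix")
        est <- estimate_phase(S, config, fov_mask = fov[[k]])
        if (pass == "in") acc_in[[k]] <- acc_in[[k]] + est$increment
        else acc_out[[k]] <- acc_out[[k]] + est$increment
        Rw <- col_scale(Rw, exp(-1i * as.vector(est$increment)))
        max_rms <- max(max_rms, est$rms)
      }
      Rw <- apply_spectral_rows(Rw, g, prop_transfer(g, -cur))
      if (pass == "out") Rw <- t(Rw)
    }
    cycles <- cyc
    # per-cycle diagnostics
    eta_c <- sum(Mod(diag(Rw))^2) / diag0
    phi_mean <- lapply(seq_len(N), function(k) (acc_in[[k]] + acc_out[[k]]) / 2)
    ident <- identified_medium_from_phases(g, depths, phi_mean)
    eta_hat <- eta_T_probe(ident, n_probe = config$trace_n_probe)
    xi1 <- eta_hat^-2
    xi2 <- if (is.na(config$alpha)) NA_real_ else eta_c / config$alpha
    traces[[cyc]] <- data.frame(cycle = cyc, eta_c = eta_c, xi1 = xi1,
                                xi2 = xi2, max_rms_increment = max_rms)
    if (config$verbose)
      message(sprintf("cycle %d: max RMS increment %.4f rad, xi1 ~ %.1f",
                      cyc, max_rms, xi1))
    if (max_rms < config$phase_increment_tolerance) {
      converged <- TRUE
      break
    }
  }

  estimates <- lapply(seq_len(N), function(k) {
    list(layer_index = k, depth = depths[k],
         phase_in = acc_in[[k]], phase_out = acc_out[[k]],
         phase_c = (acc_in[[k]] + acc_out[[k]]) / 2,
         fov_mask = fov[[k]])
  })
  dg <- diag(Rw)
  res <- list(estimates = estimates,
              traces = do.call(rbind, traces),
              converged = converged, cycles_run = cycles,
              image = matrix(Mod(dg)^2, n, n),
              object_estimate = matrix(dg, n, n),
              grid = g, config = config)
  if (config$keep_corrected)
    res$corrected <- reflection_matrix(Rw, g, 0, 0)
  structure(res, class = "mst_result")
}

#' @export
print.mst_result <- function(x, ...) {
  cat(sprintf("<mst_result> %d layer(s), %d cycle(s), %s\n",
              length(x$estimates), x$cycles_run,
              if (x$converged) "converged" else "not converged"))
  if (!is.null(x$traces)) {
    last <- x$traces[nrow(x$traces), ]
    cat(sprintf("  final eta_c = %.3g, xi1 ~ %.4g%s\n", last$eta_c, last$xi1,
                if (is.na(last$xi2)) "" else sprintf(", xi2 ~ %.4g", last$xi2)))
  }
  invisible(x)
}

# medium_model built from bare phase maps (identified stack)
identified_medium_from_phases <- function(grid, depths, phases) {
  plates <- lapply(seq_along(depths), function(k)
    structure(list(phase = phases[[k]], depth = depths[k], pitch = grid$pitch,
                   extent = grid$extent, correlation_length = NA_real_,
                   phase_std = stats::sd(as.vector(phases[[k]])),
                   seed = NA_integer_),
              class = "phase_plate"))
  medium_model(grid, plates)
}

#' Identified medium / transmission matrix from an MST result
#'
#' Assembles the stack of identified phase plates `phi_k^c` (a
#' [medium_model()]) and, on request, the dense identified transmission
#' matrix `T^c`.
#'
#' @param result an [mst_iterate()] result.
#' @param as_matrix return the dense [transmission_matrix()] instead of the
#'   `medium_model`?
#' @return a `medium_model` or `transmission_matrix` (provenance
#'   `"identified"`).
#' @export
identified_stack <- function(result, as_matrix = FALSE) {
  stopifnot(inherits(result, "mst_result"))
  med <- identified_medium_from_phases(
    result$grid,
    vapply(result$estimates, function(e) e$depth, numeric(1)),
    lapply(result$estimates, function(e) e$phase_c))
  if (!as_matrix) return(med)
  tm <- medium_transmission(med)
  tm$provenance <- "identified"
  tm
}

#' Correct a reflection matrix with an identified stack
#'
#' Applies the structural inverse of the stack transmission operator on both
#' sides: `R^c = (T^T)^{-1} R T^{-1}`, where the inverse is the
#' reversed-order product of the conjugated unitary factors (never a dense
#' numerical inversion). With the ground-truth stack and a forward-model
#' matrix, the corrected matrix is exactly diagonal with the object on the
#' diagonal.
#'
#' @param R a [reflection_matrix()] at `(z0, z0)` or `(zN, zN)`, space basis.
#' @param stack a [medium_model()] holding the correction phases (e.g. from
#'   [identified_stack()], or the ground-truth medium).
#' @return the corrected `reflection_matrix` at the same reference planes.
#' @export
corrected_reflection <- function(R, stack) {
  stopifnot(inherits(R, "reflection_matrix"), inherits(stack, "medium_model"))
  if (R$basis != "space")
    stop("corrected_reflection: R must be in the space basis")
  g <- R$grid
  if (!same_grid(g, stack$grid))
    stop("corrected_reflection: grid mismatch between R and the stack")
  at_z0 <- R$input_plane == 0 && R$output_plane == 0
  at_zN <- R$input_plane == stack$surface_z && R$output_plane == stack$surface_z
  if (!at_z0 && !at_zN)
    stop("corrected_reflection: R must be referenced to (z0, z0) or (zN, zN)")
  if (length(stack$plates) == 0) return(R)
  # B = A^{-1} with A the (z0- or zN-referenced) stack operator; all factors
  # are symmetric, so B^T is the same factors applied in reverse order.
  Bt_cols <- function(X) {
    if (at_z0)
      X <- apply_spectral_cols(X, g, prop_transfer(g, stack$surface_z))
    z <- c(0, stack$depths)
    for (k in rev(seq_along(stack$plates))) {
      X <- row_mult_field(X, exp(-1i * stack$plates[[k]]$phase), g)
      X <- apply_spectral_cols(X, g, Conj(prop_transfer(g, z[k + 1] - z[k])))
    }
    X
  }
  R$values <- Bt_cols(t(Bt_cols(t(R$values))))
  # the corrected matrix describes the medium-free roundtrip: both indices
  # now refer to the object plane
  R$input_plane <- 0
  R$output_plane <- 0
  R
}

#' Reconstruct the object from a corrected reflection matrix
#'
#' Reshapes the diagonal of the object-plane corrected matrix into the
#' complex amplitude-reflectance estimate (the MST image is its squared
#' magnitude). Applied to an uncorrected matrix this is the confocal image.
#'
#' @param R_c a `reflection_matrix` at `(z0, z0)`, space basis.
#' @return an `object_map` estimate.
#' @export
reconstruct_object <- function(R_c) {
  stopifnot(inherits(R_c, "reflection_matrix"))
  if (R_c$basis != "space" || R_c$input_plane != 0 || R_c$output_plane != 0)
    stop("reconstruct_object: R must be at (z0, z0) in the space basis")
  g <- R_c$grid
  structure(list(reflectance = matrix(diag(R_c$values), g$n, g$n),
                 grid = g, extent = g$extent),
            class = "object_map")
}
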