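#' Random phase plate with Gaussian correlation
#'
#' Generates a thin scattering screen: a stationary Gaussian random phase map
#' with autocorrelation `C(r) = sd^2 * exp(-r^2 / l_c^2)` (so `l_c` is the 1/e
#' half-width), produced by spectral filtering of seeded white noise. An
#' optional binary overlay pattern is added as a phase step, emulating
#' structured features superimposed on the random screen. Generation is
#' bit-reproducible for a fixed seed and leaves the caller's RNG state
#' untouched.
#'
#' @param grid a [make_grid()] grid the plate is sampled on (the plate shares
#'   the object-grid pitch; see the methods vignette for the field-of-view
#'   discussion).
#' @param depth axial position `z_k` in um above the object plane (> 0).
#' @param correlation_length Gaussian correlation length `l_c` in um; must be
#'   at least the pixel pitch.
#' @param phase_std target standard deviation of the phase in radians.
#' @param seed integer seed.
#' @param overlay optional `list(mask = <logical n x n matrix>, amplitude =
#'   <radians>)` added where the mask is `TRUE`.
#' @return an object of class `phase_plate`: list with `phase` (radians,
#'   `n` x `n`), `depth`, `pitch`, `extent`, `correlation_length`,
#'   `phase_std`, `seed`.
#' @export
random_phase_plate <- function(grid, depth, correlation_length, phase_std,
                               seed, overlay = NULL) {
  stopifnot(is_field_grid(grid))
  if (depth <= 0) stop("random_phase_plate: 'depth' must be positive")
  if (correlation_length < grid$pitch)
    stop("random_phase_plate: 'correlation_length' must be >= pixel pitch")
  if (phase_std < 0) stop("random_phase_plate: 'phase_std' must be >= 0")
  n <- grid$n
  phase <- matrix(0, n, n)
  if (phase_std > 0) {
    w <- with_seed(seed, matrix(stats::rnorm(n * n), n, n))
    # amplitude filter sqrt(S(k)) with S(k) = exp(-k^2 l_c^2 / 4) giving
    # C(r) = exp(-r^2 / l_c^2)
    filt <- exp(-(grid$kr2) * correlation_length^2 / 8)
    f <- stats::fft(w) * filt
    ph <- Re(stats::fft(f, inverse = TRUE)) / (n * n)
    # scale so the theoretical (ensemble) standard deviation equals phase_std:
    # Var(ph) = mean(filt^2) for unit white noise under this normalisation
    ph <- ph / sqrt(mean(filt^2))
    phase <- ph * phase_std
  }
  if (!is.null(overlay)) {
    if (is.null(overlay$mask) || !all(dim(overlay$mask) == c(n, n)))
      stop("random_phase_plate: overlay mask must be an ", n, " x ", n, " matrix")
    amp <- if (is.null(overlay$amplitude)) 1.0 else overlay$amplitude
    phase <- phase + amp * (overlay$mask != 0)
  }
  structure(list(phase = phase, depth = depth, pitch = grid$pitch,
                 extent = grid$extent, correlation_length = correlation_length,
                 phase_std = phase_std, seed = seed),
            class = "phase_plate")
}

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.phase_plate <- function(x, ...) {
  cat(sprintf("<phase_plate> z = %g um, sd %.3g rad, l_c %.3g um, %d x %d\n",
              x$depth, stats::sd(as.vector(x$phase)), x$correlation_length,
              nrow(x$phase), ncol(x$phase)))
  invisible(x)
}

#' Ordered stack of phase plates over an object plane
#'
#' @param grid a [make_grid()] grid shared by all plates.
#' @param plates list of [random_phase_plate()] objects; depths must be
#'   strictly increasing and positive. May be empty.
#' @return object of class `medium_model` with elements `grid`, `plates`,
#'   `depths`, `surface_z` (the input plane `z_N`; 0 for an empty medium),
#'   `object_depth = 0`.
#' @export
medium_model <- function(grid, plates = list()) {
  stopifnot(is_field_grid(grid))
  depths <- vapply(plates, function(p) p$depth, numeric(1))
  if (length(depths)) {
    if (any(depths <= 0)) stop("medium_model: plate depths must be positive")
    if (any(diff(depths) <= 0))
      stop("medium_model: plate depths must be strictly increasing")
    for (p in plates)
      if (!all(dim(p$phase) == c(grid$n, grid$n)))
        stop("medium_model: plate grid mismatch")
  }
  structure(list(grid = grid, plates = plates, depths = depths,
                 surface_z = if (length(depths)) max(depths) else 0,
                 object_depth = 0),
            class = "medium_model")
}

#' @export
print.medium_model <- function(x, ...) {
  cat(sprintf("<medium_model> %d plate(s) at {%s} um over the object plane\n",
              length(x$plates), paste(signif(x$depths, 4), collapse = ", ")))
  invisible(x)
}

#' Calibrate plate strength to a target optical thickness
#'
#' Finds the phase standard deviation for which a stack of unit-variance
#' random screens, scaled by that value, has the requested one-way optical
#' thickness (in scattering mean free paths) as measured from the
#' transmission matrix itself: `OD = -log(eta_T)` with `eta_T` the
#' frequency-diagonal power fraction ([optical_thickness()]). The search is a
#' bracketed root find; the measurement uses a deterministic strided probe
#' over pupil modes (`n_probe` columns) so calibration stays cheap on large
#' grids.
#'
#' @param grid a [make_grid()] grid.
#' @param depths plate depths in um (strictly increasing).
#' @param correlation_length Gaussian correlation length in um.
#' @param target_od target one-way optical thickness (>= 0), in units of the
#'   scattering mean free path.
#' @param seed integer seed for the unit screens.
#' @param tolerance absolute tolerance on the measured optical thickness.
#' @param n_probe number of probe modes for the matrix measurement.
#' @param overlays optional list of overlay specs, one per plate (or `NULL`).
#' @return list with `phase_std` (the calibrated scale), `medium` (the
#'   calibrated `medium_model`), `measured_od` (probe measurement at the
#'   returned scale).
#' @export
calibrate_plate_strength <- function(grid, depths, correlation_length,
                                     target_od, seed, tolerance = 0.02,
                                     n_probe = 256, overlays = NULL) {
  if (target_od < 0) stop("calibrate_plate_strength: 'target_od' must be >= 0")
  make_medium <- function(s) {
    plates <- lapply(seq_along(depths), function(k)
      random_phase_plate(grid, depths[k], correlation_length, s,
                         seed = seed + k,
                         overlay = if (!is.null(overlays)) overlays[[k]] else NULL))
    medium_model(grid, plates)
  }
  if (target_od == 0) {
    med <- make_medium(0)
    return(list(phase_std = 0, medium = med, measured_od = 0))
  }
  od_of <- function(s) -log(eta_T_probe(make_medium(s), n_probe = n_probe))
  # bracket: the measurable OD saturates once the screens fully scramble the
  # pupil, so a target beyond that is unreachable
  hi <- sqrt(target_od / length(depths)) * 2
  it <- 0
  while (od_of(hi) < target_od && it < 8) { hi <- hi * 1.6; it <- it + 1 }
  if (od_of(hi) < target_od)
    stop("calibrate_plate_strength: target optical thickness is unreachable ",
         "with this parameterization (unbracketable)")
  root <- stats::uniroot(function(s) od_of(s) - target_od,
                         lower = 0, upper = hi, tol = tolerance / 8)
  s <- root$root
  med <- make_medium(s)
  list(phase_std = s, medium = med, measured_od = od_of(s))
}

#' Synthetic target objects
#'
#' Builds the complex amplitude-reflectance map `O(rho, z0)` of the buried
#' object. Supported kinds:
#' * `"siemens_star"`: multi-spoke star (binary), parameters `n_spokes`
#'   (default 8), `radius` (um, default 45% of the grid extent),
#'   `inner_radius` (um, default 0), `rotation` (radians).
#' * `"bitmap"`: grayscale image resampled (nearest neighbour) onto the grid,
#'   parameters `image` (numeric matrix in `[0, 1]`), `extent` (um side the
#'   image spans, default the grid extent).
#' * `"point_array"`: isolated unit reflectors, parameter `positions`
#'   (matrix/data.frame of `x, y` in um), `amplitudes` (default 1).
#'
#' @param kind one of `"siemens_star"`, `"bitmap"`, `"point_array"`.
#' @param params named list of kind-specific parameters.
#' @param grid a [make_grid()] grid.
#' @return object of class `object_map`: list with `reflectance` (complex
#'   `n` x `n`, `max |O| <= 1`), `grid`, `extent`.
#' @export
make_target_object <- function(kind, params = list(), grid) {
  stopifnot(is_field_grid(grid))
  n <- grid$n
  O <- switch(kind,
    siemens_star = {
      ns <- params$n_spokes %||% 8
      rmax <- params$radius %||% (0.45 * grid$extent)
      rmin <- params$inner_radius %||% 0
      # rotation only matters modulo the spoke period; reducing it first
      # makes the n-fold rotational symmetry exact in floating point
      rot <- (params$rotation %||% 0) %% (2 * pi / ns)
      xx <- matrix(grid$x, n, n)
      yy <- t(xx)
      r <- sqrt(xx^2 + yy^2)
      th <- atan2(yy, xx)
      1 * (sin(ns * (th + rot)) > 0 & r <= rmax & r >= rmin)
    },
    bitmap = {
      img <- params$image
      if (is.null(img) || !is.matrix(img))
        stop("make_target_object: bitmap needs params$image (a matrix)")
      ext <- params$extent %||% grid$extent
      # nearest-neighbour resample of the image onto the grid, centred
      out <- matrix(0, n, n)
      for (j in seq_len(n)) {
        v <- grid$x[j] / ext + 0.5
        cj <- floor(v * ncol(img)) + 1
        if (cj < 1 || cj > ncol(img)) next
        u <- grid$x / ext + 0.5
        ri <- floor(u * nrow(img)) + 1
        ok <- ri >= 1 & ri <= nrow(img)
        out[ok, j] <- img[ri[ok], cj]
      }
      out
    },
    point_array = {
      pos <- params$positions %||% matrix(c(0, 0), 1, 2)
      pos <- as.matrix(pos)
      amp <- params$amplitudes %||% rep(1, nrow(pos))
      out <- matrix(0, n, n)
      for (i in seq_len(nrow(pos)))
        out[grid_linear_index(grid, pos[i, ])] <- amp[i]
      out
    },
    stop("make_target_object: unknown kind '", kind, "'")
  )
  O <- as_complex_matrix(as.matrix(O))
  mx <- max(Mod(O))
  if (mx > 1) O <- O / mx  # passive reflector: |O| <= 1
  structure(list(reflectance = O, grid = grid, extent = grid$extent),
            class = "object_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.object_map <- function(x, ...) {
  cat(sprintf("<object_map> %d x %d over %.4g um, max |O| = %.3g\n",
              nrow(x$reflectance), ncol(x$reflectance), x$extent,
              max(Mod(x$reflectance))))
  invisible(x)
}

#' Regular-polygon overlay mask
#'
#' Convenience generator for plate overlays: a filled regular polygon.
#' @param grid a `field_grid`.
#' @param n_sides number of polygon sides (>= 3).
#' @param radius circumradius in um.
#' @param center polygon centre `c(x, y)` in um.
#' @param rotation rotation in radians.
#' @return logical `n` x `n` matrix.
#' @export
regular_polygon_mask <- function(grid, n_sides, radius, center = c(0, 0),
                                 rotation = 0) {
  stopifnot(n_sides >= 3)
  n <- grid$n
  xx <- matrix(grid$x, n, n) - center[1]
  yy <- t(matrix(grid$x, n, n)) - center[2]
  th <- atan2(yy, xx) - rotation
  r <- sqrt(xx^2 + yy^2)
  # apothem-based inequality for a regular polygon
  apo <- radius * cos(pi / n_sides)
  sector <- (th %% (2 * pi / n_sides)) - pi / n_sides
  r * cos(sector) <= apo
}

#' Field-of-view diameter of a recovered phase function
#'
#' The circular region of a plate at depth `z_k` that the roundtrip cone
#' geometry illuminates from a square region of interest of side `L0` at the
#' object plane: `L_k = L0 + 2 z_k tan(asin(na_eff))`. The default effective
#' aperture reproduces the cone-opening coefficient 1.2 (i.e.
#' `2 tan(asin(na_eff)) = 1.2`), the empirical value for a high-NA
#' reflection-matrix geometry; at `z_k = 0` the diameter is exactly `L0`.
#'
#' @param z_k plate depth in um (>= 0).
#' @param L0 region-of-interest side at the object plane, um.
#' @param na_eff effective aperture of the cone; default solves
#'   `2*tan(asin(na_eff)) = 1.2`.
#' @return diameter `L_k` in um.
#' @export
plate_fov_diameter <- function(z_k, L0, na_eff = sin(atan(0.6))) {
  if (any(z_k < 0)) stop("plate_fov_diameter: 'z_k' must be >= 0")
  if (na_eff <= 0 || na_eff >= 1)
    stop("plate_fov_diameter: 'na_eff' must lie in (0, 1)")
  L0 + 2 * z_k * tan(asin(na_eff))
}

#' Lateral and axial resolution of mapping a phase function
#'
#' The square region of interest of side `L0` at the object plane acts as the
#' aperture for quantifying a plate at depth `z_k`, giving an effective
#' numerical aperture `L0 / (2 z_k)`. The lateral resolution is
#' `(lambda/2) * (2 z_k / L0)` and the axial resolution
#' `2 lambda * (2 z_k / L0)^2` (standard diffraction scaling at unit
#' effective aperture).
#'
#' @param z_k plate depth in um (> 0).
#' @param L0 region-of-interest side, um.
#' @param wavelength wavelength in um.
#' @return named list `list(lateral, axial)` in um.
#' @export
mapping_resolution <- function(z_k, L0, wavelength) {
  if (any(z_k <= 0))
    stop("mapping_resolution: 'z_k' must be positive (object plane excluded)")
  if (L0 <= 0) stop("mapping_resolution: 'L0' must be positive")
  s <- 2 * z_k / L0
  list(lateral = wavelength / 2 * s, axial = 2 * wavelength * s^2)
}
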