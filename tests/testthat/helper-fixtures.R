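# Shared fixtures for the test suite.  All phantoms are generated in code at
# fixed seeds; grids are kept small (16^2 / 32^2) so the default run stays
# fast.

tiny_grid <- function(n = 16) make_grid(n, 0.45, 0.9, 1.0)

small_grid <- function() make_grid(32, 0.45, 0.9, 1.0)

# passband-projected random field
random_passband_field <- function(grid, seed = 1) {
  set.seed(seed)
  n <- grid$n
  v <- matrix(complex(real = stats::rnorm(n^2), imaginary = stats::rnorm(n^2)),
              n, n)
  sp <- stats::fft(v)
  sp[!grid$pupil] <- 0
  complex_field(grid, stats::fft(sp, inverse = TRUE) / n^2)
}

# single calibrated plate over a Siemens star: the workhorse phantom
single_plate_phantom <- function(grid = small_grid(), depth = 10,
                                 phase_std = 0.9, seed = 7,
                                 correlation_length = 2) {
  plate <- random_phase_plate(grid, depth, correlation_length, phase_std,
                              seed = seed)
  medium <- medium_model(grid, list(plate))
  object <- make_target_object("siemens_star", list(n_spokes = 8), grid)
  list(grid = grid, plate = plate, medium = medium, object = object,
       R = reflection_from_medium(medium, object))
}

# brute-force O(N^4) angular-spectrum propagation by explicit mode summation
# (independent of the package's FFT path); for tiny grids only
brute_force_propagate <- function(field, distance) {
  g <- field$grid
  n <- g$n
  out <- matrix(0 + 0i, n, n)
  kzv <- sqrt(pmax(g$k0^2 - g$kr2, 0))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    # spectral coefficient of mode (a, b) by direct summation
    ph <- exp(-1i * outer(g$kx[a] * ((seq_len(n) - 1) * g$pitch),
                          g$kx[b] * ((seq_len(n) - 1) * g$pitch), `+`))
    coef <- sum(field$values * ph) / n^2
    ph2 <- exp(1i * outer(g$kx[a] * ((seq_len(n) - 1) * g$pitch),
                          g$kx[b] * ((seq_len(n) - 1) * g$pitch), `+`))
    out <- out + coef * ph2 * exp(1i * kzv[a, b] * distance)
  }
  out
}

frob <- function(m) sqrt(sum(Mod(m)^2))

rel_err <- function(a, b) frob(a - b) / frob(b)
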