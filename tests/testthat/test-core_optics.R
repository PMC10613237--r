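test_that("make_grid validates arguments and exposes derived quantities", {
  g <- make_grid(100, 0.45, 0.9, 1.0)
  expect_equal(g$extent, 45)
  expect_equal(g$k0, 2 * pi / 0.9)

  g2 <- make_grid(2, 1.0, 2.0, 1.0)
  expect_equal(g2$k0, pi)

  # pitch exactly lambda/2 is accepted at the boundary
  expect_s3_class(make_grid(64, 0.65, 1.3, 1.0), "field_grid")
  expect_error(make_grid(64, 0.66, 1.3, 1.0), "pitch")

  expect_error(make_grid(1, 0.45, 0.9, 1.0), "'n'")
  expect_error(make_grid(16, -0.1, 0.9, 1.0), "'pitch'")
  expect_error(make_grid(16, 0.45, 0, 1.0), "'wavelength'")
  expect_error(make_grid(16, 0.45, 0.9, 1.5), "'na'")
})

test_that("angular-spectrum propagation matches the analytic dispersion relation", {
  g <- tiny_grid()
  n <- g$n
  # a grid-resident plane wave with sin(theta) ~ 0.5
  qi <- which.min(abs(g$kx - 0.5 * g$k0))
  kxg <- g$kx[qi]
  xx <- matrix(g$x, n, n)
  pw <- exp(1i * kxg * xx)
  dz <- 7.3
  out <- angular_spectrum_propagate(complex_field(g, pw), dz)
  kz <- sqrt(g$k0^2 - kxg^2)
  expect_lt(max(Mod(out$values - pw * exp(1i * kz * dz))), 1e-12)

  # zero distance is the identity
  f <- random_passband_field(g, 3)
  expect_lt(max(Mod(angular_spectrum_propagate(f, 0)$values - f$values)), 1e-12)

  expect_error(angular_spectrum_propagate(f, NaN), "finite")
})

test_that("propagation agrees with a brute-force mode-summation oracle", {
  g <- tiny_grid(8)
  f <- random_passband_field(g, 11)
  for (dz in c(0.9, -2.7)) {
    got <- angular_spectrum_propagate(f, dz)$values
    ref <- brute_force_propagate(f, dz)
    expect_lt(rel_err(got, ref), 1e-10)
  }
})

test_that("propagation is unitary, reversible and composable", {
  g <- tiny_grid()
  f <- random_passband_field(g, 5)
  e0 <- field_energy(f)
  for (dz in c(0.45, 3.1, 17, 100)) {
    fd <- angular_spectrum_propagate(f, dz)
    expect_lt(abs(field_energy(fd) - e0) / e0, 1e-9)
    back <- angular_spectrum_propagate(fd, -dz)
    expect_lt(rel_err(back$values, f$values), 1e-9)
  }
  # composition P(a->c) = P(b->c) P(a->b)
  one <- angular_spectrum_propagate(f, 5.2)
  two <- angular_spectrum_propagate(angular_spectrum_propagate(f, 2.1), 3.1)
  expect_lt(rel_err(two$values, one$values), 1e-9)
})

test_that("paraxial propagation reproduces the Fresnel limit", {
  # a wide Gaussian beam on a fine grid: low effective NA
  g <- make_grid(64, 0.45, 0.9, 1.0)
  n <- g$n
  xx <- matrix(g$x, n, n)
  rr2 <- xx^2 + t(xx)^2
  w0 <- 6
  beam <- exp(-rr2 / w0^2)
  dz <- 40
  got <- angular_spectrum_propagate(complex_field(g, beam + 0i), dz)$values
  # Fresnel transfer function (quadratic dispersion), computed independently
  Hf <- exp(1i * g$k0 * dz) * exp(-1i * g$kr2 * dz / (2 * g$k0))
  ref <- stats::fft(stats::fft(beam) * Hf, inverse = TRUE) / n^2
  expect_lt(rel_err(got, ref), 0.01)
})

test_that("dense propagation operator matches the FFT path and is reciprocal", {
  g <- tiny_grid()
  n <- g$n
  P <- propagation_matrix(g, 0, 0.9)
  # a delta column equals propagation of that delta
  delta <- matrix(0 + 0i, n, n); delta[5, 9] <- 1
  pd <- angular_spectrum_propagate(complex_field(g, delta), 0.9)$values
  expect_lt(max(Mod(P$values[, (9 - 1) * n + 5] - as.vector(pd))), 1e-12)
  # reciprocity: symmetric in the space basis
  expect_lt(max(Mod(P$values - t(P$values))), 1e-10)
  # identity at zero distance
  P0 <- propagation_matrix(g, 3, 3)
  expect_lt(max(Mod(P0$values - diag(1 + 0i, n^2))), 1e-12)
  # composition P(0 -> 2 lambda) = P(lambda -> 2 lambda) P(0 -> lambda)
  Pa <- propagation_matrix(g, 0, 1.8)
  Pb <- propagation_matrix(g, 0.9, 1.8)
  expect_lt(rel_err(Pb$values %*% P$values, Pa$values), 1e-9)
})

test_that("Green's reference is a shifted band-limited point response", {
  g <- tiny_grid()
  expect_error(greens_reference(g, c(0, 0), 0), "non-zero")
  G0 <- greens_reference(g, c(0, 0), 5)
  G1 <- greens_reference(g, c(2 * g$pitch, -g$pitch), 5)
  # translation invariance: identical up to the lateral shift
  shifted <- G0$values[((seq_len(g$n) - 1 - 2) %% g$n) + 1,
                       ((seq_len(g$n) - 1 + 1) %% g$n) + 1]
  expect_lt(max(Mod(G1$values - shifted)), 1e-12)
  # consistency with the dense propagation operator's delta column
  P <- propagation_matrix(g, 0, 5)
  o <- floor(g$n / 2) + 1
  expect_lt(max(Mod(G0$values - matrix(P$values[, (o - 1) * g$n + o], g$n))),
            1e-10)
})

test_that("frequency-basis transform is unitary, invertible and shifts tilts", {
  g <- tiny_grid()
  n <- g$n
  d <- n^2
  P <- propagation_matrix(g, 0, 2.3)
  Tm <- transmission_matrix(P$values, g, input_plane = 2.3)
  Tf <- to_frequency_basis(Tm)
  expect_identical(Tf$basis, "frequency")
  expect_error(to_frequency_basis(Tf), "already")
  # round trip
  Tb <- to_space_basis(Tf)
  expect_lt(rel_err(Tb$values, Tm$values), 1e-10)
  # Parseval: total power preserved
  expect_lt(abs(sum(Mod(Tf$values)^2) - sum(Mod(Tm$values)^2)) /
              sum(Mod(Tm$values)^2), 1e-9)
  # the identity is Fourier-invariant
  If <- to_frequency_basis(transmission_matrix(diag(1 + 0i, d), g, 0))
  expect_lt(max(Mod(If$values - diag(1 + 0i, d))), 1e-10)
  # a pure tilt plate becomes a shifted (permutation-like) diagonal
  qi <- 3  # fft-order mode index along x
  xx <- matrix(g$x, n, n)
  tilt <- exp(1i * g$kx[qi] * xx)
  D <- transmission_matrix(diag(as.vector(tilt)), g, 0)
  Df <- to_frequency_basis(D)
  per_row_max <- apply(Mod(Df$values), 1, max)
  off_diag_mass <- sum(Mod(Df$values)^2) - sum(per_row_max^2)
  expect_lt(off_diag_mass / sum(Mod(Df$values)^2), 1e-9)
  # and the diagonal itself is (nearly) empty: the energy moved off-diagonal
  expect_lt(sum(Mod(diag(Df$values))^2) / sum(Mod(Df$values)^2), 1e-9)
})
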