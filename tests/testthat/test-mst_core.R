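test_that("plane transforms compose and invert on the passband", {
  ph <- single_plate_phantom(tiny_grid(), depth = 5)
  R <- ph$R
  # no-op transform
  expect_identical(transform_to_layer(R)$values, R$values)
  # there and back
  R1 <- transform_to_layer(R, input_plane = 5)
  back <- transform_to_layer(R1, input_plane = 0)
  expect_lt(rel_err(back$values, R$values), 1e-9)
  # composition of two partial transforms equals the direct transform
  mid <- transform_to_layer(R, input_plane = 2, output_plane = 1)
  two <- transform_to_layer(mid, input_plane = 5, output_plane = 0)
  expect_lt(rel_err(two$values, R1$values), 1e-9)
  expect_error(transform_to_layer(to_frequency_basis(R)), "space basis")
})

test_that("layer-referenced matrices factor as object x Green x phase", {
  # structural identity: for a single plate, the (z0, z1)-referenced matrix
  # equals t(A) O P Phi1 with the dense operators as an independent oracle
  g <- tiny_grid()
  obj <- make_target_object("siemens_star", list(n_spokes = 4), g)
  pl <- random_phase_plate(g, 4, 2, 0.8, seed = 3)
  med <- medium_model(g, list(pl))
  R <- reflection_from_medium(med, obj)
  R1 <- transform_to_layer(R, input_plane = 4)
  P <- propagation_matrix(g, 0, 4)$values
  A <- medium_transmission(med)$values %*% Conj(P)
  ref <- t(A) %*% (as.vector(obj$reflectance) *
                     (P %*% diag(exp(1i * as.vector(pl$phase)))))
  expect_lt(rel_err(R1$values, ref), 1e-8)
})

test_that("Green's normalization exposes the rank-1 phase structure", {
  g <- small_grid()
  obj_d <- make_target_object("point_array",
                              list(positions = matrix(c(0, 0), 1)), g)
  # no plate (zero-phase screen): every normalized column is the same
  # single-pixel spike, flat in phase across columns
  pl0 <- random_phase_plate(g, 6, 2, 0, seed = 1)
  R <- reflection_from_medium(medium_model(g, list(pl0)), obj_d)
  S <- normalize_by_greens(transform_to_layer(R, input_plane = 6),
                           regularization = 1e-9, normalization = "amplitude")
  o <- (floor(g$n / 2)) * g$n + floor(g$n / 2) + 1
  amp <- Mod(S$values[o, ])
  expect_lt(stats::sd(amp) / mean(amp), 1e-6)
  expect_lt(max(abs(Arg(S$values[o, ] / S$values[o, 1]))), 1e-6)

  # with no unmodelled term (single scattering event on the way in, clean
  # output path) the normalized matrix is exactly rank-1
  ph <- single_plate_phantom(g, depth = 10)
  obj_v <- as.vector(ph$object$reflectance)
  P <- propagation_matrix(g, 0, 10)$values
  first_term <- obj_v * (P %*% diag(exp(1i * as.vector(ph$plate$phase))))
  R1w <- reflection_matrix(first_term, g, input_plane = 10, output_plane = 0)
  S1 <- normalize_by_greens(R1w, regularization = 1e-9,
                            normalization = "amplitude")
  sv <- svd(S1$values, nu = 0, nv = 0)$d
  expect_gt(sv[1]^2 / sum(sv^2), 0.99)

  # the roundtrip phantom carries unmodelled output-path scattering, and a
  # second plate adds more still: the rank-1 fraction drops in that order
  Sr <- normalize_by_greens(transform_to_layer(ph$R, input_plane = 10),
                            regularization = 1e-9,
                            normalization = "amplitude")
  svr <- svd(Sr$values, nu = 0, nv = 0)$d
  p2 <- random_phase_plate(g, 20, 2, 0.9, seed = 8)
  med2 <- medium_model(g, list(ph$plate, p2))
  R2 <- reflection_from_medium(med2, ph$object)
  S2 <- normalize_by_greens(transform_to_layer(R2, input_plane = 10),
                            regularization = 1e-9,
                            normalization = "amplitude")
  sv2 <- svd(S2$values, nu = 0, nv = 0)$d
  expect_lt(svr[1]^2 / sum(svr^2), sv[1]^2 / sum(sv^2))
  expect_lt(sv2[1]^2 / sum(sv2^2), svr[1]^2 / sum(svr^2))

  expect_error(normalize_by_greens(ph$R), "z_k > 0")
})

test_that("power iteration recovers the rank-1 phase factor", {
  g <- tiny_grid()
  n <- g$n
  d <- n^2
  set.seed(4)
  o <- complex(real = stats::rnorm(d), imaginary = stats::rnorm(d))
  phi <- 2 * (stats::runif(d) - 0.5) * 2
  ref_idx <- mstrace:::grid_linear_index(g, c(0, 0))
  phi <- phi - phi[ref_idx]
  Sv <- o %o% exp(1i * phi)
  conf <- mst_config(layer_depths = 5)
  Sobj <- structure(list(values = Sv, mask = NULL, layer_depth = 5, grid = g),
                    class = "normalized_matrix")
  est <- estimate_phase(Sobj, conf)
  err <- atan2(sin(est$increment - matrix(phi, n, n)),
               cos(est$increment - matrix(phi, n, n)))
  expect_lt(sqrt(mean(err^2)), 1e-6)

  # 1% perturbation: still within 0.1 rad RMS of the svd oracle and truth
  set.seed(5)
  noise <- matrix(complex(real = stats::rnorm(d * d),
                          imaginary = stats::rnorm(d * d)), d, d)
  noise <- noise * sqrt(0.01 * sum(Mod(Sv)^2) / sum(Mod(noise)^2))
  Sp <- Sobj; Sp$values <- Sv + noise
  estp <- estimate_phase(Sp, conf)
  err2 <- atan2(sin(estp$increment - matrix(phi, n, n)),
                cos(estp$increment - matrix(phi, n, n)))
  expect_lt(sqrt(mean(err2^2)), 0.1)
  v_svd <- svd(Sp$values, nu = 0, nv = 1)$v[, 1]
  phi_svd <- Arg(Conj(v_svd)); phi_svd <- phi_svd - phi_svd[ref_idx]
  err3 <- atan2(sin(as.vector(estp$increment) - phi_svd),
                cos(as.vector(estp$increment) - phi_svd))
  expect_lt(sqrt(mean(err3^2)), 0.05)

  # pairwise column-correlation estimator (the two-field limit) agrees on
  # strong columns within 0.2 rad RMS
  phi_pair <- Arg(crossprod(Conj(Sp$values), Sp$values[, ref_idx]))
  err4 <- atan2(sin(as.vector(estp$increment) + phi_pair),
                cos(as.vector(estp$increment) + phi_pair))
  expect_lt(sqrt(mean(err4^2)), 0.2)
})

test_that("phase corrections apply per side and invert exactly", {
  ph <- single_plate_phantom(small_grid(), depth = 10)
  R1 <- transform_to_layer(ph$R, input_plane = 10)
  inc <- matrix(stats::rnorm(ph$grid$n^2, sd = 0.5), ph$grid$n)
  Rc <- apply_phase_correction(R1, inc, side = "input")
  Rb <- apply_phase_correction(Rc, -inc, side = "input")
  expect_lt(rel_err(Rb$values, R1$values), 1e-12)
  expect_identical(apply_phase_correction(R1, matrix(0, ph$grid$n, ph$grid$n),
                                          "input")$values, R1$values)

  # ground-truth correction at the right depth restores the confocal image;
  # a wrong-depth correction does strictly worse
  truth <- Mod(ph$object$reflectance)^2
  correct_at <- function(z) {
    Rz <- transform_to_layer(ph$R, input_plane = z)
    Rz <- apply_phase_correction(Rz, ph$plate$phase, "input")
    Rz <- transform_to_layer(Rz, input_plane = 0)
    # same correction on the output path via the transpose
    Rt <- reflection_matrix(t(Rz$values), ph$grid)
    Rt <- transform_to_layer(Rt, input_plane = z)
    Rt <- apply_phase_correction(Rt, ph$plate$phase, "input")
    Rt <- transform_to_layer(Rt, input_plane = 0)
    pearson_score(matrix(Mod(diag(Rt$values))^2, ph$grid$n), truth)
  }
  cc_right <- correct_at(10)
  cc_wrong <- correct_at(30)
  expect_gt(cc_right, 0.99)
  expect_lt(cc_wrong, cc_right)
})

test_that("structural correction with the ground truth is an exact inverse", {
  g <- small_grid()
  obj <- make_target_object("siemens_star", list(n_spokes = 8), g)
  cal <- calibrate_plate_strength(g, c(10, 20), 2, 1.5, seed = 17)
  R <- reflection_from_medium(cal$medium, obj)
  Rc <- corrected_reflection(R, cal$medium)
  expect_lt(max(Mod(diag(Rc$values) - as.vector(obj$reflectance))), 1e-8)
  # identity stack leaves the matrix unchanged
  expect_identical(corrected_reflection(R, medium_model(g, list()))$values,
                   R$values)
  # reconstruct_object returns O up to numerical precision
  est <- reconstruct_object(Rc)
  expect_lt(max(Mod(est$reflectance - obj$reflectance)), 1e-8)
})

test_that("the global piston is a gauge freedom of the intensity images", {
  g <- tiny_grid()
  obj <- make_target_object("siemens_star", list(n_spokes = 4), g)
  pl <- random_phase_plate(g, 5, 2, 0.8, seed = 2)
  med1 <- medium_model(g, list(pl))
  pl2 <- pl; pl2$phase <- pl$phase + 1.234
  med2 <- medium_model(g, list(pl2))
  R1 <- reflection_from_medium(med1, obj)
  R2 <- reflection_from_medium(med2, obj)
  expect_lt(max(abs(confocal_image(R1) - confocal_image(R2))), 1e-12)
  i1 <- Mod(diag(corrected_reflection(R1, med1)$values))^2
  i2 <- Mod(diag(corrected_reflection(R2, med2)$values))^2
  expect_lt(max(abs(i1 - i2)), 1e-10)
})

test_that("the MST loop handles a scattering-free matrix gracefully", {
  g <- tiny_grid()
  obj <- make_target_object("siemens_star", list(n_spokes = 4), g)
  R <- reflection_from_medium(medium_model(g, list()), obj)
  res <- mst_iterate(R, mst_config(layer_depths = 5, max_cycles = 5))
  expect_true(res$converged)
  expect_equal(res$cycles_run, 1L)
  expect_lt(sqrt(mean(res$estimates[[1]]$phase_c^2)), 0.02)
  expect_lt(abs(res$traces$xi1[nrow(res$traces)] - 1), 0.05)
})

test_that("a single plate at moderate thickness is recovered essentially exactly", {
  ph <- single_plate_phantom(small_grid(), depth = 10, phase_std = 0.9)
  res <- mst_iterate(ph$R, mst_config(layer_depths = 10, max_cycles = 8))
  expect_true(res$converged)
  cc <- pearson_score(res$estimates[[1]]$phase_c, ph$plate$phase,
                      mode = "complex_phase",
                      mask = res$estimates[[1]]$fov_mask)
  expect_gt(cc, 0.99)
  expect_gt(pearson_score(res$image, Mod(ph$object$reflectance)^2), 0.99)
})

test_that("recovery is robust to object-uncorrelated background scattering", {
  ph <- single_plate_phantom(small_grid(), depth = 10, phase_std = 0.9)
  Rn <- add_background_scattering(ph$R, relative_power = 3,
                                  correlation_length = 2, seed = 99)
  res <- mst_iterate(Rn, mst_config(layer_depths = 10, max_cycles = 8))
  cc <- pearson_score(res$estimates[[1]]$phase_c, ph$plate$phase,
                      mode = "complex_phase",
                      mask = res$estimates[[1]]$fov_mask)
  expect_gt(cc, 0.8)
})

test_that("the single-plate depth scan peaks at the true plate depth", {
  ph <- single_plate_phantom(small_grid(), depth = 20, phase_std = 0.9)
  sweep <- sweep_depth(ph$R, c(8, 14, 20, 26, 32), max_cycles = 2)
  expect_equal(sweep$depth_um[which.max(sweep$eta_c)], 20)
})

test_that("enhancement traces rise monotonically to saturation", {
  g <- small_grid()
  obj <- make_target_object("siemens_star", list(n_spokes = 8), g)
  cal <- calibrate_plate_strength(g, c(10, 20), 2, 1.5, seed = 23)
  R <- reflection_from_medium(cal$medium, obj)
  res <- mst_iterate(R, mst_config(layer_depths = c(10, 20), max_cycles = 8))
  # confocal enhancement rises to saturation within a 1% band
  ec <- res$traces$eta_c
  expect_true(all(diff(ec) > -0.01 * ec[-length(ec)]))
  # and so does the image correlation with ground truth, cycle by cycle
  truth <- Mod(obj$reflectance)^2
  cc <- vapply(1:4, function(m)
    pearson_score(mst_iterate(R, mst_config(layer_depths = c(10, 20),
                                            max_cycles = m))$image, truth),
    numeric(1))
  expect_true(all(diff(cc) > -0.01 * cc[-length(cc)]))
})
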