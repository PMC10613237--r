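test_that("layer transmission composes a phase factor with propagation", {
  g <- tiny_grid()
  n <- g$n
  d <- n^2
  # zero plate, zero distance -> identity
  p0 <- random_phase_plate(g, 5, 2, 0, seed = 1)
  P0 <- propagation_matrix(g, 5, 5)
  T0 <- layer_transmission(p0, P0)
  expect_lt(max(Mod(T0$values - diag(1 + 0i, d))), 1e-12)
  # zero plate, distance d -> the propagation matrix alone
  Pd <- propagation_matrix(g, 0, 5)
  Td <- layer_transmission(p0, Pd)
  expect_lt(max(Mod(Td$values - Pd$values)), 1e-12)
  # tilt-ramp plate: a normal plane wave exits as the tilted one, propagated
  qi <- 3
  xx <- matrix(g$x, n, n)
  tilt <- g$kx[qi] * xx
  pt <- p0; pt$phase <- tilt
  Tt <- layer_transmission(pt, Pd)
  outw <- matrix(Tt$values %*% rep(1 + 0i, d), n, n)
  kz <- sqrt(g$k0^2 - g$kx[qi]^2)
  expected <- exp(1i * tilt) * exp(1i * kz * 5)
  expect_lt(rel_err(outw, expected), 1e-10)
})

test_that("medium transmission is the ordered unitary product of its layers", {
  g <- tiny_grid()
  d <- g$n^2
  # empty medium -> identity
  T0 <- medium_transmission(medium_model(g, list()))
  expect_lt(max(Mod(T0$values - diag(1 + 0i, d))), 1e-12)
  # single plate: equals the explicit two-factor product (dense oracle)
  pl <- random_phase_plate(g, 4, 2, 0.8, seed = 5)
  med <- medium_model(g, list(pl))
  Tm <- medium_transmission(med)
  Pd <- propagation_matrix(g, 0, 4)$values
  ref <- Pd %*% diag(exp(1i * as.vector(pl$phase)))
  expect_lt(rel_err(Tm$values, ref), 1e-10)
  # unitarity of the phase-only lossless model
  expect_lt(max(Mod(Conj(t(Tm$values)) %*% Tm$values - diag(1 + 0i, d))),
            1e-9)
  expect_lte(max(svd(Tm$values, nu = 0, nv = 0)$d), 1 + 1e-6)
})

test_that("optical thickness is additive over independent stacked plates", {
  g <- small_grid()
  p1 <- random_phase_plate(g, 8, 2, 0.8, seed = 21)
  p2 <- random_phase_plate(g, 16, 2, 0.8, seed = 22)
  od1 <- optical_thickness(medium_transmission(medium_model(g, list(p1))))
  od2 <- optical_thickness(medium_transmission(medium_model(g, list(p2))))
  od12 <- optical_thickness(medium_transmission(medium_model(g, list(p1, p2))))
  expect_lt(abs(od12 - (od1 + od2)) / (od1 + od2), 0.10)
})

test_that("reflection matrices follow R = T^T O T with reciprocity", {
  g <- small_grid()
  obj <- make_target_object("siemens_star", list(n_spokes = 8), g)
  Ov <- as.vector(obj$reflectance)
  # no medium: R is exactly diag(O); identity mirror gives the identity
  R0 <- reflection_from_medium(medium_model(g, list()), obj)
  expect_lt(max(Mod(R0$values - diag(Ov))), 1e-12)
  mirror <- obj; mirror$reflectance <- matrix(1 + 0i, g$n, g$n)
  Rm <- reflection_from_medium(medium_model(g, list()), mirror)
  expect_lt(max(Mod(Rm$values - diag(1 + 0i, g$n^2))), 1e-12)
  # dense-oracle cross-check of the kernel route on a tiny grid
  gt <- tiny_grid()
  objt <- make_target_object("siemens_star", list(n_spokes = 4), gt)
  pl <- random_phase_plate(gt, 4, 2, 0.8, seed = 13)
  medt <- medium_model(gt, list(pl))
  Rt <- reflection_from_medium(medt, objt)
  A <- medium_transmission(medt)$values %*%
    Conj(propagation_matrix(gt, 0, 4)$values)
  ref <- t(A) %*% (as.vector(objt$reflectance) * A)
  expect_lt(rel_err(Rt$values, ref), 1e-9)
  # reciprocity
  expect_lt(rel_err(Rt$values, t(Rt$values)), 1e-8)
})

test_that("a strongly scattering stack obscures the measured confocal image", {
  g <- small_grid()
  cal <- calibrate_plate_strength(g, c(17, 25, 35, 50), 2, 3.3, seed = 31)
  obj <- make_target_object("siemens_star", list(n_spokes = 8), g)
  R <- reflection_from_medium(cal$medium, obj, aperture = "pupil")
  cc <- pearson_score(confocal_image(R), Mod(obj$reflectance)^2)
  expect_lt(cc, 0.5)
})

test_that("background clutter is seeded, symmetric and power-scaled", {
  ph <- single_plate_phantom(tiny_grid())
  R <- ph$R
  expect_identical(add_background_scattering(R, 0, 2, seed = 1)$values,
                   R$values)
  Ra <- add_background_scattering(R, 1, 2, seed = 5)
  Rb <- add_background_scattering(R, 1, 2, seed = 5)
  expect_identical(Ra$values, Rb$values)
  C <- Ra$values - R$values
  expect_lt(rel_err(C, t(C)), 1e-10)
  expect_lt(abs(sum(Mod(C)^2) / sum(Mod(R$values)^2) - 1), 1e-10)
})

test_that("scan-stack assembly round-trips and has the stated structure", {
  g <- tiny_grid()
  d <- g$n^2
  ph <- single_plate_phantom(g)
  st <- synthesize_scan(ph$R)
  R2 <- assemble_from_scan(st)
  expect_identical(R2$values, ph$R$values)   # exact round trip
  # perfect mirror at focus: delta responses assemble to the identity
  mirror <- ph$object; mirror$reflectance <- matrix(1 + 0i, g$n, g$n)
  Rmir <- reflection_from_medium(medium_model(g, list()), mirror)
  st2 <- synthesize_scan(Rmir)
  expect_lt(max(Mod(assemble_from_scan(st2)$values - diag(1 + 0i, d))), 1e-12)
  # a single off-centre point scatterer gives a rank-1 matrix whose columns
  # share one pattern
  pt <- make_target_object("point_array",
                           list(positions = matrix(c(2 * g$pitch, -g$pitch), 1)), g)
  Rpt <- reflection_from_medium(medium_model(g, list()), pt)
  sv <- svd(Rpt$values, nu = 0, nv = 0)$d
  expect_lt(sv[2] / sv[1], 1e-10)
  # off-lattice positions are rejected
  pos <- mstrace:::raster_positions(g)
  pos[1, 1] <- pos[1, 1] + 0.3 * g$pitch
  expect_error(scan_stack(g, st$fields, pos), "lattice")
})

test_that("confocal images are the squared diagonal and validate metadata", {
  g <- tiny_grid()
  obj <- make_target_object("siemens_star", list(n_spokes = 4), g)
  R <- reflection_from_medium(medium_model(g, list()), obj)
  img <- confocal_image(R)
  expect_equal(img, Mod(obj$reflectance)^2, tolerance = 1e-12)
  Rf <- to_frequency_basis(R)
  expect_error(confocal_image(Rf), "space basis")
  Rz <- transform_to_layer(R, input_plane = 5)
  expect_error(confocal_image(Rz), "co-located")
})
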