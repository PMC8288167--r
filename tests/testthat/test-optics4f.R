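# 4f propagation, lens transform, oracles and broadband synthesis

test_that("lens transform maps a Gaussian to its Fourier pair and conserves power", {
  g <- grid2d(256, 256, 4)
  w <- 60
  field <- gaussian_probe(g, LAMBDA, w)
  ft <- lens_fourier_transform(field, FOCAL)
  # closed form: waist w maps to lambda f / (pi w) at the Fourier plane
  wf <- LAMBDA * FOCAL / (pi * w)
  rf <- sqrt(grid_mesh(ft$grid)$X^2 + grid_mesh(ft$grid)$Y^2)
  expected <- exp(-rf^2 / wf^2)
  got <- Mod(ft$ex) / max(Mod(ft$ex))
  expect_lt(max(abs(got - expected)), 1e-8)
  expect_equal(field_power(ft), field_power(field), tolerance = 1e-10)
  # uniform (periodic plane wave) concentrates in the DC bin
  pw <- scalar_field(matrix(1, 256, 256), g, LAMBDA)
  fpw <- lens_fourier_transform(pw, FOCAL)
  I <- intensity(fpw)
  expect_gt(I[129, 129] / sum(I), 1 - 1e-12)
})

test_that("the empty 4f relay reproduces the input upright and conserves power", {
  g <- grid2d(128, 128, 5)
  set.seed(21)
  ob <- random_bandlimited(g)
  fld <- scalar_field(ob, g, LAMBDA)
  relay <- system_4f(FOCAL, design = NULL, analyzer = FALSE, pad_factor = 2)
  out <- propagate_4f(fld, relay)
  expect_lt(rel_l2(out$ex, fld$ex), 1e-10)
  expect_lt(abs(field_power(out) / field_power(fld) - 1), 1e-10)
  # magnifying relay (f2 = 2 f1) scales the grid and conserves power
  mag <- system_4f(FOCAL, 2 * FOCAL, design = NULL, analyzer = FALSE, pad_factor = 1)
  outm <- propagate_4f(fld, mag)
  expect_equal(outm$grid$dx, 2 * g$dx, tolerance = 1e-12)
  expect_lt(abs(field_power(outm) / field_power(fld) - 1), 1e-10)
})

test_that("linear design between crossed polarizers is the shifted difference", {
  g <- grid2d(128, 128, 5)
  sys <- system_4f(FOCAL, design = linear_orientation_map(PERIOD, aperture_d = 1e7),
                   pad_factor = 1)
  set.seed(22)
  for (k in 1:5) {
    ob <- random_bandlimited(g)
    sim <- propagate_4f(scalar_field(ob, g, LAMBDA), sys)
    orc <- shifted_difference_oracle(ob, DELTA, g, "linear")
    cc <- fit_const(sim$ey, orc)
    expect_lt(rel_l2(sim$ey, cc * orc), 1e-6)
  }
})

test_that("radial design between crossed polarizers is the sin(2 pi Delta k_r) filter", {
  g <- grid2d(128, 128, 5)
  sys <- system_4f(FOCAL, design = radial_orientation_map(PERIOD, aperture_d = 1e7),
                   pad_factor = 1)
  set.seed(23)
  ob <- random_bandlimited(g)
  sim <- propagate_4f(scalar_field(ob, g, LAMBDA), sys)
  ref <- sin_filter(ob, DELTA, g)
  cc <- fit_const(sim$ey, ref)
  expect_lt(rel_l2(sim$ey, cc * ref), 1e-6)
})

test_that("a uniform object is fully extinguished by the crossed analyzer", {
  g <- grid2d(128, 128, 5)
  sys <- system_4f(FOCAL, design = radial_orientation_map(PERIOD, aperture_d = 1e7),
                   pad_factor = 1)
  u <- scalar_field(matrix(1, 128, 128), g, LAMBDA)
  out <- propagate_4f(u, sys)
  expect_lt(field_power(out) / field_power(u), 1e-10)
})

test_that("shifted-difference oracle obeys the shift theorem and annulus support", {
  g <- grid2d(128, 128, 5)
  expect_equal(shifted_difference_oracle(matrix(1 + 0i, 128, 128), 0, g, "linear"),
               matrix(0 + 0i, 128, 128))
  # pure harmonic: output is 2 i sin(2 pi Delta u) times the input
  u0 <- 10 / (128 * 5)
  m <- grid_mesh(g)
  harm <- exp(2i * pi * u0 * m$X)
  out <- shifted_difference_oracle(harm, DELTA, g, "linear")
  expect_lt(rel_l2(out, 2i * sin(2 * pi * DELTA * u0) * harm), 1e-10)
  # radial difference of a disk lives in the annulus [R - Delta, R + Delta]
  sc <- render_scene(scene_spec("disk", g, radius = 120))
  outr <- shifted_difference_oracle(sc$map + 0i, DELTA, g, "radial")
  r <- sqrt(m$X^2 + m$Y^2)
  outside <- r < 120 - DELTA - 2 * g$dx | r > 120 + DELTA + 2 * g$dx
  expect_lt(max(Mod(outr[outside])), 1e-10 * max(Mod(outr)))
  expect_error(shifted_difference_oracle(harm, 1e6, g, "linear"),
               class = "metaedge_domain_error")
})

test_that("derivative model vanishes on constants and peaks where the gradient peaks", {
  g <- grid2d(128, 128, 2)
  expect_equal(derivative_model(matrix(3, 128, 128), DELTA, g), matrix(0, 128, 128))
  w <- 60
  A <- exp(-radius_mesh_test(g)^2 / w^2)
  dm <- derivative_model(A, DELTA, g, "amplitude")
  r <- radius_mesh_test(g)
  r_peak <- mean(r[dm == max(dm)])
  expect_equal(r_peak, w / sqrt(2), tolerance = 2 * g$dx / (w / sqrt(2)))
})

test_that("derivative model converges to the oracle at second order in Delta", {
  g <- grid2d(4096, 8, 1)
  w <- 300
  ax <- axis_coords(g)$x
  A <- matrix(rep(exp(-ax^2 / w^2), 8), 4096, 8)
  deltas <- exp(seq(log(3), log(30), length.out = 6))
  errs <- vapply(deltas, function(dd) {
    orc <- Mod(shifted_difference_oracle(A + 0i, dd, g, "linear"))
    rel_l2(derivative_model(A, dd, g, "amplitude", axis = "x"), orc)
  }, 0)
  slope <- unname(stats::coef(stats::lm(log(errs) ~ log(deltas)))[2])
  expect_equal(slope, 2.0, tolerance = 0.1)
})

test_that("broadband synthesis reduces to monochromatic and ignores weight order", {
  g <- grid2d(128, 128, 5)
  sc <- render_scene(scene_spec("disk", g, radius = 120))
  sys <- system_4f(FOCAL, design = radial_orientation_map(PERIOD), pad_factor = 2)
  maker <- function(lam) as_input_field(sc, lam)
  single <- broadband_intensity(maker, sys, source_spectrum(LAMBDA))
  expect_equal(single, intensity(propagate_4f(maker(LAMBDA), sys)), tolerance = 1e-12)
  sp1 <- source_spectrum(c(0.45, 0.55, 0.65), c(1, 2, 3))
  sp2 <- source_spectrum(c(0.65, 0.45, 0.55), c(3, 1, 2))
  expect_equal(broadband_intensity(maker, sys, sp1),
               broadband_intensity(maker, sys, sp2), tolerance = 1e-12)
})

test_that("broadband disk image is an edge ring over a dark interior", {
  g <- grid2d(128, 128, 8)
  R <- 240
  sc <- render_scene(scene_spec("disk", g, radius = R))
  sys <- system_4f(FOCAL, design = radial_orientation_map(PERIOD), pad_factor = 2)
  sp <- source_spectrum(seq(0.40, 0.80, by = 0.08))
  img <- broadband_intensity(function(lam) as_input_field(sc, lam), sys, sp)
  r <- radius_mesh_test(g)
  dmax <- expected_shift(0.80, FOCAL, PERIOD)
  ring <- r > R - dmax & r < R + dmax
  interior <- r < R - 3 * dmax
  expect_gt(mean(img[ring]) / mean(img[interior]), 10)
})

test_that("source spectra validate their domain", {
  expect_error(source_spectrum(numeric(0)), class = "metaedge_invalid_argument")
  expect_error(source_spectrum(5), class = "metaedge_invalid_argument")
  expect_error(source_spectrum(0.5, -1), class = "metaedge_invalid_argument")
  sp <- source_spectrum(c(0.4, 0.6), c(2, 2))
  expect_equal(sp$weights, c(0.5, 0.5))
})
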