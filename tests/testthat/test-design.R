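# Metasurface designs: orientation maps, PB phases, splitting, polariscope

test_that("radial orientation follows (pi r / period) mod pi", {
  g <- grid2d(64, 64, 100)
  d <- radial_orientation_map(PERIOD, aperture_d = 1e6)
  phi <- orientation_map(d, g)
  m <- grid_mesh(g)
  r <- sqrt(m$X^2 + m$Y^2)
  expect_equal(phi, (pi * r / PERIOD) %% pi, tolerance = 1e-12)
  # origin pixel: phi(0,0) = 0 by convention
  expect_equal(phi[33, 33], 0)
  # half-period radius gives a pi/2 axis; full period wraps to 0
  expect_equal(d$phi_fun(PERIOD / 2, 0) %% pi, pi / 2, tolerance = 1e-12)
  expect_equal(d$phi_fun(PERIOD, 0) %% pi, 0, tolerance = 1e-12)
  # the physical device: one 0 -> pi cycle per 1000 um of radius
  expect_equal(d$phi_fun(250, 0), pi / 4, tolerance = 1e-12)
})

test_that("linear orientation ramps with slope pi / period and wraps", {
  d <- linear_orientation_map(PERIOD, axis = "x")
  expect_equal(d$phi_fun(0, 123), 0)
  expect_equal(d$phi_fun(3 * PERIOD / 4, 0), 3 * pi / 4, tolerance = 1e-12)
  # PB phase 2 phi is a ramp of slope 2 pi / period (finite difference of
  # the unwrapped map, i.e. before modulo)
  x <- seq(0, PERIOD / 2 - 1, by = 1)
  slope <- diff(2 * pi * x / PERIOD) / diff(x)
  expect_equal(unique(round(slope, 12)), 2 * pi / PERIOD)
})

test_that("PB phase maps are conjugate ramps equal to +/- 2 phi", {
  g <- grid2d(32, 32, 100)
  d <- radial_orientation_map(PERIOD)
  pb <- geometric_phase_maps(d, g)
  phi <- orientation_map(d, g)
  expect_equal(pb$plus, (2 * phi) %% (2 * pi), tolerance = 1e-12)
  # the two branches are conjugate: their phases sum to a multiple of 2 pi
  expect_lt(max(Mod(exp(1i * (pb$plus + pb$minus)) - 1)), 1e-10)
  # r = period/2: both branches wrap to pi
  expect_equal((2 * d$phi_fun(PERIOD / 2, 0)) %% (2 * pi), pi, tolerance = 1e-12)
})

test_that("Jones propagation of circular light equals the PB phase maps", {
  g <- grid2d(32, 32, 100)
  d <- radial_orientation_map(PERIOD, aperture_d = 1e6)
  jm <- build_jones_map(d, g)
  pb <- geometric_phase_maps(d, g)
  lcp <- scalar_field(matrix(1, 32, 32), g, LAMBDA, jones = c(1, 1i) / sqrt(2))
  out <- apply_jones_map(lcp, jm)
  # converted component (opposite handedness) carries exp(+2 i phi)
  conv <- circular_components(out)$right
  expected <- exp(1i * pb$plus)
  cc <- fit_const(conv, expected)
  expect_lt(rel_l2(conv, cc * expected), 1e-10)
  expect_equal(Mod(cc), 1, tolerance = 1e-10)
})

test_that("orientation is headless: phi and phi + pi give identical waveplates", {
  for (phi in c(0, 0.4, 1.1, 2.9)) {
    expect_lt(max(Mod(waveplate(phi, pi) - waveplate(phi + pi, pi))), 1e-14)
  }
})

test_that("radial design restricted to a ray reproduces the linear profile", {
  d_rad <- radial_orientation_map(PERIOD)
  d_lin <- linear_orientation_map(PERIOD, axis = "x")
  t <- seq(0, 3 * PERIOD, length.out = 301)
  for (th in c(0, pi / 5, 2.1)) {
    along_ray <- d_rad$phi_fun(t * cos(th), t * sin(th)) %% pi
    expect_lt(max(abs(along_ray - d_lin$phi_fun(t, 0) %% pi)), 1e-12)
  }
})

test_that("expected shift is lambda f / period, errors on bad input", {
  expect_equal(expected_shift(0.532, 25000, 1000), 13.3)
  expect_equal(expected_shift(2 * 0.532, 25000, 1000), 2 * 13.3)
  expect_lt(expected_shift(0.532, 25000, 1e9), 1e-4)  # no gradient, no split
  expect_error(expected_shift(-1, 25000, 1000), class = "metaedge_invalid_argument")
  expect_error(expected_shift(0.532, 0, 1000), class = "metaedge_invalid_argument")
})

test_that("polariscope image equals brute-force Jones computation", {
  g <- grid2d(64, 64, 80)
  d <- radial_orientation_map(PERIOD, aperture_d = 4000)
  img <- polariscope_image(d, g)
  # brute force: x-polarized plane wave -> Jones map -> y analyzer
  jm <- build_jones_map(d, g)
  pw <- scalar_field(matrix(1, 64, 64), g, LAMBDA)
  out <- apply_jones(apply_jones_map(apply_jones(pw, polarizer(0)), jm), polarizer(pi / 2))
  expect_lt(max(abs(img - intensity(out))), 1e-12)
  # analytic: sin^2(2 phi) rings, zero retardance goes dark
  phi <- orientation_map(d, g)
  ap <- sqrt(grid_mesh(g)$X^2 + grid_mesh(g)$Y^2) <= 2000
  expect_equal(img, sin(2 * phi)^2 * ap, tolerance = 1e-12)
  d0 <- radial_orientation_map(PERIOD, gamma = 0)
  expect_equal(max(polariscope_image(d0, g)), 0)
})

test_that("polariscope rings of the radial design repeat every period/2", {
  d <- radial_orientation_map(PERIOD)
  r <- seq(0, 2 * PERIOD, by = 1)
  prof <- sin(2 * d$phi_fun(r, 0 * r))^2
  # zeros at multiples of period/2
  zeros <- r[prof < 1e-20]
  expect_equal(zeros, seq(0, 2 * PERIOD, by = PERIOD / 2))
})

test_that("rasterization enforces the sampling rule and the aperture", {
  g_coarse <- grid2d(16, 16, PERIOD / 4)   # pitch > period/8
  d <- radial_orientation_map(PERIOD)
  expect_error(build_jones_map(d, g_coarse), class = "metaedge_sampling_error")
  expect_error(radial_orientation_map(PERIOD, grid = g_coarse),
               class = "metaedge_sampling_error")

  g <- grid2d(64, 64, 100)
  d2 <- radial_orientation_map(PERIOD, aperture_d = 4000)
  jm <- build_jones_map(d2, g)
  r <- sqrt(grid_mesh(g)$X^2 + grid_mesh(g)$Y^2)
  blocked <- r > 2000
  expect_true(all(Mod(jm$j11[blocked]) == 0))
  expect_true(all(Mod(jm$j12[blocked]) == 0))
  # inside the aperture every pixel is unitary
  ins <- which(!blocked)[1:50]
  for (i in ins) {
    J <- matrix(c(jm$j11[i], jm$j21[i], jm$j12[i], jm$j22[i]), 2, 2)
    expect_lt(max(Mod(J %*% Conj(t(J)) - diag(2))), 1e-12)
  }
})
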