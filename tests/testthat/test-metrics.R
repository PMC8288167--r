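# Measurement procedures

test_that("transfer magnitude is 1 for an identity system and scale invariant", {
  g <- grid2d(64, 64, 10)
  I0 <- exp(-radius_mesh_test(g)^2 / 150^2)
  tfr <- estimate_transfer_magnitude(I0, I0, g, LAMBDA, FOCAL)
  expect_true(all(abs(tfr$H[tfr$mask] - 1) < 1e-12))
  # joint rescaling leaves |H| unchanged exactly
  tfr2 <- estimate_transfer_magnitude(7.3 * I0, 7.3 * 0.6 * I0, g, LAMBDA, FOCAL)
  h2 <- tfr2$H
  expect_equal(tfr2$mask, tfr$mask)
  expect_true(all(abs(h2[tfr2$mask] - 1) < 1e-12))  # peak normalization
  expect_error(estimate_transfer_magnitude(I0, I0[1:32, 1:32], g, LAMBDA, FOCAL),
               class = "metaedge_invalid_argument")
  expect_error(estimate_transfer_magnitude(I0 * 0, I0, g, LAMBDA, FOCAL),
               class = "metaedge_degenerate_input")
  expect_error(estimate_transfer_magnitude(I0, I0, g, LAMBDA, FOCAL, floor = 1.5),
               class = "metaedge_invalid_argument")
})

test_that("transfer estimation recovers the sine transfer function of the device", {
  g <- grid2d(256, 256, 2)
  sys <- system_4f(FOCAL, design = radial_orientation_map(PERIOD), pad_factor = 1)
  rec <- fourier_plane_intensities(gaussian_probe(g, LAMBDA, 6), sys)
  tfr <- estimate_transfer_magnitude(rec$I0, rec$I1, rec$grid, LAMBDA, FOCAL)
  kr <- sqrt(outer(tfr$u^2, tfr$v^2, `+`))
  analytic <- abs(sin(2 * pi * DELTA * kr))
  expect_lt(max(abs(tfr$H[tfr$mask] - analytic[tfr$mask])), 0.02)
  fz <- first_zero_kr(tfr)
  expect_lt(abs(fz - 1 / (2 * DELTA)), tfr$bin_width)
})

test_that("linear double-image separation matches the splitting and its errors", {
  g <- grid2d(128, 128, 5)
  # construct a field whose circular components are Gaussians at +/- Delta
  m <- grid_mesh(g)
  blob <- function(x0) exp(-((m$X - x0)^2 + m$Y^2) / 80^2) + 0i
  f <- from_circular_components(blob(-DELTA), blob(DELTA), g, LAMBDA)
  expect_equal(double_image_separation(f, "linear"), 2 * DELTA, tolerance = 1e-9)
  f0 <- from_circular_components(blob(0), blob(0), g, LAMBDA)
  expect_equal(double_image_separation(f0, "linear"), 0)
  f_small <- from_circular_components(blob(-2), blob(2), g, LAMBDA)
  expect_error(double_image_separation(f_small, "linear"),
               class = "metaedge_resolution_error")
})

test_that("separation through the full system is unbiased over random objects", {
  g <- grid2d(96, 96, 6)
  sys <- system_4f(FOCAL, design = linear_orientation_map(PERIOD),
                   analyzer = FALSE, pad_factor = 2)
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    cx <- stats::runif(1, -60, 60); cy <- stats::runif(1, -60, 60)
    m <- grid_mesh(g)
    A <- exp(-((m$X - cx)^2 + (m$Y - cy)^2) / 70^2)
    out <- propagate_4f(scalar_field(A, g, LAMBDA), sys)
    double_image_separation(out, "linear") - 2 * DELTA
  }, 0)
  expect_lt(abs(mean(errs)), 0.5 * g$dx)
})

test_that("radial separation reads the split boundary of a disk edge image", {
  g <- grid2d(512, 512, 4)
  sc <- render_scene(scene_spec("disk", g, radius = 240))
  sys <- system_4f(FOCAL, design = radial_orientation_map(PERIOD), pad_factor = 2)
  out <- propagate_4f(as_input_field(sc, LAMBDA), sys)
  sep <- double_image_separation(out, "radial")
  expect_equal(sep, 2 * DELTA, tolerance = 0.5 * g$dx / (2 * DELTA))
})

test_that("line profiles sample bilinearly between the endpoints", {
  g <- grid2d(64, 64, 4)
  img <- matrix(5, 64, 64)
  p <- line_profile(img, g, c(-100, -50), c(80, 60), n = 50)
  expect_true(all(abs(p$value - 5) < 1e-12))
  expect_equal(nrow(p), 50)
  p2 <- line_profile(img, g, c(0, 0), c(40, 0), n = 2)
  expect_equal(p2$distance, c(0, 40))
  expect_error(line_profile(img, g, c(-1e4, 0), c(0, 0)),
               class = "metaedge_invalid_argument")
  expect_error(line_profile(img, g, c(0, 0), c(10, 0), n = 1),
               class = "metaedge_invalid_argument")
  # profile across a disk edge image shows two symmetric boundary peaks
  sc <- render_scene(scene_spec("disk", g, radius = 50))
  edge <- derivative_model(sc$map, 4, g)
  pr <- line_profile(edge, g, c(-120, 0), c(120, 0), n = 241)
  left <- pr[pr$distance < 120, ]; right <- pr[pr$distance > 120, ]
  pk <- c(left$distance[which.max(left$value)], right$distance[which.max(right$value)])
  expect_equal(diff(pk), 100, tolerance = 0.05)
})

test_that("edge enhancement score contrasts edges against background", {
  g <- grid2d(64, 64, 4)
  img <- matrix(0.01, 64, 64); img[30:34, ] <- 1
  truth <- matrix(FALSE, 64, 64); truth[32, ] <- TRUE
  s <- edge_enhancement_score(img, truth, halo = 2)
  expect_gt(s$ratio, 20)
  expect_equal(s$michelson, (1 - 0.01) / (1 + 0.01), tolerance = 1e-12)
  expect_error(edge_enhancement_score(img, matrix(FALSE, 64, 64)),
               class = "metaedge_invalid_argument")
  expect_error(edge_enhancement_score(img, matrix(TRUE, 64, 64)),
               class = "metaedge_invalid_argument")
})
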