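# Reproducible demo pipelines mirroring the three experiments: device
# characterization (design), transfer-function measurement (transfer) and
# edge imaging of amplitude/phase objects (edge). Each run writes its
# outputs plus a machine-readable JSON run report into `out_dir`; a rerun
# with the same config and seed produces byte-identical numbers.

resolve_config <- function(config) {
  if (is.character(config)) config <- load_config(config)
  else config <- merge_config(default_config(), config)
  validate_config(config)
  config
}

start_report <- function(config, command) {
  list(command = command,
       package = "metaedge",
       version = as.character(utils::packageVersion("metaedge")),
       config_hash = object_hash(config),
       seed = config$seed,
       config = config)
}

finish_report <- function(report, out_dir, config) {
  path <- file.path(out_dir, sprintf("report_%s.json", report$command))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  if ((config$verbosity %||% 1L) > 0L) {
    message(sprintf("[metaedge] %s: wrote %s", report$command, path))
  }
  invisible(report)
}

#' Characterize a metasurface design (design pipeline)
#'
#' Writes the slow-axis orientation map (16-bit TIFF), the two
#' Pancharatnam-Berry phase maps, the crossed-polarizer polariscope image
#' and a design summary (period, aperture, retardance, splitting
#' `Delta = lambda f / Lambda` per configured wavelength).
#'
#' @param config a configuration list or path to a YAML file; see
#'   [default_config()].
#' @return the run report list, invisibly.
#' @export
run_design <- function(config = default_config()) {
  config <- resolve_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  design <- config_design(config)
  # characterization raster spans the full aperture regardless of system grid
  n <- 2L * as.integer(ceiling(config$system$grid$nx / 2))
  pitch <- min(design$period / 8, 1.1 * design$aperture_d / n)
  grid <- grid2d(n, n, pitch)
  lambdas <- config$spectrum$wavelengths_nm / 1000

  write_orientation_tiff(design, grid, file.path(out, "orientation.tif"))
  pb <- geometric_phase_maps(design, grid)
  write_image(pb$plus, file.path(out, "pb_phase_plus.tif"))
  write_image(pb$minus, file.path(out, "pb_phase_minus.tif"))
  pol <- polariscope_image(design, grid, wavelength = lambdas[1])
  write_image(pol, file.path(out, "polariscope.tif"))
  write_image(pol, file.path(out, "polariscope.png"))

  report <- start_report(config, "design")
  report$summary <- list(
    period_um = design$period,
    aperture_um = design$aperture_d,
    gamma_rad = gamma_at(design, lambdas[1]),
    ring_period_um = design$period / 2,
    delta_um = stats::setNames(
      as.list(expected_shift(lambdas, config$system$f1_um, design$period)),
      sprintf("%.0fnm", lambdas * 1000)))
  finish_report(report, out, config)
}

#' Measure the transfer function (transfer pipeline)
#'
#' Simulates the intensity pair of the transfer-function experiment for the
#' configured Gaussian probe, estimates `|H|` with
#' [estimate_transfer_magnitude()], writes the radial `(k_r, |H|)` table
#' next to the analytic `|sin(2 pi Delta k_r)|` curve, and reports their
#' maximum deviation on the valid mask together with the first-zero
#' location against its ideal position `k_r = 1/(2 Delta)`.
#'
#' @inheritParams run_design
#' @return the run report, invisibly (fields `max_deviation`,
#'   `first_zero_kr`, `expected_first_zero_kr`, `delta_um`).
#' @export
run_transfer <- function(config = default_config()) {
  config <- resolve_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  grid <- config_grid(config)
  system <- config_system(config, analyzer = TRUE)
  lambda <- config$spectrum$wavelengths_nm[1] / 1000
  f <- config$system$f1_um
  delta <- expected_shift(lambda, f, config$design$period_um)

  probe <- gaussian_probe(grid, lambda, config$probe$waist_um)
  rec <- fourier_plane_intensities(probe, system)
  tfr <- estimate_transfer_magnitude(rec$I0, rec$I1, rec$grid, lambda, f)

  kr_pix <- sqrt(outer(tfr$u^2, tfr$v^2, `+`))
  analytic_pix <- abs(sin(2 * pi * delta * kr_pix))
  max_dev <- max(abs(tfr$H[tfr$mask] - analytic_pix[tfr$mask]))
  tab <- tfr$profile
  tab$analytic <- abs(sin(2 * pi * delta * tab$kr))
  write_table(tab, file.path(out, "transfer_function.tsv"))
  write_image(rec$I0, file.path(out, "I0.tif"))
  write_image(rec$I1, file.path(out, "I1.tif"))

  report <- start_report(config, "transfer")
  report$delta_um <- delta
  report$max_deviation <- max_dev
  report$first_zero_kr <- first_zero_kr(tfr)
  report$expected_first_zero_kr <- 1 / (2 * delta)
  report$bin_width <- tfr$bin_width
  finish_report(report, out, config)
}

#' Edge-imaging experiment (edge pipeline)
#'
#' Reproduces the imaging demonstrations on the configured synthetic scene:
#' per-wavelength edge images (crossed polarizers), the broadband incoherent
#' image, the no-analyzer double image with its measured separation, the
#' bright-field reference (no element, no analyzer), a line profile through
#' the image center, and the edge-enhancement score against the scene's
#' true edges.
#'
#' @inheritParams run_design
#' @return the run report, invisibly (fields `separation_um`,
#'   `expected_separation_um`, `edge_ratio`, `brightfield_michelson`, ...).
#' @export
run_edge <- function(config = default_config()) {
  config <- resolve_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  scene <- render_scene(config_scene(config))
  spectrum <- config_spectrum(config)
  system_on <- config_system(config, analyzer = TRUE)
  system_off <- config_system(config, analyzer = FALSE)
  relay <- system_4f(config$system$f1_um, config$system$f2_um, design = NULL,
                     analyzer = FALSE, pad_factor = config$system$pad_factor)
  maker <- function(lambda) as_input_field(scene, lambda)
  grid <- scene$grid

  per_lambda <- list()
  for (lam in spectrum$wavelengths) {
    img <- intensity(propagate_4f(maker(lam), system_on))
    name <- sprintf("edge_%04.0fnm.tif", lam * 1000)
    write_image(img, file.path(out, name))
    per_lambda[[name]] <- sum(img)
  }
  broad <- broadband_intensity(maker, system_on, spectrum)
  write_image(broad, file.path(out, "edge_broadband.tif"))

  lam1 <- spectrum$wavelengths[1]
  delta1 <- expected_shift(lam1, config$system$f2_um, config$design$period_um)
  no_an <- propagate_4f(maker(lam1), system_off)
  write_image(intensity(no_an), file.path(out, "double_image.tif"))
  # linear mode reads the no-analyzer circular components; radial mode reads
  # the split boundary of the with-analyzer edge image
  separation <- tryCatch({
    if (config$design$kind == "linear") {
      double_image_separation(no_an, "linear")
    } else {
      double_image_separation(propagate_4f(maker(lam1), system_on), "radial")
    }
  }, metaedge_error = function(e) NA_real_)

  bright <- intensity(propagate_4f(maker(lam1), relay))
  write_image(bright, file.path(out, "bright_field.tif"))
  interior <- interior_mask(grid, config$system$pad_factor)

  half <- grid$nx * grid$dx / 2
  prof <- line_profile(broad, grid, c(-0.9 * half, 0), c(0.9 * half, 0),
                       n = 2L * grid$nx)
  write_table(prof, file.path(out, "line_profile.tsv"))

  truth <- scene_edge_mask(scene)
  score <- edge_enhancement_score(broad, truth, halo = 3L, exclude = !interior)

  report <- start_report(config, "edge")
  report$separation_um <- separation
  report$expected_separation_um <- 2 * delta1
  report$edge_ratio <- score$ratio
  report$edge_michelson <- score$michelson
  report$brightfield_michelson <- michelson_contrast(bright, interior)
  finish_report(report, out, config)
}

# true-edge mask of a scene: pixels where the map's gradient magnitude
# exceeds 20% of its maximum
scene_edge_mask <- function(scene) {
  g <- scene$grid
  gx <- central_diff(scene$map, 1L) / g$dx
  gy <- central_diff(scene$map, 2L) / g$dy
  gm <- sqrt(gx^2 + gy^2)
  gm > 0.2 * max(gm)
}

# central region untouched by wraparound/vignette: inner 80% box
interior_mask <- function(grid, pad_factor) {
  m <- grid_mesh(grid)
  fx <- 0.4 * grid$nx * grid$dx
  fy <- 0.4 * grid$ny * grid$dy
  abs(m$X) <= fx & abs(m$Y) <= fy
}
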