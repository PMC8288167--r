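# Run configuration: YAML-backed, strictly validated (unknown keys are
# rejected with their full key path) before any computation.

#' Default run configuration
#'
#' The paper-device geometry: f1 = f2 = 25 mm, radial design with period
#' 1000 um and 4 mm aperture, half-wave retardance, crossed polarizers,
#' 532 nm source.
#'
#' @return nested list of configuration values.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "metaedge-out",
    verbosity = 1L,
    system = list(
      f1_um = 25000, f2_um = 25000,
      polarizer_deg = 0, analyzer = TRUE, pad_factor = 2,
      grid = list(nx = 256L, ny = 256L, dx_um = 4)
    ),
    design = list(
      kind = "radial", period_um = 1000, aperture_um = 4000,
      gamma_rad = pi, dispersive = FALSE, lambda0_nm = 532
    ),
    scene = list(kind = "disk", radius_um = 240),
    spectrum = list(wavelengths_nm = 532, weights = NULL),
    probe = list(waist_um = 6)
  )
}

config_schema <- function() {
  num <- "numeric"; int <- "numeric"; lgl <- "logical"; chr <- "character"
  list(
    seed = int, out_dir = chr, verbosity = int,
    system = list(f1_um = num, f2_um = num, polarizer_deg = num,
                  analyzer = lgl, pad_factor = num,
                  grid = list(nx = int, ny = int, dx_um = num)),
    design = list(kind = chr, period_um = num, aperture_um = num,
                  gamma_rad = num, dispersive = lgl, lambda0_nm = num),
    scene = list(kind = chr, radius_um = num, bar_widths_um = num,
                 orientation = chr, n_spokes = int, text = chr,
                 letter_height_um = num, n_cells = int, phase_max_rad = num,
                 cell_radius_um = num, margin_um = num),
    spectrum = list(wavelengths_nm = num, weights = num),
    probe = list(waist_um = num)
  )
}

#' Validate a run configuration
#'
#' Checks every key against the published schema; unknown keys and wrongly
#' typed values raise a config error naming the offending key path.
#'
#' @param config nested list, e.g. from [load_config()] or [default_config()].
#' @return `config`, invisibly, if valid.
#' @export
validate_config <- function(config) {
  walk <- function(cfg, schema, path) {
    for (key in names(cfg)) {
      here <- paste(c(path, key), collapse = ".")
      if (!key %in% names(schema)) {
        stop_metaedge(sprintf("unknown configuration key '%s'", here),
                      "metaedge_config_error")
      }
      spec <- schema[[key]]
      val <- cfg[[key]]
      if (is.null(val)) next
      if (is.list(spec)) {
        if (!is.list(val)) {
          stop_metaedge(sprintf("'%s' must be a mapping", here), "metaedge_config_error")
        }
        walk(val, spec, c(path, key))
      } else if (spec == "numeric") {
        if (!is.numeric(val) || any(!is.finite(val))) {
          stop_metaedge(sprintf("'%s' must be finite numeric", here), "metaedge_config_error")
        }
      } else if (spec == "logical") {
        if (!is.logical(val) || length(val) != 1L || is.na(val)) {
          stop_metaedge(sprintf("'%s' must be TRUE or FALSE", here), "metaedge_config_error")
        }
      } else if (spec == "character") {
        if (!is.character(val) || length(val) != 1L) {
          stop_metaedge(sprintf("'%s' must be a string", here), "metaedge_config_error")
        }
      }
    }
  }
  walk(config, config_schema(), character())
  if (!is.null(config$design$kind) &&
      !config$design$kind %in% c("radial", "linear")) {
    stop_metaedge("'design.kind' must be 'radial' or 'linear'", "metaedge_config_error")
  }
  invisible(config)
}

#' Load and validate a YAML run configuration
#'
#' Values in the file override the defaults of [default_config()];
#' everything else stays at its default.
#'
#' @param path YAML file.
#' @return validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop_metaedge(sprintf("config file '%s' not found", path), "metaedge_io_error")
  }
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_config(), user)
  validate_config(cfg)
  cfg
}

merge_config <- function(base, user) {
  if (is.null(user)) return(base)
  for (key in names(user)) {
    if (is.list(user[[key]]) && is.list(base[[key]])) {
      base[[key]] <- merge_config(base[[key]], user[[key]])
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

# Build core objects from a validated config.
config_grid <- function(config) {
  g <- config$system$grid
  grid2d(g$nx, g$ny, g$dx_um)
}

config_design <- function(config) {
  d <- config$design
  gamma <- if (isTRUE(d$dispersive)) dispersive_retardance(d$lambda0_nm / 1000)
           else d$gamma_rad
  if (d$kind == "radial") {
    radial_orientation_map(d$period_um, aperture_d = d$aperture_um, gamma = gamma)
  } else {
    linear_orientation_map(d$period_um, aperture_d = d$aperture_um, gamma = gamma)
  }
}

config_system <- function(config, analyzer = NULL) {
  s <- config$system
  system_4f(s$f1_um, s$f2_um, design = config_design(config),
            theta1 = s$polarizer_deg * pi / 180,
            analyzer = if (is.null(analyzer)) s$analyzer else analyzer,
            pad_factor = s$pad_factor)
}

config_spectrum <- function(config) {
  source_spectrum(config$spectrum$wavelengths_nm / 1000, config$spectrum$weights)
}

config_scene <- function(config) {
  s <- config$scene
  g <- config_grid(config)
  spec <- switch(s$kind,
    bars = scene_spec("bars", g, config$seed, bar_widths = s$bar_widths_um,
                      orientation = s$orientation),
    disk = scene_spec("disk", g, config$seed, radius = s$radius_um),
    siemens = scene_spec("siemens", g, config$seed, n_spokes = s$n_spokes,
                         radius = s$radius_um),
    letters = scene_spec("letters", g, config$seed, text = s$text,
                         letter_height = s$letter_height_um),
    phase_cells = scene_spec("phase_cells", g, config$seed, n_cells = s$n_cells,
                             phase_max = s$phase_max_rad,
                             cell_radius = s$cell_radius_um, margin = s$margin_um),
    uniform = scene_spec("uniform", g, config$seed),
    stop_metaedge(sprintf("'scene.kind' value '%s' is not supported", s$kind),
                  "metaedge_config_error"))
  # drop NULL optional parameters so generator defaults apply
  structure(spec[!vapply(spec, is.null, logical(1))], class = "scene_spec")
}
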