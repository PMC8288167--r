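# File I/O: the field container (lossless complex data) and 8/16-bit raster
# images with recorded normalization.

CONTAINER_VERSION <- "metaedge-field-1"

#' Write a polarized field to a lossless container file
#'
#' Serializes the complex components together with the grid metadata,
#' wavelength, polarization basis tag and a creator/version string. The
#' round trip through [read_field()] is bit-exact.
#'
#' @param field a [polarized_field()].
#' @param path output path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "polarized_field"))
  payload <- list(container = CONTAINER_VERSION,
                  creator = paste0("metaedge ", as.character(utils::packageVersion("metaedge"))),
                  basis = "linear-xy",
                  nx = field$grid$nx, ny = field$grid$ny,
                  dx = field$grid$dx, dy = field$grid$dy, units = "um",
                  wavelength = field$wavelength,
                  ex = field$ex, ey = field$ey)
  tryCatch(saveRDS(payload, path, version = 2L),
           error = function(e) stop_metaedge(
             sprintf("cannot write field container '%s': %s", path, conditionMessage(e)),
             "metaedge_io_error"))
  invisible(path)
}

#' Read a polarized field from a container file
#'
#' @param path file written by [write_field()].
#' @return a [polarized_field()].
#' @export
read_field <- function(path) {
  payload <- tryCatch(readRDS(path),
                      error = function(e) stop_metaedge(
                        sprintf("cannot read field container '%s': %s", path, conditionMessage(e)),
                        "metaedge_io_error"))
  if (!identical(payload$container, CONTAINER_VERSION)) {
    stop_metaedge(sprintf("'%s' is not a %s container", path, CONTAINER_VERSION),
                  "metaedge_io_error")
  }
  polarized_field(payload$ex, payload$ey,
                  grid2d(payload$nx, payload$ny, payload$dx, payload$dy),
                  payload$wavelength)
}

#' Write a real image as a raster file with recorded normalization
#'
#' Peak-normalizes the image to \[0, 1\] before quantization and records the
#' physical scale in a JSON sidecar (`<path>.json`), so quantitative data
#' stay recoverable from the display file. TIFF output is 16-bit
#' (quantitative); PNG output is 8-bit (preview). Complex input is refused:
#' complex fields must go through the field container ([write_field()]).
#'
#' @param image real matrix (stored x-by-y; written with rows = y).
#' @param path output path ending in `.tif`/`.tiff` or `.png`.
#' @return the normalization scale (max pixel value), invisibly.
#' @export
write_image <- function(image, path) {
  if (is.complex(image)) {
    stop_metaedge("refusing to write complex data to a raster image; use the field container (write_field)",
                  "metaedge_io_error")
  }
  if (!is.matrix(image) || any(!is.finite(image))) {
    stop_metaedge("image must be a finite real matrix", "metaedge_invalid_argument")
  }
  peak <- max(image)
  norm <- if (peak > 0) image / peak else image
  norm <- pmin(pmax(norm, 0), 1)
  # raster rows run top-to-bottom: row = y (flipped), col = x
  raster <- t(norm)[ncol(norm):1, , drop = FALSE]
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    if (ext %in% c("tif", "tiff")) {
      tiff::writeTIFF(raster, path, bits.per.sample = 16L)
    } else if (ext == "png") {
      png::writePNG(raster, path)
    } else {
      stop_metaedge(sprintf("unsupported image format '.%s' (use .tif/.tiff or .png)", ext),
                    "metaedge_io_error")
    }
    TRUE
  }, error = function(e) {
    if (inherits(e, "metaedge_error")) stop(e)
    stop_metaedge(sprintf("cannot write image '%s': %s", path, conditionMessage(e)),
                  "metaedge_io_error")
  })
  jsonlite::write_json(list(normalization = "peak", scale_max = peak,
                            bits = if (ext == "png") 8L else 16L),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(peak)
}

#' Export a design's orientation map as a 16-bit TIFF
#'
#' Axis angles in \[0, pi) map linearly onto the 16-bit integer range; the
#' mapping is recorded in the JSON sidecar.
#'
#' @param design a `metasurface_design`.
#' @param grid a [grid2d()].
#' @param path output `.tif` path.
#' @export
write_orientation_tiff <- function(design, grid, path) {
  phi <- orientation_map(design, grid)
  raster <- t(phi / pi)[grid$ny:1, , drop = FALSE]
  tiff::writeTIFF(raster, path, bits.per.sample = 16L)
  jsonlite::write_json(list(quantity = "slow-axis angle", units = "rad",
                            mapping = "value = pi * pixel / 65535",
                            period_um = design$period,
                            aperture_um = design$aperture_d),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
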