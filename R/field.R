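#' Polarized monochromatic field
#'
#' A two-component complex field sampled on a [grid2d()] at a single
#' wavelength: the carrier of the object field, Fourier-plane field and
#' image-plane field throughout the 4f simulation. Components are stored in
#' the linear (x, y) Jones basis.
#'
#' @param ex,ey complex matrices (dim `nx` x `ny`) with the horizontal and
#'   vertical field components.
#' @param grid the [grid2d()] the samples live on.
#' @param wavelength vacuum wavelength in micrometres.
#' @return an object of class `polarized_field`.
#' @export
polarized_field <- function(ex, ey, grid, wavelength) {
  stopifnot(inherits(grid, "grid2d"))
  check_positive_scalar(wavelength, "wavelength")
  ex <- as_complex_matrix(ex, grid)
  ey <- as_complex_matrix(ey, grid)
  structure(list(ex = ex, ey = ey, grid = grid, wavelength = wavelength),
            class = "polarized_field")
}

as_complex_matrix <- function(m, grid) {
  if (!is.matrix(m) || nrow(m) != grid$nx || ncol(m) != grid$ny) {
    stop_metaedge("field component dimensions must match the grid",
                  "metaedge_invalid_argument")
  }
  if (!is.complex(m)) storage.mode(m) <- "complex"
  m
}

#' @export
print.polarized_field <- function(x, ...) {
  cat(sprintf("<polarized_field> %d x %d px (pitch %.4g um), lambda = %.4g um, power = %.6g\n",
              x$grid$nx, x$grid$ny, x$grid$dx, x$wavelength, field_power(x)))
  invisible(x)
}

#' Per-pixel intensity of a polarized field
#'
#' @param field a [polarized_field()].
#' @return nonnegative real matrix `|Ex|^2 + |Ey|^2`.
#' @export
intensity <- function(field) {
  stopifnot(inherits(field, "polarized_field"))
  Mod(field$ex)^2 + Mod(field$ey)^2
}

#' Total optical power of a field
#'
#' Discrete integral of the intensity over the grid, in field-units^2 um^2.
#'
#' @inheritParams intensity
#' @export
field_power <- function(field) {
  sum(intensity(field)) * field$grid$dx * field$grid$dy
}

#' Build a polarized field from a scalar amplitude map
#'
#' @param amplitude real or complex matrix on `grid` (for a pure amplitude
#'   object, values in \[0, 1\]).
#' @param grid a [grid2d()].
#' @param wavelength wavelength in um.
#' @param jones length-2 (complex) Jones vector giving the uniform input
#'   polarization; defaults to horizontal, the P1 axis of the standard setup.
#' @return a [polarized_field()].
#' @export
scalar_field <- function(amplitude, grid, wavelength, jones = c(1, 0)) {
  if (length(jones) != 2L) {
    stop_metaedge("`jones` must have length 2", "metaedge_invalid_argument")
  }
  jones <- as.complex(jones)
  amplitude <- as_complex_matrix(amplitude, grid)
  polarized_field(amplitude * jones[1], amplitude * jones[2], grid, wavelength)
}

#' Decompose a field into circular components
#'
#' Uses the package convention LCP = (1, +i)/sqrt(2) in the (x, y) Jones
#' basis (the handedness choice only flips which circular image deflects
#' outward under the radial design). Recombining with
#' [from_circular_components()] reproduces the input exactly.
#'
#' @inheritParams intensity
#' @return list with complex matrices `left` and `right`.
#' @export
circular_components <- function(field) {
  stopifnot(inherits(field, "polarized_field"))
  s <- sqrt(0.5)
  list(left  = s * (field$ex - 1i * field$ey),
       right = s * (field$ex + 1i * field$ey))
}

#' Recombine circular components into a linear-basis field
#'
#' @param left,right complex matrices of LCP/RCP amplitudes.
#' @inheritParams polarized_field
#' @return a [polarized_field()].
#' @export
from_circular_components <- function(left, right, grid, wavelength) {
  s <- sqrt(0.5)
  polarized_field(s * (left + right), 1i * s * (left - right), grid, wavelength)
}

# Zero-pad a field symmetrically to `factor` times its support (rounded up to
# even pixel counts); the grid origin pixel stays the origin pixel.
pad_field <- function(field, factor) {
  if (factor < 1) {
    stop_metaedge("pad factor must be >= 1", "metaedge_invalid_argument")
  }
  g <- field$grid
  nx2 <- 2L * as.integer(ceiling(g$nx * factor / 2))
  ny2 <- 2L * as.integer(ceiling(g$ny * factor / 2))
  if (nx2 == g$nx && ny2 == g$ny) return(field)
  g2 <- grid2d(nx2, ny2, g$dx, g$dy)
  off_x <- (nx2 - g$nx) / 2L
  off_y <- (ny2 - g$ny) / 2L
  put <- function(m) {
    out <- matrix(0 + 0i, nx2, ny2)
    out[off_x + seq_len(g$nx), off_y + seq_len(g$ny)] <- m
    out
  }
  polarized_field(put(field$ex), put(field$ey), g2, field$wavelength)
}

# Centered crop back to (nx, ny), inverse of pad_field's placement.
crop_field <- function(field, nx, ny) {
  g <- field$grid
  if (nx > g$nx || ny > g$ny) {
    stop_metaedge("crop size exceeds field size", "metaedge_invalid_argument")
  }
  if (nx == g$nx && ny == g$ny) return(field)
  off_x <- (g$nx - nx) / 2L
  off_y <- (g$ny - ny) / 2L
  ix <- off_x + seq_len(nx); iy <- off_y + seq_len(ny)
  g2 <- grid2d(nx, ny, g$dx, g$dy)
  polarized_field(field$ex[ix, iy], field$ey[ix, iy], g2, field$wavelength)
}
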