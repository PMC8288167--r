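# Geometric-phase metasurface designs: space-variant half-wave plates whose
# slow-axis orientation phi(x, y) encodes a Pancharatnam-Berry phase +/-2phi
# on the two circular polarization components.

new_design <- function(kind, period, aperture_d, gamma, phi_fun) {
  check_positive_scalar(period, "period")
  check_positive_scalar(aperture_d, "aperture_d")
  if (!is.function(gamma)) check_finite_scalar(gamma, "gamma")
  structure(list(kind = kind, period = period, aperture_d = aperture_d,
                 gamma = gamma, phi_fun = phi_fun),
            class = "metasurface_design")
}

#' @export
print.metasurface_design <- function(x, ...) {
  g <- if (is.function(x$gamma)) "dispersive" else sprintf("%.4g rad", x$gamma)
  cat(sprintf("<metasurface_design> kind = %s, period = %g um, aperture = %g um, retardance = %s\n",
              x$kind, x$period, x$aperture_d, g))
  invisible(x)
}

#' Radial (axicon-type) slow-axis design
#'
#' The 2D differentiator device: slow-axis angle
#' `phi(x, y) = (pi * r / period) mod pi` with `r = sqrt(x^2 + y^2)` and
#' `phi(0, 0) = 0` by convention. For a half-wave retardance the two circular
#' components acquire conjugate axicon phases `exp(+/- i 2 pi r / period)`,
#' which split the image radially by `Delta = lambda * f / period`.
#'
#' @param period slow-axis period `Lambda` in um (the physical device uses
#'   1000 um).
#' @param grid optional [grid2d()]; if supplied, the sampling rule
#'   (pitch <= period/8) is checked immediately.
#' @param aperture_d patterned-area diameter in um (physical device: 4000).
#' @param gamma retardance in radians (default `pi`, the broadband half-wave
#'   design), or a function of wavelength in um, see [dispersive_retardance()].
#' @return a `metasurface_design`.
#' @export
radial_orientation_map <- function(period, grid = NULL, aperture_d = 4000,
                                   gamma = pi) {
  d <- new_design("radial", period, aperture_d, gamma,
                  function(X, Y) (pi * sqrt(X^2 + Y^2) / period) %% pi)
  if (!is.null(grid)) check_design_sampling(d, grid)
  d
}

#' Linear slow-axis design (1D differentiator)
#'
#' `phi = (pi * x / period) mod pi` along the chosen axis; the 1D textbook
#' case whose output is the shifted difference
#' `E(x + Delta) - E(x - Delta)`.
#'
#' @inheritParams radial_orientation_map
#' @param axis `"x"` or `"y"`.
#' @export
linear_orientation_map <- function(period, grid = NULL, axis = c("x", "y"),
                                   aperture_d = 4000, gamma = pi) {
  axis <- match.arg(axis)
  f <- if (axis == "x") function(X, Y) (pi * X / period) %% pi
       else function(X, Y) (pi * Y / period) %% pi
  d <- new_design("linear", period, aperture_d, gamma, f)
  d$axis <- axis
  if (!is.null(grid)) check_design_sampling(d, grid)
  d
}

#' Wavelength-dependent retardance model
#'
#' The ideal device is achromatic (`gamma = pi` at every wavelength, since
#' the birefringence is structural, not resonant). For sensitivity studies
#' this returns the simple dispersive alternative
#' `gamma(lambda) = pi * lambda0 / lambda`.
#'
#' @param lambda0 design wavelength in um.
#' @return a function of wavelength (um) returning retardance (radians).
#' @export
dispersive_retardance <- function(lambda0) {
  check_positive_scalar(lambda0, "lambda0")
  function(lambda) pi * lambda0 / lambda
}

# Retardance of a design at a given wavelength.
gamma_at <- function(design, wavelength) {
  if (is.function(design$gamma)) design$gamma(wavelength) else design$gamma
}

check_design_sampling <- function(design, grid) {
  pitch <- max(grid$dx, grid$dy)
  if (pitch > design$period / 8) {
    stop_metaedge(sprintf(
      "grid pitch %.4g um too coarse to rasterize the design: need <= period/8 = %.4g um",
      pitch, design$period / 8), "metaedge_sampling_error")
  }
  invisible(TRUE)
}

#' Rasterize the slow-axis orientation of a design
#'
#' @param design a `metasurface_design`.
#' @param grid a [grid2d()].
#' @return matrix of axis angles in \[0, pi).
#' @export
orientation_map <- function(design, grid) {
  m <- grid_mesh(grid)
  design$phi_fun(m$X, m$Y) %% pi
}

#' Pancharatnam-Berry phase maps of a design
#'
#' The phases imparted to the two circular components by an ideal half-wave
#' element: `(+2 phi, -2 phi)`, wrapped to \[0, 2 pi).
#'
#' @inheritParams orientation_map
#' @return list of matrices `plus` and `minus` (radians).
#' @export
geometric_phase_maps <- function(design, grid) {
  phi <- orientation_map(design, grid)
  list(plus = (2 * phi) %% (2 * pi), minus = (-2 * phi) %% (2 * pi))
}

aperture_mask <- function(design, grid) {
  radius_mesh(grid) <= design$aperture_d / 2
}

#' Expected image-plane splitting
#'
#' The displacement between the two circular-polarization images produced by
#' a geometric-phase grating of period `Lambda` at the Fourier plane:
#' `Delta = lambda * f / Lambda` (um).
#'
#' @param lambda wavelength, um.
#' @param f focal length, um.
#' @param period grating period `Lambda`, um.
#' @export
expected_shift <- function(lambda, f, period) {
  check_positive_scalar(lambda, "lambda")
  check_positive_scalar(f, "f")
  check_positive_scalar(period, "period")
  lambda * f / period
}

#' Rasterize a design into a per-pixel Jones map
#'
#' Every pixel inside the circular aperture carries the waveplate matrix
#' `waveplate(phi(x, y), gamma)`; pixels outside are opaque (zero matrix):
#' the unpatterned surround transmits unrotated light that the crossed
#' analyzer extinguishes, so the ideal model blocks it.
#'
#' @inheritParams orientation_map
#' @param wavelength wavelength in um used to evaluate a dispersive
#'   retardance; ignored for a scalar retardance.
#' @return an object of class `jones_map` with per-pixel entries `j11`,
#'   `j12`, `j21`, `j22` and the logical `aperture` mask.
#' @export
build_jones_map <- function(design, grid, wavelength = NULL) {
  stopifnot(inherits(design, "metasurface_design"), inherits(grid, "grid2d"))
  check_design_sampling(design, grid)
  if (is.function(design$gamma) && is.null(wavelength)) {
    stop_metaedge("dispersive retardance needs `wavelength`",
                  "metaedge_invalid_argument")
  }
  gam <- if (is.null(wavelength)) gamma_at(design, NA) else gamma_at(design, wavelength)
  phi <- orientation_map(design, grid)
  ap <- aperture_mask(design, grid)
  cg <- cos(gam / 2); sg <- sin(gam / 2)
  c2 <- cos(2 * phi); s2 <- sin(2 * phi)
  # R(phi) diag(e^{-i g/2}, e^{+i g/2}) R(-phi), expanded per pixel
  j11 <- (cg - 1i * sg * c2) * ap
  j12 <- (-1i * sg * s2) * ap
  j22 <- (cg + 1i * sg * c2) * ap
  structure(list(j11 = j11, j12 = j12, j21 = j12, j22 = j22,
                 aperture = ap, grid = grid, design = design),
            class = "jones_map")
}

#' Apply a per-pixel Jones map to a field
#'
#' @param field a [polarized_field()] on the same grid as `jmap`.
#' @param jmap a `jones_map` from [build_jones_map()].
#' @return the transformed [polarized_field()].
#' @export
apply_jones_map <- function(field, jmap) {
  stopifnot(inherits(field, "polarized_field"), inherits(jmap, "jones_map"))
  if (!grids_compatible(field$grid, jmap$grid)) {
    stop_metaedge("field and Jones map grids differ", "metaedge_invalid_argument")
  }
  polarized_field(jmap$j11 * field$ex + jmap$j12 * field$ey,
                  jmap$j21 * field$ex + jmap$j22 * field$ey,
                  field$grid, field$wavelength)
}

#' Polariscope image of a design
#'
#' Intensity of the element between crossed linear polarizers at (0, pi/2)
#' under uniform illumination: `sin(gamma/2)^2 * sin(2 phi)^2` inside the
#' aperture, 0 outside. For the radial design this is the concentric
#' bright/dark ring pattern with radial period `Lambda/2` seen in the
#' physical device's characterization.
#'
#' @inheritParams build_jones_map
#' @return nonnegative intensity matrix.
#' @export
polariscope_image <- function(design, grid, wavelength = NULL) {
  gam <- if (is.function(design$gamma)) gamma_at(design, wavelength) else design$gamma
  if (is.function(design$gamma) && is.null(wavelength)) {
    stop_metaedge("dispersive retardance needs `wavelength`",
                  "metaedge_invalid_argument")
  }
  phi <- orientation_map(design, grid)
  (sin(gam / 2)^2 * sin(2 * phi)^2) * aperture_mask(design, grid)
}
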