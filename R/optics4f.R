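# Coherent propagation through the 4f system with the metasurface at the
# Fourier plane, plus broadband (incoherent) synthesis.
#
# Conventions: forward Fourier kernel exp(-i 2 pi (u x + v y)); arrays are
# center-origin (DC at pixel nx/2+1); the Fourier-plane position of
# frequency (u, v) is (lambda f u, lambda f v). Two forward lens transforms
# invert the image; propagate_4f undoes this with a final point reflection
# so outputs are upright.

#' 4f system description
#'
#' Holds the optical geometry of the two-lens relay with the metasurface at
#' the shared focal (Fourier) plane between an input polarizer P1 and an
#' optional crossed analyzer P2.
#'
#' @param f1,f2 focal lengths of L1 and L2 in um (the transfer-function
#'   experiment uses f1 = f2 = 25000).
#' @param design a `metasurface_design`, or `NULL` for an empty Fourier
#'   plane (plain relay).
#' @param theta1 P1 transmission axis, radians.
#' @param analyzer logical; is the analyzer P2 present?
#' @param theta2 P2 axis; defaults to `theta1 + pi/2` (crossed), the paper
#'   configuration. Other angles are allowed but flagged `nonstandard`.
#' @param pad_factor zero-padding factor (>= 1) applied before propagation to
#'   suppress cyclic wraparound of the shifted images; default 2.
#' @return an object of class `system_4f`.
#' @export
system_4f <- function(f1, f2 = f1, design = NULL, theta1 = 0,
                      analyzer = TRUE, theta2 = theta1 + pi / 2,
                      pad_factor = 2) {
  check_positive_scalar(f1, "f1")
  check_positive_scalar(f2, "f2")
  check_finite_scalar(theta1, "theta1")
  check_finite_scalar(theta2, "theta2")
  if (pad_factor < 1) stop_metaedge("pad_factor must be >= 1", "metaedge_invalid_argument")
  if (!is.null(design)) stopifnot(inherits(design, "metasurface_design"))
  nonstandard <- analyzer &&
    abs(((theta2 - theta1) %% pi) - pi / 2) > 1e-9
  structure(list(f1 = f1, f2 = f2, design = design, theta1 = theta1,
                 analyzer = isTRUE(analyzer), theta2 = theta2,
                 pad_factor = pad_factor, nonstandard = nonstandard),
            class = "system_4f")
}

#' @export
print.system_4f <- function(x, ...) {
  cat(sprintf("<system_4f> f1 = %g um, f2 = %g um, analyzer %s, element: %s%s\n",
              x$f1, x$f2,
              if (x$analyzer) sprintf("at %.3g rad", x$theta2) else "absent",
              if (is.null(x$design)) "none" else x$design$kind,
              if (x$nonstandard) " [non-crossed polarizers]" else ""))
  invisible(x)
}

#' Ideal thin-lens Fourier transform (2f step)
#'
#' Maps a field in the front focal plane of a lens to its back focal plane:
#' the scaled continuous Fourier transform of each component, with the
#' Fourier-plane position `x_f = lambda * f * u`. The amplitude scale
#' `dx dy / (lambda f)` makes the transform exactly power-conserving
#' (Parseval) on the discrete grid.
#'
#' @param field a [polarized_field()].
#' @param f focal length, um.
#' @return a [polarized_field()] on the Fourier-plane grid (same pixel
#'   counts, pitch `lambda * f / (n * dx)`).
#' @export
lens_fourier_transform <- function(field, f) {
  stopifnot(inherits(field, "polarized_field"))
  check_positive_scalar(f, "f")
  g <- field$grid
  lam <- field$wavelength
  gf <- grid2d(g$nx, g$ny,
               lam * f / (g$nx * g$dx), lam * f / (g$ny * g$dy))
  scale <- g$dx * g$dy / (lam * f)
  tr <- function(m) fftshift2(stats::fft(fftshift2(m))) * scale
  polarized_field(tr(field$ex), tr(field$ey), gf, lam)
}

#' Propagate an object field through the 4f system
#'
#' Applies, in order: input polarizer P1, zero padding, the L1 lens
#' transform, the rasterized metasurface Jones map (per-wavelength, since
#' the Fourier-plane scale is `lambda f u`), the L2 lens transform, the
#' upright point reflection undoing the 4f image inversion, the optional
#' analyzer P2, and a centered crop back to the object pixel count. With
#' `f1 != f2` the output grid pitch is `dx * f2 / f1` (the relay magnifies).
#'
#' @param object a [polarized_field()] at the input plane.
#' @param system a [system_4f()].
#' @return the image-plane [polarized_field()].
#' @export
propagate_4f <- function(object, system) {
  stopifnot(inherits(object, "polarized_field"), inherits(system, "system_4f"))
  g0 <- object$grid
  field <- apply_jones(object, polarizer(system$theta1))
  field <- pad_field(field, system$pad_factor)
  field <- lens_fourier_transform(field, system$f1)
  if (!is.null(system$design)) {
    jmap <- build_jones_map(system$design, field$grid, object$wavelength)
    field <- apply_jones_map(field, jmap)
  }
  field <- lens_fourier_transform(field, system$f2)
  field <- polarized_field(flip_center(field$ex), flip_center(field$ey),
                           field$grid, field$wavelength)
  if (system$analyzer) field <- apply_jones(field, polarizer(system$theta2))
  crop_field(field, g0$nx, g0$ny)
}

#' Source spectrum for broadband synthesis
#'
#' @param wavelengths wavelengths in um, each in (0.2, 2.0).
#' @param weights nonnegative weights (normalized to sum 1); equal by
#'   default.
#' @return an object of class `source_spectrum`.
#' @export
source_spectrum <- function(wavelengths, weights = NULL) {
  if (length(wavelengths) < 1L) {
    stop_metaedge("spectrum needs at least one line", "metaedge_invalid_argument")
  }
  if (any(!is.finite(wavelengths)) || any(wavelengths <= 0.2) || any(wavelengths >= 2.0)) {
    stop_metaedge("wavelengths must lie in (0.2, 2.0) um", "metaedge_invalid_argument")
  }
  if (is.null(weights)) weights <- rep(1, length(wavelengths))
  if (length(weights) != length(wavelengths) || any(!is.finite(weights)) ||
      any(weights < 0) || sum(weights) <= 0) {
    stop_metaedge("weights must be nonnegative with positive sum",
                  "metaedge_invalid_argument")
  }
  structure(list(wavelengths = as.numeric(wavelengths),
                 weights = weights / sum(weights)),
            class = "source_spectrum")
}

#' Broadband image intensity (incoherent sum)
#'
#' Simulates each spectral line independently through the 4f system and
#' accumulates the weighted per-wavelength intensities; each line carries
#' its own splitting `Delta(lambda) = lambda f / Lambda`. The incoherent sum
#' models a source (supercontinuum + filter, white light) whose 10 nm bands
#' have negligible mutual coherence.
#'
#' @param object_maker function of wavelength (um) returning the input
#'   [polarized_field()] at that wavelength.
#' @param system a [system_4f()].
#' @param spectrum a [source_spectrum()].
#' @return nonnegative intensity matrix on the image-plane grid.
#' @export
broadband_intensity <- function(object_maker, system, spectrum) {
  stopifnot(is.function(object_maker), inherits(spectrum, "source_spectrum"))
  acc <- NULL
  for (k in seq_along(spectrum$wavelengths)) {
    img <- propagate_4f(object_maker(spectrum$wavelengths[k]), system)
    ik <- intensity(img) * spectrum$weights[k]
    acc <- if (is.null(acc)) ik else acc + ik
  }
  acc
}

#' Fourier-plane intensity pair for the transfer-function procedure
#'
#' Simulates the two recordings the transfer-function measurement needs: the
#' probe-spectrum intensity at the plane conjugate to the metasurface,
#' without (`I0`) and with (`I1`) the differentiator between crossed
#' polarizers. The pointwise ratio `sqrt(I1)/sqrt(I0)` under the position-
#' to-frequency mapping `u = x / (lambda f)` is the transfer-function
#' magnitude; see [estimate_transfer_magnitude()].
#'
#' @param probe a [polarized_field()] probe at the input plane (a small
#'   Gaussian spot, so its Fourier-plane spectrum is broad).
#' @param system a [system_4f()] whose `design` is the element under test.
#' @return list with matrices `I0`, `I1`, the Fourier-plane `grid`, and
#'   `wavelength`.
#' @export
fourier_plane_intensities <- function(probe, system) {
  stopifnot(inherits(probe, "polarized_field"), inherits(system, "system_4f"))
  if (is.null(system$design)) {
    stop_metaedge("system has no element to characterize", "metaedge_invalid_argument")
  }
  field <- apply_jones(probe, polarizer(system$theta1))
  field <- pad_field(field, system$pad_factor)
  fp <- lens_fourier_transform(field, system$f1)
  I0 <- intensity(fp)
  jmap <- build_jones_map(system$design, fp$grid, probe$wavelength)
  out <- apply_jones_map(fp, jmap)
  if (system$analyzer) out <- apply_jones(out, polarizer(system$theta2))
  list(I0 = I0, I1 = intensity(out), grid = fp$grid, wavelength = probe$wavelength)
}

#' Gaussian probe beam
#'
#' @param grid a [grid2d()].
#' @param wavelength um.
#' @param waist 1/e amplitude radius in um.
#' @param jones input Jones vector (default horizontal).
#' @return a [polarized_field()].
#' @export
gaussian_probe <- function(grid, wavelength, waist, jones = c(1, 0)) {
  check_positive_scalar(waist, "waist")
  if (waist < grid$dx) {
    stop_metaedge("probe waist narrower than one pixel; refine the grid",
                  "metaedge_degenerate_input")
  }
  r2 <- radius_mesh(grid)^2
  scalar_field(exp(-r2 / waist^2), grid, wavelength, jones)
}
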