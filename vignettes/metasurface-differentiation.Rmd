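---
title: "Simulating a geometric-phase metasurface spatial differentiator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a geometric-phase metasurface spatial differentiator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaedge)
```

## The instrument being simulated

A dielectric metasurface — a space-variant half-wave plate written into
silica — sits at the Fourier plane of a two-lens 4f relay between an input
polarizer P1 and a crossed analyzer P2. Its slow-axis orientation grows
linearly with radius, `phi(x, y) = (pi r / Lambda) mod pi`, with period
`Lambda = 1000` um over a 4 mm aperture in the physical device. Because a
half-wave plate flips circular polarization handedness while adding the
geometric (Pancharatnam–Berry) phase `±2 phi`, the element multiplies the
left/right circular components of the Fourier-plane field by the conjugate
axicon phases `exp(±i 2 pi r_f / Lambda)`. With the Fourier-plane position
mapped to spatial frequency by `x_f = lambda f u`, the crossed-polarizer
combination acts on the object spectrum as the scalar filter

$$H(k_x, k_y) \propto \sin(2\pi\Delta k_r), \qquad
  k_r = \sqrt{k_x^2 + k_y^2}, \qquad \Delta = \frac{\lambda f}{\Lambda}.$$

`H(0,0) = 0`: uniform regions are extinguished and edges of both amplitude
objects and pure phase objects `exp(i Phi)` are rendered bright,
isotropically. Because the retardance is structural (form birefringence, no
resonance), `Gamma = pi` holds across the visible band and the device works
at every wavelength simultaneously, with `Delta` scaling linearly in
`lambda`. In the 1D variant (`phi = pi x / Lambda`) the output field is
exactly the shifted difference `E(x + Delta) − E(x − Delta)`, which for
`Delta` much smaller than the feature size approximates
`2 Delta \, \partial E / \partial x`.

## Model and conventions

The simulator is an ideal coherent Jones-calculus model:

* **Propagation.** Each lens is an ideal thin-lens 2f Fourier transform
  (kernel `exp(-i 2 pi (ux + vy))`, arrays center-origin, amplitude scale
  `dx\,dy/(\lambda f)` so the discrete transform is exactly
  power-conserving). Two forward transforms invert the image; a final point
  reflection restores an upright image. No Fresnel steps, aberrations,
  partial coherence or detector noise are modelled.
* **Element.** The design is stored functionally (closed-form `phi`) and
  rasterized per wavelength on the Fourier-plane grid, whose pitch is
  `\lambda f/(n\,dx)`; a sampling rule `pitch <= Lambda/8` guarantees at
  least 8 samples per `2 pi` cycle of the PB phase. Pixels outside the
  circular aperture carry the opaque zero matrix: the unpatterned surround
  transmits unrotated light that the crossed analyzer removes anyway, so
  blocking is the faithful ideal limit.
* **Circular basis.** LCP is `(1, +i)/sqrt(2)` in the (x, y) Jones basis.
  The choice is a convention: flipping it swaps which circular image moves
  outward, nothing else. Global phases are never normalized away; tests
  compare fields up to one fitted global complex constant.
* **Padding.** `propagate_4f()` zero-pads to twice the object support by
  default to keep the cyclically shifted images from wrapping. Pure phase
  objects (unit modulus everywhere) and deliberately periodic fields are
  propagated with `pad_factor = 1`, where the DFT model is exact: this is
  how the DC-extinction property is measured, since the zero-padding border
  of a "uniform" object is itself a real edge whose diffraction tails would
  otherwise be attributed to leakage.
* **Broadband light.** Spectra are synthesized incoherently (weighted sum of
  per-wavelength intensities), each line with its own `Delta(lambda)`;
  filtered-supercontinuum and white-light sources have negligible mutual
  coherence between 10 nm bands. Retardance is `pi` at every wavelength by
  default; `dispersive_retardance(lambda0)` provides the
  `pi lambda0/lambda` alternative for sensitivity studies. Transmission is
  ideal (the physical device reports ~95%; whether the residual is
  absorption or reflection is not modelled).

## Validity of the analytic models — and where they genuinely fail

Two reference models accompany the full simulation:
`shifted_difference_oracle()` (the exact 1D result, and its per-azimuth
polar generalization) and `derivative_model()` (`|2 Delta d(.)/dr|` by
centered finite differences, with `axis = "x"/"y"`, the radial projection
`"r"`, or the gradient magnitude `"grad"`).

Their status differs sharply between 1D and 2D, and the package treats this
honestly rather than averaging over it:

* **1D is exact.** The linear design's crossed-polarizer filter
  `\sin(2\pi\Delta u)` is *odd* in the signed frequency `u`, which is
  precisely the Fourier symbol of the shifted difference. The full Jones
  simulation agrees with the oracle to machine precision, and the
  first-order model converges to it at order `Delta^2` (measured log–log
  slope 2.01 over `Delta` from `w/100` to `w/10` on Gaussian ridges).
* **2D is the even filter.** Radially, `r_f \ge 0` forces
  `\sin(2\pi\Delta k_r)` to be *even* in every radial frequency component.
  Three verified consequences:
  1. For any real object the two circular components of the no-analyzer
     output are complex conjugates — their intensities are identical, and
     no measurement of the separate circular images can reveal the
     splitting. `double_image_separation(mode = "radial")` therefore reads
     the splitting from the *split boundary* instead: the edge ring of a
     centered disk of radius `R` carries two intensity peaks at exactly
     `R − Delta` and `R + Delta`, and their distance recovers `2 Delta` to
     a tenth of a pixel. (The linear design does produce two displaced
     circular images; there the centroid distance is used.)
  2. Across a smooth edge the even filter returns the *quadrature* of the
     derivative: twin logarithmic peaks at `±Delta` with a null on the edge
     itself, rather than a single derivative-shaped ridge. The pointwise
     intensity therefore does not converge to `|2 Delta\, dPhi/dr|^2`
     however gently the phase varies; the first-order picture predicts
     where edge energy concentrates (within `±Delta` of boundaries, which
     is what `edge_enhancement_score()` quantifies) but not the pointwise
     profile. The "superposition of 1D differentiators over all azimuths"
     heuristic fails for the same reason: along any azimuth the radial
     design presents `\sin(2\pi|x|/\Lambda)`, not the signed 1D ramp.
  3. Inside a closed boundary the filter's slow `1/x` tails arrive
     coherently from the whole rim (a Poisson-spot-like focusing), leaving
     a faint interior glow: the disk edge ring is ~10-40x brighter than the
     interior, not arbitrarily so.

* `axis = "grad"` exists because a local edge with in-plane wavevector `k`
  sees the filter `\sin(2\pi\Delta|k|)` — a shifted difference along its
  *own* gradient direction wherever it sits in the field. The radial
  projection `"r"` (the polar-coordinate form) coincides with it only for
  features centered on the optical axis.

## The transfer-function measurement

The experiment estimates the transfer magnitude from two recorded
intensities via `E_i \propto \sqrt{I_i}` and `|H| = \sqrt{I_1}/\sqrt{I_0}`
under the position-to-frequency mapping `u = x/(\lambda f)`. A pointwise
ratio of two *image-plane* recordings of a Gaussian probe is monotone in
`r` (a `sinh` profile) and can never exhibit the zeros of
`|\sin(2\pi\Delta k_r)|`; the ratio displays the transfer function only
when the recordings are made at the plane conjugate to the metasurface,
where the probe's spectrum is laid out spatially. `fourier_plane_intensities()`
therefore simulates `I_0` and `I_1` at the Fourier plane, without and with
the differentiator between crossed polarizers — consistent with the ring
pattern (`\Lambda/2` spacing) of the device's characterization images. The
probe is a 6 um-waist Gaussian, so its focal-plane spectrum spans several
sine periods; the estimator masks pixels below 5% of the peak denominator
(the ratio is ill-conditioned on the probe's skirts, exactly as in the
physical measurement, and masking is more honest than clipping), peak-
normalizes `|H|` on the valid mask, and azimuthally averages into
one-pixel-wide `k_r` bins. Phase information is lost by the square root —
sign changes of the sine appear as zeros of `|H|`. Recovered: maximum
pixelwise deviation from `|\sin(2\pi\Delta k_r)|` about `5\times10^{-7}`,
first zero at `1/(2\Delta)` within half a bin.

## The synthetic scenes

All generators are pure functions of their `scene_spec` (same seed, same
scene, bit for bit) and anti-alias every binary mask with a 1-pixel cosine
ramp so the band-limitation assumptions behind the oracles hold on the
grid. The bar target emulates a negative three-bar resolution element
(5:1 bar length:width) without reproducing the standard's exact group
dimensions; block letters are axis-aligned rectangle strokes from a
built-in table, with no font dependency.

The phase phantom emulates transparent adherent cells: per cell an
anisotropic super-Gaussian body, a membrane-sharp higher-phase rim
(1/e half-width 12% of the body radius) and 1-3 organelle bumps, at seeded
random positions and orientations, scaled so `max |Phi| = 0.3` rad — inside
the small-phase regime where `exp(i Phi) \approx 1 + i Phi` and the
bright-field image is featureless (Michelson contrast at machine
precision). No quantitative phase maps of real cultured cells back these
statistics; they are invented stand-ins with every parameter surfaced in
the spec, so passing tests demonstrate the *instrument model*, not fidelity
to any particular cell line. Real specimens add amplitude contrast, phase
noise, coverslip reflections and partial coherence, none of which are
modelled.

## Problem sizes and numerical tolerances

The shipped tests and the acceptance script run the oracle equivalences on
128x128 grids (5 um pixels, machine-precision agreement), the
transfer-function recovery on 512x512 at 2 um, the phase phantom on 512x512
at 4 um, and the isotropy check on 1024x1024 at 2 um, where the azimuthal
coefficient of variation of the disk edge ring over 36 wedges is 1.7%
(the residual comes from rasterizing a circle on a square grid). Exact
algebraic identities (unitarity, conversion efficiency
`\sin^2(\Gamma/2)` against brute-force Jones projection, polariscope
`\sin^2(\Gamma/2)\sin^2(2\phi)`) are held to `10^{-12}`; propagation
identities (Parseval, relay round trip, oracle equivalence) to `10^{-10}`
or better; procedure-level recoveries (transfer deviation, boundary
splitting) to their physical discretization limits.

## Known limitations

Ideal polarizers and a lossless element; thin-lens transforms only; no
spatial-coherence or noise model; `phi(0, 0) = 0` by convention (the axis
orientation is undefined at `r = 0`; one pixel is immaterial at the stated
sampling); the device's measured transmission efficiency and the
birefringence dispersion of laser-written nanogratings are not modelled.
The slow-axis reading implemented is the axicon-type profile (axis *angle*
growing with radius); the alternative reading — axis pointing along the
local radius, a q-plate — would impose vortex phases and contradict the
radial splitting the instrument demonstrably produces, so it is documented
but not implemented.
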