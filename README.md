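# metaedge

Simulation of broadband two-dimensional optical spatial differentiation with
a geometric-phase metasurface.

A transparent specimen (an unstained cell, say) changes only the *phase* of
the light passing through it, so a bright-field microscope shows almost
nothing. One optical-analog-computing answer is a **Pancharatnam–Berry
(geometric-phase) metasurface** placed at the Fourier plane of a 4f imaging
system between crossed polarizers: a space-variant half-wave plate whose
slow-axis angle grows linearly with radius, `phi(x, y) = (pi r / Lambda) mod
pi`. The element imprints conjugate phases `exp(+/- i 2 phi)` on the two
circular polarization components; with input polarizer P1 and crossed
analyzer P2 the system acts on the object spectrum as the isotropic filter

    H(k_x, k_y) = sin(2 pi Delta k_r),   k_r = sqrt(k_x^2 + k_y^2),
    Delta = lambda f / Lambda,

which vanishes at DC: uniform regions go dark and every edge — of an
amplitude object or of a pure phase object `exp(i Phi)` — lights up,
isotropically, at every visible wavelength (the half-wave retardance is
structural, not resonant). In the 1D (linear-ramp) version the output is the
shifted difference `E(x + Delta) - E(x - Delta) ~ 2 Delta dE/dx`.

`metaedge` is a desk-scale simulator of this instrument for people who want
to study such differentiators quantitatively without a laser bench: Jones
calculus primitives, radial/linear metasurface designs, coherent 4f
propagation (per-wavelength Fourier-plane rasterization), broadband
incoherent synthesis, the analytic reference models, seeded synthetic scenes
(bar targets, disks, Siemens stars, block letters, cell-like phase
phantoms), and the measurement procedures of the physical experiment
(transfer-function magnitude from an intensity pair, double-image
separation, line profiles, edge-contrast scores).

## Worked example

```r
library(metaedge)

design <- radial_orientation_map(1000)        # period 1000 um, aperture 4 mm
sys    <- system_4f(25000, design = design)   # f = 25 mm, crossed polarizers
expected_shift(0.532, 25000, 1000)
#> [1] 13.3                                    # Delta at 532 nm, in um

# edge image of a disk: the boundary splits into rings at R - Delta, R + Delta
g     <- grid2d(512, 512, 4)                  # 2.048 mm field, 4 um pixels
scene <- render_scene(scene_spec("disk", g, radius = 240))
edge  <- propagate_4f(as_input_field(scene, 0.532), sys)
double_image_separation(edge, "radial")
#> [1] 26.98356                                # ~ 2 Delta = 26.6 um

# transfer-function measurement: |H| = sqrt(I1)/sqrt(I0), u = x/(lambda f)
gp  <- grid2d(512, 512, 2)
rec <- fourier_plane_intensities(gaussian_probe(gp, 0.532, 6), sys)
tfr <- estimate_transfer_magnitude(rec$I0, rec$I1, rec$grid, 0.532, 25000)
first_zero_kr(tfr)
#> [1] 0.03759766                              # 1/(2 Delta) = 0.03759398 /um
```

The measured splitting of the disk boundary (26.98 um) agrees with the model
`2 Delta = 26.6 um` to a tenth of a pixel, and the first zero of the
recovered transfer-function magnitude falls on `k_r = 1/(2 Delta)` to within
one frequency bin — the two signatures of a working radial differentiator.

A phase phantom run (`run_edge()` with `scene$kind = "phase_cells"`) shows
the bright-field reference with Michelson contrast at machine precision
(~1e-15: the object is invisible) while the differentiator image
concentrates ~30-40x more intensity near the true cell boundaries than
elsewhere.

Demo pipelines mirror the three experiments and are scriptable from a shell:

```sh
Rscript exec/metaedge design   --out out/design
Rscript exec/metaedge transfer --out out/transfer
Rscript exec/metaedge edge     --config my_run.yaml --seed 2
```

Each run writes 16-bit TIFF images (with JSON sidecars recording the
intensity normalization), TSV tables and a JSON run report, and is
byte-reproducible for a fixed config and seed.

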