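# Seeded generators of synthetic test scenes: USAF-style bar groups, disks,
# Siemens stars, block letters (amplitude targets) and smooth cell-like
# phase phantoms. All generators are pure functions of (spec, seed) and
# anti-alias binary masks with a 1-pixel cosine edge ramp so the
# band-limitation assumptions of the analytic oracles stay honest.

#' Scene specification
#'
#' Bundles a grid, a scene kind, kind-specific parameters and a random seed
#' into a single reproducible description of a synthetic test object.
#'
#' @param kind one of `"bars"`, `"disk"`, `"siemens"`, `"letters"`,
#'   `"phase_cells"`, `"uniform"`.
#' @param grid a [grid2d()].
#' @param seed integer seed (same seed, same scene, bit for bit).
#' @param ... kind-specific parameters, see the individual generators.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(kind = c("bars", "disk", "siemens", "letters",
                                "phase_cells", "uniform"),
                       grid, seed = 1L, ...) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "grid2d"))
  structure(c(list(kind = kind, grid = grid, seed = as.integer(seed)),
              list(...)),
            class = "scene_spec")
}

#' Render a scene specification
#'
#' Dispatches to the generator named by `spec$kind`.
#'
#' @param spec a [scene_spec()].
#' @return a `scene` object: list with `kind` (`"amplitude"` or `"phase"`),
#'   the real `map` matrix (amplitude in \[0, 1\], or phase in radians), and
#'   the `grid`.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  switch(spec$kind,
         bars = bar_target(spec),
         disk = disk_target(spec),
         siemens = siemens_star(spec),
         letters = letters_target(spec),
         phase_cells = phase_cell_phantom(spec),
         uniform = new_scene("amplitude",
                             matrix(1, spec$grid$nx, spec$grid$ny), spec$grid))
}

new_scene <- function(kind, map, grid) {
  structure(list(kind = kind, map = map, grid = grid), class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %s object, %d x %d px, range [%.3g, %.3g]\n",
              x$kind, x$grid$nx, x$grid$ny, min(x$map), max(x$map)))
  invisible(x)
}

#' Turn a scene into a polarized input field
#'
#' Amplitude scenes become `A * jones`; phase scenes become the unit-modulus
#' field `exp(i Phi)` (a pure phase object, invisible in bright field).
#'
#' @param scene a `scene` from [render_scene()] or a generator.
#' @param wavelength um.
#' @param jones input Jones vector; default horizontal (the P1 axis).
#' @return a [polarized_field()].
#' @export
as_input_field <- function(scene, wavelength, jones = c(1, 0)) {
  stopifnot(inherits(scene, "scene"))
  amp <- if (scene$kind == "phase") exp(1i * scene$map) else scene$map
  scalar_field(amp, scene$grid, wavelength, jones)
}

# 1-px cosine coverage ramp on a signed distance (px into the shape).
edge_ramp <- function(d) {
  t <- pmin(pmax(d + 0.5, 0), 1)
  0.5 * (1 - cos(pi * t))
}

#' Three-bar resolution target
#'
#' Negative-target convention (bright bars on dark background) emulating a
#' 1951 USAF-style element: groups of three parallel bars with 5:1
#' length:width ratio, one group per requested bar width, laid out side by
#' side and centered on the grid.
#'
#' @param spec a [scene_spec()] with parameters `bar_widths` (numeric vector
#'   of bar widths in um, one group each; default 6%, 4.5% and 3% of the
#'   field width) and
#'   `orientation` (`"vertical"` or `"horizontal"`, default vertical bars).
#' @return an amplitude `scene`.
#' @export
bar_target <- function(spec) {
  fov_x0 <- spec$grid$nx * spec$grid$dx
  widths <- spec$bar_widths %||% (fov_x0 * c(0.06, 0.045, 0.03))
  orient <- spec$orientation %||% "vertical"
  if (any(widths <= 0)) stop_metaedge("bar widths must be positive", "metaedge_invalid_argument")
  g <- spec$grid
  # each group: 3 bars of width w at pitch 2w (so group width 5w), length 5w
  group_w <- 5 * widths
  gap <- max(widths)
  total_w <- sum(group_w) + gap * (length(widths) - 1)
  fov_x <- g$nx * g$dx; fov_y <- g$ny * g$dy
  if (total_w > fov_x || max(5 * widths) > fov_y) {
    stop_metaedge("bar groups exceed the grid field of view", "metaedge_invalid_argument")
  }
  m <- grid_mesh(g)
  A <- matrix(0, g$nx, g$ny)
  x0 <- -total_w / 2
  for (k in seq_along(widths)) {
    w <- widths[k]
    len <- 5 * w
    for (b in 0:2) {
      cx <- x0 + w / 2 + b * 2 * w
      A <- pmax(A, soft_rect(m, cx, 0, w, len, g, rotate = orient == "horizontal"))
    }
    x0 <- x0 + group_w[k] + gap
  }
  new_scene("amplitude", A, g)
}

# axis-aligned soft-edged rectangle centered at (cx, cy), size wx x wy um
soft_rect <- function(mesh, cx, cy, wx, wy, grid, rotate = FALSE) {
  if (rotate) { tmp <- cx; cx <- cy; cy <- tmp; tmp <- wx; wx <- wy; wy <- tmp }
  dx_in <- (wx / 2 - abs(mesh$X - cx)) / grid$dx
  dy_in <- (wy / 2 - abs(mesh$Y - cy)) / grid$dy
  edge_ramp(dx_in) * edge_ramp(dy_in)
}

#' Anti-aliased disk target
#'
#' The canonical isotropy fixture for the radial differentiator: a centered
#' disk of radius `radius` um with a 1-px smoothed edge.
#'
#' @param spec a [scene_spec()] with parameter `radius` (um). `radius = 0`
#'   yields the zero field; the radius must stay below a quarter of the
#'   field of view so the split images do not wrap.
#' @return an amplitude `scene`.
#' @export
disk_target <- function(spec) {
  R <- spec$radius %||% (spec$grid$nx * spec$grid$dx / 8)
  g <- spec$grid
  if (R < 0) stop_metaedge("radius must be >= 0", "metaedge_invalid_argument")
  if (R >= min(g$nx * g$dx, g$ny * g$dy) / 4) {
    stop_metaedge("disk radius must be below a quarter of the field of view",
                  "metaedge_invalid_argument")
  }
  A <- if (R == 0) matrix(0, g$nx, g$ny)
       else edge_ramp((R - radius_mesh(g)) / g$dx)
  new_scene("amplitude", A, g)
}

#' Siemens star target
#'
#' Binary star of `n_spokes` bright wedges (2 n radial edges) whose local
#' edge density grows toward the center: an azimuthal-frequency sweep for
#' resolution and isotropy checks.
#'
#' @param spec a [scene_spec()] with parameters `n_spokes` (even, >= 4;
#'   default 8) and `radius` (um; default 3/8 of the half field of view).
#' @return an amplitude `scene`.
#' @export
siemens_star <- function(spec) {
  n <- spec$n_spokes %||% 8L
  g <- spec$grid
  if (n < 4 || n %% 2 != 0) {
    stop_metaedge("spoke count must be even and >= 4", "metaedge_invalid_argument")
  }
  R <- spec$radius %||% (min(g$nx * g$dx, g$ny * g$dy) * 3 / 8)
  m <- grid_mesh(g)
  r <- sqrt(m$X^2 + m$Y^2)
  theta <- atan2(m$Y, m$X)
  a <- (n * theta) %% (2 * pi)          # bright wedge where a < pi
  d_ang <- pmin(a %% pi, pi - (a %% pi)) / n   # angular distance to an edge
  sgn <- ifelse(a < pi, 1, -1)
  d_px <- sgn * d_ang * r / max(g$dx, g$dy)    # arclength distance in px
  A <- edge_ramp(d_px) * edge_ramp((R - r) / g$dx)
  A[r == 0] <- 0
  new_scene("amplitude", A, g)
}

# block-letter stroke tables: non-overlapping axis-aligned rects in the unit
# cell (x0, y0, x1, y1), origin bottom-left, stroke width 0.2
letter_strokes <- list(
  E = rbind(c(0, 0, 0.2, 1), c(0.2, 0.8, 1, 1), c(0.2, 0.4, 0.8, 0.6), c(0.2, 0, 1, 0.2)),
  D = rbind(c(0, 0, 0.2, 1), c(0.2, 0.8, 0.8, 1), c(0.2, 0, 0.8, 0.2), c(0.8, 0.2, 1, 0.8)),
  G = rbind(c(0, 0.2, 0.2, 0.8), c(0.2, 0.8, 1, 1), c(0.2, 0, 0.8, 0.2),
            c(0.8, 0.2, 1, 0.4), c(0.6, 0.4, 1, 0.6)),
  F = rbind(c(0, 0, 0.2, 1), c(0.2, 0.8, 1, 1), c(0.2, 0.4, 0.8, 0.6)),
  L = rbind(c(0, 0, 0.2, 1), c(0.2, 0, 1, 0.2)),
  T = rbind(c(0, 0.8, 1, 1), c(0.4, 0, 0.6, 0.8)),
  I = rbind(c(0.4, 0, 0.6, 1)),
  H = rbind(c(0, 0, 0.2, 1), c(0.8, 0, 1, 1), c(0.2, 0.4, 0.8, 0.6)),
  O = rbind(c(0, 0.2, 0.2, 0.8), c(0.8, 0.2, 1, 0.8), c(0.2, 0.8, 0.8, 1), c(0.2, 0, 0.8, 0.2)),
  C = rbind(c(0, 0.2, 0.2, 0.8), c(0.2, 0.8, 1, 1), c(0.2, 0, 1, 0.2)),
  U = rbind(c(0, 0.2, 0.2, 1), c(0.8, 0.2, 1, 1), c(0.2, 0, 0.8, 0.2)),
  N = rbind(c(0, 0, 0.2, 1), c(0.8, 0, 1, 1), c(0.4, 0.4, 0.6, 1)))

#' Block-letter amplitude target
#'
#' Renders text as axis-aligned rectangle strokes from a built-in table (no
#' font dependency); bright letters on dark background.
#'
#' @param spec a [scene_spec()] with parameters `text` (string from the
#'   supported set) and `letter_height` (um; default half the field height).
#' @return an amplitude `scene`.
#' @export
letters_target <- function(spec) {
  text <- spec$text %||% "EDGE"
  g <- spec$grid
  chars <- strsplit(toupper(text), "")[[1]]
  bad <- setdiff(chars, names(letter_strokes))
  if (length(bad)) {
    stop_metaedge(sprintf("unsupported glyph(s) %s; supported: %s",
                          paste(bad, collapse = ", "),
                          paste(names(letter_strokes), collapse = "")),
                  "metaedge_invalid_argument")
  }
  A <- matrix(0, g$nx, g$ny)
  if (length(chars) == 0L) return(new_scene("amplitude", A, g))
  # default height: half the field, shrunk so the whole text fits in width
  h <- spec$letter_height %||%
    min(g$ny * g$dy / 2, g$nx * g$dx / (0.9 * length(chars) - 0.2) * 0.95)
  cell_w <- 0.7 * h; adv <- 0.9 * h
  total <- adv * length(chars) - (adv - cell_w)
  if (total > g$nx * g$dx || h > g$ny * g$dy) {
    stop_metaedge("text exceeds the grid field of view", "metaedge_invalid_argument")
  }
  m <- grid_mesh(g)
  x0 <- -total / 2
  for (ch in chars) {
    for (k in seq_len(nrow(letter_strokes[[ch]]))) {
      s <- letter_strokes[[ch]][k, ]
      A <- pmax(A, soft_rect(m,
                             x0 + (s[1] + s[3]) / 2 * cell_w,
                             -h / 2 + (s[2] + s[4]) / 2 * h,
                             (s[3] - s[1]) * cell_w, (s[4] - s[2]) * h, g))
    }
    x0 <- x0 + adv
  }
  new_scene("amplitude", A, g)
}

#' Cell-like phase phantom
#'
#' Emulates a field of transparent adherent cells (unit amplitude, smooth
#' phase): each cell is an anisotropic super-Gaussian body with a thin
#' higher-phase rim and 1-3 interior organelle bumps, at a seeded random
#' position, size and orientation. The phase maximum defaults to 0.3 rad to
#' stay inside the first-order (small-phase) regime of the differentiator
#' model; real cultured cells are not quantified here and the morphology
#' statistics are invented stand-ins with every parameter surfaced in the
#' spec.
#'
#' @param spec a [scene_spec()] with parameters `n_cells` (default 4),
#'   `phase_max` (radians, in \[0, pi\]; default 0.3), `cell_radius` (mean
#'   body radius in um; default 1/10 of the field of view), `margin` (um
#'   kept free at the border; default one cell radius).
#' @return a phase `scene` (map = Phi in radians).
#' @export
phase_cell_phantom <- function(spec) {
  g <- spec$grid
  n_cells <- spec$n_cells %||% 4L
  phase_max <- spec$phase_max %||% 0.3
  if (n_cells < 1) stop_metaedge("need at least one cell", "metaedge_invalid_argument")
  if (phase_max < 0 || phase_max > pi) {
    stop_metaedge("phase_max must lie in [0, pi]", "metaedge_invalid_argument")
  }
  fov <- min(g$nx * g$dx, g$ny * g$dy)
  R0 <- spec$cell_radius %||% (fov / 10)
  margin <- spec$margin %||% R0
  half_x <- g$nx * g$dx / 2 - margin - R0
  half_y <- g$ny * g$dy / 2 - margin - R0
  if (half_x <= 0 || half_y <= 0) {
    stop_metaedge("cells do not fit in the grid with the requested margin",
                  "metaedge_invalid_argument")
  }
  m <- grid_mesh(g)
  phi <- with_seed(spec$seed, {
    acc <- matrix(0, g$nx, g$ny)
    centers <- matrix(NA_real_, 0, 2)
    for (k in seq_len(n_cells)) {
      placed <- FALSE
      for (try in 1:200) {
        cx <- stats::runif(1, -half_x, half_x)
        cy <- stats::runif(1, -half_y, half_y)
        if (nrow(centers) == 0 ||
            all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) > 1.6 * R0)) {
          placed <- TRUE; break
        }
      }
      if (!placed) {
        stop_metaedge("could not place all cells without overlap; reduce n_cells",
                      "metaedge_invalid_argument")
      }
      centers <- rbind(centers, c(cx, cy))
      a <- R0 * stats::runif(1, 0.8, 1.3)       # semi-axes
      b <- R0 * stats::runif(1, 0.6, 1.0)
      ang <- stats::runif(1, 0, pi)
      p <- stats::runif(1, 1.6, 2.6)            # super-Gaussian exponent
      xr <- (m$X - cx) * cos(ang) + (m$Y - cy) * sin(ang)
      yr <- -(m$X - cx) * sin(ang) + (m$Y - cy) * cos(ang)
      rho <- sqrt((xr / a)^2 + (yr / b)^2)
      body <- exp(-rho^(2 * p))
      rim <- 0.6 * exp(-((rho - 1) / 0.12)^2)   # membrane-sharp higher-phase rim
      org <- matrix(0, g$nx, g$ny)
      for (q in seq_len(sample(1:3, 1))) {
        ox <- stats::runif(1, -0.4, 0.4) * a
        oy <- stats::runif(1, -0.4, 0.4) * b
        ow <- R0 * stats::runif(1, 0.1, 0.2)
        org <- org + 0.5 * exp(-(((m$X - cx - ox)^2 + (m$Y - cy - oy)^2) / ow^2))
      }
      acc <- acc + body + rim + org
    }
    acc
  })
  mx <- max(phi)
  if (mx > 0) phi <- phi * (phase_max / mx)
  new_scene("phase", phi, g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
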