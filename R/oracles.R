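# Analytic reference models of the differentiator: the exact shifted-
# difference form and its first-order derivative approximation.

#' Shifted-difference model of the differentiator output
#'
#' The exact output of the geometric-phase differentiator between crossed
#' polarizers, up to a global complex constant:
#' `E(x, y) = E_in(x + Delta, y) - E_in(x - Delta, y)` for the linear (1D)
#' design, and the per-azimuth radial difference
#' `E(r + Delta, theta) - E(r - Delta, theta)` for the radial design.
#'
#' The linear mode is implemented spectrally (phase ramps, periodic
#' boundary) and is exact for grid-sampled fields. The radial mode resamples
#' the field on polar shifts with bilinear interpolation; a point at signed
#' radius `r - Delta < 0` along direction `theta` is, geometrically, the
#' point at radius `|r - Delta|` along `theta + pi`, which the Cartesian
#' evaluation yields automatically.
#'
#' @param object complex (or real) matrix: the scalar object field.
#' @param delta shift in um, >= 0.
#' @param grid the [grid2d()] of `object`.
#' @param mode `"linear"` or `"radial"`.
#' @param axis shift axis for linear mode, `"x"` or `"y"`.
#' @return complex matrix of the same dimension.
#' @export
shifted_difference_oracle <- function(object, delta, grid,
                                      mode = c("linear", "radial"),
                                      axis = c("x", "y")) {
  mode <- match.arg(mode)
  axis <- match.arg(axis)
  stopifnot(inherits(grid, "grid2d"))
  if (!is.numeric(delta) && !is.complex(delta)) delta <- as.numeric(delta)
  if (!is.finite(delta) || delta < 0) {
    stop_metaedge("`delta` must be finite and >= 0", "metaedge_invalid_argument")
  }
  fov <- if (mode[1] == "linear" && axis[1] == "x") grid$nx * grid$dx
         else if (mode[1] == "linear") grid$ny * grid$dy
         else min(grid$nx * grid$dx, grid$ny * grid$dy)
  if (delta > fov / 2) {
    stop_metaedge("`delta` exceeds half the field of view", "metaedge_domain_error")
  }
  if (!is.matrix(object) || nrow(object) != grid$nx || ncol(object) != grid$ny) {
    stop_metaedge("`object` dimensions must match the grid", "metaedge_invalid_argument")
  }
  if (!is.complex(object)) storage.mode(object) <- "complex"
  if (delta == 0) return(matrix(0 + 0i, grid$nx, grid$ny))
  if (mode == "linear") {
    fr <- freq_coords(grid)
    u <- if (axis == "x") matrix(fr$u, grid$nx, grid$ny)
         else matrix(fr$v, grid$nx, grid$ny, byrow = TRUE)
    spec <- fftshift2(stats::fft(fftshift2(object)))
    spec <- spec * (2i * sin(2 * pi * delta * u))
    fftshift2(stats::fft(fftshift2(spec), inverse = TRUE)) / (grid$nx * grid$ny)
  } else {
    m <- grid_mesh(grid)
    r <- sqrt(m$X^2 + m$Y^2)
    # unit radial vector; the origin pixel contributes E(Delta,0)-E(Delta,pi)
    cs <- ifelse(r > 0, m$X / pmax(r, .Machine$double.eps), 1)
    sn <- ifelse(r > 0, m$Y / pmax(r, .Machine$double.eps), 0)
    ep <- bilinear_interp(object, (r + delta) * cs, (r + delta) * sn, grid)
    em <- bilinear_interp(object, (r - delta) * cs, (r - delta) * sn, grid)
    ep - em
  }
}

#' Bilinear interpolation of a matrix field at arbitrary points
#'
#' @param m complex or real matrix sampled on `grid`.
#' @param xq,yq query coordinates (um), any shape; points outside the grid
#'   return 0.
#' @param grid the [grid2d()] of `m`.
#' @return interpolated values with the shape of `xq`.
#' @export
bilinear_interp <- function(m, xq, yq, grid) {
  ax <- axis_coords(grid)
  fi <- (xq - ax$x[1]) / grid$dx + 1
  fj <- (yq - ax$y[1]) / grid$dy + 1
  i0 <- floor(fi); j0 <- floor(fj)
  ti <- fi - i0; tj <- fj - j0
  inside <- i0 >= 1 & i0 <= grid$nx - 1 & j0 >= 1 & j0 <= grid$ny - 1
  i0c <- pmin(pmax(i0, 1), grid$nx - 1)
  j0c <- pmin(pmax(j0, 1), grid$ny - 1)
  idx <- function(di, dj) cbind(as.vector(i0c) + di, as.vector(j0c) + dj)
  v <- (1 - ti) * (1 - tj) * m[idx(0L, 0L)] +
       ti * (1 - tj)       * m[idx(1L, 0L)] +
       (1 - ti) * tj       * m[idx(0L, 1L)] +
       ti * tj             * m[idx(1L, 1L)]
  v[!inside] <- 0
  out <- v
  dim(out) <- dim(fi)
  out
}

#' First-order derivative approximation of the edge image
#'
#' When the splitting is much smaller than the image feature size, the
#' shifted difference reduces to `2 Delta dA/dr` for an amplitude object `A`
#' and (after first-order Taylor expansion of `exp(i Phi)`) to
#' `2 Delta dPhi/dr` for a phase object. This evaluates
#' `|2 Delta * d(.)/dr|` with centered finite differences projected onto the
#' radial unit vector from the optical axis (or onto a Cartesian axis for
#' the 1D design).
#'
#' @param map real matrix: amplitude map `A` or phase map `Phi`.
#' @param delta shift in um, > 0.
#' @param grid the [grid2d()] of `map`.
#' @param kind `"amplitude"` or `"phase"` (semantic tag for the input map).
#' @param axis projection direction: `"r"` projects onto the radial unit
#'   vector from the optical axis (the polar-coordinate form of the 1D
#'   superposition argument, exact for centered features); `"x"`/`"y"` give
#'   the 1D design's directional derivative; `"grad"` takes the gradient
#'   magnitude `|2 Delta grad(.)|`, the small-shift limit of the isotropic
#'   differentiator for features anywhere in the field (a local edge with
#'   in-plane wavevector `k` sees the filter `sin(2 pi Delta |k|)`, i.e. a
#'   shifted difference along its own gradient direction, wherever it sits).
#' @return nonnegative edge-strength matrix.
#' @export
derivative_model <- function(map, delta, grid, kind = c("amplitude", "phase"),
                             axis = c("r", "x", "y", "grad")) {
  kind <- match.arg(kind)
  axis <- match.arg(axis)
  check_positive_scalar(delta, "delta")
  if (!is.matrix(map) || nrow(map) != grid$nx || ncol(map) != grid$ny) {
    stop_metaedge("`map` dimensions must match the grid", "metaedge_invalid_argument")
  }
  gx <- central_diff(map, 1L) / grid$dx
  gy <- central_diff(map, 2L) / grid$dy
  proj <- switch(axis,
    x = gx,
    y = gy,
    grad = sqrt(gx^2 + gy^2),
    r = {
      m <- grid_mesh(grid)
      r <- sqrt(m$X^2 + m$Y^2)
      ifelse(r > 0, (m$X * gx + m$Y * gy) / pmax(r, .Machine$double.eps), 0)
    })
  abs(2 * delta * proj)
}

# Centered finite differences along margin 1 (rows/x) or 2 (cols/y);
# one-sided at the borders.
central_diff <- function(m, margin) {
  n <- dim(m)[margin]
  d <- m
  if (margin == 1L) {
    d[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / 2
    d[1, ] <- m[2, ] - m[1, ]
    d[n, ] <- m[n, ] - m[n - 1, ]
  } else {
    d[, 2:(n - 1)] <- (m[, 3:n] - m[, 1:(n - 2)]) / 2
    d[, 1] <- m[, 2] - m[, 1]
    d[, n] <- m[, n] - m[, n - 1]
  }
  d
}
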