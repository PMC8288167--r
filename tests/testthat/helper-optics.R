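# Shared fixtures: the physical device parameters and small numeric helpers.

LAMBDA <- 0.532   # um
FOCAL <- 25000    # um (f = 25 mm)
PERIOD <- 1000    # um (metasurface period)
DELTA <- LAMBDA * FOCAL / PERIOD  # 13.3 um

rel_l2 <- function(a, b) sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))

# least-squares global complex constant c minimizing ||a - c b||
fit_const <- function(a, b) sum(Conj(b) * a) / sum(Mod(b)^2)

fshift <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  m[c((nx / 2 + 1):nx, 1:(nx / 2)), c((ny / 2 + 1):ny, 1:(ny / 2))]
}

# random band-limited periodic complex object on a grid (spectrum confined
# to |k| <= kfrac of the Nyquist band)
random_bandlimited <- function(grid, kfrac = 0.15) {
  fr <- freq_coords(grid)
  U <- matrix(fr$u, grid$nx, grid$ny)
  V <- matrix(fr$v, grid$nx, grid$ny, byrow = TRUE)
  keep <- sqrt(U^2 + V^2) <= kfrac / max(grid$dx, grid$dy)
  spec <- (matrix(stats::rnorm(grid$nx * grid$ny), grid$nx) +
           1i * matrix(stats::rnorm(grid$nx * grid$ny), grid$nx)) * keep
  ob <- fshift(stats::fft(fshift(spec), inverse = TRUE)) / (grid$nx * grid$ny)
  ob / max(Mod(ob))
}

# scalar sin(2 pi Delta k_r) Fourier filter: the independent reference for
# the radial design's action
sin_filter <- function(object, delta, grid) {
  fr <- freq_coords(grid)
  U <- matrix(fr$u, grid$nx, grid$ny)
  V <- matrix(fr$v, grid$nx, grid$ny, byrow = TRUE)
  spec <- fshift(stats::fft(fshift(object))) * sin(2 * pi * delta * sqrt(U^2 + V^2))
  fshift(stats::fft(fshift(spec), inverse = TRUE)) / (grid$nx * grid$ny)
}

interior_box <- function(grid, frac = 0.4) {
  m <- grid_mesh(grid)
  abs(m$X) <= frac * grid$nx * grid$dx & abs(m$Y) <= frac * grid$ny * grid$dy
}

radius_mesh_test <- function(grid) {
  m <- grid_mesh(grid)
  sqrt(m$X^2 + m$Y^2)
}
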