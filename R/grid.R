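#' Spatial sampling grid
#'
#' Defines the centered Cartesian grid every field, design and image in the
#' package lives on. The coordinate of pixel `(i, j)` (1-based) is
#' `((i - 1 - nx/2) * dx, (j - 1 - ny/2) * dy)` micrometres, so the origin
#' sits on the pixel `(nx/2 + 1, ny/2 + 1)` and arrays are stored
#' "center-shifted" (DC in the middle), matching how spectra are displayed.
#'
#' @param nx,ny pixel counts; must be even and at least 8 so the
#'   center-shifted Fourier bookkeeping is exact.
#' @param dx,dy pixel pitch in micrometres.
#' @return an object of class `grid2d`.
#' @export
grid2d <- function(nx, ny = nx, dx, dy = dx) {
  for (n in c(nx, ny)) {
    if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 8 || n %% 2 != 0) {
      stop_metaedge("grid dimensions must be even integers >= 8",
                    "metaedge_invalid_argument")
    }
  }
  check_positive_scalar(dx, "dx")
  check_positive_scalar(dy, "dy")
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = dx, dy = dy),
            class = "grid2d")
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf("<grid2d> %d x %d px, pitch %.4g x %.4g um, extent %.4g x %.4g um\n",
              x$nx, x$ny, x$dx, x$dy, x$nx * x$dx, x$ny * x$dy))
  invisible(x)
}

#' Axis coordinates of a grid
#'
#' @param grid a [grid2d()].
#' @return list with numeric vectors `x` (length nx) and `y` (length ny), um.
#' @export
axis_coords <- function(grid) {
  list(x = (seq_len(grid$nx) - 1 - grid$nx / 2) * grid$dx,
       y = (seq_len(grid$ny) - 1 - grid$ny / 2) * grid$dy)
}

#' Coordinate meshes of a grid
#'
#' @inheritParams axis_coords
#' @return list of matrices `X`, `Y` (dim `nx` x `ny`), um.
#' @export
grid_mesh <- function(grid) {
  ax <- axis_coords(grid)
  list(X = matrix(ax$x, grid$nx, grid$ny),
       Y = matrix(ax$y, grid$nx, grid$ny, byrow = TRUE))
}

#' Spatial-frequency coordinates of a grid
#'
#' Frequencies (cycles per um) of the center-shifted DFT of an array sampled
#' on `grid`, with DC at pixel `(nx/2 + 1, ny/2 + 1)`.
#'
#' @inheritParams axis_coords
#' @return list with vectors `u` (length nx) and `v` (length ny).
#' @export
freq_coords <- function(grid) {
  list(u = (seq_len(grid$nx) - 1 - grid$nx / 2) / (grid$nx * grid$dx),
       v = (seq_len(grid$ny) - 1 - grid$ny / 2) / (grid$ny * grid$dy))
}

radius_mesh <- function(grid) {
  m <- grid_mesh(grid)
  sqrt(m$X^2 + m$Y^2)
}

# Center-shift a matrix with even dimensions (fftshift; self-inverse here).
fftshift2 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  m[c((nx / 2 + 1):nx, 1:(nx / 2)), c((ny / 2 + 1):ny, 1:(ny / 2))]
}

# Point reflection about the grid origin in center-shifted indexing: the
# image of index i is the index carrying coordinate -x_i (Nyquist row fixed).
# This is exactly the reversal produced by two successive forward DFTs.
flip_center <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  m[c(1L, nx:2L), c(1L, ny:2L)]
}

grids_compatible <- function(a, b, tol = 1e-9) {
  a$nx == b$nx && a$ny == b$ny &&
    abs(a$dx - b$dx) < tol * a$dx && abs(a$dy - b$dy) < tol * a$dy
}
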