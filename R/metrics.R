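# Measurement procedures mirroring the physical experiment: transfer-
# function magnitude from an intensity pair, double-image separation,
# line cross-sections and edge-contrast scoring.

#' Estimate the transfer-function magnitude from an intensity pair
#'
#' Implements the measurement procedure of the experiment: the field
#' magnitudes are recovered as `E_i = sqrt(I_i)` (the phase is lost, exactly
#' as in the physical measurement, so sign changes of the underlying
#' transfer function appear as zeros of `|H|`), the pointwise ratio
#' `|H| = sqrt(I1)/sqrt(I0)` is formed where the denominator exceeds
#' `floor * max(sqrt(I0))`, the measurement-plane position is mapped to
#' spatial frequency `u = x / (lambda f)`, `|H|` is peak-normalized to 1 on
#' the valid mask, and a radial profile is obtained by azimuthal averaging
#' over one-pixel-wide frequency annuli.
#'
#' @param I0,I1 co-registered intensity matrices on the same grid (the
#'   recordings without and with the differentiator; see
#'   [fourier_plane_intensities()]).
#' @param grid [grid2d()] of the measurement plane (um).
#' @param lambda wavelength, um.
#' @param f focal length, um.
#' @param floor denominator floor as a fraction of `max(sqrt(I0))`, in
#'   (0, 1); default 0.05. Below it the ratio is masked, not clipped.
#' @return an object of class `transfer_function_result`: list with
#'   frequency axes `u`, `v` (cycles/um), matrix `H` (`NA` outside the valid
#'   mask), logical `mask`, and `profile` (data.frame `kr`, `H`).
#' @export
estimate_transfer_magnitude <- function(I0, I1, grid, lambda, f, floor = 0.05) {
  stopifnot(inherits(grid, "grid2d"))
  if (!is.matrix(I0) || !is.matrix(I1) || !all(dim(I0) == dim(I1)) ||
      nrow(I0) != grid$nx || ncol(I0) != grid$ny) {
    stop_metaedge("I0 and I1 must be matrices on the stated grid",
                  "metaedge_invalid_argument")
  }
  check_positive_scalar(lambda, "lambda")
  check_positive_scalar(f, "f")
  if (floor <= 0 || floor >= 1) {
    stop_metaedge("floor must lie in (0, 1)", "metaedge_invalid_argument")
  }
  a0 <- sqrt(pmax(I0, 0)); a1 <- sqrt(pmax(I1, 0))
  if (max(a0) <= 0) {
    stop_metaedge("reference intensity I0 carries no signal",
                  "metaedge_degenerate_input")
  }
  mask <- a0 >= floor * max(a0)
  if (!any(mask)) {
    stop_metaedge("all pixels fall below the denominator floor",
                  "metaedge_degenerate_input")
  }
  H <- matrix(NA_real_, grid$nx, grid$ny)
  H[mask] <- a1[mask] / a0[mask]
  H <- H / max(H[mask])
  ax <- axis_coords(grid)
  u <- ax$x / (lambda * f)
  v <- ax$y / (lambda * f)
  kr <- sqrt(outer(u^2, v^2, `+`))
  dkr <- min(grid$dx, grid$dy) / (lambda * f)
  bin <- as.integer(round(kr / dkr))  # note: `floor` is the mask argument here
  ok <- mask & is.finite(H)
  sums <- tapply(H[ok], bin[ok], mean)
  prof <- data.frame(kr = as.numeric(names(sums)) * dkr,
                     H = as.numeric(sums))
  prof <- prof[order(prof$kr), , drop = FALSE]
  structure(list(u = u, v = v, H = H, mask = mask, profile = prof,
                 bin_width = dkr, lambda = lambda, f = f),
            class = "transfer_function_result")
}

#' @export
print.transfer_function_result <- function(x, ...) {
  cat(sprintf("<transfer_function_result> %d x %d px, %d valid, %d radial bins (dk = %.3g /um)\n",
              length(x$u), length(x$v), sum(x$mask), nrow(x$profile), x$bin_width))
  invisible(x)
}

#' First zero of a transfer-function radial profile
#'
#' Locates the first local minimum of the radial `|H|` profile that dips
#' below `threshold`; for the ideal differentiator this sits at
#' `k_r = 1/(2 Delta)`.
#'
#' @param tfr a `transfer_function_result`.
#' @param threshold profile value a minimum must dip below (default 0.1).
#' @return frequency `k_r` in cycles/um, or `NA` if no zero is found.
#' @export
first_zero_kr <- function(tfr, threshold = 0.1) {
  p <- tfr$profile
  n <- nrow(p)
  if (n < 3) return(NA_real_)
  for (i in 2:(n - 1)) {
    if (p$H[i] < threshold && p$H[i] <= p$H[i - 1] && p$H[i] <= p$H[i + 1]) {
      return(p$kr[i])
    }
  }
  NA_real_
}

#' Separation of the two circular-polarization images
#'
#' With the analyzer removed, the 1D (linear-design) differentiator
#' transmits two displaced copies of the object, one per circular
#' polarization; linear mode measures the distance between the intensity
#' centroids of the LCP and RCP components of the image-plane field.
#'
#' In the radial geometry the two circular components of a real object's
#' no-analyzer image carry *identical* intensities (they are complex
#' conjugates of each other), so the splitting is read off the split
#' boundary instead: radial mode takes the edge image of a centered disk
#' fixture (analyzer present), azimuthally averages the intensity, and
#' returns the radial distance between the two boundary peaks, which sit at
#' `R - Delta` and `R + Delta`. For the ideal system both modes equal
#' `2 Delta`.
#'
#' @param field the image-plane [polarized_field()]: a no-analyzer run
#'   (linear mode) or a with-analyzer disk edge image (radial mode).
#' @param mode `"linear"` or `"radial"`.
#' @return separation in um.
#' @export
double_image_separation <- function(field, mode = c("linear", "radial")) {
  mode <- match.arg(mode)
  stopifnot(inherits(field, "polarized_field"))
  g <- field$grid
  sep <- if (mode == "linear") {
    cc <- circular_components(field)
    IL <- Mod(cc$left)^2; IR <- Mod(cc$right)^2
    if (sum(IL) <= 0 || sum(IR) <= 0) {
      stop_metaedge("one circular component carries no power",
                    "metaedge_resolution_error")
    }
    m <- grid_mesh(g)
    cL <- c(sum(m$X * IL), sum(m$Y * IL)) / sum(IL)
    cR <- c(sum(m$X * IR), sum(m$Y * IR)) / sum(IR)
    sqrt(sum((cL - cR)^2))
  } else {
    ring_peak_separation(intensity(field), g)
  }
  if (sep > 0 && sep < 2 * min(g$dx, g$dy)) {
    stop_metaedge(sprintf("components unresolved: separation %.3g um < 2 px", sep),
                  "metaedge_resolution_error")
  }
  sep
}

# Distance between the two peaks of the azimuthally averaged radial
# intensity profile (parabolic sub-bin refinement around each peak).
ring_peak_separation <- function(I, grid) {
  if (max(I) <= 0) {
    stop_metaedge("image carries no signal", "metaedge_degenerate_input")
  }
  r <- radius_mesh(grid)
  db <- min(grid$dx, grid$dy) / 2
  bin <- as.integer(round(r / db))
  prof <- tapply(as.vector(I), as.vector(bin), mean)
  rb <- as.numeric(names(prof)) * db
  o <- order(rb); rb <- rb[o]; prof <- as.numeric(prof)[o]
  n <- length(prof)
  # local maxima above a quarter of the global peak
  pk <- which(prof > 0.25 * max(prof))
  pk <- pk[pk > 1 & pk < n]
  pk <- pk[prof[pk] >= prof[pk - 1] & prof[pk] >= prof[pk + 1]]
  if (length(pk) < 2) {
    stop_metaedge("no resolved split boundary (fewer than two ring peaks)",
                  "metaedge_resolution_error")
  }
  pk <- pk[order(prof[pk], decreasing = TRUE)][1:2]
  refine <- function(i) {
    num <- prof[i - 1] - prof[i + 1]
    den <- prof[i - 1] - 2 * prof[i] + prof[i + 1]
    rb[i] + if (abs(den) > 0) 0.5 * num / den * db else 0
  }
  abs(refine(pk[1]) - refine(pk[2]))
}

#' Intensity cross-section along a segment
#'
#' Bilinear samples of an intensity image along the segment from `p0` to
#' `p1` (the "intensity cross-section along the dashed line" measurement).
#'
#' @param image real matrix on `grid`.
#' @param grid [grid2d()].
#' @param p0,p1 numeric length-2 endpoints (um), inside the grid.
#' @param n number of samples, >= 2.
#' @return data.frame with `distance` (um from `p0`) and `value`.
#' @export
line_profile <- function(image, grid, p0, p1, n = 200L) {
  stopifnot(inherits(grid, "grid2d"))
  if (n < 2) stop_metaedge("need n >= 2 samples", "metaedge_invalid_argument")
  ax <- axis_coords(grid)
  for (p in list(p0, p1)) {
    if (length(p) != 2 || p[1] < ax$x[1] || p[1] > ax$x[grid$nx] ||
        p[2] < ax$y[1] || p[2] > ax$y[grid$ny]) {
      stop_metaedge("profile endpoints must lie inside the grid",
                    "metaedge_invalid_argument")
    }
  }
  t <- seq(0, 1, length.out = n)
  xs <- p0[1] + t * (p1[1] - p0[1])
  ys <- p0[2] + t * (p1[2] - p0[2])
  vals <- Re(bilinear_interp(image, matrix(xs), matrix(ys), grid))
  data.frame(distance = t * sqrt(sum((p1 - p0)^2)), value = as.numeric(vals))
}

#' Edge-enhancement score of an edge image
#'
#' Quantifies how strongly an image concentrates intensity at known object
#' boundaries: the mean intensity within `halo` pixels of the truth edges
#' divided by the mean intensity elsewhere (optionally excluding a vignette
#' or padding region), plus the Michelson contrast of the considered region.
#'
#' @param image real intensity matrix.
#' @param truth_edges logical matrix marking true edge pixels.
#' @param halo dilation radius in pixels (Chebyshev), >= 1.
#' @param exclude optional logical matrix of pixels to ignore entirely
#'   (e.g. the aperture vignette).
#' @return list with `ratio` (edge/background mean intensity) and
#'   `michelson` contrast.
#' @export
edge_enhancement_score <- function(image, truth_edges, halo = 3L, exclude = NULL) {
  if (!is.matrix(truth_edges) || !all(dim(truth_edges) == dim(image))) {
    stop_metaedge("truth_edges must match the image dimensions",
                  "metaedge_invalid_argument")
  }
  if (!any(truth_edges)) {
    stop_metaedge("truth edge mask is empty", "metaedge_invalid_argument")
  }
  if (halo < 1) stop_metaedge("halo must be >= 1", "metaedge_invalid_argument")
  keep <- if (is.null(exclude)) matrix(TRUE, nrow(image), ncol(image)) else !exclude
  near <- dilate_mask(truth_edges, halo)
  bg <- keep & !near
  fg <- keep & near
  if (!any(bg)) {
    stop_metaedge("no background pixels left: truth mask (after dilation) covers the image",
                  "metaedge_invalid_argument")
  }
  list(ratio = mean(image[fg]) / mean(image[bg]),
       michelson = (max(image[keep]) - min(image[keep])) /
                   (max(image[keep]) + min(image[keep])))
}

# binary dilation with a (2h+1)^2 square structuring element via shift-OR
dilate_mask <- function(mask, h) {
  out <- mask
  nx <- nrow(mask); ny <- ncol(mask)
  for (di in -h:h) for (dj in -h:h) {
    if (di == 0 && dj == 0) next
    si <- pmin(pmax(seq_len(nx) + di, 1L), nx)
    sj <- pmin(pmax(seq_len(ny) + dj, 1L), ny)
    out <- out | mask[si, sj]
  }
  out
}

#' Michelson contrast of an image region
#'
#' @param image real matrix.
#' @param region optional logical matrix selecting the pixels considered.
#' @return `(max - min) / (max + min)` over the region.
#' @export
michelson_contrast <- function(image, region = NULL) {
  v <- if (is.null(region)) image else image[region]
  (max(v) - min(v)) / (max(v) + min(v))
}
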