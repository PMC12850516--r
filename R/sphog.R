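# Smoothed pyramid histogram of oriented gradients (S-PHOG): Gaussian
# smoothing before centered-difference gradients, neighborhood-normalized
# magnitudes, neighborhood-averaged orientations (unit-vector mean), and
# magnitude-weighted orientation histograms over a spatial pyramid, L1
# normalized to sum one. An unsmoothed PHOG baseline is provided for
# ablation comparisons.

#' S-PHOG parameters
#'
#' @param sigma Gaussian smoothing sd in pixels (> 0, default 1).
#' @param n_bins Number of orientation bins Z (>= 2, default 9).
#' @param levels Pyramid levels, contiguous from 0 (default `0:1`); level `l`
#'   splits each axis into `2^l` cells.
#' @param signed If `FALSE` (default) orientations are folded into [0, 180);
#'   if `TRUE` the range is [0, 360).
#' @param eps Positive guard against division by zero (default 1e-8).
#' @param neigh Odd neighborhood side for magnitude normalization and
#'   orientation averaging (default 3).
#' @return An object of class `sphog_params`.
#' @export
sphog_params <- function(sigma = 1, n_bins = 9L, levels = 0:1, signed = FALSE,
                         eps = 1e-8, neigh = 3L) {
  check_number(sigma, "sigma", lower = 0, open_lower = TRUE)
  n_bins <- check_count(n_bins, "n_bins", lower = 2L)
  levels <- sort(unique(as.integer(levels)))
  if (!length(levels) || !identical(levels, seq.int(0L, max(levels))))
    stop_bad_arg("levels must be contiguous from 0")
  check_number(eps, "eps", lower = 0, open_lower = TRUE)
  if (!is_odd_window(neigh)) stop_bad_arg("`neigh` must be odd and >= 3")
  structure(list(sigma = sigma, n_bins = n_bins, levels = levels,
                 signed = isTRUE(signed), eps = eps, neigh = as.integer(neigh)),
            class = "sphog_params")
}

#' Gaussian smoothing of an image
#'
#' Separable Gaussian convolution (reflect padding, kernel renormalized to
#' sum one); the stabilization step applied before gradient computation.
#'
#' @param img 2-D numeric matrix (or `brain_image`).
#' @param sigma Kernel sd in pixels (> 0).
#' @return Smoothed matrix.
#' @export
gaussian_smooth <- function(img, sigma = 1) gaussian_filter_2d(img, sigma)

#' Centered-difference gradients of the smoothed image
#'
#' Filters the Gaussian-smoothed image with the centered derivative masks
#' `[-1, 0, 1]` (x = column direction) and its transpose (y = row direction),
#' reflect padding; returned as correlation responses
#' `Ax(i,j) = s(i,j+1) - s(i,j-1)`, `Ay(i,j) = s(i-1,j) - s(i+1,j)`.
#'
#' @param img 2-D numeric matrix (or `brain_image`), at least 3x3.
#' @param sigma Smoothing sd (> 0); use [raw_gradients()] for no smoothing.
#' @return A list with matrices `Ax` and `Ay`.
#' @export
smoothed_gradients <- function(img, sigma = 1) {
  img <- as_image_matrix(img)
  if (any(dim(img) < 3L)) stop_bad_arg("image must be at least 3x3")
  raw_gradients(gaussian_smooth(img, sigma))
}

#' Centered-difference gradients without smoothing
#'
#' @param img 2-D numeric matrix (or `brain_image`), at least 3x3.
#' @return A list with matrices `Ax` and `Ay`.
#' @export
raw_gradients <- function(img) {
  img <- as_image_matrix(img)
  if (any(dim(img) < 3L)) stop_bad_arg("image must be at least 3x3")
  n <- nrow(img); m <- ncol(img)
  p <- pad_reflect_2d(img, 1L)
  Ax <- p[2:(n + 1L), 3:(m + 2L), drop = FALSE] - p[2:(n + 1L), 1:m, drop = FALSE]
  Ay <- p[1:n, 2:(m + 1L), drop = FALSE] - p[3:(n + 2L), 2:(m + 1L), drop = FALSE]
  list(Ax = Ax, Ay = Ay)
}

#' Neighborhood-normalized gradient magnitude
#'
#' `A_new = A / (eps_local + eps)` where `A = sqrt(Ax^2 + Ay^2)` and
#' `eps_local` sums `A` over the `neigh x neigh` neighborhood (reflect
#' padding). Since each pixel contributes to its own neighborhood sum, values
#' are bounded by 1; a uniform gradient field maps interior pixels to
#' `1 / neigh^2`.
#'
#' @param Ax,Ay Gradient component matrices of equal shape.
#' @param params An [sphog_params()].
#' @return Matrix of normalized magnitudes in [0, 1].
#' @export
normalized_magnitude <- function(Ax, Ay, params = sphog_params()) {
  if (!identical(dim(Ax), dim(Ay))) stop_bad_arg("Ax and Ay shapes differ")
  A <- sqrt(Ax^2 + Ay^2)
  A / (box_sum_2d(A, params$neigh) + params$eps)
}

#' Neighborhood-averaged gradient orientation
#'
#' Per-pixel raw angle `atan2(Ay, Ax)` is turned into a unit vector; the
#' orientation is the angle of the neighborhood mean vector, which averages
#' noisy directions without wrap-around artifacts. Where opposite directions
#' cancel (mean vector near zero) the angle is set to 0 and flagged.
#'
#' @param Ax,Ay Gradient component matrices of equal shape.
#' @param params An [sphog_params()].
#' @param tol Mean-vector norm below which the cancellation guard fires.
#' @return Matrix of angles in (-pi, pi]; attribute `"zero_vector"` is a
#'   logical matrix marking guarded pixels.
#' @export
smoothed_orientation <- function(Ax, Ay, params = sphog_params(), tol = 1e-12) {
  if (!identical(dim(Ax), dim(Ay))) stop_bad_arg("Ax and Ay shapes differ")
  ao <- atan2(Ay, Ax)
  k2 <- params$neigh^2
  mvx <- box_sum_2d(cos(ao), params$neigh) / k2
  mvy <- box_sum_2d(sin(ao), params$neigh) / k2
  guard <- sqrt(mvx^2 + mvy^2) < tol
  ang <- atan2(mvy, mvx)
  ang[guard] <- 0
  attr(ang, "zero_vector") <- guard
  ang
}

#' Magnitude-weighted orientation histogram of a region
#'
#' Accumulates gradient magnitudes into `Z` equal-width orientation bins over
#' [0, 180) degrees (unsigned; angles are folded modulo 180) or [0, 360)
#' (signed).
#'
#' @param mag Magnitude matrix (vote weights).
#' @param ori Orientation matrix in radians.
#' @param region List with integer vectors `rows` and `cols` delimiting the
#'   cell, or `NULL` for the whole image.
#' @param Z Number of bins.
#' @param signed Logical; use the full 360-degree range.
#' @return Numeric vector of `Z` nonnegative bin masses.
#' @export
orientation_histogram <- function(mag, ori, region = NULL, Z = 9L,
                                  signed = FALSE) {
  Z <- check_count(Z, "Z", lower = 2L)
  if (!is.null(region)) {
    mag <- mag[region$rows, region$cols, drop = FALSE]
    ori <- ori[region$rows, region$cols, drop = FALSE]
  }
  if (!length(mag)) return(numeric(Z))
  deg <- ori * 180 / pi
  span <- if (signed) 360 else 180
  deg <- deg %% span
  idx <- pmin(floor(deg / (span / Z)) + 1L, Z)
  as.numeric(vapply(seq_len(Z), function(b) sum(mag[idx == b]), 0))
}

#' S-PHOG descriptor of an image
#'
#' Smooths, computes normalized gradient magnitudes and averaged
#' orientations, histograms them over a spatial pyramid (level `l` splits the
#' image into a `2^l x 2^l` grid of cells, concatenated level by level with
#' cells in row-major order) and L1-normalizes the concatenated vector to sum
#' one. Length is `Z * sum(4^levels)` (45 for Z = 9, levels 0-1). A
#' zero-gradient image yields the uniform vector, flagged via the
#' `"degenerate"` attribute.
#'
#' @param img 2-D numeric matrix (or `brain_image`).
#' @param params An [sphog_params()].
#' @return Nonnegative numeric vector summing to 1, with attribute `"layout"`
#'   giving each level's offset.
#' @export
sphog_descriptor <- function(img, params = sphog_params()) {
  img <- as_image_matrix(img)
  maxl <- max(params$levels)
  if (any(dim(img) < 2^maxl * 2))
    stop_bad_arg("image dims %s too small for pyramid level %d",
                 paste(dim(img), collapse = "x"), maxl)
  g <- smoothed_gradients(img, params$sigma)
  mag <- normalized_magnitude(g$Ax, g$Ay, params)
  ori <- smoothed_orientation(g$Ax, g$Ay, params)
  pyramid_histograms(mag, ori, params)
}

#' Unsmoothed PHOG baseline descriptor
#'
#' The same pyramid and binning as [sphog_descriptor()] but with raw
#' centered-difference gradients, raw magnitude `sqrt(Ax^2 + Ay^2)` and
#' per-pixel `atan2` orientations — the conventional PHOG against which the
#' smoothed variant's noise robustness is measured.
#'
#' @inheritParams sphog_descriptor
#' @return Nonnegative numeric vector summing to 1.
#' @export
phog_descriptor <- function(img, params = sphog_params()) {
  img <- as_image_matrix(img)
  g <- raw_gradients(img)
  mag <- sqrt(g$Ax^2 + g$Ay^2)
  ori <- atan2(g$Ay, g$Ax)
  pyramid_histograms(mag, ori, params)
}

pyramid_histograms <- function(mag, ori, params) {
  out <- numeric(0)
  layout <- list()
  for (l in params$levels) {
    ncell <- 2L^l
    rsplit <- split_indices(nrow(mag), ncell)
    csplit <- split_indices(ncol(mag), ncell)
    start <- length(out) + 1L
    for (r in seq_len(ncell)) for (cc in seq_len(ncell)) {
      out <- c(out, orientation_histogram(
        mag, ori, region = list(rows = rsplit[[r]], cols = csplit[[cc]]),
        Z = params$n_bins, signed = params$signed))
    }
    layout[[paste0("level", l)]] <- c(start, length(out))
  }
  tot <- sum(out)
  degenerate <- tot <= 0
  out <- if (degenerate) rep(1 / length(out), length(out)) else out / tot
  attr(out, "layout") <- layout
  attr(out, "degenerate") <- degenerate
  out
}

split_indices <- function(n, k) {
  cuts <- floor(seq(0, n, length.out = k + 1L))
  lapply(seq_len(k), function(i) seq.int(cuts[i] + 1L, cuts[i + 1L]))
}
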