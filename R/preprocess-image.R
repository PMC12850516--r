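# 2-D denoising: local window statistics, the clamped-gain local Wiener
# filter, Sobel gradients, the hybrid adaptive weighting beta, and the
# adaptive weight-based Wiener filter (AW-WF) that convexly mixes a local
# median with the Wiener estimate. Reflect padding everywhere.

#' AW-WF parameters
#'
#' @param window Odd square mask side (>= 3).
#' @param lam Edge-sensitivity parameter in (0, 1) weighting the Sobel
#'   gradient magnitude in the beta denominator.
#' @param eps Small positive guard against division by zero.
#' @param noise_var_mode `"global_mean_of_local_vars"` estimates the global
#'   noise variance as the mean of the local variances (classic local-Wiener
#'   practice) or `"user_supplied"` to require an explicit `v2`.
#' @return An object of class `awwf_params`.
#' @export
awwf_params <- function(window = 5L, lam = 0.5, eps = 1e-8,
                        noise_var_mode = c("global_mean_of_local_vars",
                                           "user_supplied")) {
  if (!is_odd_window(window)) stop_bad_arg("`window` must be odd and >= 3")
  check_number(lam, "lam", lower = 0, upper = 1, open_lower = TRUE, open_upper = TRUE)
  check_number(eps, "eps", lower = 0, open_lower = TRUE)
  structure(list(window = as.integer(window), lam = lam, eps = eps,
                 noise_var_mode = match.arg(noise_var_mode)),
            class = "awwf_params")
}

as_image_matrix <- function(img) {
  if (inherits(img, "brain_image")) img <- img$data
  if (is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 1L)
    img <- img[, , 1L]
  if (!is.matrix(img)) stop_bad_arg("expected a 2-D image matrix")
  img
}

#' Local mean and variance over a square window
#'
#' Per-pixel mean and population variance over a `window x window`
#' neighbourhood with reflect padding, computed with integral images.
#'
#' @param img 2-D numeric matrix (or `brain_image`).
#' @param window Odd window side, at most the smaller image dimension.
#' @return A list with matrices `mean` and `var` (variance clamped >= 0).
#' @export
local_stats <- function(img, window) {
  img <- as_image_matrix(img)
  if (!is_odd_window(window)) stop_bad_arg("`window` must be odd and >= 3")
  if (window > min(dim(img)))
    stop_bad_arg("window %d exceeds the smaller image dim %d", window, min(dim(img)))
  w2 <- window^2
  m <- box_sum_2d(img, window) / w2
  v <- box_sum_2d(img^2, window) / w2 - m^2
  list(mean = m, var = pmax(v, 0))
}

#' Estimate global noise variance from local variances
#'
#' The mean over all pixels of the local window variance — the standard plug-in
#' noise estimate for local Wiener filtering of homogeneous noise.
#'
#' @inheritParams local_stats
#' @return A single nonnegative number.
#' @export
estimate_noise_variance <- function(img, window = 5L) {
  mean(local_stats(img, window)$var)
}

#' Local Wiener filter with clamped gain
#'
#' Per-pixel `M + g * (I - M)` with gain `g = (var - v2) / var` clamped to
#' [0, 1]; flat regions (`var = 0`) return the local mean. Smooths where the
#' local variance is at the noise floor and passes detail where it is far
#' above it.
#'
#' @param img 2-D numeric matrix (or `brain_image`).
#' @param window Odd window side.
#' @param v2 Noise variance (>= 0); if `NULL`, estimated via
#'   [estimate_noise_variance()].
#' @return Filtered matrix, same shape as `img`.
#' @export
wiener_filter <- function(img, window = 5L, v2 = NULL) {
  img <- as_image_matrix(img)
  st <- local_stats(img, window)
  if (is.null(v2)) v2 <- mean(st$var)
  check_number(v2, "v2", lower = 0)
  gain <- ifelse(st$var > 0, clamp((st$var - v2) / st$var, 0, 1), 0)
  st$mean + gain * (img - st$mean)
}

#' Sobel gradient magnitude
#'
#' `sqrt(Bx^2 + By^2)` with the standard 3x3 Sobel kernels and reflect
#' padding; nonnegative everywhere, zero on constant images.
#'
#' @param img 2-D numeric matrix (or `brain_image`), at least 3x3.
#' @return Matrix of gradient magnitudes.
#' @export
sobel_gradient_magnitude <- function(img) {
  img <- as_image_matrix(img)
  if (any(dim(img) < 3L)) stop_bad_arg("image must be at least 3x3 for Sobel")
  p <- pad_reflect_2d(img, 1L)
  n <- nrow(img); m <- ncol(img)
  sh <- function(dr, dc) p[(1L + dr):(n + dr), (1L + dc):(m + dc), drop = FALSE]
  # x: column direction; y: row direction
  bx <- (sh(0, 2) + 2 * sh(1, 2) + sh(2, 2)) - (sh(0, 0) + 2 * sh(1, 0) + sh(2, 0))
  by <- (sh(2, 0) + 2 * sh(2, 1) + sh(2, 2)) - (sh(0, 0) + 2 * sh(0, 1) + sh(0, 2))
  sqrt(bx^2 + by^2)
}

#' Hybrid adaptive mixing weight for AW-WF
#'
#' `beta = v2 / (var + lam * alpha + eps)` clamped to [0, 1], where `alpha` is
#' the Sobel gradient magnitude. Beta approaches 1 (median dominates) in flat
#' noisy regions and falls toward 0 (Wiener dominates) on edges or
#' high-variance structure.
#'
#' @param img 2-D numeric matrix (or `brain_image`).
#' @param params An [awwf_params()] object.
#' @param v2 Noise variance (>= 0); `NULL` to estimate.
#' @return Matrix of weights in [0, 1].
#' @export
adaptive_beta <- function(img, params = awwf_params(), v2 = NULL) {
  img <- as_image_matrix(img)
  stopifnot(inherits(params, "awwf_params"))
  st <- local_stats(img, params$window)
  if (is.null(v2)) {
    if (params$noise_var_mode == "user_supplied")
      stop_bad_arg("noise_var_mode = 'user_supplied' requires `v2`")
    v2 <- mean(st$var)
  }
  check_number(v2, "v2", lower = 0)
  alpha <- sobel_gradient_magnitude(img)
  clamp(v2 / (st$var + params$lam * alpha + params$eps), 0, 1)
}

#' 2-D median filter
#'
#' Window median per pixel with reflect padding; the impulse-noise workhorse
#' that AW-WF falls back to where `beta = 1`.
#'
#' @inheritParams local_stats
#' @return Filtered matrix.
#' @export
median_filter_2d <- function(img, window = 3L) {
  img <- as_image_matrix(img)
  if (!is_odd_window(window)) stop_bad_arg("`window` must be odd and >= 3")
  h <- (window - 1L) %/% 2L
  p <- pad_reflect_2d(img, h)
  n <- nrow(img); m <- ncol(img)
  cols <- matrix(0, n * m, window^2)
  j <- 0L
  for (dc in 0:(window - 1L)) for (dr in 0:(window - 1L)) {
    j <- j + 1L
    cols[, j] <- as.vector(p[(1L + dr):(n + dr), (1L + dc):(m + dc)])
  }
  matrix(row_medians(cols), n, m)
}

#' 2-D Gaussian smoothing filter
#'
#' Separable Gaussian convolution with reflect padding and a kernel truncated
#' at `ceiling(3 * sigma)` and renormalized to sum one.
#'
#' @param img 2-D numeric matrix (or `brain_image`).
#' @param sigma Kernel standard deviation in pixels (> 0).
#' @return Smoothed matrix, same shape.
#' @export
gaussian_filter_2d <- function(img, sigma = 1) {
  img <- as_image_matrix(img)
  check_number(sigma, "sigma", lower = 0, open_lower = TRUE)
  N <- max(1L, as.integer(ceiling(3 * sigma)))
  g <- gaussian_kernel_1d(N, sigma)
  conv_sep_2d(img, g)
}

# Separable symmetric-kernel convolution (rows then columns), reflect padding.
conv_sep_2d <- function(img, g) {
  N <- (length(g) - 1L) %/% 2L
  n <- nrow(img); m <- ncol(img)
  p <- img[reflect_index(n, N), , drop = FALSE]
  out <- matrix(0, n, m)
  for (k in seq_along(g)) out <- out + g[k] * p[k:(k + n - 1L), , drop = FALSE]
  p <- out[, reflect_index(m, N), drop = FALSE]
  out2 <- matrix(0, n, m)
  for (k in seq_along(g)) out2 <- out2 + g[k] * p[, k:(k + m - 1L), drop = FALSE]
  out2
}

#' Adaptive weight-based Wiener filter (AW-WF)
#'
#' Per-pixel convex mix of the local median and the clamped-gain Wiener
#' estimate, `beta * Med + (1 - beta) * Wiener`, with `beta` from
#' [adaptive_beta()]. The median term suppresses impulsive outliers in flat
#' regions while the Wiener term preserves edges and texture.
#'
#' @param img 2-D numeric matrix (or `brain_image`).
#' @param params An [awwf_params()] object.
#' @param v2 Optional noise variance; `NULL` to estimate per
#'   `params$noise_var_mode`.
#' @param beta Optional fixed mixing weight (scalar or matrix in [0, 1]),
#'   overriding the adaptive rule; `beta = 0` reduces the filter to
#'   [wiener_filter()] and `beta = 1` to [median_filter_2d()].
#' @return Filtered matrix, same shape as the input; the estimated `v2` and
#'   mean `beta` are attached as attributes `"v2"` and `"mean_beta"`.
#' @export
awwf_filter <- function(img, params = awwf_params(), v2 = NULL, beta = NULL) {
  img <- as_image_matrix(img)
  stopifnot(inherits(params, "awwf_params"))
  st <- local_stats(img, params$window)
  if (is.null(v2)) {
    if (params$noise_var_mode == "user_supplied" && is.null(beta))
      stop_bad_arg("noise_var_mode = 'user_supplied' requires `v2`")
    v2 <- mean(st$var)
  }
  check_number(v2, "v2", lower = 0)
  if (is.null(beta)) beta <- adaptive_beta(img, params, v2 = v2)
  if (any(beta < 0 | beta > 1)) stop_bad_arg("`beta` must lie in [0, 1]")
  med <- median_filter_2d(img, params$window)
  gain <- ifelse(st$var > 0, clamp((st$var - v2) / st$var, 0, 1), 0)
  wie <- st$mean + gain * (img - st$mean)
  out <- beta * med + (1 - beta) * wie
  attr(out, "v2") <- v2
  attr(out, "mean_beta") <- mean(beta)
  out
}

#' AW-WF auxiliary diagnostics
#'
#' Side computations of the filtering procedure that do not feed the estimate
#' itself: the mean-assignment pass (every pixel replaced by its window mean)
#' and the power spectral density obtained as the Fourier transform of the
#' autocorrelation function.
#'
#' @inheritParams awwf_filter
#' @return A list with `mean_pass` (matrix) and `psd` (matrix, nonnegative).
#' @export
awwf_diagnostics <- function(img, params = awwf_params()) {
  img <- as_image_matrix(img)
  st <- local_stats(img, params$window)
  ft <- fft(img - mean(img))
  psd <- Re(ft * Conj(ft)) / length(img)   # FT of the circular autocorrelation
  list(mean_pass = st$mean, psd = psd)
}
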