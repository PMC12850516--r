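# 1-D denoising: plain median filtering and the two-stage Gauss-based median
# filter (G-MF), where stage 1 smooths with a per-sample Gaussian kernel whose
# width follows the local variance and stage 2 applies a running median.
# Boundaries use whole-sample reflect padding throughout.

#' G-MF parameters
#'
#' @param N Window half-width; the filter window has length `2N + 1`.
#' @param phi Variance-to-width gain in (0, 1) mapping local variance to the
#'   per-sample Gaussian width.
#' @param sigma_min Floor on the kernel width (> 0) so flat stretches fall
#'   back to near-delta smoothing.
#' @param sigma_mode `"variance"` uses `sigma_i = phi * var_i` (the literal
#'   rule); `"sd"` uses `phi * sqrt(var_i)`, exposed because a variance is
#'   being assigned to a width in the literal rule.
#' @return An object of class `gmf_params`.
#' @export
gmf_params <- function(N = 3L, phi = 0.5, sigma_min = 0.5,
                       sigma_mode = c("variance", "sd")) {
  N <- check_count(N, "N", lower = 1L)
  check_number(phi, "phi", lower = 0, upper = 1, open_lower = TRUE, open_upper = TRUE)
  check_number(sigma_min, "sigma_min", lower = 0, open_lower = TRUE)
  structure(list(N = N, phi = phi, sigma_min = sigma_min,
                 sigma_mode = match.arg(sigma_mode)),
            class = "gmf_params")
}

#' Running median filter for 1-D signals
#'
#' Replaces every sample by the median of its `2N + 1` neighbourhood, the
#' classic order-statistic filter for impulsive artifacts; boundaries are
#' handled by reflect padding (boundary sample not duplicated).
#'
#' @param x Numeric vector with `length(x) >= 2N + 1`.
#' @param N Window half-width (>= 1).
#' @return Filtered vector, same length as `x`.
#' @export
median_filter_1d <- function(x, N) {
  N <- check_count(N, "N", lower = 1L)
  n <- length(x)
  if (n < 2L * N + 1L)
    stop_bad_arg("signal of length %d is shorter than the window 2N+1 = %d",
                 n, 2L * N + 1L)
  xp <- pad_reflect_1d(x, N)
  stats::runmed(xp, 2L * N + 1L, endrule = "keep")[(N + 1L):(N + n)]
}

#' Normalized 1-D Gaussian kernel
#'
#' Discrete Gaussian weights on offsets `-N..N`, renormalized to sum to one so
#' that constant signals pass through unchanged.
#'
#' @param N Half-width (>= 1); kernel length is `2N + 1`.
#' @param sigma Kernel width (> 0).
#' @return Numeric vector of `2N + 1` positive weights summing to 1.
#' @export
gaussian_kernel_1d <- function(N, sigma) {
  N <- check_count(N, "N", lower = 1L)
  check_number(sigma, "sigma", lower = 0, open_lower = TRUE)
  k <- seq.int(-N, N)
  g <- exp(-k^2 / (2 * sigma^2))
  g / sum(g)
}

# Local (population) variance over 2N+1 windows with reflect padding.
local_variance_1d <- function(x, N) {
  n <- length(x)
  xp <- pad_reflect_1d(x, N)
  w <- 2L * N + 1L
  cs <- cumsum(c(0, xp)); cs2 <- cumsum(c(0, xp^2))
  i <- seq_len(n)
  m <- (cs[i + w] - cs[i]) / w
  v <- (cs2[i + w] - cs2[i]) / w - m^2
  pmax(v, 0)
}

#' Gauss-based median filter (G-MF)
#'
#' Two-stage signal denoiser: first an adaptive Gaussian smoother whose kernel
#' width at sample `i` is `max(phi * var_i, sigma_min)` (local variance over
#' the same `2N + 1` window), then a running median of the smoothed signal.
#' Wider kernels are therefore applied exactly where the signal is volatile,
#' while the median stage removes residual impulses.
#'
#' @param x Numeric vector with `length(x) >= 2N + 1`.
#' @param params A [gmf_params()] object.
#' @return Filtered vector, same length as `x`.
#' @export
gmf_filter <- function(x, params = gmf_params()) {
  stopifnot(inherits(params, "gmf_params"))
  N <- params$N
  n <- length(x)
  if (n < 2L * N + 1L)
    stop_bad_arg("signal of length %d is shorter than the window 2N+1 = %d",
                 n, 2L * N + 1L)
  v <- local_variance_1d(x, N)
  sig <- if (params$sigma_mode == "variance") params$phi * v else params$phi * sqrt(v)
  sig <- pmax(sig, params$sigma_min)
  xp <- pad_reflect_1d(x, N)
  num <- numeric(n); den <- numeric(n)
  inv2s2 <- 1 / (2 * sig^2)
  for (k in -N:N) {
    w <- exp(-k^2 * inv2s2)     # per-sample weight for this offset
    num <- num + w * xp[(N + 1L):(N + n) + k]
    den <- den + w
  }
  median_filter_1d(num / den, N)
}
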