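# Enhanced common spatial patterns (E-CSP): an activation chain that centers
# task trials on resting-state statistics and squashes them (softsign then
# swish), frequency weighting concentrated on the ictal band, shrinkage-
# regularized class covariances, and spatial filters from the generalized
# eigenproblem that extremizes the between-class variance ratio.

#' E-CSP parameters
#'
#' @param gamma1,gamma2 Shrinkage weights in [0, 1] blending each class
#'   covariance with the identity (stabilizes inversion; 0 = sample
#'   covariance, 1 = identity).
#' @param fc Center frequency of the weighting function in Hz (default 5, the
#'   middle of the 3-7 Hz ictal rhythm).
#' @param delta_f Bandwidth of the weighting function in Hz (> 0, default 4).
#' @param n_filters Number of spatial filters (default 32, drawn half from
#'   each end of the eigenvalue spectrum; at most `2 * channels`).
#' @param feature_mode `"mean_power"` (mean squared projected sample, the
#'   default: the literal mean of a zero-mean projection is uninformative) or
#'   `"literal_mean"` (arithmetic mean of the projection).
#' @param weight_mode `"spectral"` multiplies each trial's spectrum by
#'   `sqrt(W_freq(f))` inside `[fc - delta_f, fc + delta_f]` and zero outside
#'   before covariance estimation; `"scalar"` weights each trial covariance by
#'   `W_freq` at the trial's spectral peak; `"none"` disables weighting.
#' @return An object of class `ecsp_params`.
#' @export
ecsp_params <- function(gamma1 = 0.1, gamma2 = 0.1, fc = 5, delta_f = 4,
                        n_filters = 32L,
                        feature_mode = c("mean_power", "literal_mean"),
                        weight_mode = c("spectral", "scalar", "none")) {
  check_number(gamma1, "gamma1", lower = 0, upper = 1)
  check_number(gamma2, "gamma2", lower = 0, upper = 1)
  check_number(fc, "fc", lower = 0)
  check_number(delta_f, "delta_f", lower = 0, open_lower = TRUE)
  n_filters <- check_count(n_filters, "n_filters", lower = 1L)
  structure(list(gamma1 = gamma1, gamma2 = gamma2, fc = fc, delta_f = delta_f,
                 n_filters = n_filters, feature_mode = match.arg(feature_mode),
                 weight_mode = match.arg(weight_mode)),
            class = "ecsp_params")
}

#' E-CSP activation chain
#'
#' Standardizes task samples against resting-state statistics,
#' `(z - mu_rest) / sd_rest`, squashes with softsign `u / (1 + |u|)` into
#' (-1, 1), then applies swish `u * sigmoid(u)`. The composition is monotone
#' and bounded in roughly (-0.27, 1), damping outliers while preserving order.
#'
#' @param task Numeric vector or matrix of task-condition samples.
#' @param rest Numeric vector or matrix of resting-state samples (must not be
#'   constant).
#' @return Activated values, same shape as `task`.
#' @export
ecsp_activate <- function(task, rest) {
  mu <- mean(rest)
  sdr <- sqrt(mean((rest - mu)^2))
  if (!is.finite(sdr) || sdr <= 0)
    stop_bad_arg("resting-state signal is constant (sd = 0); cannot standardize")
  z <- (task - mu) / sdr
  s <- z / (1 + abs(z))
  s * stats::plogis(s)
}

#' Frequency weighting function
#'
#' `w(f) = 1 / (1 + 4 ((f - fc) / delta_f)^2)`: 1 at the center frequency,
#' 0.5 at `fc +/- delta_f / 2`, 0.2 at `fc +/- delta_f`.
#'
#' @param f Frequencies in Hz (vectorized).
#' @param fc Center frequency in Hz.
#' @param delta_f Bandwidth in Hz (> 0).
#' @return Weights in (0, 1].
#' @export
frequency_weight <- function(f, fc, delta_f) {
  check_number(delta_f, "delta_f", lower = 0, open_lower = TRUE)
  1 / (1 + 4 * ((f - fc) / delta_f)^2)
}

# Band-limit a channels x samples trial to [fc - df, fc + df] and scale the
# spectrum by sqrt(W_freq) so the PSD is weighted by W_freq.
spectral_weight_trial <- function(trial, fs, fc, delta_f) {
  n <- ncol(trial)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)                    # fold to physical frequency
  w <- sqrt(frequency_weight(f, fc, delta_f))
  w[f < max(0, fc - delta_f) | f > fc + delta_f] <- 0
  ft <- mvfft(t(trial)) * w
  t(Re(mvfft(ft, inverse = TRUE))) / n
}

#' Shrink a covariance matrix toward the identity
#'
#' `(1 - gamma) * G + gamma * I`.
#'
#' @param G Symmetric covariance matrix.
#' @param gamma Shrinkage weight in [0, 1].
#' @return Shrunk covariance matrix.
#' @export
shrink_covariance <- function(G, gamma) {
  check_number(gamma, "gamma", lower = 0, upper = 1)
  (1 - gamma) * G + gamma * diag(nrow(G))
}

#' Class covariances for E-CSP
#'
#' Averages per-trial outer-product covariances within each class (label 1 =
#' task/seizure, label 0 = rest/background), applying the configured frequency
#' weighting first, then shrinks each class covariance toward the identity.
#'
#' @param trials List of (activated) channels x samples matrices.
#' @param labels Integer vector of 0/1 labels, one per trial.
#' @param params An [ecsp_params()].
#' @param fs Sampling rate in Hz (needed unless `weight_mode = "none"`).
#' @return An object of class `ecsp_covariances` with symmetric PSD members
#'   `G1_shrunk` (task) and `G2_shrunk` (rest).
#' @export
ecsp_covariances <- function(trials, labels, params = ecsp_params(), fs = NULL) {
  stopifnot(inherits(params, "ecsp_params"))
  labels <- as.integer(labels)
  if (length(trials) != length(labels))
    stop_bad_arg("need one label per trial")
  if (!all(c(0L, 1L) %in% labels))
    stop_bad_arg("both classes must be present to build E-CSP covariances")
  if (params$weight_mode != "none" && is.null(fs))
    stop_bad_arg("`fs` is required for frequency weighting")
  trial_cov <- function(tr) {
    if (params$weight_mode == "spectral") {
      tr <- spectral_weight_trial(tr, fs, params$fc, params$delta_f)
      tcrossprod(tr) / ncol(tr)
    } else if (params$weight_mode == "scalar") {
      ps <- welch_psd(tr, fs)
      fpk <- ps$freq[which.max(colMeans(ps$psd))]
      frequency_weight(fpk, params$fc, params$delta_f) * tcrossprod(tr) / ncol(tr)
    } else tcrossprod(tr) / ncol(tr)
  }
  avg_cov <- function(idx) Reduce(`+`, lapply(trials[idx], trial_cov)) / length(idx)
  G1 <- avg_cov(which(labels == 1L))
  G2 <- avg_cov(which(labels == 0L))
  structure(list(G1_shrunk = shrink_covariance(G1, params$gamma1),
                 G2_shrunk = shrink_covariance(G2, params$gamma2)),
            class = "ecsp_covariances")
}

#' Derive the E-CSP spatial filter bank
#'
#' Solves the generalized eigenproblem `G1' w = lambda G2' w` by whitening
#' (`G2'^(-1/2) G1' G2'^(-1/2)`), giving filters that extremize the
#' task-to-rest variance ratio: large eigenvalues emphasize task variance,
#' small ones rest variance. `n_filters` rows are taken alternately from the
#' two ends of the eigenvalue spectrum (eigenvectors are reused when
#' `n_filters` exceeds the channel count) and normalized to unit length.
#'
#' @param cov An [ecsp_covariances()] object.
#' @param n_filters Number of filters (<= 2 * channels).
#' @return An object of class `spatial_filter_bank`: `filters`
#'   (n_filters x channels, unit-norm rows), `lambda` (Rayleigh quotient of
#'   each row), `eigenvalues` (full spectrum, descending).
#' @export
ecsp_filters <- function(cov, n_filters = 32L) {
  stopifnot(inherits(cov, "ecsp_covariances"))
  n_filters <- check_count(n_filters, "n_filters", lower = 1L)
  C <- nrow(cov$G2_shrunk)
  if (n_filters > 2L * C)
    stop_bad_arg("n_filters = %d exceeds 2 * channels = %d", n_filters, 2L * C)
  G2 <- (cov$G2_shrunk + t(cov$G2_shrunk)) / 2
  e2 <- eigen(G2, symmetric = TRUE)
  if (min(e2$values) <= 1e-12 * max(abs(e2$values))) {
    warning("rest covariance is singular; adding a small ridge", call. = FALSE)
    ridge <- 1e-8 * max(mean(diag(G2)), 1)
    e2$values <- e2$values + ridge
  }
  wh <- e2$vectors %*% (t(e2$vectors) / sqrt(e2$values))
  S <- wh %*% ((cov$G1_shrunk + t(cov$G1_shrunk)) / 2) %*% wh
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)           # descending eigenvalues
  W_full <- t(wh %*% es$vectors)             # rows are generalized eigenvectors
  W_full <- W_full / sqrt(rowSums(W_full^2))
  n_top <- ceiling(n_filters / 2); n_bot <- n_filters - n_top
  sel <- integer(0)
  for (i in seq_len(max(n_top, n_bot))) {
    if (i <= n_top) sel <- c(sel, min(i, C))
    if (i <= n_bot) sel <- c(sel, max(C - i + 1L, 1L))
  }
  structure(list(filters = W_full[sel, , drop = FALSE],
                 lambda = es$values[sel],
                 eigenvalues = es$values,
                 selected = sel),
            class = "spatial_filter_bank")
}

#' @export
print.spatial_filter_bank <- function(x, ...) {
  cat(sprintf("<spatial_filter_bank> %d filters x %d channels, lambda in [%.3g, %.3g]\n",
              nrow(x$filters), ncol(x$filters),
              min(x$eigenvalues), max(x$eigenvalues)))
  invisible(x)
}

#' Variance-ratio objective of a spatial filter
#'
#' Diagnostic Rayleigh quotient `(w' G1' w) / (w' G2' w)` for a candidate
#' filter; the bank's eigenvalues are the extrema of this objective.
#'
#' @param cov An [ecsp_covariances()] object.
#' @param w Numeric filter vector.
#' @return A single number.
#' @export
ecsp_objective <- function(cov, w) {
  stopifnot(inherits(cov, "ecsp_covariances"))
  as.numeric((t(w) %*% cov$G1_shrunk %*% w) / (t(w) %*% cov$G2_shrunk %*% w))
}

#' Fit the full E-CSP chain on labelled trials
#'
#' Pools resting-state (label 0) trials for the activation statistics,
#' activates every trial, builds frequency-weighted shrunk class covariances
#' and derives the filter bank. The returned bank carries the activation
#' statistics and parameters so that [ecsp_features()] applies the identical
#' transform to new trials.
#'
#' @param trials List of raw channels x samples matrices (or
#'   [eeg_record()]s).
#' @param labels 0/1 labels per trial (taken from records when omitted).
#' @param params An [ecsp_params()].
#' @param fs Sampling rate (taken from records when omitted).
#' @return A `spatial_filter_bank` with elements `rest_mu`, `rest_sd`,
#'   `params`, `fs` added.
#' @export
ecsp_fit <- function(trials, labels = NULL, params = ecsp_params(), fs = NULL) {
  if (length(trials) && inherits(trials[[1]], "eeg_record")) {
    if (is.null(labels)) labels <- vapply(trials, function(r) r$label, 0L)
    if (is.null(fs)) fs <- trials[[1]]$fs
    trials <- lapply(trials, function(r) r$data)
  }
  labels <- as.integer(labels)
  rest <- do.call(cbind, trials[labels == 0L])
  mu <- mean(rest)
  sdr <- sqrt(mean((rest - mu)^2))
  if (sdr <= 0) stop_bad_arg("resting-state trials are constant")
  act <- lapply(trials, function(tr) {
    s <- ((tr - mu) / sdr); s <- s / (1 + abs(s)); s * stats::plogis(s)
  })
  cov <- ecsp_covariances(act, labels, params, fs = fs)
  bank <- ecsp_filters(cov, params$n_filters)
  bank$rest_mu <- mu; bank$rest_sd <- sdr
  bank$params <- params; bank$fs <- fs
  bank
}

#' Project a trial through the spatial filter bank
#'
#' Applies the bank's stored activation and frequency weighting (when fitted
#' via [ecsp_fit()]) and projects through each filter row;
#' `"mean_power"` returns the mean squared projected sample per filter,
#' `"literal_mean"` the arithmetic mean.
#'
#' @param trial Channels x samples matrix (activated already if the bank has
#'   no stored statistics).
#' @param bank A `spatial_filter_bank`.
#' @param mode Feature mode; defaults to the bank's fitted mode, else
#'   `"mean_power"`.
#' @return Numeric vector of length `nrow(bank$filters)`.
#' @export
ecsp_features <- function(trial, bank, mode = NULL) {
  stopifnot(inherits(bank, "spatial_filter_bank"))
  if (inherits(trial, "eeg_record")) trial <- trial$data
  if (ncol(bank$filters) != nrow(trial))
    stop_bad_arg("bank has %d channels but trial has %d",
                 ncol(bank$filters), nrow(trial))
  if (is.null(mode)) mode <- bank$params$feature_mode %||% "mean_power"
  if (!is.null(bank$rest_mu)) {
    s <- (trial - bank$rest_mu) / bank$rest_sd
    s <- s / (1 + abs(s))
    trial <- s * stats::plogis(s)
    if (!is.null(bank$params) && bank$params$weight_mode == "spectral")
      trial <- spectral_weight_trial(trial, bank$fs, bank$params$fc,
                                     bank$params$delta_f)
  }
  proj <- bank$filters %*% trial
  if (mode == "mean_power") rowMeans(proj^2) else rowMeans(proj)
}
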