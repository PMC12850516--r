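# Handcrafted EEG descriptors: Welch band powers over the canonical clinical
# bands, Hjorth/time-domain statistics, and spectral roll-off. Together with
# the E-CSP projections these form the fixed-layout EEG feature vector
# (5 spectral + 5 temporal per electrode, electrode-major, then the spatial
# block): 10*C + n_filters values, 252 for 22 channels and 32 filters.

#' Canonical EEG frequency bands
#'
#' Named `[low, high)` band edges in Hz: delta 0.5-4, theta 4-8, alpha 8-13,
#' beta 13-30, gamma 30-80 (the gamma edge is capped at Nyquist when powers
#' are computed). Edges must be ascending and non-overlapping.
#'
#' @param bands Named list of numeric `c(low, high)` pairs.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(bands = list(delta = c(0.5, 4), theta = c(4, 8),
                                   alpha = c(8, 13), beta = c(13, 30),
                                   gamma = c(30, 80))) {
  if (is.null(names(bands)) || any(!nzchar(names(bands))))
    stop_bad_arg("bands must be named")
  edges <- do.call(rbind, bands)
  if (any(edges[, 1] >= edges[, 2])) stop_bad_arg("each band needs low < high")
  if (any(diff(as.vector(t(edges))) < 0))
    stop_bad_arg("bands must be ascending and non-overlapping")
  if (edges[1, 1] <= 0) stop_bad_arg("band edges must be positive")
  structure(list(bands = bands), class = "band_spec")
}

#' Welch power spectral density
#'
#' One-sided Welch PSD with Hann-windowed segments (default 2 s, 50% overlap),
#' vectorized across channels. The density is scaled so that the PSD summed
#' over frequency times the bin width recovers the signal power (Parseval).
#'
#' @param x Numeric vector (one channel) or channels x samples matrix.
#' @param fs Sampling rate in Hz.
#' @param seg_s Segment length in seconds (default 2; capped at the signal
#'   length).
#' @param overlap Fractional segment overlap in [0, 1) (default 0.5).
#' @return A list with `freq` (Hz) and `psd` (channels x bins matrix).
#' @export
welch_psd <- function(x, fs, seg_s = 2, overlap = 0.5) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  check_number(fs, "fs", lower = 0, open_lower = TRUE)
  check_number(overlap, "overlap", lower = 0, upper = 1, open_upper = TRUE)
  n <- ncol(x)
  nseg <- min(n, max(8L, as.integer(round(seg_s * fs))))
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq.int(1L, n - nseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq.int(0L, nseg - 1L) / nseg))  # Hann
  u <- sum(w^2)
  nb <- nseg %/% 2L + 1L
  acc <- matrix(0, nrow(x), nb)
  for (s in starts) {
    seg <- x[, s:(s + nseg - 1L), drop = FALSE] * rep(w, each = nrow(x))
    ft <- mvfft(t(seg))
    p <- Mod(ft[seq_len(nb), , drop = FALSE])^2
    acc <- acc + t(p)
  }
  acc <- acc / (length(starts) * u * fs)
  if (nb > 2L) acc[, 2:(nb - 1L)] <- 2 * acc[, 2:(nb - 1L)]
  if (nseg %% 2L == 1L) acc[, nb] <- 2 * acc[, nb]
  list(freq = (seq_len(nb) - 1L) * fs / nseg, psd = acc)
}

#' Per-channel band powers
#'
#' Integrates the Welch PSD over each band of a [band_spec()]. A band lying
#' entirely at or above Nyquist is reported as zero and flagged in the
#' `"flagged_bands"` attribute.
#'
#' @param x An [eeg_record()] or channels x samples matrix.
#' @param bands A [band_spec()].
#' @param fs Sampling rate (taken from the record when `x` is one).
#' @param ... Passed to [welch_psd()].
#' @return Channels x bands matrix of nonnegative powers.
#' @export
band_powers <- function(x, bands = band_spec(), fs = NULL, ...) {
  if (inherits(x, "eeg_record")) { fs <- x$fs; x <- x$data }
  if (is.null(fs)) stop_bad_arg("`fs` is required for matrix input")
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  stopifnot(inherits(bands, "band_spec"))
  ps <- welch_psd(x, fs, ...)
  df <- ps$freq[2] - ps$freq[1]
  nyq <- fs / 2
  out <- matrix(0, nrow(x), length(bands$bands),
                dimnames = list(NULL, names(bands$bands)))
  flagged <- character()
  for (b in names(bands$bands)) {
    lo <- bands$bands[[b]][1]; hi <- min(bands$bands[[b]][2], nyq)
    if (lo >= nyq) { flagged <- c(flagged, b); next }
    sel <- ps$freq >= lo & ps$freq < hi
    out[, b] <- rowSums(ps$psd[, sel, drop = FALSE]) * df
  }
  attr(out, "flagged_bands") <- flagged
  out
}

#' Per-channel temporal descriptors
#'
#' Hjorth activity (variance), mobility (`sqrt(var(dx)/var(x))`), complexity
#' (mobility of the derivative over mobility of the signal), line length
#' (sum of absolute successive differences) and zero-crossing rate (sign
#' changes per second). Mobility and complexity are defined as 0 on constant
#' channels.
#'
#' @param x An [eeg_record()] or channels x samples matrix (>= 3 samples).
#' @param fs Sampling rate (from the record when `x` is one); used for the
#'   zero-crossing rate's time base.
#' @return Channels x 5 matrix with columns `hjorth_activity`,
#'   `hjorth_mobility`, `hjorth_complexity`, `line_length`,
#'   `zero_crossing_rate`.
#' @export
temporal_descriptors <- function(x, fs = NULL) {
  if (inherits(x, "eeg_record")) { fs <- x$fs; x <- x$data }
  if (is.null(fs)) stop_bad_arg("`fs` is required for matrix input")
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) < 3L) stop_bad_arg("need >= 3 samples per channel")
  dur <- ncol(x) / fs
  out <- t(apply(x, 1L, function(ch) {
    v0 <- stats::var(ch)
    d1 <- diff(ch); d2 <- diff(d1)
    v1 <- stats::var(d1); v2 <- stats::var(d2)
    mob <- if (v0 > 0) sqrt(v1 / v0) else 0
    mob_d <- if (v1 > 0) sqrt(v2 / v1) else 0
    cpx <- if (mob > 0) mob_d / mob else 0
    ll <- sum(abs(d1))
    s <- sign(ch); s <- s[s != 0]
    zc <- if (length(s) > 1L) sum(diff(s) != 0) else 0
    c(v0, mob, cpx, ll, zc / dur)
  }))
  colnames(out) <- c("hjorth_activity", "hjorth_mobility", "hjorth_complexity",
                     "line_length", "zero_crossing_rate")
  out
}

#' Spectral roll-off frequency
#'
#' The smallest frequency bin at which the cumulative Welch PSD reaches
#' `pct` of the total spectral power; 0 (flagged) for an all-zero channel.
#'
#' @param x Numeric vector, one channel.
#' @param fs Sampling rate in Hz.
#' @param pct Fraction of total power in (0, 1) (default 0.85).
#' @param ... Passed to [welch_psd()].
#' @return Roll-off frequency in Hz; attribute `"zero_signal"` is `TRUE` when
#'   the guard fired.
#' @export
spectral_rolloff <- function(x, fs, pct = 0.85, ...) {
  check_number(pct, "pct", lower = 0, upper = 1, open_lower = TRUE, open_upper = TRUE)
  ps <- welch_psd(as.numeric(x), fs, ...)
  tot <- sum(ps$psd)
  if (tot <= 0) return(structure(0, zero_signal = TRUE))
  cum <- cumsum(ps$psd[1L, ])
  structure(ps$freq[which(cum >= pct * tot)[1L]], zero_signal = FALSE)
}

#' Assemble the fixed-layout EEG feature vector
#'
#' Concatenates, in electrode-major order, the 5 band powers and the 5
#' temporal descriptors per channel, followed by the E-CSP block projected
#' through a fitted [spatial filter bank][ecsp_fit()]. With C channels and
#' `n_filters` spatial filters the vector has length `10 * C + n_filters`
#' (252 for the 22-channel, 32-filter default).
#'
#' @param x An [eeg_record()].
#' @param bank A `spatial_filter_bank` from [ecsp_fit()] (or `NULL` to omit
#'   the E-CSP block).
#' @param bands A [band_spec()].
#' @return Named numeric vector with attribute `"layout"` documenting block
#'   offsets.
#' @export
eeg_feature_vector <- function(x, bank = NULL, bands = band_spec()) {
  stopifnot(inherits(x, "eeg_record"))
  C <- nrow(x$data)
  bp <- band_powers(x, bands)
  td <- temporal_descriptors(x)
  ch <- sprintf("ch%02d", seq_len(C))
  spec_block <- as.vector(t(bp))
  names(spec_block) <- paste0("bp_", rep(colnames(bp), times = C), "_",
                              rep(ch, each = ncol(bp)))
  temp_block <- as.vector(t(td))
  names(temp_block) <- paste0(rep(colnames(td), times = C), "_",
                              rep(ch, each = ncol(td)))
  out <- c(spec_block, temp_block)
  layout <- list(spectral = c(1L, length(spec_block)),
                 temporal = c(length(spec_block) + 1L,
                              length(spec_block) + length(temp_block)))
  if (!is.null(bank)) {
    stopifnot(inherits(bank, "spatial_filter_bank"))
    s4 <- ecsp_features(x$data, bank)
    names(s4) <- sprintf("ecsp%02d", seq_along(s4))
    layout$ecsp <- c(length(out) + 1L, length(out) + length(s4))
    out <- c(out, s4)
  }
  attr(out, "layout") <- layout
  out
}
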