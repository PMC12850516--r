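# Synthetic data generators: balanced two-class EEG segments (1/f background
# vs. rhythmic seizure-like oscillation), smooth brain phantoms with optional
# lesion blobs, and clean/noisy pairs under Gaussian, impulse or mixed noise.
# Every generator is a pure function of its arguments including the seed.

#' Construct an EEG record
#'
#' A light container for one multichannel EEG segment: a channels x samples
#' matrix on the microvolt scale, its sampling rate, a binary label
#' (0 = healthy background, 1 = seizure) and an opaque subject identifier.
#'
#' @param data Numeric matrix, channels x samples; all values finite.
#' @param fs Sampling rate in Hz.
#' @param label 0 or 1.
#' @param subject_id Character scalar.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(data, fs, label, subject_id = "s01") {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop_bad_arg("EEG data must be finite")
  if (nrow(data) < 1L) stop_bad_arg("EEG record needs >= 1 channel")
  check_number(fs, "fs", lower = 1)
  if (!label %in% c(0L, 1L)) stop_bad_arg("label must be 0 or 1")
  structure(list(data = data, fs = fs, label = as.integer(label),
                 subject_id = as.character(subject_id)),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d ch x %d samples @ %g Hz, label %d, subject %s\n",
              nrow(x$data), ncol(x$data), x$fs, x$label, x$subject_id))
  invisible(x)
}

#' Construct a brain image
#'
#' A nonnegative 2-D (H x W) or 3-D (H x W x D) intensity grid with a binary
#' label and subject id; the unit intensity scale is [0, 1] for phantoms.
#'
#' @param data Nonnegative numeric matrix or 3-D array, each dim >= 8.
#' @param label 0 or 1.
#' @param subject_id Character scalar.
#' @return An object of class `brain_image`.
#' @export
brain_image <- function(data, label = 0L, subject_id = "s01") {
  if (!(is.matrix(data) || (is.array(data) && length(dim(data)) == 3L)))
    stop_bad_arg("brain image data must be a matrix or 3-D array")
  if (any(dim(data) < 8L)) stop_bad_arg("each image dim must be >= 8")
  if (!all(is.finite(data)) || any(data < 0))
    stop_bad_arg("brain image intensities must be finite and >= 0")
  if (!label %in% c(0L, 1L)) stop_bad_arg("label must be 0 or 1")
  structure(list(data = data, label = as.integer(label),
                 subject_id = as.character(subject_id)),
            class = "brain_image")
}

#' @export
print.brain_image <- function(x, ...) {
  cat(sprintf("<brain_image> %s, label %d, subject %s, range [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = " x "), x$label, x$subject_id,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Specify a noise model
#'
#' Describes synthetic corruption applied by [add_noise()]: additive Gaussian
#' noise, salt-and-pepper impulse noise at the data's extremes, or both.
#'
#' @param model One of `"gaussian"`, `"impulse"`, `"mixed"`.
#' @param gaussian_sd Standard deviation of the additive component (>= 0).
#' @param impulse_prob Per-entry probability of impulse corruption in [0, 1].
#' @param seed Integer seed controlling the realization.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(model = c("gaussian", "impulse", "mixed"),
                       gaussian_sd = 0, impulse_prob = 0, seed = 1L) {
  model <- match.arg(model)
  check_number(gaussian_sd, "gaussian_sd", lower = 0)
  check_number(impulse_prob, "impulse_prob", lower = 0, upper = 1)
  if (model == "mixed" && (gaussian_sd <= 0 || impulse_prob <= 0))
    stop_bad_arg("mixed noise requires gaussian_sd > 0 and impulse_prob > 0")
  structure(list(model = model, gaussian_sd = gaussian_sd,
                 impulse_prob = impulse_prob, seed = as.integer(seed)),
            class = "noise_spec")
}

# 1/f ("pink") noise via spectral shaping; unit RMS.
pink_noise <- function(n) {
  spec <- complex(real = rnorm(n), imaginary = rnorm(n))
  f <- c(1, seq_len(n - 1))
  shaped <- Re(fft(spec / sqrt(f), inverse = TRUE)) / n
  shaped / sd(shaped)
}

# One background channel: pink noise + low-amplitude 10 Hz alpha.
background_channel <- function(ns, fs, rms = 10) {
  t <- seq_len(ns) / fs
  x <- rms * pink_noise(ns) +
    0.6 * rms * sin(2 * pi * 10 * t + runif(1, 0, 2 * pi))
  x
}

#' Generate a balanced synthetic EEG dataset
#'
#' Produces `n_samples` EEG segments, half labelled 0 (background: pink-noise
#' floor plus low-amplitude 10 Hz alpha) and half labelled 1 (the same
#' background plus a rhythmic 3-7 Hz oscillation with a second harmonic and a
#' smooth onset envelope, active over at least half the segment at an
#' amplitude several times the background RMS). Records are partitioned into
#' `n_subjects` disjoint subjects, each holding both classes, so
#' subject-independent splits are well defined.
#'
#' @param n_samples Even total number of records (default 2500).
#' @param n_channels Number of channels (default 22; >= 2).
#' @param fs Sampling rate in Hz (default 256).
#' @param duration_s Segment duration in seconds (default 8).
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @param n_subjects Number of disjoint subjects (default 24).
#' @return A list of `n_samples` [eeg_record()] objects.
#' @export
generate_eeg_dataset <- function(n_samples = 2500, n_channels = 22, fs = 256,
                                 duration_s = 8, seed = 1L, n_subjects = 24) {
  n_samples <- check_count(n_samples, "n_samples", lower = 2L)
  if (n_samples %% 2L != 0L)
    stop_bad_arg("n_samples must be even so classes balance, got %d", n_samples)
  n_channels <- check_count(n_channels, "n_channels", lower = 2L)
  check_number(fs, "fs", lower = 1, open_lower = TRUE)
  check_number(duration_s, "duration_s", lower = 0, open_lower = TRUE)
  ns <- fs * duration_s
  if (abs(ns - round(ns)) > 1e-9)
    stop_bad_arg("fs * duration_s must be integral, got %g", ns)
  ns <- as.integer(round(ns))
  n_subjects <- check_count(n_subjects, "n_subjects", lower = 1L)
  if (n_samples / 2 < n_subjects)
    stop_bad_arg("need n_samples/2 >= n_subjects so every subject has both classes")

  with_seed(seed, {
    per_class <- n_samples %/% 2L
    subj <- sprintf("subj%02d", ((seq_len(per_class) - 1L) %% n_subjects) + 1L)
    records <- vector("list", n_samples)
    t <- seq_len(ns) / fs
    for (i in seq_len(per_class)) {
      bg0 <- vapply(seq_len(n_channels), function(ch) background_channel(ns, fs), numeric(ns))
      records[[i]] <- eeg_record(t(bg0), fs = fs, label = 0L, subject_id = subj[i])

      bg1 <- vapply(seq_len(n_channels), function(ch) background_channel(ns, fs), numeric(ns))
      bg_rms <- sqrt(mean(bg1^2))
      f0 <- runif(1, 3, 7)
      frac <- runif(1, 0.55, 0.9)                       # active fraction >= 50%
      onset <- runif(1, 0, duration_s * (1 - frac))
      env <- ictal_envelope(t, onset, onset + frac * duration_s)
      amp <- 3 * sqrt(2) * bg_rms * runif(1, 1.1, 1.6)  # RMS >= 3x background
      phase <- runif(n_channels, 0, 2 * pi)
      gain <- runif(n_channels, 0.7, 1.3)
      osc <- outer(t, rep(1, n_channels))
      for (ch in seq_len(n_channels))
        osc[, ch] <- gain[ch] * amp * env *
          (sin(2 * pi * f0 * t + phase[ch]) + 0.3 * sin(2 * pi * 2 * f0 * t + phase[ch]))
      records[[per_class + i]] <- eeg_record(t(bg1 + osc), fs = fs, label = 1L,
                                             subject_id = subj[i])
    }
    records
  })
}

# Raised-cosine (Tukey-style) on/off envelope over [t_on, t_off].
ictal_envelope <- function(t, t_on, t_off, ramp = 0.25) {
  env <- numeric(length(t))
  inside <- t >= t_on & t <= t_off
  env[inside] <- 1
  up <- t >= t_on & t < t_on + ramp
  env[up] <- 0.5 * (1 - cos(pi * (t[up] - t_on) / ramp))
  dn <- t > t_off - ramp & t <= t_off
  env[dn] <- 0.5 * (1 - cos(pi * (t_off - t[dn]) / ramp))
  env
}

#' Generate a synthetic brain phantom
#'
#' Builds a smooth ellipsoidal foreground ("brain") on a dark background with
#' intensities in [0, 1]. With `lesion = TRUE`, a localized Gaussian blob
#' raises the mean intensity inside a recorded mask (stored as the
#' `lesion_mask` element). This is a synthetic stand-in for functional brain
#' volumes, intended for filter and descriptor benchmarking only.
#'
#' @param shape Integer vector of length 2 (H, W) or 3 (H, W, D); dims >= 8.
#' @param lesion Logical; add a lesion-like blob.
#' @param seed Integer seed.
#' @param subject_id Subject identifier.
#' @return A [brain_image()] whose `lesion_mask` element is a logical array
#'   (all `FALSE` when `lesion = FALSE`) and `control_mask` a matched
#'   mirror-region mask.
#' @export
generate_brain_phantom <- function(shape = c(32, 32), lesion = FALSE, seed = 1L,
                                   subject_id = "s01") {
  if (!length(shape) %in% c(2L, 3L) || any(shape < 8))
    stop_bad_arg("shape must have 2 or 3 dims, each >= 8")
  shape <- as.integer(shape)
  with_seed(seed, {
    semi <- runif(length(shape), 0.65, 0.85)
    r2 <- Reduce(`+`, lapply(seq_along(shape), function(k) {
      g <- ((seq_len(shape[k]) - (shape[k] + 1) / 2) / (shape[k] / 2)) / semi[k]
      axis_field(shape, k, g^2)
    }))
    body <- 0.25 + 0.6 / (1 + exp((sqrt(r2) - 1) / 0.08))  # soft ellipsoid edge
    tex <- array(rnorm(prod(shape), 0, 0.02), dim = shape)
    img <- body + tex * (r2 < 1)
    mask <- array(FALSE, dim = shape)
    if (isTRUE(lesion)) {
      cen <- vapply(shape, function(n) runif(1, 0.3 * n, 0.45 * n), 0)
      rad <- max(2.5, 0.1 * min(shape))
      d2 <- Reduce(`+`, lapply(seq_along(shape), function(k) {
        g <- (seq_len(shape[k]) - cen[k]) / rad
        axis_field(shape, k, g^2)
      }))
      img <- img + 0.3 * exp(-d2 / 2)
      mask <- d2 <= 1
    }
    ctrl <- flip_dim1(mask)  # mirrored control region, same size and shape
    img <- clamp(img, 0, 1)
    out <- brain_image(img, label = as.integer(isTRUE(lesion)),
                       subject_id = subject_id)
    out$lesion_mask <- mask
    out$control_mask <- ctrl
    out
  })
}

#' Generate a balanced cohort of brain phantoms
#'
#' Produces `n_samples` phantoms, half with a lesion-like blob (label 1) and
#' half without, partitioned into `n_subjects` disjoint subjects (default 52,
#' matching a two-arm imaging cohort of 26 patients and 26 controls).
#'
#' @param n_samples Even number of phantoms.
#' @param shape Grid dims as in [generate_brain_phantom()].
#' @param seed Integer seed.
#' @param n_subjects Number of disjoint subjects (default 52).
#' @return A list of [brain_image()] objects.
#' @export
generate_phantom_dataset <- function(n_samples = 2500, shape = c(32, 32),
                                     seed = 1L, n_subjects = 52) {
  n_samples <- check_count(n_samples, "n_samples", lower = 2L)
  if (n_samples %% 2L != 0L)
    stop_bad_arg("n_samples must be even so classes balance, got %d", n_samples)
  n_subjects <- check_count(n_subjects, "n_subjects", lower = 2L)
  per_class <- n_samples %/% 2L
  # patients (lesion) and controls occupy disjoint subject halves
  n_pat <- n_subjects %/% 2L
  subj_pat <- sprintf("pat%02d", ((seq_len(per_class) - 1L) %% n_pat) + 1L)
  subj_ctl <- sprintf("ctl%02d", ((seq_len(per_class) - 1L) %% (n_subjects - n_pat)) + 1L)
  out <- vector("list", n_samples)
  for (i in seq_len(per_class)) {
    out[[i]] <- generate_brain_phantom(shape, lesion = FALSE,
                                       seed = derive_seed(seed, paste0("c", i)),
                                       subject_id = subj_ctl[i])
    out[[per_class + i]] <- generate_brain_phantom(shape, lesion = TRUE,
                                                   seed = derive_seed(seed, paste0("p", i)),
                                                   subject_id = subj_pat[i])
  }
  out
}

#' Corrupt a record or image with synthetic noise
#'
#' Returns the untouched input alongside a corrupted copy. Gaussian noise adds
#' i.i.d. normal deviates of sd `gaussian_sd`; impulse noise replaces a
#' fraction `impulse_prob` of entries with the clean data's minimum or maximum
#' (salt and pepper); mixed noise applies both.
#'
#' @param x An [eeg_record()] or [brain_image()] (or a bare numeric array).
#' @param spec A [noise_spec()].
#' @return A list with elements `clean` and `noisy` of the same class as `x`.
#' @export
add_noise <- function(x, spec) {
  if (!inherits(spec, "noise_spec")) stop_bad_arg("`spec` must be a noise_spec")
  dat <- if (inherits(x, c("eeg_record", "brain_image"))) x$data else x
  noisy <- with_seed(spec$seed, {
    out <- dat
    if (spec$model %in% c("gaussian", "mixed") && spec$gaussian_sd > 0)
      out <- out + array(rnorm(length(out), 0, spec$gaussian_sd), dim = dim(out) %||% length(out))
    if (spec$model %in% c("impulse", "mixed") && spec$impulse_prob > 0) {
      hit <- runif(length(out)) < spec$impulse_prob
      lohi <- runif(length(out)) < 0.5
      out[hit & lohi] <- min(dat)
      out[hit & !lohi] <- max(dat)
    }
    out
  })
  noisy_obj <- x
  if (inherits(x, "brain_image")) {
    noisy <- clamp(noisy, min(0, min(noisy)), max(noisy)) # keep >= 0 contract below
    noisy <- pmax(noisy, 0)
    noisy_obj$data <- noisy
  } else if (inherits(x, "eeg_record")) {
    noisy_obj$data <- noisy
  } else noisy_obj <- noisy
  list(clean = x, noisy = noisy_obj)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Array whose value at every element equals vals[index along dim k].
axis_field <- function(shape, k, vals) {
  array(vals[slice.index(array(0L, dim = shape), k)], dim = shape)
}

flip_dim1 <- function(a) {
  idx <- rep(list(quote(expr = )), length(dim(a)))
  idx[[1]] <- rev(seq_len(dim(a)[1]))
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

#' Export a 2-D phantom as a PNG image
#'
#' Optional convenience for eyeballing phantoms; requires the `png` package.
#'
#' @param img A [brain_image()] with 2-D data in [0, 1].
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
export_phantom_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop_bad_arg("the 'png' package is needed for PNG export")
  png::writePNG(clamp(img$data, 0, 1), path)
  invisible(path)
}
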