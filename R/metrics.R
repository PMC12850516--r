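# Reconstruction-quality metrics (PSNR, SSIM, SNR) and the nine-metric
# classification report computed from confusion counts.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in dB; identical inputs give `Inf`.
#'
#' @param reference,test Numeric arrays of identical shape.
#' @param peak Peak signal value (> 0; default 1 for unit-scale images).
#' @return PSNR in dB (`Inf` when MSE is 0).
#' @export
psnr <- function(reference, test, peak = 1) {
  if (!identical(dim(reference) %||% length(reference),
                 dim(test) %||% length(test)))
    stop_bad_arg("reference and test shapes differ")
  check_number(peak, "peak", lower = 0, open_lower = TRUE)
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Structural similarity index
#'
#' Mean SSIM over the image with a 7x7 Gaussian window (sd 1.5) and the
#' standard stabilization constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`
#' where `L` is the dynamic range.
#'
#' @param reference,test Numeric matrices of identical shape.
#' @param L Dynamic range (default 1).
#' @return SSIM in [-1, 1]; 1 for identical images.
#' @export
ssim <- function(reference, test, L = 1) {
  reference <- as_image_matrix(reference); test <- as_image_matrix(test)
  if (!identical(dim(reference), dim(test)))
    stop_bad_arg("reference and test shapes differ")
  if (any(dim(reference) < 7L))
    stop_bad_arg("image smaller than the 7x7 SSIM window")
  g <- gaussian_kernel_1d(3L, 1.5)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  mu1 <- conv_sep_2d(reference, g); mu2 <- conv_sep_2d(test, g)
  s11 <- conv_sep_2d(reference^2, g) - mu1^2
  s22 <- conv_sep_2d(test^2, g) - mu2^2
  s12 <- conv_sep_2d(reference * test, g) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' Signal-to-noise ratio of a processed signal
#'
#' `10 * log10(power(clean) / power(processed - clean))` in dB; a perfect
#' reconstruction gives `Inf`.
#'
#' @param clean,processed Numeric vectors/arrays of identical shape.
#' @return SNR in dB.
#' @export
snr_db <- function(clean, processed) {
  if (length(clean) != length(processed))
    stop_bad_arg("clean and processed shapes differ")
  p_res <- mean((processed - clean)^2)
  if (p_res == 0) return(Inf)
  10 * log10(mean(clean^2) / p_res)
}

#' Classification report from confusion counts
#'
#' Accuracy, precision, sensitivity, specificity, FNR, FPR, F1, MCC and NPV
#' from the four confusion-matrix counts; the positive class is seizure
#' (label 1). Metrics with an undefined denominator are reported as 0 with a
#' warning.
#'
#' @param tp,tn,fp,fn Nonnegative counts.
#' @return An object of class `metrics_report`: a list of the nine metrics
#'   plus the counts.
#' @export
metrics_from_counts <- function(tp, tn, fp, fn) {
  for (v in c(tp, tn, fp, fn)) check_number(v, "count", lower = 0)
  total <- tp + tn + fp + fn
  if (total == 0) stop_bad_arg("empty confusion matrix")
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reported as 0", what),
              call. = FALSE)
      return(0)
    }
    num / den
  }
  sens <- safe(tp, tp + fn, "sensitivity")
  spec <- safe(tn, tn + fp, "specificity")
  prec <- safe(tp, tp + fp, "precision")
  npv <- safe(tn, tn + fn, "NPV")
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den > 0) clamp((tp * tn - fp * fn) / mcc_den, -1, 1) else {
    warning("MCC undefined (zero denominator); reported as 0", call. = FALSE)
    0
  }
  structure(list(accuracy = (tp + tn) / total, precision = prec,
                 sensitivity = sens, specificity = spec,
                 FNR = 1 - sens, FPR = 1 - spec, F1 = f1, MCC = mcc,
                 NPV = npv, TP = tp, TN = tn, FP = fp, FN = fn),
            class = "metrics_report")
}

#' Classification report from labels or probabilities
#'
#' Accepts predicted labels, a probability vector for the seizure class, or a
#' samples x 2 probability matrix (thresholded at 0.5, ties to class 0), and
#' reduces to [metrics_from_counts()].
#'
#' @param y_true True 0/1 labels.
#' @param y_pred Predicted labels, seizure-class probabilities, or a 2-column
#'   probability matrix.
#' @return An object of class `metrics_report`.
#' @export
classification_metrics <- function(y_true, y_pred) {
  y_true <- as.integer(y_true)
  if (is.matrix(y_pred)) y_pred <- y_pred[, 2L]
  if (length(y_true) != length(y_pred))
    stop_bad_arg("y_true and y_pred lengths differ (%d vs %d)",
                 length(y_true), length(y_pred))
  lab <- if (all(y_pred %in% c(0, 1))) as.integer(y_pred)
         else as.integer(y_pred > 0.5)
  metrics_from_counts(tp = sum(lab == 1L & y_true == 1L),
                      tn = sum(lab == 0L & y_true == 0L),
                      fp = sum(lab == 1L & y_true == 0L),
                      fn = sum(lab == 0L & y_true == 1L))
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat("Classification report (positive class = seizure)\n")
  cat(sprintf("  counts: TP=%d TN=%d FP=%d FN=%d\n", x$TP, x$TN, x$FP, x$FN))
  for (m in c("accuracy", "precision", "sensitivity", "specificity",
              "FNR", "FPR", "F1", "MCC", "NPV"))
    cat(sprintf("  %-12s %.*f\n", m, digits, x[[m]]))
  invisible(x)
}

#' Coerce a metrics report to a one-row data frame
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return A one-row data frame of the nine metrics.
#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(accuracy = x$accuracy, precision = x$precision,
             sensitivity = x$sensitivity, specificity = x$specificity,
             FNR = x$FNR, FPR = x$FPR, F1 = x$F1, MCC = x$MCC, NPV = x$NPV)
}
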