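# Internal helpers shared across modules: reflect padding, windowed box
# statistics via integral images, seeded evaluation, argument checks.

stop_bad_arg <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_bad_arg("`%s` must be a single finite number, got %s", name,
                 paste(format(x), collapse = ", "))
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_bad_arg("`%s` = %g is outside the %s%g, %g%s range", name, x,
                 if (open_lower) "(" else "[", lower, upper,
                 if (open_upper) ")" else "]")
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < lower)
    stop_bad_arg("`%s` must be an integer >= %d, got %s", name, lower,
                 paste(format(x), collapse = ", "))
  as.integer(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so generators are pure in their seed.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a child seed from a base seed and a stream label, keeping the result
# inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) * 48271 + sum(utf8ToInt(as.character(stream)) *
         seq_along(utf8ToInt(as.character(stream))) * 7919)) %% 2147483629
  as.integer(s) + 1L
}

# Whole-sample reflection indices for positions 1-n extended by `pad` on both
# sides (boundary sample not duplicated): ..., x3, x2, | x1, x2, ..., xn |,
# x(n-1), x(n-2), ...
reflect_index <- function(n, pad) {
  if (n == 1L) return(rep(1L, n + 2L * pad))
  idx <- seq.int(1L - pad, n + pad)
  period <- 2L * (n - 1L)
  idx <- (idx - 1L) %% period
  idx <- ifelse(idx >= n, period - idx, idx)
  idx + 1L
}

pad_reflect_1d <- function(x, pad) x[reflect_index(length(x), pad)]

pad_reflect_2d <- function(img, pad_r, pad_c = pad_r) {
  img[reflect_index(nrow(img), pad_r), reflect_index(ncol(img), pad_c), drop = FALSE]
}

# Sliding-window sums of a matrix over w x w windows (reflect padding) via an
# integral image; returns a matrix of the original size.
box_sum_2d <- function(img, w) {
  h <- (w - 1L) %/% 2L
  p <- pad_reflect_2d(img, h)
  S <- apply(apply(p, 2L, cumsum), 1L, cumsum) # t(cumsum rows of colcumsum)
  S <- t(S)
  S <- rbind(0, cbind(0, S))
  n <- nrow(img); m <- ncol(img)
  r1 <- seq_len(n); r2 <- r1 + w - 1L
  c1 <- seq_len(m); c2 <- c1 + w - 1L
  S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
}

# Row-wise medians of a matrix (small windows; used by 2-D median filtering).
row_medians <- function(m) {
  k <- ncol(m)
  s <- t(apply(m, 1L, sort.int, method = "quick"))
  if (k %% 2L == 1L) s[, (k + 1L) %/% 2L] else
    0.5 * (s[, k %/% 2L] + s[, k %/% 2L + 1L])
}

is_odd_window <- function(w) is.numeric(w) && length(w) == 1L && w >= 3 && w %% 2 == 1

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
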