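# Independent brute-force oracles used across the filter tests. These are
# deliberately naive (double loops, explicit padding) and share no code with
# the package internals they check.

# Whole-sample reflect index (scalar version).
refl <- function(i, n) {
  if (n == 1) return(1)
  period <- 2 * (n - 1)
  j <- (i - 1) %% period
  if (j >= n) j <- period - j
  j + 1
}

oracle_median_1d <- function(x, N) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    win <- vapply(-N:N, function(k) x[refl(t + k, n)], 0)
    out[t] <- median(win)
  }
  out
}

oracle_gmf <- function(x, params) {
  n <- length(x)
  N <- params$N
  v <- numeric(n)
  for (t in seq_len(n)) {
    win <- vapply(-N:N, function(k) x[refl(t + k, n)], 0)
    v[t] <- mean(win^2) - mean(win)^2
  }
  sig <- pmax(if (params$sigma_mode == "variance") params$phi * v
              else params$phi * sqrt(v), params$sigma_min)
  sm <- numeric(n)
  for (t in seq_len(n)) {
    w <- exp(-(-N:N)^2 / (2 * sig[t]^2))
    win <- vapply(-N:N, function(k) x[refl(t + k, n)], 0)
    sm[t] <- sum(w * win) / sum(w)
  }
  oracle_median_1d(sm, N)
}

oracle_local_stats <- function(img, w) {
  h <- (w - 1) / 2
  n <- nrow(img); m <- ncol(img)
  M <- matrix(0, n, m); V <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    vals <- c()
    for (di in -h:h) for (dj in -h:h)
      vals <- c(vals, img[refl(i + di, n), refl(j + dj, m)])
    M[i, j] <- mean(vals)
    V[i, j] <- mean(vals^2) - mean(vals)^2
  }
  list(mean = M, var = pmax(V, 0))
}

oracle_median_2d <- function(img, w) {
  h <- (w - 1) / 2
  n <- nrow(img); m <- ncol(img)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    vals <- c()
    for (di in -h:h) for (dj in -h:h)
      vals <- c(vals, img[refl(i + di, n), refl(j + dj, m)])
    out[i, j] <- median(vals)
  }
  out
}

oracle_awwf <- function(img, params, v2, beta = NULL) {
  st <- oracle_local_stats(img, params$window)
  med <- oracle_median_2d(img, params$window)
  n <- nrow(img); m <- ncol(img)
  # Sobel via explicit loops
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)       # column direction
  ky <- t(kx)
  alpha <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    bx <- 0; by <- 0
    for (di in -1:1) for (dj in -1:1) {
      px <- img[refl(i + di, n), refl(j + dj, m)]
      bx <- bx + kx[di + 2, dj + 2] * px
      by <- by + ky[di + 2, dj + 2] * px
    }
    alpha[i, j] <- sqrt(bx^2 + by^2)
  }
  if (is.null(beta))
    beta <- pmin(pmax(v2 / (st$var + params$lam * alpha + params$eps), 0), 1)
  gain <- ifelse(st$var > 0, pmin(pmax((st$var - v2) / st$var, 0), 1), 0)
  wie <- st$mean + gain * (img - st$mean)
  beta * med + (1 - beta) * wie
}

# Single-segment Hann periodogram band power (independent of welch_psd).
oracle_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
  X <- fft(x * w)
  nb <- n %/% 2 + 1
  p <- Mod(X[1:nb])^2 / (sum(w^2) * fs)
  p[2:(nb - 1)] <- 2 * p[2:(nb - 1)]
  f <- (0:(nb - 1)) * fs / n
  sum(p[f >= lo & f < hi]) * fs / n
}

# Deterministic label shuffle that leaves the global RNG untouched.
with_seed_shuffle <- function(y, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample(y)
}

make_two_class_trials <- function(n_per_class, C = 4, T = 128, seed = 1,
                                  boost = 3) {
  set.seed(seed)
  trials <- list(); labels <- integer(0)
  for (i in seq_len(n_per_class)) {
    trials[[length(trials) + 1L]] <- matrix(rnorm(C * T), C, T)
    labels <- c(labels, 0L)
  }
  for (i in seq_len(n_per_class)) {
    tr <- matrix(rnorm(C * T), C, T)
    tr[1, ] <- tr[1, ] * boost      # class-specific variance on channel 1
    trials[[length(trials) + 1L]] <- tr
    labels <- c(labels, 1L)
  }
  list(trials = trials, labels = labels)
}
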