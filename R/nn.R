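# Forward-pass building blocks of the classifier stack: the piecewise chaotic
# map used to draw activation scaling factors, the StGE composite activation,
# mixed max/average pooling, attention-based normalization, the updated batch
# normalization (UBN) that gates standardized activations, the SPCII
# height/width attention block, and the ghost module that synthesizes part of
# its output channels with cheap depthwise transforms.

#' Piecewise chaotic map sequence
#'
#' Iterates `x <- x/q` when `x < q`, else `(1 - x)/(1 - q)`; all iterates lie
#' in [0, 1]. Used to draw the StGE scaling factors at initialization.
#'
#' @param x0 Start value in (0, 1).
#' @param q Breakpoint in (0, 1); `x = q` takes the upper branch.
#' @param n Number of iterates to return.
#' @return Numeric vector of `n` iterates (excluding `x0`).
#' @export
chaotic_map_sequence <- function(x0, q, n) {
  check_number(x0, "x0", lower = 0, upper = 1, open_lower = TRUE, open_upper = TRUE)
  check_number(q, "q", lower = 0, upper = 1, open_lower = TRUE, open_upper = TRUE)
  n <- check_count(n, "n", lower = 1L)
  out <- numeric(n)
  x <- x0
  for (i in seq_len(n)) {
    x <- if (x < q) x / q else (1 - x) / (1 - q)
    out[i] <- x
  }
  out
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

#' StGE composite activation
#'
#' `x * tanh(softplus(x))` for `x >= 0` (the mish-like branch) and
#' `varpi * ELU(x) + vartheta * GELU(x)` for `x < 0`; both branches vanish at
#' 0, so the function is continuous there and finite for all finite inputs.
#'
#' @param x Numeric vector/array.
#' @param varpi,vartheta Scaling factors in (0, 1) for the negative branch
#'   (typically consecutive chaotic-map iterates).
#' @return Activated values, same shape as `x`.
#' @export
stge_activation <- function(x, varpi = 0.6, vartheta = 0.8) {
  check_number(varpi, "varpi", lower = 0, upper = 1, open_lower = TRUE, open_upper = TRUE)
  check_number(vartheta, "vartheta", lower = 0, upper = 1, open_lower = TRUE, open_upper = TRUE)
  out <- x
  pos <- x >= 0
  xp <- x[pos]; xn <- x[!pos]
  out[pos] <- xp * tanh(log1p(exp(-abs(xp))) + pmax(xp, 0))
  out[!pos] <- varpi * expm1(xn) + vartheta * xn * stats::pnorm(xn)
  out
}

#' Mixed max/average pooling
#'
#' `chi * max(s) + (1 - chi) * mean(s)` over a nonempty pooling region.
#'
#' @param s Numeric vector of region values.
#' @param chi Mixing weight in [0, 1]; 1 = pure max, 0 = pure average.
#' @return A single number.
#' @export
mixed_pool <- function(s, chi = 0.5) {
  if (!length(s)) stop_bad_arg("pooling region must be nonempty")
  check_number(chi, "chi", lower = 0, upper = 1)
  chi * max(s) + (1 - chi) * mean(s)
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Attention-based normalization
#'
#' Standardizes a channel vector and scales it by one plus a softmax
#' attention over the channels: `((x - mu)/sigma) * (1 + softmax(w1*x + b))`.
#' A constant input (sigma = 0) maps to zeros.
#'
#' @param x Numeric vector (one channel axis).
#' @param w1,b Scalar (or per-channel) attention weight and bias.
#' @return Numeric vector, same length.
#' @export
attention_norm <- function(x, w1 = 0, b = 0) {
  mu <- mean(x)
  sg <- sqrt(mean((x - mu)^2))
  if (sg <= 0) return(rep(0, length(x)))
  ((x - mu) / sg) * (1 + softmax(w1 * x + b))
}

# Row-wise attention normalization (vectorized form of attention_norm
# applied to every row of a samples x channels matrix).
attention_norm_rows <- function(m, w1 = 0, b = 0) {
  rm <- rowMeans(m)
  rs <- sqrt(pmax(rowMeans(m^2) - rm^2, 0))
  z <- (m - rm)
  nz <- rs > 0
  z[nz, ] <- z[nz, , drop = FALSE] / rs[nz]
  z[!nz, ] <- 0
  a <- w1 * m + b
  a <- exp(a - apply(a, 1L, max))
  a <- a / rowSums(a)
  z * (1 + a)
}

#' StGEN parameters for UBN
#'
#' Bundles the StGE scaling factors (drawn as consecutive iterates of the
#' chaotic map, nudged into the open unit interval), the pooling mix `chi`
#' and the map parameters.
#'
#' @param chi Pooling mix in [0, 1].
#' @param q,x0 Chaotic-map parameters in (0, 1).
#' @return An object of class `stgen_params` with elements `varpi`,
#'   `vartheta`, `chi`, `q`, `x0`.
#' @export
stgen_params <- function(chi = 0.5, q = 0.7, x0 = 0.3) {
  check_number(chi, "chi", lower = 0, upper = 1)
  it <- chaotic_map_sequence(x0, q, 2L)
  it <- clamp(it, 0.01, 0.99)   # keep strictly inside (0, 1)
  structure(list(varpi = it[1], vartheta = it[2], chi = chi, q = q, x0 = x0),
            class = "stgen_params")
}

#' UBN state
#'
#' @param eps Positive variance guard (default 1e-5).
#' @param scale,shift Affine parameters applied after gating (defaults 1, 0).
#' @param stgen An [stgen_params()] object.
#' @param w1,b Attention-normalization weight and bias.
#' @param force_q Optional fixed gate; `force_q = 1` reduces UBN to standard
#'   batch normalization.
#' @return An object of class `ubn_state`.
#' @export
ubn_state <- function(eps = 1e-5, scale = 1, shift = 0,
                      stgen = stgen_params(), w1 = 0, b = 0, force_q = NULL) {
  check_number(eps, "eps", lower = 0, open_lower = TRUE)
  structure(list(eps = eps, scale = scale, shift = shift, stgen = stgen,
                 w1 = w1, b = b, force_q = force_q),
            class = "ubn_state")
}

#' Updated batch normalization forward pass
#'
#' Standardizes each channel with batch statistics, then multiplies by the
#' gate `Q`: elementwise `f''(xhat) = StGE(xhat) * attention_norm(xhat)`
#' scaled by a per-channel mixed-pool (max/mean blend) of `f''` over the
#' batch. With `force_q = 1` and identity affine parameters, the layer is
#' exactly standard batch normalization.
#'
#' @param x Batch matrix (samples x channels) or array (samples x channels x
#'   positions); needs >= 2 samples.
#' @param state A [ubn_state()].
#' @return Normalized batch, same shape; per-channel batch `mean` and `var`
#'   attached as attributes.
#' @export
ubn_forward <- function(x, state = ubn_state()) {
  stopifnot(inherits(state, "ubn_state"))
  dm <- dim(x) %||% c(length(x), 1L)
  if (length(dm) == 1L) dim(x) <- dm <- c(dm, 1L)
  if (dm[1] < 2L) stop_bad_arg("UBN in training mode needs a batch of >= 2")
  nch <- dm[2]
  xm <- if (length(dm) == 3L) matrix(aperm(x, c(1, 3, 2)), ncol = nch) else x
  mu <- colMeans(xm)
  v <- colMeans(xm^2) - mu^2
  v <- pmax(v, 0)
  xhat <- sweep(sweep(xm, 2L, mu), 2L, sqrt(v + state$eps), "/")
  if (!is.null(state$force_q)) {
    Q <- state$force_q
    out <- xhat * Q
  } else {
    f <- stge_activation(xhat, state$stgen$varpi, state$stgen$vartheta)
    fp <- attention_norm_rows(xhat, state$w1, state$b)
    fpp <- f * fp
    chi <- state$stgen$chi
    gate <- chi * apply(fpp, 2L, max) + (1 - chi) * colMeans(fpp)
    out <- xhat * sweep(fpp, 2L, gate, "*")
  }
  out <- sweep(sweep(out, 2L, state$scale, "*"), 2L, state$shift, "+")
  if (length(dm) == 3L)
    out <- aperm(array(out, dim = c(dm[1], dm[3], dm[2])), c(1, 3, 2))
  else dim(out) <- dm
  attr(out, "mean") <- mu
  attr(out, "var") <- v
  out
}

# ---- convolution helpers (reflect padding; channel-last layouts) ----------

# x: L x Cin sequence, kern: (k*Cin) x Cout (offset-major rows).
conv1d_chan <- function(x, kern, k) {
  L <- nrow(x); cin <- ncol(x)
  h <- (k - 1L) %/% 2L
  p <- x[reflect_index(L, h), , drop = FALSE]
  cols <- matrix(0, L, k * cin)
  for (d in 0:(k - 1L))
    cols[, d * cin + seq_len(cin)] <- p[(1L + d):(L + d), , drop = FALSE]
  cols %*% kern
}

# x: H x W x Cin, kern: (k^2*Cin) x Cout (offset-major rows).
conv2d_chan <- function(x, kern, k) {
  dm <- dim(x)
  h <- (k - 1L) %/% 2L
  p <- x[reflect_index(dm[1], h), reflect_index(dm[2], h), , drop = FALSE]
  npos <- dm[1] * dm[2]
  cols <- matrix(0, npos, k^2 * dm[3])
  j <- 0L
  for (dc in 0:(k - 1L)) for (dr in 0:(k - 1L)) {
    cols[, j * dm[3] + seq_len(dm[3])] <-
      matrix(p[(1L + dr):(dm[1] + dr), (1L + dc):(dm[2] + dc), , drop = FALSE],
             npos, dm[3])
    j <- j + 1L
  }
  array(cols %*% kern, dim = c(dm[1:2], ncol(kern)))
}

# Depthwise 2-D convolution: kern is k x k x C.
dwconv2d <- function(x, kern) {
  dm <- dim(x); k <- dim(kern)[1]
  h <- (k - 1L) %/% 2L
  p <- x[reflect_index(dm[1], h), reflect_index(dm[2], h), , drop = FALSE]
  out <- array(0, dim = dm)
  for (dr in 0:(k - 1L)) for (dc in 0:(k - 1L)) {
    blk <- p[(1L + dr):(dm[1] + dr), (1L + dc):(dm[2] + dc), , drop = FALSE]
    w <- kern[dr + 1L, dc + 1L, ]
    out <- out + sweep(blk, 3L, w, "*")
  }
  out
}

# Depthwise 1-D convolution: x L x C, kern k x C.
dwconv1d <- function(x, kern) {
  L <- nrow(x); k <- nrow(kern)
  h <- (k - 1L) %/% 2L
  p <- x[reflect_index(L, h), , drop = FALSE]
  out <- matrix(0, L, ncol(x))
  for (d in 0:(k - 1L))
    out <- out + p[(1L + d):(L + d), , drop = FALSE] *
      rep(kern[d + 1L, ], each = L)
  out
}

maxpool1d <- function(x, f = 2L) {
  L <- (nrow(x) %/% f) * f
  if (L < f) return(x)
  a <- x[seq.int(1L, L, by = f), , drop = FALSE]
  for (d in 1:(f - 1L)) a <- pmax(a, x[seq.int(1L + d, L, by = f), , drop = FALSE])
  a
}

maxpool2d <- function(x, f = 2L) {
  dm <- dim(x)
  oh <- max(dm[1] %/% f, 1L); ow <- max(dm[2] %/% f, 1L)
  out <- array(-Inf, dim = c(oh, ow, dm[3]))
  for (dr in 0:(f - 1L)) for (dc in 0:(f - 1L)) {
    out <- pmax(out, x[seq.int(1L + dr, by = f, length.out = oh),
                       seq.int(1L + dc, by = f, length.out = ow), , drop = FALSE])
  }
  out
}

# Per-map standardization followed by ReLU (the "norm + rectifier" step).
instnorm_relu <- function(x) {
  dm <- dim(x)
  m <- matrix(x, prod(dm[1:2]), dm[3])
  mu <- colMeans(m)
  sg <- sqrt(pmax(colMeans(m^2) - mu^2, 0))
  m <- sweep(m, 2L, mu)
  nz <- sg > 0
  m[, nz] <- sweep(m[, nz, drop = FALSE], 2L, sg[nz], "/")
  array(pmax(m, 0), dim = dm)
}

# Fast aggregations over one axis of a 3-d array (dropping that axis).
agg3 <- function(x, drop_dim, fun = c("mean", "max")) {
  fun <- match.arg(fun)
  dm <- dim(x)
  perm <- c(setdiff(1:3, drop_dim), drop_dim)
  xp <- aperm(x, perm)
  m <- matrix(xp, prod(dm[perm[1:2]]), dm[drop_dim])
  v <- if (fun == "mean") rowMeans(m) else do.call(pmax, asplit(m, 2L))
  matrix(v, dm[perm[1]], dm[perm[2]])
}

spcii_weights <- function(C, seed, mid = NULL) {
  if (is.null(mid)) mid <- max(4L, C %/% 4L)
  with_seed(derive_seed(seed, "spcii"), {
    list(mid = mid,
         conv_h = matrix(rnorm(9 * 2 * mid, 0, 1 / sqrt(18)), 9 * 2, mid),
         conv_w = matrix(rnorm(9 * 2 * mid, 0, 1 / sqrt(18)), 9 * 2, mid),
         acci_h = rnorm(3, 0, 1 / sqrt(3)),
         acci_w = rnorm(3, 0, 1 / sqrt(3)))
  })
}

acci_conv1d <- function(v, w) {
  n <- length(v)
  p <- v[reflect_index(n, 1L)]
  w[1] * p[1:n] + w[2] * p[2:(n + 1L)] + w[3] * p[3:(n + 2L)]
}

#' SPCII spatial attention over height and width
#'
#' Two parallel branches each aggregate the feature map (average and max
#' pooling across the opposite spatial axis), pass the stacked aggregations
#' through a small 2-D convolution with normalization and a rectifier,
#' aggregate again across channels, add the two contexts, refine with a 1-D
#' cross-channel (ACCI) convolution and squash through a sigmoid, producing
#' attention profiles `p_H` over height and `p_W` over width in (0, 1). The
#' input is re-weighted elementwise by both profiles.
#'
#' @param x Feature map array `C x H x W` with `H, W >= 2`.
#' @param seed Integer seed fixing the block's weights (ignored when
#'   `weights` is supplied).
#' @param weights Optional precomputed weights from an earlier call.
#' @return Re-weighted array of the same shape; attention profiles attached
#'   as attributes `"p_H"` and `"p_W"`.
#' @export
spcii_attention <- function(x, seed = 1L, weights = NULL) {
  dm <- dim(x)
  if (length(dm) != 3L) stop_bad_arg("`x` must be C x H x W")
  C <- dm[1]; H <- dm[2]; W <- dm[3]
  if (H < 2L || W < 2L) stop_bad_arg("spatial dims must be >= 2")
  if (is.null(weights)) weights <- spcii_weights(C, seed)

  branch <- function(ap, mp, conv, acci) {
    # ap, mp: C x A maps; stack as 2-channel (C x A) image
    stacked <- array(0, dim = c(nrow(ap), ncol(ap), 2L))
    stacked[, , 1] <- ap; stacked[, , 2] <- mp
    feat <- conv2d_chan(stacked, conv, 3L)          # C x A x mid
    feat <- instnorm_relu(feat)
    agg <- agg3(feat, 1L, "mean") + agg3(feat, 1L, "max")  # A x mid
    ctx <- rowMeans(agg)                            # length A
    stats::plogis(acci_conv1d(ctx, acci))
  }

  p_H <- branch(agg3(x, 3L, "mean"), agg3(x, 3L, "max"),
                weights$conv_h, weights$acci_h)
  p_W <- branch(agg3(x, 2L, "mean"), agg3(x, 2L, "max"),
                weights$conv_w, weights$acci_w)
  out <- x * rep(p_H, each = C) *
    rep(p_W, each = C * H)
  attr(out, "p_H") <- p_H
  attr(out, "p_W") <- p_W
  attr(out, "weights") <- weights
  out
}

#' Ghost module configuration
#'
#' @param ratio Integer ghost ratio `s >= 2`: a fraction `1/s` of the output
#'   channels are produced by a dense ("primary") convolution, the rest by
#'   cheap depthwise transforms of those intrinsic maps.
#' @param kernel Primary kernel side (default 3).
#' @param cheap_kernel Depthwise cheap-op kernel side (default 3).
#' @return An object of class `ghost_config`.
#' @export
ghost_config <- function(ratio = 2L, kernel = 3L, cheap_kernel = 3L) {
  ratio <- check_count(ratio, "ratio", lower = 2L)
  structure(list(ratio = ratio, kernel = as.integer(kernel),
                 cheap_kernel = as.integer(cheap_kernel)),
            class = "ghost_config")
}

ghost_weights <- function(cin, out_channels, config, seed,
                          identity_cheap = FALSE) {
  m <- out_channels %/% config$ratio
  with_seed(derive_seed(seed, "ghost"), {
    k <- config$kernel; ck <- config$cheap_kernel
    primary <- matrix(rnorm(k^2 * cin * m, 0, 1 / sqrt(k^2 * cin)),
                      k^2 * cin, m)
    cheap <- array(rnorm(ck^2 * m * (config$ratio - 1L), 0, 1 / sqrt(ck^2)),
                   dim = c(ck, ck, m * (config$ratio - 1L)))
    if (identity_cheap) {
      cheap[] <- 0
      cheap[(ck + 1L) %/% 2L, (ck + 1L) %/% 2L, ] <- 1
    }
    list(primary = primary, cheap = cheap, m = m)
  })
}

#' Ghost module forward pass
#'
#' A dense convolution produces `out_channels / ratio` intrinsic maps; cheap
#' depthwise convolutions of those maps synthesize the remaining "ghost"
#' channels, and the two groups are concatenated. Parameter count is strictly
#' below that of a dense convolution with the same in/out shape.
#'
#' @param x Feature map `H x W x Cin`.
#' @param out_channels Output channel count, divisible by `ratio`.
#' @param config A [ghost_config()].
#' @param seed Integer seed for the weights (ignored when `weights` given).
#' @param weights Optional precomputed weights.
#' @param identity_cheap If `TRUE`, cheap ops are identity (delta) kernels so
#'   ghost channels duplicate the intrinsic maps.
#' @return Array `H x W x out_channels`; weights attached as an attribute.
#' @export
ghost_module <- function(x, out_channels, config = ghost_config(), seed = 1L,
                         weights = NULL, identity_cheap = FALSE) {
  stopifnot(inherits(config, "ghost_config"))
  out_channels <- check_count(out_channels, "out_channels", lower = config$ratio)
  if (out_channels %% config$ratio != 0L)
    stop_bad_arg("out_channels = %d not divisible by ratio = %d",
                 out_channels, config$ratio)
  dm <- dim(x)
  if (is.null(weights))
    weights <- ghost_weights(dm[3], out_channels, config, seed,
                             identity_cheap = identity_cheap)
  intrinsic <- conv2d_chan(x, weights$primary, config$kernel)
  ghosts <- vector("list", config$ratio - 1L)
  for (g in seq_len(config$ratio - 1L)) {
    kern <- weights$cheap[, , (g - 1L) * weights$m + seq_len(weights$m),
                          drop = FALSE]
    ghosts[[g]] <- dwconv2d(intrinsic, kern)
  }
  out <- array(0, dim = c(dm[1:2], out_channels))
  out[, , seq_len(weights$m)] <- intrinsic
  for (g in seq_len(config$ratio - 1L))
    out[, , weights$m * g + seq_len(weights$m)] <- ghosts[[g]]
  attr(out, "weights") <- weights
  out
}

#' Parameter counts for ghost vs. dense convolutions
#'
#' Closed-form weight counts (biases excluded) for a ghost module and for the
#' dense convolution with identical in/out channels and kernel.
#'
#' @param cin,cout Channel counts.
#' @param config A [ghost_config()].
#' @return Named list with `ghost` and `dense` counts.
#' @export
ghost_param_count <- function(cin, cout, config = ghost_config()) {
  m <- cout %/% config$ratio
  list(ghost = config$kernel^2 * cin * m +
         config$cheap_kernel^2 * m * (config$ratio - 1L),
       dense = config$kernel^2 * cin * cout)
}
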