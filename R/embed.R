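# Compact seed-deterministic volumetric embedder: a two-stage 3-D
# convolutional encoder (3x3x3 kernels, 32 then 64 channels, max pooling)
# with fixed random weights, followed by two random linear projections — a
# globally pooled 256-dim "activation" block and a 128-dim block pooled over
# a fixed lateral region mask (a stand-in for regional connectivity
# descriptors; no anatomical claim is made). Output is 256 + 128 = 384 values,
# deterministic in (image, seed).

#' Embedder configuration
#'
#' @param kernel Cubic kernel side per axis (default 3).
#' @param widths Channel widths of the two convolution stages (default
#'   `c(32, 64)`).
#' @param out_dims Output block sizes (default `c(256, 128)`).
#' @param seed Integer seed fixing all weights.
#' @return An object of class `embedder_config`.
#' @export
embedder_config <- function(kernel = 3L, widths = c(32L, 64L),
                            out_dims = c(256L, 128L), seed = 1L) {
  kernel <- check_count(kernel, "kernel", lower = 1L)
  if (kernel %% 2L == 0L) stop_bad_arg("`kernel` must be odd")
  if (length(widths) != 2L || any(widths < 1))
    stop_bad_arg("`widths` must be two positive counts")
  if (length(out_dims) != 2L || any(out_dims < 1))
    stop_bad_arg("`out_dims` must be two positive counts")
  structure(list(kernel = as.integer(kernel), widths = as.integer(widths),
                 out_dims = as.integer(out_dims), seed = as.integer(seed)),
            class = "embedder_config")
}

# Reflect-padded 3-D convolution: x is H x W x D x C_in, kern is
# (k^3 * C_in) x C_out with rows ordered offset-major then channel.
conv3d_reflect <- function(x, kern, k) {
  dm <- dim(x)
  h <- (k - 1L) %/% 2L
  p <- x[reflect_index(dm[1], h), reflect_index(dm[2], h),
         reflect_index(dm[3], h), , drop = FALSE]
  npos <- prod(dm[1:3])
  cin <- dm[4]
  cols <- matrix(0, npos, k^3 * cin)
  j <- 0L
  for (dd in 0:(k - 1L)) for (dc in 0:(k - 1L)) for (dr in 0:(k - 1L)) {
    blk <- p[(1L + dr):(dm[1] + dr), (1L + dc):(dm[2] + dc),
             (1L + dd):(dm[3] + dd), , drop = FALSE]
    cols[, j * cin + seq_len(cin)] <- matrix(blk, npos, cin)
    j <- j + 1L
  }
  out <- cols %*% kern
  array(out, dim = c(dm[1:3], ncol(kern)))
}

# 3-D max pooling by factor 2 per axis (depth pooled only when >= 2 deep);
# trailing odd slices are dropped.
maxpool3d <- function(x) {
  dm <- dim(x)
  f <- c(2L, 2L, if (dm[3] >= 2L) 2L else 1L)
  od <- pmax(dm[1:3] %/% f, 1L)
  out <- array(-Inf, dim = c(od, dm[4]))
  for (dr in 0:(f[1] - 1L)) for (dc in 0:(f[2] - 1L)) for (dd in 0:(f[3] - 1L)) {
    sub <- x[seq.int(1L + dr, by = f[1], length.out = od[1]),
             seq.int(1L + dc, by = f[2], length.out = od[2]),
             seq.int(1L + dd, by = f[3], length.out = od[3]), , drop = FALSE]
    out <- pmax(out, sub)
  }
  out
}

# Per-channel mean / max / sd over a logical position mask.
pooled_stats <- function(x, mask = NULL) {
  dm <- dim(x)
  m <- matrix(x, prod(dm[1:3]), dm[4])
  if (!is.null(mask)) m <- m[as.vector(mask), , drop = FALSE]
  c(colMeans(m), apply(m, 2L, max), apply(m, 2L, stats::sd))
}

embed_weights <- function(config, cin1 = 1L) {
  with_seed(derive_seed(config$seed, "deep_embed"), {
    k3 <- config$kernel^3
    w1 <- matrix(rnorm(k3 * cin1 * config$widths[1], 0, 1 / sqrt(k3 * cin1)),
                 k3 * cin1, config$widths[1])
    w2 <- matrix(rnorm(k3 * config$widths[1] * config$widths[2], 0,
                       1 / sqrt(k3 * config$widths[1])),
                 k3 * config$widths[1], config$widths[2])
    nstat <- 3L * config$widths[2]
    p_global <- matrix(rnorm(nstat * config$out_dims[1], 0, 1 / sqrt(nstat)),
                       nstat, config$out_dims[1])
    p_region <- matrix(rnorm(nstat * config$out_dims[2], 0, 1 / sqrt(nstat)),
                       nstat, config$out_dims[2])
    list(w1 = w1, w2 = w2, p_global = p_global, p_region = p_region)
  })
}

#' Seed-deterministic deep embedding of a brain volume
#'
#' Runs the image (2-D inputs are lifted to single-slice volumes) through the
#' fixed random convolutional encoder and returns the concatenation of the
#' globally pooled projection (first block) and the lateral-region pooled
#' projection (second block) — 384 values under the default configuration.
#' Identical `(image, seed)` pairs give identical vectors.
#'
#' @param img A [brain_image()], matrix, or 3-D array.
#' @param config An [embedder_config()].
#' @return Numeric vector of length `sum(config$out_dims)`.
#' @export
deep_embed <- function(img, config = embedder_config()) {
  if (inherits(img, "brain_image")) img <- img$data
  if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1L))
  if (!(is.array(img) && length(dim(img)) == 3L))
    stop_bad_arg("`img` must be a 2-D or 3-D numeric array")
  if (any(dim(img)[1:2] < 8L)) stop_bad_arg("image height/width must be >= 8")
  w <- embed_weights(config)
  x <- array(img, dim = c(dim(img), 1L))
  a1 <- maxpool3d(tanh_act(conv3d_reflect(x, w$w1, config$kernel)))
  a2 <- maxpool3d(tanh_act(conv3d_reflect(a1, w$w2, config$kernel)))
  dm <- dim(a2)
  # fixed lateral mask: outer thirds of the width axis (both hemispheres)
  wcut <- max(1L, dm[2] %/% 3L)
  mask <- array(FALSE, dim = dm[1:3])
  mask[, c(seq_len(wcut), seq.int(dm[2] - wcut + 1L, dm[2])), ] <- TRUE
  g <- pooled_stats(a2)
  r <- pooled_stats(a2, mask)
  out <- c(as.vector(g %*% w$p_global), as.vector(r %*% w$p_region))
  names(out) <- c(sprintf("act%03d", seq_len(config$out_dims[1])),
                  sprintf("conn%03d", seq_len(config$out_dims[2])))
  out
}

tanh_act <- function(x) tanh(x)
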