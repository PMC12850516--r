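# Classifier architectures. Both networks share a design: a seed-fixed
# convolutional trunk implementing the stated layer layout (depthwise
# convolution stages with UBN and tanh, max pooling, SPCII attention or ghost
# bottlenecks) and a trainable fully connected head (128-64-2 with dropout)
# fitted by seiz_train(). Freezing the trunk at its seeded initialization
# keeps the whole stack deterministic and CPU-scale while every forward
# contract holds exactly.

#' IAPCNet configuration
#'
#' Dual-branch convolutional network: a 1-D branch for the EEG feature
#' sequence and a 2-D branch for the image-feature map, each with two
#' DwConv-UBN-tanh-maxpool stages (widths 32 and 64, kernel 3) and an SPCII
#' attention block, fused by concatenated pooled summaries into a 128-64-2
#' fully connected head with dropout 0.3.
#'
#' @param eeg_dim Length of the EEG feature vector (default 252).
#' @param fmri_dim Length of the image feature vector (default 384).
#' @param fmri_shape 2-D map shape the image features are reshaped to
#'   (default `c(16, 24)`; must multiply to `fmri_dim`).
#' @param widths Stage widths (default `c(32, 64)`).
#' @param kernel Convolution kernel size (default 3).
#' @param fc Fully connected widths (default `c(128, 64)`), head output 2.
#' @param dropout Dropout rate after the first FC layer (default 0.3).
#' @return An object of class `iapcnet_config`.
#' @export
iapcnet_config <- function(eeg_dim = 252L, fmri_dim = 384L,
                           fmri_shape = c(16L, 24L), widths = c(32L, 64L),
                           kernel = 3L, fc = c(128L, 64L), dropout = 0.3) {
  if (prod(fmri_shape) != fmri_dim)
    stop_bad_arg("fmri_shape %s does not multiply to fmri_dim %d",
                 paste(fmri_shape, collapse = "x"), fmri_dim)
  structure(list(eeg_dim = as.integer(eeg_dim), fmri_dim = as.integer(fmri_dim),
                 fmri_shape = as.integer(fmri_shape),
                 widths = as.integer(widths), kernel = as.integer(kernel),
                 fc = as.integer(fc), dropout = dropout),
            class = "iapcnet_config")
}

#' GhostNet classifier configuration
#'
#' A stem convolution followed by ghost bottleneck stages (width multiplier
#' 0.5 relative to the IAPCNet widths) on the combined feature vector
#' reshaped to a 2-D map, with the same trainable FC head.
#'
#' @param in_dim Combined feature length (default 252 + 384 = 636).
#' @param map_shape 2-D map shape after zero-padding `in_dim` up to its
#'   product (default `c(20, 32)`).
#' @param stage_widths Ghost stage output widths (default `c(16, 32, 64)`).
#' @param ghost A [ghost_config()].
#' @param fc FC widths (default `c(128, 64)`).
#' @param dropout Dropout rate (default 0.3).
#' @return An object of class `ghostnet_config`.
#' @export
ghostnet_config <- function(in_dim = 636L, map_shape = c(20L, 32L),
                            stage_widths = c(16L, 32L, 64L),
                            ghost = ghost_config(), fc = c(128L, 64L),
                            dropout = 0.3) {
  if (prod(map_shape) < in_dim)
    stop_bad_arg("map_shape %s too small for in_dim %d",
                 paste(map_shape, collapse = "x"), in_dim)
  structure(list(in_dim = as.integer(in_dim), map_shape = as.integer(map_shape),
                 stage_widths = as.integer(stage_widths), ghost = ghost,
                 fc = as.integer(fc), dropout = dropout),
            class = "ghostnet_config")
}

# Depthwise-separable weights for one 1-D stage: depthwise k x Cin plus
# pointwise Cin x Cout.
dwsep1d_weights <- function(cin, cout, k, seed, tag) {
  with_seed(derive_seed(seed, tag), {
    list(dw = matrix(rnorm(k * cin, 0, 1 / sqrt(k)), k, cin),
         pw = matrix(rnorm(cin * cout, 0, 1 / sqrt(cin)), cin, cout))
  })
}

dwsep2d_weights <- function(cin, cout, k, seed, tag) {
  with_seed(derive_seed(seed, tag), {
    list(dw = array(rnorm(k * k * cin, 0, 1 / sqrt(k^2)), dim = c(k, k, cin)),
         pw = matrix(rnorm(cin * cout, 0, 1 / sqrt(cin)), cin, cout))
  })
}

#' Build an IAPCNet model
#'
#' Instantiates all trunk weights (both branches, UBN states, SPCII blocks)
#' deterministically from `seed`; the FC head is untrained until
#' [seiz_train()] is called.
#'
#' @param config An [iapcnet_config()].
#' @param seed Integer seed.
#' @return An object of class `c("iapcnet", "seiz_classifier")`.
#' @export
build_iapcnet <- function(config = iapcnet_config(), seed = 1L) {
  stopifnot(inherits(config, "iapcnet_config"))
  k <- config$kernel; w <- config$widths
  model <- list(
    type = "iapcnet", config = config, seed = as.integer(seed),
    b1_s1 = dwsep1d_weights(1L, w[1], k, seed, "b1s1"),
    b1_s2 = dwsep1d_weights(w[1], w[2], k, seed, "b1s2"),
    b2_s1 = dwsep2d_weights(1L, w[1], k, seed, "b2s1"),
    b2_s2 = dwsep2d_weights(w[1], w[2], k, seed, "b2s2"),
    ubn = ubn_state(stgen = stgen_params()),
    spcii1 = NULL, spcii2 = NULL,  # lazily built (need map dims)
    head = NULL)
  class(model) <- c("iapcnet", "seiz_classifier")
  model
}

#' Build a GhostNet classifier
#'
#' @param config A [ghostnet_config()].
#' @param seed Integer seed.
#' @return An object of class `c("ghostnet", "seiz_classifier")`.
#' @export
build_ghostnet <- function(config = ghostnet_config(), seed = 1L) {
  stopifnot(inherits(config, "ghostnet_config"))
  model <- list(type = "ghostnet", config = config, seed = as.integer(seed),
                stage_weights = NULL, head = NULL)
  class(model) <- c("ghostnet", "seiz_classifier")
  model
}

#' Build a plain multilayer-perceptron classifier
#'
#' A trainable FC head applied directly to the input features — the simplest
#' member of the classifier family, useful as a baseline and for training
#' diagnostics.
#'
#' @param in_dim Input feature length.
#' @param fc FC widths (default `c(128, 64)`).
#' @param dropout Dropout rate (default 0.3).
#' @param seed Integer seed.
#' @return An object of class `c("mlp", "seiz_classifier")`.
#' @export
build_mlp <- function(in_dim, fc = c(128L, 64L), dropout = 0.3, seed = 1L) {
  model <- list(type = "mlp",
                config = list(in_dim = as.integer(in_dim),
                              fc = as.integer(fc), dropout = dropout),
                seed = as.integer(seed), head = NULL)
  class(model) <- c("mlp", "seiz_classifier")
  model
}

# Pooled per-channel summary (mean, max, sd) of an H x W x C map.
map_summary <- function(x) {
  dm <- dim(x)
  m <- matrix(x, prod(dm[1:2]), dm[3])
  mu <- colMeans(m)
  c(mu, apply(m, 2L, max), sqrt(pmax(colMeans(m^2) - mu^2, 0)))
}

seq_summary <- function(x) {  # L x C
  mu <- colMeans(x)
  c(mu, apply(x, 2L, max), sqrt(pmax(colMeans(x^2) - mu^2, 0)))
}

# Reshape a length-L vector map (C x H x W) for SPCII and back.
apply_spcii_seq <- function(x, seed, tag) {      # x: L x C -> same
  L <- nrow(x); C <- ncol(x)
  hw <- closest_factor_pair(L)
  m <- aperm(array(t(x), dim = c(C, hw[1], hw[2])), c(1, 2, 3))
  out <- spcii_attention(m, seed = derive_seed(seed, tag))
  t(matrix(out, C, L))
}

closest_factor_pair <- function(L) {
  f <- floor(sqrt(L))
  while (L %% f != 0L) f <- f - 1L
  c(f, L %/% f)
}

# UBN over a batch-of-maps representation: values (positions*batch) x C.
ubn_batchmaps <- function(mats, state) {
  nb <- length(mats)
  stacked <- do.call(rbind, mats)
  out <- ubn_forward(stacked, state)
  rows <- nrow(mats[[1]])
  lapply(seq_len(nb), function(i) out[(i - 1L) * rows + seq_len(rows), , drop = FALSE])
}

#' Trunk representation of a classifier
#'
#' Runs the frozen convolutional trunk over all samples and returns the
#' representation matrix the FC head consumes. UBN batch statistics are taken
#' over the supplied record set.
#'
#' @param model A `seiz_classifier`.
#' @param eeg Samples x eeg_dim matrix (IAPCNet) or `NULL`.
#' @param fmri Samples x fmri_dim matrix (IAPCNet) or `NULL`.
#' @param x Samples x in_dim matrix (GhostNet / MLP).
#' @return Samples x d representation matrix.
#' @export
seiz_represent <- function(model, eeg = NULL, fmri = NULL, x = NULL) {
  UseMethod("seiz_represent")
}

#' @export
seiz_represent.mlp <- function(model, eeg = NULL, fmri = NULL, x = NULL) {
  if (is.null(x)) x <- cbind(eeg, fmri)
  if (ncol(x) != model$config$in_dim)
    stop_bad_arg("expected %d input features, got %d", model$config$in_dim, ncol(x))
  x
}

#' @export
seiz_represent.iapcnet <- function(model, eeg = NULL, fmri = NULL, x = NULL) {
  cfg <- model$config
  if (is.null(eeg) || is.null(fmri))
    stop_bad_arg("iapcnet needs both `eeg` and `fmri` feature matrices")
  if (ncol(eeg) != cfg$eeg_dim)
    stop_bad_arg("expected %d EEG features, got %d", cfg$eeg_dim, ncol(eeg))
  if (ncol(fmri) != cfg$fmri_dim)
    stop_bad_arg("expected %d image features, got %d", cfg$fmri_dim, ncol(fmri))
  n <- nrow(eeg)
  k <- cfg$kernel
  # ---- 1-D branch ----
  s1 <- lapply(seq_len(n), function(i) {
    z <- matrix(eeg[i, ], ncol = 1L)
    dwconv1d(z, model$b1_s1$dw[, 1L, drop = FALSE]) %*% model$b1_s1$pw
  })
  s1 <- ubn_batchmaps(s1, model$ubn)
  s1 <- lapply(s1, function(m) maxpool1d(tanh(m)))
  s2 <- lapply(s1, function(m) dwconv1d(m, model$b1_s2$dw) %*% model$b1_s2$pw)
  s2 <- ubn_batchmaps(s2, model$ubn)
  s2 <- lapply(s2, function(m) maxpool1d(tanh(m)))
  rep1 <- t(vapply(s2, function(m)
    seq_summary(apply_spcii_seq(m, model$seed, "spcii1")),
    numeric(3L * cfg$widths[2])))
  # ---- 2-D branch ----
  t1 <- lapply(seq_len(n), function(i) {
    z <- array(fmri[i, ], dim = c(cfg$fmri_shape, 1L))
    m <- dwconv2d(z, array(model$b2_s1$dw, dim = c(k, k, 1L)))
    dm <- dim(m)
    array(matrix(m, prod(dm[1:2]), 1L) %*% model$b2_s1$pw, dim = c(dm[1:2], cfg$widths[1]))
  })
  t1m <- ubn_batchmaps(lapply(t1, function(a) matrix(a, prod(dim(a)[1:2]), dim(a)[3])),
                       model$ubn)
  t1 <- lapply(seq_len(n), function(i)
    maxpool2d(array(tanh(t1m[[i]]), dim = dim(t1[[i]]))))
  t2 <- lapply(t1, function(a) {
    m <- dwconv2d(a, model$b2_s2$dw)
    dm <- dim(m)
    array(matrix(m, prod(dm[1:2]), dm[3]) %*% model$b2_s2$pw, dim = c(dm[1:2], cfg$widths[2]))
  })
  t2m <- ubn_batchmaps(lapply(t2, function(a) matrix(a, prod(dim(a)[1:2]), dim(a)[3])),
                       model$ubn)
  t2 <- lapply(seq_len(n), function(i)
    maxpool2d(array(tanh(t2m[[i]]), dim = dim(t2[[i]]))))
  rep2 <- t(vapply(t2, function(a) {
    dm <- dim(a)
    cmap <- aperm(a, c(3, 1, 2))  # C x H x W for SPCII
    att <- spcii_attention(cmap, seed = derive_seed(model$seed, "spcii2"))
    map_summary(aperm(att, c(2, 3, 1)))
  }, numeric(3L * cfg$widths[2])))
  cbind(rep1, rep2)
}

#' @export
seiz_represent.ghostnet <- function(model, eeg = NULL, fmri = NULL, x = NULL) {
  cfg <- model$config
  if (is.null(x)) x <- cbind(eeg, fmri)
  if (ncol(x) != cfg$in_dim)
    stop_bad_arg("expected %d input features, got %d", cfg$in_dim, ncol(x))
  n <- nrow(x)
  pad <- prod(cfg$map_shape) - cfg$in_dim
  stem_w <- with_seed(derive_seed(model$seed, "stem"),
                      matrix(rnorm(9 * cfg$stage_widths[1], 0, 1 / 3),
                             9, cfg$stage_widths[1]))
  reps <- t(vapply(seq_len(n), function(i) {
    a <- array(c(x[i, ], rep(0, pad)), dim = c(cfg$map_shape, 1L))
    a <- tanh(conv2d_chan(a, stem_w, 3L))
    cin <- cfg$stage_widths[1]
    for (s in seq_along(cfg$stage_widths)[-1]) {
      a <- ghost_module(a, cfg$stage_widths[s], cfg$ghost,
                        seed = derive_seed(model$seed, paste0("ghost", s)))
      a <- maxpool2d(tanh(a))
    }
    map_summary(a)
  }, numeric(3L * cfg$stage_widths[length(cfg$stage_widths)])))
  reps
}

#' Class probabilities from a trained classifier
#'
#' @param object A trained `seiz_classifier` (after [seiz_train()]).
#' @param eeg,fmri,x Feature matrices as in [seiz_represent()].
#' @param representation Optional precomputed trunk representation (rows =
#'   samples to score), bypassing `eeg`/`fmri`/`x`.
#' @param ... Unused.
#' @return Samples x 2 matrix of class probabilities (columns `healthy`,
#'   `seizure`), each row summing to 1.
#' @export
predict.seiz_classifier <- function(object, eeg = NULL, fmri = NULL, x = NULL,
                                    representation = NULL, ...) {
  if (is.null(object$head))
    stop_bad_arg("model head is untrained; call seiz_train() first")
  rep <- representation %||%
    seiz_represent(object, eeg = eeg, fmri = fmri, x = x)
  mlp_predict(object$head, rep)
}

#' @export
print.seiz_classifier <- function(x, ...) {
  cat(sprintf("<%s> %s head, seed %d\n", x$type,
              if (is.null(x$head)) "untrained" else "trained", x$seed))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs (best val loss %.4f)\n",
                nrow(x$history), min(x$history$val_loss)))
  invisible(x)
}
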