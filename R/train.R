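# Head training and ensemble fusion. The FC head (128-64-2 by default, ReLU,
# dropout after the first layer, softmax output) is trained with Adam on
# binary cross-entropy, monitoring validation loss with early stopping and
# best-weight restoration. Splits are always subject-disjoint.

#' Training configuration
#'
#' @param lr Learning rate (default 0.001).
#' @param batch_size Mini-batch size (default 32; image-stream models often
#'   use 16).
#' @param epochs Maximum epochs (default 100).
#' @param patience Early-stopping patience in epochs on validation loss
#'   (default 10).
#' @param fractions Subject-level train/validation/test fractions
#'   (default `c(0.7, 0.15, 0.15)`).
#' @param seed Integer seed governing split, initialization, shuffling and
#'   dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 0.001, batch_size = 32L, epochs = 100L,
                         patience = 10L, fractions = c(0.7, 0.15, 0.15),
                         seed = 1L) {
  check_number(lr, "lr", lower = 0, open_lower = TRUE)
  batch_size <- check_count(batch_size, "batch_size", lower = 1L)
  epochs <- check_count(epochs, "epochs", lower = 1L)
  patience <- check_count(patience, "patience", lower = 1L)
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop_bad_arg("fractions must be three positive numbers summing to 1")
  structure(list(lr = lr, batch_size = batch_size, epochs = epochs,
                 patience = patience, fractions = fractions,
                 seed = as.integer(seed)),
            class = "train_config")
}

# ---- minimal dense network with Adam ---------------------------------------

mlp_init <- function(d_in, fc, seed) {
  with_seed(derive_seed(seed, "head"), {
    dims <- c(d_in, fc, 2L)
    W <- list(); bv <- list()
    for (i in seq_len(length(dims) - 1L)) {
      W[[i]] <- matrix(rnorm(dims[i] * dims[i + 1L], 0, sqrt(2 / dims[i])),
                       dims[i], dims[i + 1L])
      bv[[i]] <- rep(0, dims[i + 1L])
    }
    list(W = W, b = bv)
  })
}

mlp_forward <- function(par, X, dropout = 0, drop_masks = NULL) {
  L <- length(par$W)
  acts <- vector("list", L + 1L)
  acts[[1]] <- X
  for (i in seq_len(L)) {
    z <- acts[[i]] %*% par$W[[i]]
    z <- sweep(z, 2L, par$b[[i]], "+")
    if (i < L) {
      z <- pmax(z, 0)
      if (i == 1L && dropout > 0) {
        if (is.null(drop_masks)) z <- z * (1 - dropout)  # inference scaling
        else z <- z * drop_masks
      }
    }
    acts[[i + 1L]] <- z
  }
  zs <- acts[[L + 1L]]
  zs <- zs - apply(zs, 1L, max)
  P <- exp(zs); P <- P / rowSums(P)
  list(acts = acts, probs = P)
}

mlp_backward <- function(par, fwd, y01, dropout = 0, drop_masks = NULL) {
  L <- length(par$W)
  n <- length(y01)
  Y <- cbind(1 - y01, y01)
  delta <- (fwd$probs - Y) / n
  gW <- vector("list", L); gb <- vector("list", L)
  for (i in L:1) {
    gW[[i]] <- crossprod(fwd$acts[[i]], delta)
    gb[[i]] <- colSums(delta)
    if (i > 1L) {
      delta <- delta %*% t(par$W[[i]])
      delta <- delta * (fwd$acts[[i]] > 0)
      if (i - 1L == 1L && dropout > 0 && !is.null(drop_masks))
        delta <- delta * drop_masks
    }
  }
  list(W = gW, b = gb)
}

bce_loss <- function(P, y01) {
  p <- pmin(pmax(P[, 2L], 1e-12), 1 - 1e-12)
  -mean(y01 * log(p) + (1 - y01) * log(1 - p))
}

# Adam on the full parameter list.
mlp_fit <- function(X, y, Xval, yval, fc, dropout, config) {
  scal <- list(mu = colMeans(X),
               sd = pmax(apply(X, 2L, stats::sd), 1e-8))
  std <- function(M) sweep(sweep(M, 2L, scal$mu), 2L, scal$sd, "/")
  X <- std(X); Xval <- std(Xval)
  par <- mlp_init(ncol(X), fc, config$seed)
  m <- lapply(c(par$W, par$b), function(w) w * 0)
  v <- m
  b1 <- 0.9; b2 <- 0.999; epsa <- 1e-8; t <- 0
  best <- list(loss = Inf, par = par, epoch = 0L)
  hist <- data.frame()
  n <- nrow(X)
  with_seed(derive_seed(config$seed, "sgd"), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (s in seq.int(1L, n, by = config$batch_size)) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        if (length(idx) < 2L) next
        masks <- if (dropout > 0)
          matrix(stats::rbinom(length(idx) * fc[1], 1L, 1 - dropout) / (1 - dropout),
                 length(idx), fc[1]) else NULL
        fwd <- mlp_forward(par, X[idx, , drop = FALSE], dropout, masks)
        gr <- mlp_backward(par, fwd, y[idx], dropout, masks)
        gl <- c(gr$W, gr$b)
        pl <- c(par$W, par$b)
        t <- t + 1
        for (j in seq_along(pl)) {
          m[[j]] <- b1 * m[[j]] + (1 - b1) * gl[[j]]
          v[[j]] <- b2 * v[[j]] + (1 - b2) * gl[[j]]^2
          mh <- m[[j]] / (1 - b1^t); vh <- v[[j]] / (1 - b2^t)
          pl[[j]] <- pl[[j]] - config$lr * mh / (sqrt(vh) + epsa)
        }
        nw <- length(par$W)
        par$W <- pl[seq_len(nw)]; par$b <- pl[nw + seq_len(nw)]
      }
      ptr <- mlp_forward(par, X)$probs
      pva <- mlp_forward(par, Xval)$probs
      hist <- rbind(hist, data.frame(
        epoch = ep,
        train_loss = bce_loss(ptr, y), train_acc = mean((ptr[, 2] > 0.5) == y),
        val_loss = bce_loss(pva, yval), val_acc = mean((pva[, 2] > 0.5) == yval)))
      if (hist$val_loss[ep] < best$loss - 1e-6) {
        best <- list(loss = hist$val_loss[ep], par = par, epoch = ep)
      } else if (ep - best$epoch >= config$patience) break
    }
  })
  list(par = best$par, scal = scal, fc = fc, dropout = dropout,
       history = hist, best_epoch = best$epoch)
}

mlp_predict <- function(head, X) {
  X <- sweep(sweep(X, 2L, head$scal$mu), 2L, head$scal$sd, "/")
  P <- mlp_forward(head$par, X, head$dropout, drop_masks = NULL)$probs
  colnames(P) <- c("healthy", "seizure")
  P
}

# Subject-disjoint train/val/test assignment honouring fractions at subject
# granularity, stratified so each partition holds both classes.
subject_split <- function(subjects, labels, fractions, seed) {
  subj <- unique(subjects)
  if (length(subj) < 3L)
    stop_bad_arg("need >= 3 subjects for a three-way subject-disjoint split")
  subj_lab <- vapply(subj, function(s) round(mean(labels[subjects == s])), 0)
  with_seed(derive_seed(seed, "split"), {
    assign <- character(length(subj)); names(assign) <- subj
    for (g in unique(subj_lab)) {
      grp <- sample(subj[subj_lab == g])
      k <- length(grp)
      if (k == 1L) { assign[grp] <- "train"; next }
      if (k == 2L) { assign[grp] <- c("train", "val"); next }
      n_tr <- max(1L, round(fractions[1] * k))
      n_va <- max(1L, round(fractions[2] * k))
      if (n_tr + n_va >= k) { n_tr <- max(1L, k - 2L); n_va <- 1L }
      assign[grp] <- rep(c("train", "val", "test"),
                         c(n_tr, n_va, k - n_tr - n_va))
    }
    assign
  })
}

#' Train a classifier head on labelled features
#'
#' Computes the frozen-trunk representation, splits samples subject-wise into
#' train/validation/test partitions, and fits the FC head with Adam on binary
#' cross-entropy, early-stopping on validation loss and restoring the best
#' weights. The fitted model carries the epoch history and the split for
#' later evaluation. Identical seeds give identical trajectories.
#'
#' @param model An untrained `seiz_classifier` from [build_iapcnet()],
#'   [build_ghostnet()] or [build_mlp()].
#' @param dataset List with `labels` (0/1), `subjects` (ids per sample) and
#'   feature matrices: `eeg` and/or `fmri` (IAPCNet uses both; GhostNet and
#'   MLP use their column-bound combination unless `x` is given).
#' @param config A [train_config()].
#' @param split Optional precomputed assignment (named "train"/"val"/"test"
#'   character vector per sample) overriding the internal subject split.
#' @param representation Optional precomputed [seiz_represent()] matrix for
#'   the dataset (avoids recomputing the trunk and keeps its batch statistics
#'   shared with later predictions).
#' @return The fitted model with elements `head`, `history`, `split`.
#' @export
seiz_train <- function(model, dataset, config = train_config(), split = NULL,
                       representation = NULL) {
  stopifnot(inherits(model, "seiz_classifier"), inherits(config, "train_config"))
  y <- as.integer(dataset$labels)
  subjects <- as.character(dataset$subjects)
  rep_all <- representation %||%
    seiz_represent(model, eeg = dataset$eeg, fmri = dataset$fmri, x = dataset$x)
  if (is.null(split)) {
    assign <- subject_split(subjects, y, config$fractions, config$seed)
    split <- assign[subjects]
  }
  itr <- split == "train"; iva <- split == "val"
  if (length(unique(y[iva])) < 2L)
    stop_bad_arg("validation set lacks a class; use more subjects or a different seed")
  fc <- if (!is.null(model$config$fc)) model$config$fc else c(128L, 64L)
  dropout <- model$config$dropout %||% 0.3
  fit <- mlp_fit(rep_all[itr, , drop = FALSE], y[itr],
                 rep_all[iva, , drop = FALSE], y[iva],
                 fc = fc, dropout = dropout, config = config)
  model$head <- fit[c("par", "scal", "fc", "dropout")]
  model$history <- fit$history
  model$best_epoch <- fit$best_epoch
  model$split <- split
  model$train_config <- config
  model
}

#' Soft-voting fusion of classifier probabilities
#'
#' Weighted average of per-classifier class-probability matrices,
#' `fused = sum_i psi_i * c_i`, with nonnegative weights renormalized to sum
#' one; the predicted label is the fused argmax, ties resolved to class 0.
#'
#' @param scores List of >= 2 samples x 2 probability matrices of equal
#'   shape.
#' @param psi Nonnegative classifier weights (default equal).
#' @return List with `probabilities` (samples x 2) and `labels` (0/1).
#' @export
soft_vote <- function(scores, psi = NULL) {
  if (!is.list(scores) || length(scores) < 2L)
    stop_bad_arg("soft voting needs >= 2 probability matrices")
  dims <- lapply(scores, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop_bad_arg("probability matrices must share a shape")
  if (is.null(psi)) psi <- rep(1, length(scores))
  if (length(psi) != length(scores) || any(psi < 0) || sum(psi) <= 0)
    stop_bad_arg("psi must be nonnegative weights, one per classifier")
  psi <- psi / sum(psi)
  fused <- Reduce(`+`, Map(function(s, w) w * s, scores, psi))
  labels <- as.integer(fused[, 2L] > fused[, 1L])  # tie -> class 0
  list(probabilities = fused, labels = labels)
}
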