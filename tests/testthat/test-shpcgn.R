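# Classifier stack: exact reductions of the normalization and pooling
# primitives, attention/ghost forward contracts, trainable-head behaviour on
# separable and label-shuffled data, seeded determinism, and the ensemble
# dominance of soft voting.

test_that("chaotic map iterates as derived and stays in the unit interval", {
  expect_equal(chaotic_map_sequence(0.3, 0.5, 5), c(0.6, 0.8, 0.4, 0.8, 0.4))
  # x0 = q takes the upper branch: (1 - q)/(1 - q) = 1, then 0
  expect_equal(chaotic_map_sequence(0.5, 0.5, 2)[1], 1)
  set.seed(50)
  for (i in 1:200) {
    xs <- chaotic_map_sequence(runif(1, 0.01, 0.99), runif(1, 0.01, 0.99), 50)
    expect_true(all(xs >= 0 & xs <= 1))
  }
  expect_error(chaotic_map_sequence(1.2, 0.5, 3), "x0")
})

test_that("StGE activation is continuous at zero and matches plug-ins", {
  expect_equal(stge_activation(0), 0)
  expect_equal(stge_activation(1), tanh(log(1 + exp(1))), tolerance = 1e-12)
  expect_equal(stge_activation(1), 0.8651, tolerance = 1e-4)
  eps <- 1e-9
  expect_lt(abs(stge_activation(eps) - stge_activation(-eps)), 1e-8)
  x <- seq(-20, 20, by = 0.01)
  y <- stge_activation(x, 0.6, 0.8)
  expect_true(all(is.finite(y)))
  # negative branch combines ELU and GELU with the given scalings
  xn <- -2.5
  expect_equal(stge_activation(xn, 0.3, 0.7),
               0.3 * (exp(xn) - 1) + 0.7 * xn * pnorm(xn), tolerance = 1e-12)
})

test_that("mixed pooling interpolates between max and mean", {
  s <- c(1, 3)
  expect_equal(mixed_pool(s, 1), 3)
  expect_equal(mixed_pool(s, 0), 2)
  expect_equal(mixed_pool(s, 0.5), 2.5)
  expect_error(mixed_pool(numeric(0), 0.5), "nonempty")
})

test_that("attention normalization standardizes and applies uniform softmax", {
  expect_equal(attention_norm(rep(4, 6)), rep(0, 6))
  set.seed(51)
  x <- rnorm(8)
  got <- attention_norm(x, w1 = 0, b = 0)
  mu <- mean(x); sg <- sqrt(mean((x - mu)^2))
  expect_equal(got, ((x - mu) / sg) * (1 + 1 / 8), tolerance = 1e-12)
  expect_equal(mean(got), 0, tolerance = 1e-12)
})

test_that("UBN reduces to plain batch normalization when Q is forced to 1", {
  set.seed(52)
  X <- matrix(rnorm(400), 100, 4)
  # population-standardized batch passes through unchanged
  Xs <- sweep(X, 2, colMeans(X))
  Xs <- sweep(Xs, 2, sqrt(colMeans(Xs^2)), "/")
  out <- ubn_forward(Xs, ubn_state(force_q = 1, eps = 1e-14))
  expect_equal(out, Xs, tolerance = 1e-6, ignore_attr = TRUE)
  # pre-gate standardization moments on an arbitrary batch
  out2 <- ubn_forward(X, ubn_state(force_q = 1, eps = 1e-12))
  expect_equal(colMeans(out2), rep(0, 4), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(apply(out2, 2, function(v) mean(v^2)), rep(1, 4),
               tolerance = 1e-5, ignore_attr = TRUE)
  # constant channel collapses to zero under the eps guard
  Xc <- cbind(rnorm(50), rep(2, 50))
  outc <- ubn_forward(Xc, ubn_state(force_q = 1))
  expect_equal(unname(outc[, 2]), rep(0, 50))
  expect_error(ubn_forward(matrix(1, 1, 3), ubn_state()), "batch")
  # full gated path stays finite and deterministic
  g1 <- ubn_forward(X, ubn_state())
  expect_true(all(is.finite(g1)))
  expect_equal(g1, ubn_forward(X, ubn_state()))
})

test_that("SPCII attention re-weights without changing shape", {
  set.seed(53)
  x <- array(rnorm(6 * 5 * 7), c(6, 5, 7))
  out <- spcii_attention(x, seed = 3)
  expect_equal(dim(out), dim(x))
  pH <- attr(out, "p_H"); pW <- attr(out, "p_W")
  expect_length(pH, 5); expect_length(pW, 7)
  expect_true(all(pH > 0 & pH < 1))
  expect_true(all(pW > 0 & pW < 1))
  # re-weighting is exactly the outer product of the two profiles
  manual <- x * rep(pH, each = 6) * rep(pW, each = 30)
  expect_equal(unname(out[seq_along(out)]), manual[seq_along(manual)])
  # zero input: zero-bias sigmoid gives 0.5 profiles, zero output
  z <- spcii_attention(array(0, c(6, 5, 7)), seed = 3)
  expect_equal(attr(z, "p_H"), rep(0.5, 5))
  expect_equal(max(abs(z)), 0)
  expect_error(spcii_attention(array(0, c(3, 1, 5)), seed = 1), "spatial")
})

test_that("ghost module channel arithmetic and parameter savings hold", {
  set.seed(54)
  x <- array(rnorm(10 * 10 * 4), c(10, 10, 4))
  out <- ghost_module(x, 64, seed = 2)
  expect_equal(dim(out), c(10L, 10L, 64L))
  # s = 2: 32 intrinsic + 32 ghost channels
  w <- attr(out, "weights")
  expect_equal(w$m, 32L)
  cnt <- ghost_param_count(4, 64)
  expect_lt(cnt$ghost, cnt$dense)
  expect_equal(cnt$ghost, 9 * 4 * 32 + 9 * 32)
  # identity cheap op duplicates intrinsic maps
  dup <- ghost_module(x, 8, seed = 2, identity_cheap = TRUE)
  expect_equal(dup[, , 5:8], dup[, , 1:4])
  expect_error(ghost_module(x, 9), "divisible")
})

test_that("classifier forward passes emit probability simplices deterministically", {
  set.seed(55)
  n <- 12
  eegF <- matrix(rnorm(n * 252), n)
  fmriF <- matrix(rnorm(n * 384), n)
  subj <- sprintf("s%d", rep(1:6, each = 2))
  y <- rep(c(0, 1), 6)
  cfg <- train_config(epochs = 3, batch_size = 4, seed = 2)
  m <- build_iapcnet(seed = 9)
  m <- seiz_train(m, list(labels = y, subjects = subj, eeg = eegF, fmri = fmriF),
                  cfg)
  p <- predict(m, eeg = eegF, fmri = fmriF)
  expect_equal(rowSums(p), rep(1, n), tolerance = 1e-6)
  expect_true(all(p >= 0))
  p2 <- predict(m, eeg = eegF, fmri = fmriF)
  expect_identical(p, p2)
  # batch equivariance: permuting samples permutes outputs identically
  perm <- sample(n)
  p_perm <- predict(m, eeg = eegF[perm, ], fmri = fmriF[perm, ])
  expect_equal(p_perm, p[perm, ], tolerance = 1e-8)
  expect_error(predict(m, eeg = eegF[, 1:100], fmri = fmriF), "expected")
  expect_error(seiz_represent(m, eeg = eegF, fmri = NULL), "both")
})

test_that("well-separated blobs reach high validation accuracy; shuffled labels sit at chance", {
  set.seed(56)
  n <- 400
  X <- rbind(matrix(rnorm(n / 2 * 16, -1.5), n / 2),
             matrix(rnorm(n / 2 * 16, 1.5), n / 2))
  y <- rep(c(0L, 1L), each = n / 2)
  subj <- sprintf("s%02d", rep(1:20, length.out = n))
  m <- build_mlp(16, seed = 3)
  fit <- seiz_train(m, list(labels = y, subjects = subj, x = X),
                    train_config(epochs = 20, seed = 6))
  expect_gte(max(fit$history$val_acc), 0.95)
  expect_lte(nrow(fit$history), 20)
  # same seed twice: identical loss history
  fit2 <- seiz_train(build_mlp(16, seed = 3),
                     list(labels = y, subjects = subj, x = X),
                     train_config(epochs = 20, seed = 6))
  expect_identical(fit$history, fit2$history)

  yshuf <- sample(y)   # destroys any feature-label relation
  fitn <- seiz_train(build_mlp(16, seed = 3),
                     list(labels = yshuf, subjects = subj, x = X),
                     train_config(epochs = 25, seed = 8))
  test_idx <- fitn$split == "test"
  pn <- predict(fitn, x = X[test_idx, ])
  acc <- mean((pn[, 2] > 0.5) == yshuf[test_idx])
  expect_gte(acc, 0.4); expect_lte(acc, 0.6)
})

test_that("soft voting fuses probabilities per the weighted-average rule", {
  a <- matrix(c(0.6, 0.4), 1); b <- matrix(c(0.2, 0.8), 1)
  sv <- soft_vote(list(a, b))
  expect_equal(sv$probabilities, matrix(c(0.4, 0.6), 1))
  expect_equal(sv$labels, 1L)
  sv_same <- soft_vote(list(a, a))
  expect_equal(sv_same$probabilities, a)
  expect_equal(sv_same$labels, 0L)
  sv_first <- soft_vote(list(a, b), psi = c(1, 0))
  expect_equal(sv_first$probabilities, a)
  tie <- soft_vote(list(matrix(c(0.5, 0.5), 1), matrix(c(0.5, 0.5), 1)))
  expect_equal(tie$labels, 0L)                     # tie resolves to class 0
  expect_error(soft_vote(list(a)), ">= 2")
  expect_error(soft_vote(list(a, matrix(0.5, 2, 2))), "shape")
  expect_error(soft_vote(list(a, b), psi = c(-1, 2)), "psi")
})

test_that("soft-voted accuracy dominates the weaker member across seeds", {
  accs <- matrix(0, 20, 3)
  for (s in 1:20) {
    set.seed(s + 900)
    n <- 120
    mu <- 0.9
    X1 <- rbind(matrix(rnorm(n / 2 * 8, -mu), n / 2),
                matrix(rnorm(n / 2 * 8, mu), n / 2))
    X2 <- rbind(matrix(rnorm(n / 2 * 8, -mu), n / 2),
                matrix(rnorm(n / 2 * 8, mu), n / 2))
    y <- rep(c(0L, 1L), each = n / 2)
    subj <- sprintf("s%02d", rep(1:12, length.out = n))
    cfg1 <- train_config(epochs = 15, seed = s)
    m1 <- seiz_train(build_mlp(8, seed = s), list(labels = y, subjects = subj, x = X1), cfg1)
    m2 <- seiz_train(build_mlp(8, seed = s + 1), list(labels = y, subjects = subj, x = X2),
                     train_config(epochs = 15, seed = s + 1), split = m1$split)
    idx <- m1$split == "test"
    p1 <- predict(m1, x = X1[idx, ]); p2 <- predict(m2, x = X2[idx, ])
    fused <- soft_vote(list(p1, p2))
    accs[s, ] <- c(mean((p1[, 2] > 0.5) == y[idx]),
                   mean((p2[, 2] > 0.5) == y[idx]),
                   mean(fused$labels == y[idx]))
  }
  expect_true(all(accs[, 3] >= pmin(accs[, 1], accs[, 2])))
  expect_gte(mean(accs[, 3]), mean(pmax(accs[, 1], accs[, 2])) - 0.02)
})
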