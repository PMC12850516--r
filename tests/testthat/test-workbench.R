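# Quality metrics, classification report (with an independent caret
# cross-check), subject-independent fold plans and the end-to-end pipeline
# contract on a compact benchmark.

test_that("psnr matches closed forms and sentinels", {
  img <- matrix(runif(64), 8)
  expect_equal(psnr(img, img), Inf)
  ref <- matrix(0, 10, 10)
  test255 <- ref; test255[] <- 1   # MSE = 1 against 0 image
  expect_equal(psnr(ref, test255, peak = 255), 10 * log10(255^2), tolerance = 1e-6)
  expect_equal(psnr(ref, test255, peak = 255), 48.13, tolerance = 0.01)
  test01 <- ref; test01[] <- 0.1   # MSE = 0.01
  expect_equal(psnr(ref, test01, peak = 1), 20)
  expect_error(psnr(ref, matrix(0, 9, 9)), "shapes")
})

test_that("ssim is 1 on identity, symmetric, negative on contrast inversion", {
  set.seed(60)
  img <- matrix(runif(400), 20)
  expect_equal(ssim(img, img), 1)
  noisy <- img + rnorm(400, 0, 0.1)
  expect_equal(ssim(img, noisy), ssim(noisy, img), tolerance = 1e-12)
  expect_lt(ssim(img, noisy), 1)
  inverted <- 1 - img            # negated structure about midrange
  expect_lt(ssim(img, inverted), 0)
  expect_gte(ssim(img, noisy), -1)
})

test_that("snr matches the power-ratio closed form and decreases with noise", {
  t <- seq_len(2^15) / 256
  clean <- sin(2 * pi * 6 * t)
  set.seed(61)
  noisy <- clean + rnorm(length(t), 0, sqrt(0.05))
  expect_equal(snr_db(clean, noisy), 10 * log10(0.5 / 0.05), tolerance = 0.5)
  noisier <- clean + rnorm(length(t), 0, sqrt(0.2))
  expect_lt(snr_db(clean, noisier), snr_db(clean, noisy))
  expect_equal(snr_db(clean, clean), Inf)
})

test_that("the printed confusion worked example reproduces its headline metrics", {
  rep <- metrics_from_counts(tp = 520, tn = 612, fp = 46, fn = 25)
  expect_equal(round(rep$accuracy, 3), 0.941)
  expect_equal(rep$accuracy, (520 + 612) / 1203, tolerance = 1e-12)
  expect_equal(rep$FNR, 1 - rep$sensitivity, tolerance = 1e-12)
  expect_equal(rep$FPR, 1 - rep$specificity, tolerance = 1e-12)
})

test_that("metric formulas agree with caret and identities on random confusions", {
  set.seed(62)
  for (i in 1:5) {
    y <- rbinom(200, 1, 0.5)
    p <- rbinom(200, 1, 0.5)
    rep <- classification_metrics(y, p)
    cm <- caret::confusionMatrix(factor(p, levels = c(0, 1)),
                                 factor(y, levels = c(0, 1)),
                                 positive = "1")
    expect_equal(rep$accuracy, unname(cm$overall["Accuracy"]), tolerance = 1e-12)
    expect_equal(rep$sensitivity, unname(cm$byClass["Sensitivity"]), tolerance = 1e-12)
    expect_equal(rep$specificity, unname(cm$byClass["Specificity"]), tolerance = 1e-12)
    expect_equal(rep$precision, unname(cm$byClass["Pos Pred Value"]), tolerance = 1e-12)
    expect_equal(rep$NPV, unname(cm$byClass["Neg Pred Value"]), tolerance = 1e-12)
    mcc_direct <- with(rep, (TP * TN - FP * FN) /
                        sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)))
    expect_equal(rep$MCC, mcc_direct, tolerance = 1e-12)
  }
  perfect <- classification_metrics(c(0, 1, 1, 0), c(0, 1, 1, 0))
  for (m in c("accuracy", "precision", "sensitivity", "specificity", "F1",
              "MCC", "NPV"))
    expect_equal(perfect[[m]], 1)
  expect_equal(perfect$FNR, 0); expect_equal(perfect$FPR, 0)
  w <- capture_warnings(classification_metrics(c(1, 1), c(1, 1)))
  expect_true(all(grepl("undefined", w)) && length(w) >= 1)
  expect_error(classification_metrics(c(0, 1), c(1, 1, 0)), "lengths")
})

test_that("probability inputs are thresholded consistently", {
  y <- c(0, 1, 1, 0)
  pm <- cbind(c(0.9, 0.2, 0.4, 0.4), c(0.1, 0.8, 0.6, 0.6))
  rep <- classification_metrics(y, pm)
  expect_equal(rep$accuracy, 0.75)   # fourth sample 0.6 -> predicted 1, a miss
  rep2 <- classification_metrics(y, pm[, 2])
  expect_equal(as.data.frame(rep), as.data.frame(rep2))
})

test_that("fold plans are subject-disjoint, exhaustive and seeded", {
  ds <- generate_eeg_dataset(n_samples = 96, n_channels = 2, fs = 64,
                             duration_s = 1, seed = 70, n_subjects = 12)
  subj <- vapply(ds, function(r) r$subject_id, "")
  labs <- vapply(ds, function(r) r$label, 0L)
  plan <- make_folds(subj, labs, k = 5, seed = 3)
  tested <- character(0)
  for (i in 1:5) {
    it <- plan$iterations[[i]]
    expect_length(intersect(it$train, it$val), 0)
    expect_length(intersect(it$train, it$test), 0)
    expect_length(intersect(it$val, it$test), 0)
    assign <- fold_assignment(plan, i, subj)
    # each partition carries both classes
    for (part in c("train", "val", "test"))
      expect_setequal(unique(labs[assign == part]), c(0L, 1L))
    tested <- c(tested, it$test)
  }
  expect_setequal(tested, unique(subj))           # every subject tested once
  expect_equal(anyDuplicated(tested), 0L)
  plan2 <- make_folds(subj, labs, k = 5, seed = 3)
  expect_identical(plan, plan2)
  expect_error(make_folds(subj[1:4], labs[1:4], k = 5), "subjects")
})

test_that("pipeline runs end to end, writes reports and reproduces itself", {
  dir <- withr::local_tempdir()
  cfg <- pipeline_config(n_samples = 48, n_subjects = 8, k = 3, epochs = 10,
                         duration_s = 2, image_shape = c(16L, 16L),
                         seed = 77, out_dir = dir)
  res <- run_pipeline(cfg)
  expect_s3_class(res, "seiz_pipeline")
  expect_equal(nrow(res$fold_metrics), 3)
  metric_cols <- setdiff(names(res$fold_metrics), "fold")
  for (mc in setdiff(metric_cols, "MCC"))
    expect_true(all(res$fold_metrics[[mc]] >= 0 & res$fold_metrics[[mc]] <= 1))
  expect_true(all(abs(res$fold_metrics$MCC) <= 1))
  expect_true(file.exists(file.path(dir, "fold_metrics.csv")))
  expect_true(file.exists(file.path(dir, "summary.csv")))
  expect_true(file.exists(file.path(dir, "metrics.json")))
  res2 <- run_pipeline(pipeline_config(n_samples = 48, n_subjects = 8, k = 3,
                                       epochs = 10, duration_s = 2,
                                       image_shape = c(16L, 16L), seed = 77))
  expect_identical(res$fold_metrics, res2$fold_metrics)
})

test_that("yaml configuration round-trips into the pipeline", {
  dir <- withr::local_tempdir()
  yaml::write_yaml(list(n_samples = 16, n_subjects = 4, k = 2, epochs = 2,
                        duration_s = 1, modality = "eeg", seed = 5),
                   file.path(dir, "cfg.yaml"))
  cfg <- read_pipeline_config(file.path(dir, "cfg.yaml"))
  expect_s3_class(cfg, "pipeline_config")
  expect_equal(cfg$n_samples, 16)
  expect_equal(cfg$modality, "eeg")
})
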