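# Subject-independent cross-validation: folds are built over subject ids, so
# no individual's recordings ever straddle train/validation/test within an
# iteration — the leakage-control protocol for biosignal classifiers.

#' Build a subject-independent k-fold plan
#'
#' Partitions the unique subject ids into `k` disjoint test folds (stratified
#' by each subject's dominant class) and, for every CV iteration, splits the
#' remaining subjects into train and validation groups honouring `fractions`
#' renormalized over the non-test share. Every sample is tested exactly once
#' across the plan, and identical seeds reproduce the plan bit for bit.
#'
#' @param subjects Character vector of subject ids, one per sample.
#' @param labels 0/1 labels, one per sample.
#' @param k Number of folds (default 5; needs `k <=` number of subjects).
#' @param fractions Train/validation/test fractions used to size the
#'   train/val split of the non-test subjects (default `c(0.7, 0.15, 0.15)`).
#' @param seed Integer seed.
#' @return An object of class `fold_plan`: a list of `k` iterations, each
#'   with character vectors `train`, `val`, `test` of subject ids, plus the
#'   per-sample fold index in `$fold_of`.
#' @export
make_folds <- function(subjects, labels, k = 5L, fractions = c(0.7, 0.15, 0.15),
                       seed = 1L) {
  subjects <- as.character(subjects)
  labels <- as.integer(labels)
  k <- check_count(k, "k", lower = 2L)
  subj <- unique(subjects)
  if (length(subj) < k)
    stop_bad_arg("only %d subjects for %d folds", length(subj), k)
  subj_lab <- vapply(subj, function(s) round(mean(labels[subjects == s])), 0)
  with_seed(derive_seed(seed, "folds"), {
    fold_of_subj <- integer(length(subj)); names(fold_of_subj) <- subj
    for (g in unique(subj_lab)) {
      grp <- sample(subj[subj_lab == g])
      fold_of_subj[grp] <- rep_len(seq_len(k), length(grp))
    }
    iters <- lapply(seq_len(k), function(i) {
      test <- subj[fold_of_subj == i]
      rest <- subj[fold_of_subj != i]
      frac_tr <- fractions[1] / (fractions[1] + fractions[2])
      rest <- sample(rest)
      n_tr <- max(1L, round(frac_tr * length(rest)))
      if (n_tr >= length(rest)) n_tr <- length(rest) - 1L
      list(train = rest[seq_len(n_tr)],
           val = rest[-seq_len(n_tr)],
           test = test)
    })
    structure(list(iterations = iters, k = k,
                   fold_of = fold_of_subj[subjects], seed = seed),
              class = "fold_plan")
  })
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d subject-disjoint folds over %d subjects\n",
              x$k, length(unique(names(x$fold_of)))))
  invisible(x)
}

#' Per-sample partition labels for one CV iteration
#'
#' @param plan A [make_folds()] plan.
#' @param i Iteration index in `1..k`.
#' @param subjects Subject id per sample.
#' @return Character vector of `"train"/"val"/"test"` per sample.
#' @export
fold_assignment <- function(plan, i, subjects) {
  stopifnot(inherits(plan, "fold_plan"))
  it <- plan$iterations[[i]]
  out <- rep("train", length(subjects))
  out[subjects %in% it$val] <- "val"
  out[subjects %in% it$test] <- "test"
  out
}
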