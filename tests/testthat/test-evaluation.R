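small_dataset <- function(seed = 1) {
  generate_synthetic(synthetic_spec(n_drugs = 20, n_microbes = 12,
                                    n_blocks = 2, within_block_prob = 0.5,
                                    background_prob = 0.05, seed = seed))
}

test_that("k-fold split partitions the positives into near-equal folds", {
  gen <- small_dataset()
  pos <- which(gen$dataset$S == 1, arr.ind = TRUE)
  dimnames(pos) <- NULL
  folds <- kfold_split(gen$dataset, k = 5, seed = 42)
  sizes <- vapply(folds, function(f) nrow(f$test), integer(1))
  expect_equal(sum(sizes), nrow(pos))
  expect_lte(max(sizes) - min(sizes), 1)
  # union of test folds = positive set, pairwise disjoint
  all_test <- do.call(rbind, lapply(folds, `[[`, "test"))
  key <- function(m) paste(m[, 1], m[, 2])
  expect_setequal(key(all_test), key(pos))
  expect_equal(anyDuplicated(key(all_test)), 0L)
  # train = complement of test within the positives
  for (f in folds) {
    expect_setequal(key(f$train), setdiff(key(pos), key(f$test)))
  }
})

test_that("fold assignment is deterministic in the seed", {
  gen <- small_dataset()
  f1 <- kfold_split(gen$dataset, 5, seed = 7)
  f2 <- kfold_split(gen$dataset, 5, seed = 7)
  f3 <- kfold_split(gen$dataset, 5, seed = 8)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
})

test_that("ten positives over five folds give folds of two", {
  pairs <- data.frame(drug = paste0("d", 1:10), microbe = "m1")
  pairs$microbe <- paste0("m", rep(1:2, 5))
  ds <- mda_dataset(pairs)
  folds <- kfold_split(ds, 5, seed = 1)
  expect_equal(vapply(folds, function(f) nrow(f$test), integer(1)),
               rep(2L, 5))
  expect_error(kfold_split(ds, 1, seed = 1), "at least 2")
  expect_error(kfold_split(ds, 11, seed = 1), "folds")
})

test_that("AUC handles separable, inverted and tied cases", {
  expect_equal(auc_score(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_score(c(0.9, 0.1), c(0, 1)), 0.0)
  expect_equal(auc_score(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_error(auc_score(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUC equals the pairwise oracle exactly, ties included", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 200
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    labels <- rbinom(n, 1, 0.4)
    labels[1:2] <- c(0, 1)
    expect_identical(auc_score(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  scores <- rnorm(300)
  labels <- rbinom(300, 1, 0.3); labels[1:2] <- c(0, 1)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc_score(scores, labels), ref, tolerance = 1e-12)
})

test_that("a perfect oracle scorer reaches AUC 1 through the harness", {
  gen <- small_dataset(seed = 3)
  folds <- kfold_split(gen$dataset, 4, seed = 5)
  fold <- folds[[1]]
  # oracle: score = 1 on test positives, 0 elsewhere
  lg <- matrix(0, nrow(gen$dataset$S), ncol(gen$dataset$S))
  lg[fold$test] <- 1
  neg <- which(gen$dataset$S == 0, arr.ind = TRUE)
  expect_equal(auc_score(c(lg[fold$test], lg[neg]),
                         c(rep(1, nrow(fold$test)), rep(0, nrow(neg)))),
               1.0)
})

test_that("run_fold reports AUC and class sizes under both policies", {
  gen <- small_dataset(seed = 6)
  folds <- kfold_split(gen$dataset, 4, seed = 2)
  res <- suppressWarnings(
    run_fold(gen$dataset, folds[[1]], tiny_pipeline(), cv_config(k = 4),
             seed = 3))
  expect_true(res$auc >= 0 && res$auc <= 1)
  expect_equal(res$n_test_pos, nrow(folds[[1]]$test))
  expect_equal(res$n_neg, sum(gen$dataset$S == 0))
  res1 <- suppressWarnings(
    run_fold(gen$dataset, folds[[1]], tiny_pipeline(),
             cv_config(k = 4, negative_policy = "sampled_1to1"), seed = 3))
  expect_equal(res1$n_neg, res1$n_test_pos)
})

test_that("per-fold features depend only on the training-masked adjacency", {
  gen <- small_dataset(seed = 8)
  folds <- kfold_split(gen$dataset, 4, seed = 9)
  fold <- folds[[1]]
  # scores computed by the harness must equal scores computed from a
  # dataset in which the test positives never existed at all
  res_harness <- suppressWarnings(
    run_fold(gen$dataset, fold, tiny_pipeline(), cv_config(k = 4),
             seed = 11, return_scores = TRUE))
  ds_masked <- gen$dataset
  ds_masked$S[fold$test] <- 0
  res_direct <- suppressWarnings(
    compute_scores(ds_masked$S, tiny_pipeline(), seed = 11))
  expect_identical(res_harness$scores$raw_logits,
                   res_direct$scores$raw_logits)
})

test_that("cross-validation aggregates fold AUCs reproducibly", {
  gen <- small_dataset(seed = 12)
  cvc <- cv_config(k = 3, seed = 21, negative_policy = "sampled_1to1")
  r1 <- suppressWarnings(run_cv(gen$dataset, tiny_pipeline(), cvc))
  r2 <- suppressWarnings(run_cv(gen$dataset, tiny_pipeline(), cvc))
  expect_identical(r1$per_fold_auc, r2$per_fold_auc)
  expect_length(r1$per_fold_auc, 3)
  expect_equal(r1$mean_auc, mean(r1$per_fold_auc))
  expect_equal(r1$std_auc, sd(r1$per_fold_auc))
  expect_true(all(r1$per_fold_auc >= 0 & r1$per_fold_auc <= 1))
})

test_that("ablation arms share folds and the no-op ablation is exact", {
  gen <- small_dataset(seed = 13)
  cvc <- cv_config(k = 3, seed = 5, negative_policy = "sampled_1to1")
  p_off <- tiny_pipeline(use_attention = FALSE)
  a <- suppressWarnings(ablation_attention(gen$dataset, p_off, cvc))
  b <- suppressWarnings(ablation_attention(gen$dataset, p_off, cvc))
  # identical seeds, attention off in both runs of the without arm
  expect_identical(a$without_attention$per_fold_auc,
                   b$without_attention$per_fold_auc)
  expect_length(a$per_fold_delta, 3)
  expect_equal(a$mean_delta, mean(a$per_fold_delta))
  # the two arms of one ablation really differ only in use_attention
  expect_true(a$with_attention$config$pipeline$sae$use_attention)
  expect_false(a$without_attention$config$pipeline$sae$use_attention)
  cfg_w <- a$with_attention$config$pipeline$sae
  cfg_o <- a$without_attention$config$pipeline$sae
  cfg_w$use_attention <- NULL; cfg_o$use_attention <- NULL
  expect_identical(cfg_w, cfg_o)
})

test_that("hyperparameter sweep runs a grid and resumes from disk", {
  gen <- small_dataset(seed = 14)
  cvc <- cv_config(k = 2, seed = 3, negative_policy = "sampled_1to1")
  out <- withr::local_tempfile(fileext = ".tsv")
  one <- suppressWarnings(
    hyperparameter_sweep(gen$dataset, lr_grid = 0.01, h_grid = 2,
                         pipeline = tiny_pipeline(), cv = cvc,
                         out_tsv = out))
  expect_equal(nrow(one), 1)
  expect_true(file.exists(out))
  # rerun with a wider grid: the completed point is reused verbatim
  two <- suppressWarnings(
    hyperparameter_sweep(gen$dataset, lr_grid = 0.01, h_grid = c(2, 4),
                         pipeline = tiny_pipeline(), cv = cvc,
                         out_tsv = out))
  expect_equal(nrow(two), 2)
  expect_equal(two$mean_auc[two$heads == 2], one$mean_auc)
})
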