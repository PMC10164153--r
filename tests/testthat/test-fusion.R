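make_blocks <- function(Nr, Nm, seed = 1) {
  set.seed(seed)
  list(DR = matrix(runif(Nr * Nr), Nr, Nr),
       MR = matrix(runif(Nm * Nm), Nm, Nm),
       SAEr1 = matrix(runif(Nr * Nr), Nr, Nr),
       SAEr2 = matrix(runif(Nr * Nr), Nr, Nr),
       SAEm1 = matrix(runif(Nm * Nm), Nm, Nm),
       SAEm2 = matrix(runif(Nm * Nm), Nm, Nm),
       S = random_binary_matrix(Nr, Nm, 0.4, seed = seed))
}

test_that("integrated matrices have exactly 3(Nr+Nm) columns", {
  for (dims in list(c(2, 3), c(5, 4), c(17, 9), c(40, 11))) {
    Nr <- dims[1]; Nm <- dims[2]
    b <- make_blocks(Nr, Nm, seed = Nr)
    IF <- integrate_features(b$DR, b$MR, b$SAEr1, b$SAEr2, b$SAEm1, b$SAEm2,
                             b$S)
    expect_equal(dim(IF$IFMr), c(Nr, 3 * (Nr + Nm)))
    expect_equal(dim(IF$IFMm), c(Nm, 3 * (Nr + Nm)))
    expect_equal(sum(IF$block_layout$width), 3 * (Nr + Nm))
  }
})

test_that("block order and content follow the printed layout", {
  b <- make_blocks(4, 3)
  IF <- integrate_features(b$DR, b$MR, b$SAEr1, b$SAEr2, b$SAEm1, b$SAEm2,
                           b$S)
  lay <- IF$block_layout
  expect_equal(lay$drug_side, c("DR", "S", "SAEr1", "S", "SAEr2", "S"))
  expect_equal(lay$microbe_side, c("St", "MR", "St", "SAEm1", "St", "SAEm2"))
  # the second column block of IFMr is the adjacency, exactly
  cols2 <- lay$start[2]:lay$end[2]
  expect_identical(IF$IFMr[, cols2], b$S)
  expect_identical(IF$IFMm[, lay$start[1]:lay$end[1]], t(b$S))
  expect_identical(IF$IFMr[, lay$start[1]:lay$end[1]], b$DR)
})

test_that("shape mismatches are rejected naming the offending block", {
  b <- make_blocks(4, 3)
  expect_error(
    integrate_features(b$DR[1:3, 1:3], b$MR, b$SAEr1, b$SAEr2, b$SAEm1,
                       b$SAEm2, b$S),
    "DR")
  expect_error(
    integrate_features(b$DR, b$MR, b$SAEr1, b$SAEr2, b$SAEm1,
                       b$SAEm2[, 1:2], b$S),
    "SAEm2")
})

test_that("logits match a two-loop inner product and scores its logistic", {
  b <- make_blocks(4, 3, seed = 5)
  # scale down so the logistic does not saturate
  for (k in c("DR", "MR", "SAEr1", "SAEr2", "SAEm1", "SAEm2")) {
    b[[k]] <- b[[k]] * 0.05
  }
  IF <- integrate_features(b$DR, b$MR, b$SAEr1, b$SAEr2, b$SAEm1, b$SAEm2,
                           b$S * 0.05)
  sc <- score_associations(IF)
  manual <- matrix(0, 4, 3)
  for (i in 1:4) for (j in 1:3) {
    manual[i, j] <- sum(IF$IFMr[i, ] * IF$IFMm[j, ])
  }
  expect_equal(sc$raw_logits, manual, tolerance = 1e-12)
  expect_equal(sc$values, 1 / (1 + exp(-manual)), tolerance = 1e-12)
  expect_true(all(sc$values > 0 & sc$values < 1))
})

test_that("all-zero features score exactly one half", {
  Z <- list(DR = matrix(0, 2, 2), MR = matrix(0, 3, 3),
            SAEr = matrix(0, 2, 2), SAEm = matrix(0, 3, 3),
            S = matrix(0, 2, 3))
  IF <- integrate_features(Z$DR, Z$MR, Z$SAEr, Z$SAEr, Z$SAEm, Z$SAEm, Z$S)
  sc <- score_associations(IF)
  expect_equal(sc$values, matrix(0.5, 2, 3))
})

test_that("per-block decomposition sums to the logits", {
  b <- make_blocks(6, 5, seed = 8)
  IF <- integrate_features(b$DR, b$MR, b$SAEr1, b$SAEr2, b$SAEm1, b$SAEm2,
                           b$S)
  sc <- score_associations(IF)
  dec <- score_block_decomposition(IF)
  expect_length(dec, 6)
  expect_lt(max(abs(Reduce(`+`, dec) - sc$raw_logits)), 1e-9)
})

test_that("AUC is identical on scores and raw logits", {
  b <- make_blocks(8, 6, seed = 9)
  for (k in c("DR", "MR", "SAEr1", "SAEr2", "SAEm1", "SAEm2")) {
    b[[k]] <- b[[k]] * 0.02
  }
  IF <- integrate_features(b$DR, b$MR, b$SAEr1, b$SAEr2, b$SAEm1, b$SAEm2,
                           b$S * 0.02)
  sc <- score_associations(IF)
  set.seed(10)
  labels <- rbinom(length(sc$values), 1, 0.3)
  labels[1] <- 1; labels[2] <- 0
  expect_identical(auc_score(as.vector(sc$values), labels),
                   auc_score(as.vector(sc$raw_logits), labels))
})

test_that("ranked pair list is sorted and excludes known pairs", {
  b <- make_blocks(4, 3, seed = 11)
  IF <- integrate_features(b$DR, b$MR, b$SAEr1, b$SAEr2, b$SAEm1, b$SAEm2,
                           b$S)
  sc <- score_associations(IF)
  ds <- structure(list(drug_ids = paste0("d", 1:4),
                       microbe_ids = paste0("m", 1:3), S = b$S),
                  class = "mda_dataset")
  rk <- rank_pairs(sc, ds)
  expect_equal(nrow(rk), sum(b$S == 0))
  expect_true(all(diff(rk$logit) <= 0))
  expect_equal(rk$rank, seq_len(nrow(rk)))
})
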