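test_that("generation is deterministic and respects the spec", {
  sp <- synthetic_spec(n_drugs = 30, n_microbes = 15, n_blocks = 3,
                       within_block_prob = 0.4, background_prob = 0.02,
                       seed = 5)
  g1 <- generate_synthetic(sp)
  g2 <- generate_synthetic(sp)
  expect_identical(g1$dataset$S, g2$dataset$S)
  expect_identical(g1$drug_blocks, g2$drug_blocks)
  expect_equal(dim(g1$dataset$S), c(30L, 15L))
  expect_true(all(g1$dataset$S %in% c(0, 1)))
  expect_equal(sort(unique(g1$drug_blocks)), 1:3)
  g3 <- generate_synthetic(synthetic_spec(n_drugs = 30, n_microbes = 15,
                                          n_blocks = 3, seed = 6))
  expect_false(identical(g1$dataset$S, g3$dataset$S))
})

test_that("a single block with certain association is complete bipartite", {
  g <- generate_synthetic(synthetic_spec(n_drugs = 6, n_microbes = 4,
                                         n_blocks = 1,
                                         within_block_prob = 1,
                                         background_prob = 0, seed = 2))
  expect_true(all(g$dataset$S == 1))
})

test_that("planted signal is required and empty output rejected", {
  expect_error(synthetic_spec(within_block_prob = 0.1,
                              background_prob = 0.2),
               "exceed")
  expect_error(generate_synthetic(
    synthetic_spec(n_drugs = 5, n_microbes = 5, n_blocks = 1,
                   within_block_prob = 1e-4, background_prob = 0,
                   seed = 3)),
    "no associations")
})

test_that("empirical densities sit within 3 SE of the spec", {
  sp <- synthetic_spec(n_drugs = 200, n_microbes = 60, n_blocks = 4,
                       within_block_prob = 0.3, background_prob = 0.01,
                       seed = 11)
  g <- generate_synthetic(sp)
  same <- outer(g$drug_blocks, g$microbe_blocks, "==")
  n_in <- sum(same); n_bg <- sum(!same)
  d_in <- sum(g$dataset$S[same]) / n_in
  d_bg <- sum(g$dataset$S[!same]) / n_bg
  se_in <- sqrt(0.3 * 0.7 / n_in)
  se_bg <- sqrt(0.01 * 0.99 / n_bg)
  expect_lt(abs(d_in - 0.3), 3 * se_in)
  expect_lt(abs(d_bg - 0.01), 3 * se_bg)
})

test_that("noise flips perturb the expected fraction of cells", {
  sp_clean <- synthetic_spec(n_drugs = 100, n_microbes = 50, n_blocks = 2,
                             within_block_prob = 0.4,
                             background_prob = 0.05, seed = 9)
  sp_noisy <- synthetic_spec(n_drugs = 100, n_microbes = 50, n_blocks = 2,
                             within_block_prob = 0.4,
                             background_prob = 0.05,
                             noise_flip_prob = 0.1, seed = 9)
  clean <- generate_synthetic(sp_clean)$dataset$S
  noisy <- generate_synthetic(sp_noisy)$dataset$S
  frac <- mean(clean != noisy)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / length(clean)))
})

test_that("external similarities interpolate indicator and noise", {
  set.seed(1)
  blocks_d <- rep(1:3, each = 10)
  blocks_m <- rep(1:3, each = 5)
  exact <- make_external_similarities(blocks_d, blocks_m, reliability = 1,
                                      seed = 4)
  ind <- outer(blocks_d, blocks_d, "==") * 1
  diag(ind) <- 1
  expect_equal(exact$Sr$values, ind, ignore_attr = TRUE)
  expect_equal(exact$Sr$measure, "structural")
  expect_equal(exact$Fm$entity, "microbe")

  noise <- make_external_similarities(blocks_d, blocks_m, reliability = 0,
                                      seed = 4)
  expect_identical(noise$Sr$values, t(noise$Sr$values))
  expect_equal(diag(noise$Sr$values), rep(1, 30), ignore_attr = TRUE)

  # mean within-block minus cross-block similarity tracks reliability
  for (rel in c(0.3, 0.7)) {
    sims <- make_external_similarities(blocks_d, blocks_m, reliability = rel,
                                       seed = 6)
    V <- sims$Sr$values; diag(V) <- NA
    within <- mean(V[ind == 1], na.rm = TRUE)
    cross <- mean(V[ind == 0], na.rm = TRUE)
    expect_equal(within - cross, rel, tolerance = 0.08)
  }
})

test_that("generated datasets flow into the association container API", {
  g <- generate_synthetic(synthetic_spec(n_drugs = 12, n_microbes = 8,
                                         n_blocks = 2, seed = 7))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_associations(g$dataset, f)
  ds2 <- load_associations(f, drug_ids = g$dataset$drug_ids,
                           microbe_ids = g$dataset$microbe_ids)
  expect_identical(ds2$S, g$dataset$S)
})
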