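# Brute-force reference implementations and small fixture builders.
# These stay deliberately naive (nested loops, dense solves) so they are
# independent of the vectorized code paths they check.

options(mdassoc.verbose = FALSE)

# two-nested-loop Gaussian interaction-profile kernel
oracle_gaussian <- function(S, axis) {
  P <- if (axis == "rows") S else t(S)
  n <- nrow(P)
  mu <- 1 / mean(apply(P, 1, function(r) sum(r^2)))
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    G[i, j] <- exp(-mu * sum((P[i, ] - P[j, ])^2))
  }
  G
}

# two-nested-loop cosine with the zero-profile-gets-0 convention
oracle_cosine <- function(S, axis) {
  P <- if (axis == "rows") S else t(S)
  n <- nrow(P)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ni <- sqrt(sum(P[i, ]^2)); nj <- sqrt(sum(P[j, ]^2))
    C[i, j] <- if (ni == 0 || nj == 0) 0 else sum(P[i, ] * P[j, ]) / (ni * nj)
  }
  C
}

# O(n^2) pairwise AUC with half-credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

random_binary_matrix <- function(nr, nc, p = 0.3, seed = 1) {
  set.seed(seed)
  m <- matrix(as.numeric(rbinom(nr * nc, 1, p)), nr, nc)
  # guarantee at least one association so bandwidths are defined
  if (sum(m) == 0) m[1, 1] <- 1
  m
}

random_stochastic <- function(n, normalization = "column", seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  if (normalization == "column") sweep(m, 2, colSums(m), "/")
  else m / rowSums(m)
}

tiny_sae <- function(...) {
  sae_config(hidden_sizes = c(6, 4), heads = 2, epochs = 3,
             pretrain_epochs = 2, seed = 11, ...)
}

tiny_pipeline <- function(...) {
  pipeline_config(sae = tiny_sae(...))
}

write_assoc_file <- function(pairs, path, sep = "\t", header = TRUE) {
  lines <- paste(pairs$drug, pairs$microbe, sep = sep)
  if (header) lines <- c(paste("drug", "microbe", sep = sep), lines)
  writeLines(lines, path)
  path
}
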