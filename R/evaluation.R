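#' Cross-validation configuration
#'
#' @param k number of folds (the protocol uses 5 or 10).
#' @param seed integer seed controlling fold assignment and any negative
#'   sampling.
#' @param n_repeats independent repetitions (distinct derived seeds) whose
#'   fold AUCs are pooled for the mean +/- sd report.
#' @param mask_mode \code{"per_fold_similarity"} (default: similarities,
#'   diffusion and autoencoder inputs are recomputed from the
#'   training-masked adjacency, so no test association leaks into the
#'   features) or \code{"global_similarity"} (features from the full
#'   adjacency).
#' @param negative_policy \code{"all_unknown"} (every pair unknown in the
#'   full dataset is a negative) or \code{"sampled_1to1"} (one sampled
#'   negative per test positive).
#' @return list of class \code{cv_config}.
#' @export
cv_config <- function(k = 5, seed = 42, n_repeats = 1,
                      mask_mode = c("per_fold_similarity", "global_similarity"),
                      negative_policy = c("all_unknown", "sampled_1to1")) {
  mask_mode <- match.arg(mask_mode)
  negative_policy <- match.arg(negative_policy)
  if (k < 2) stop_mdassoc("k must be at least 2", "mdassoc_validation_error")
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 n_repeats = as.integer(n_repeats), mask_mode = mask_mode,
                 negative_policy = negative_policy),
            class = "cv_config")
}

#' Partition the known positive pairs into k folds
#'
#' Seeded random partition of the 1-entries of \code{S} into \code{k}
#' near-equal folds (sizes differ by at most 1). Each fold's positives
#' serve in turn as the test set while the rest train.
#'
#' @param dataset \code{mda_dataset}.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return list of \code{k} elements, each a list with integer matrices
#'   \code{test} and \code{train} of (row, col) positive indices.
#' @export
kfold_split <- function(dataset, k = 5, seed = 42) {
  stopifnot(inherits(dataset, "mda_dataset"))
  pos <- which(dataset$S == 1, arr.ind = TRUE)
  dimnames(pos) <- NULL
  n <- nrow(pos)
  if (k < 2) stop_mdassoc("k must be at least 2", "mdassoc_validation_error")
  if (n < k) {
    stop_mdassoc(paste0("only ", n, " positives for ", k, " folds"),
                 "mdassoc_validation_error")
  }
  perm <- with_seed(seed, sample.int(n))
  fold_of <- rep(seq_len(k), length.out = n)[order(perm)]
  lapply(seq_len(k), function(f) {
    list(test = pos[fold_of == f, , drop = FALSE],
         train = pos[fold_of != f, , drop = FALSE])
  })
}

#' Rank-based AUC (Mann-Whitney, midranks for ties)
#'
#' Probability that a uniformly chosen positive outscores a uniformly
#' chosen negative, with ties counting one half.
#'
#' @param scores numeric vector.
#' @param labels binary vector (0/1), same length.
#' @return scalar AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop_mdassoc("AUC undefined: both classes must be present",
                 "mdassoc_validation_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Core feature pipeline: masked adjacency -> similarities -> RWR -> SAE ->
# integrated features -> scores. Sr/Fm are optional external similarity
# matrices; when absent the entity's cosine similarity substitutes (run
# tagged "fallback" in the log).
compute_scores <- function(S_train, pipeline, Sr = NULL, Fm = NULL,
                           seed = NULL) {
  sae_cfg <- pipeline$sae
  rwr_cfg <- pipeline$rwr
  Gr <- gaussian_kernel_similarity(S_train, "rows")
  Gm <- gaussian_kernel_similarity(S_train, "columns")
  Cr <- cosine_similarity(S_train, "rows")
  Cm <- cosine_similarity(S_train, "columns")
  fallback <- c(drug = is.null(Sr), microbe = is.null(Fm))
  if (fallback[["drug"]]) {
    msg_info("no drug structural similarity supplied; cosine fallback in use")
    Sr <- Cr$values
  } else if (inherits(Sr, "mda_similarity")) Sr <- Sr$values
  if (fallback[["microbe"]]) {
    msg_info("no microbe functional similarity supplied; cosine fallback in use")
    Fm <- Cm$values
  } else if (inherits(Fm, "mda_similarity")) Fm <- Fm$values

  DR <- rwr_profile(transition_matrix(Gr, rwr_cfg$normalization), rwr_cfg,
                    entity = "drug")
  MR <- rwr_profile(transition_matrix(Gm, rwr_cfg$normalization), rwr_cfg,
                    entity = "microbe")

  seed_for <- function(off) if (is.null(seed)) NULL else (seed + off) %% .Machine$integer.max
  cfg_k <- function(off) { cc <- sae_cfg; cc$seed <- seed_for(off); cc }
  SAEr1 <- train_sae(Cr$values, cfg_k(1L), entity = "drug",
                     source_measure = "cosine")
  SAEr2 <- train_sae(Sr, cfg_k(2L), entity = "drug",
                     source_measure = if (fallback[["drug"]]) "cosine" else "structural")
  SAEm1 <- train_sae(Cm$values, cfg_k(3L), entity = "microbe",
                     source_measure = "cosine")
  SAEm2 <- train_sae(Fm, cfg_k(4L), entity = "microbe",
                     source_measure = if (fallback[["microbe"]]) "cosine" else "functional")

  IF <- integrate_features(DR, MR, SAEr1, SAEr2, SAEm1, SAEm2, S_train)
  list(scores = score_associations(IF, standardize = pipeline$standardize),
       integrated = IF, fallback = fallback)
}

#' Pipeline configuration
#'
#' Bundles the stage configurations used by [run_fold()], [run_cv()] and
#' [run_pipeline()].
#'
#' @param rwr \code{rwr_config}.
#' @param sae \code{sae_config}.
#' @param standardize standardize integrated feature columns before scoring.
#' @return list of class \code{mda_pipeline_config}.
#' @export
pipeline_config <- function(rwr = rwr_config(), sae = sae_config(),
                            standardize = FALSE) {
  structure(list(rwr = rwr, sae = sae, standardize = standardize),
            class = "mda_pipeline_config")
}

#' Evaluate one cross-validation fold
#'
#' Zeroes the fold's test positives in \code{S}, recomputes features from
#' the masked adjacency (or the full one under
#' \code{mask_mode = "global_similarity"}), scores all pairs, and computes
#' AUC with the fold's test positives as class 1 against pairs unknown in
#' the full dataset as class 0. Training positives enter neither class.
#' Ranking uses raw logits.
#'
#' @param dataset \code{mda_dataset}.
#' @param fold one element of [kfold_split()] output.
#' @param pipeline \code{mda_pipeline_config}.
#' @param cv \code{cv_config} (mask mode, negative policy, seed).
#' @param Sr,Fm optional external similarity matrices.
#' @param seed seed for SAE initialization and negative sampling in this
#'   fold.
#' @param return_scores also return the \code{mda_scores} object.
#' @return list: \code{auc}, \code{n_test_pos}, \code{n_neg}, and
#'   optionally \code{scores}.
#' @export
run_fold <- function(dataset, fold, pipeline = pipeline_config(),
                     cv = cv_config(), Sr = NULL, Fm = NULL, seed = 1,
                     return_scores = FALSE) {
  stopifnot(inherits(dataset, "mda_dataset"))
  if (nrow(fold$test) == 0L) {
    warning("fold has no test positives; skipped", call. = FALSE)
    return(list(auc = NA_real_, n_test_pos = 0L, n_neg = 0L))
  }
  S_train <- dataset$S
  S_train[fold$test] <- 0
  S_feat <- if (cv$mask_mode == "per_fold_similarity") S_train else dataset$S
  res <- compute_scores(S_feat, pipeline, Sr = Sr, Fm = Fm, seed = seed)
  lg <- res$scores$raw_logits

  neg_idx <- which(dataset$S == 0, arr.ind = TRUE)
  if (cv$negative_policy == "sampled_1to1") {
    take <- with_seed(seed + 7L,
                      sample.int(nrow(neg_idx),
                                 min(nrow(fold$test), nrow(neg_idx))))
    neg_idx <- neg_idx[take, , drop = FALSE]
  }
  scores <- c(lg[fold$test], lg[neg_idx])
  labels <- c(rep(1L, nrow(fold$test)), rep(0L, nrow(neg_idx)))
  out <- list(auc = auc_score(scores, labels),
              n_test_pos = nrow(fold$test), n_neg = nrow(neg_idx))
  if (return_scores) out$scores <- res$scores
  out
}

#' k-fold cross-validation of the full pipeline
#'
#' @inheritParams run_fold
#' @return object of class \code{mda_cv_result}: \code{per_fold_auc}
#'   (vector over repeats x folds), \code{mean_auc}, \code{std_auc},
#'   \code{config} snapshot.
#' @export
run_cv <- function(dataset, pipeline = pipeline_config(), cv = cv_config(),
                   Sr = NULL, Fm = NULL) {
  aucs <- numeric(0)
  for (r in seq_len(cv$n_repeats)) {
    rep_seed <- cv$seed + 1000L * (r - 1L)
    folds <- kfold_split(dataset, cv$k, seed = rep_seed)
    for (f in seq_along(folds)) {
      res <- run_fold(dataset, folds[[f]], pipeline, cv, Sr = Sr, Fm = Fm,
                      seed = rep_seed + f)
      aucs <- c(aucs, res$auc)
      msg_info("repeat ", r, " fold ", f, ": AUC ", signif(res$auc, 4))
    }
  }
  aucs <- aucs[!is.na(aucs)]
  structure(list(per_fold_auc = aucs, mean_auc = mean(aucs),
                 std_auc = if (length(aucs) > 1) stats::sd(aucs) else 0,
                 config = list(pipeline = pipeline, cv = cv)),
            class = "mda_cv_result")
}

#' @export
print.mda_cv_result <- function(x, ...) {
  cat(sprintf("<mda_cv_result> %d-fold: AUC %.4f +/- %.4f (%d fold runs)\n",
              x$config$cv$k, x$mean_auc, x$std_auc, length(x$per_fold_auc)))
  invisible(x)
}

#' Paired ablation of the attention block
#'
#' Runs cross-validation twice on identical folds and seeds, once with the
#' multi-head attention block and once without; the two arms differ in
#' nothing else. Reports paired per-fold AUC deltas (with minus without).
#'
#' @inheritParams run_cv
#' @return list: \code{with_attention}, \code{without_attention}
#'   (\code{mda_cv_result}), \code{per_fold_delta}, \code{mean_delta}.
#' @export
ablation_attention <- function(dataset, pipeline = pipeline_config(),
                               cv = cv_config(), Sr = NULL, Fm = NULL) {
  p_on <- pipeline; p_on$sae$use_attention <- TRUE
  p_off <- pipeline; p_off$sae$use_attention <- FALSE
  r_on <- run_cv(dataset, p_on, cv, Sr = Sr, Fm = Fm)
  r_off <- run_cv(dataset, p_off, cv, Sr = Sr, Fm = Fm)
  delta <- r_on$per_fold_auc - r_off$per_fold_auc
  list(with_attention = r_on, without_attention = r_off,
       per_fold_delta = delta, mean_delta = mean(delta))
}

#' Grid sweep over learning rate and attention heads
#'
#' Mean cross-validated AUC at every (learning rate, heads) grid point.
#' When \code{out_tsv} exists, grid points already present in it are
#' skipped, so an interrupted sweep resumes where it stopped.
#'
#' @inheritParams run_cv
#' @param lr_grid learning rates to try.
#' @param h_grid head counts to try.
#' @param out_tsv optional TSV path for incremental results.
#' @return data.frame (lr, heads, mean_auc, std_auc).
#' @export
hyperparameter_sweep <- function(dataset,
                                 lr_grid = c(1e-4, 5e-4, 1e-3, 1e-2, 1e-1),
                                 h_grid = c(2, 4, 8, 16),
                                 pipeline = pipeline_config(),
                                 cv = cv_config(), Sr = NULL, Fm = NULL,
                                 out_tsv = NULL) {
  grid <- expand.grid(lr = lr_grid, heads = h_grid,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0) stop_mdassoc("empty grid", "mdassoc_validation_error")
  done <- NULL
  if (!is.null(out_tsv) && file.exists(out_tsv)) {
    done <- utils::read.delim(out_tsv)
  }
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    lr <- grid$lr[i]; h <- grid$heads[i]
    if (!is.null(done) &&
        any(abs(done$lr - lr) < 1e-12 & done$heads == h)) {
      j <- which(abs(done$lr - lr) < 1e-12 & done$heads == h)[1]
      rows[[i]] <- done[j, c("lr", "heads", "mean_auc", "std_auc")]
      next
    }
    p <- pipeline
    p$sae$learning_rate <- lr
    p$sae$heads <- as.integer(h)
    res <- run_cv(dataset, p, cv, Sr = Sr, Fm = Fm)
    rows[[i]] <- data.frame(lr = lr, heads = h, mean_auc = res$mean_auc,
                            std_auc = res$std_auc)
    if (!is.null(out_tsv)) {
      tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
      utils::write.table(tab, out_tsv, sep = "\t", row.names = FALSE,
                         quote = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
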