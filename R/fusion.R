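#' Assemble integrated feature matrices
#'
#' Horizontally concatenates, in fixed block order, the drug diffusion
#' profiles, adjacency copies and drug attribute features into
#' \code{IFMr = [DR | S | SAEr1 | S | SAEr2 | S]} (\code{Nr x 3(Nr+Nm)}),
#' and the microbe-side analogue
#' \code{IFMm = [S' | MR | S' | SAEm1 | S' | SAEm2]} (\code{Nm x 3(Nr+Nm)},
#' \code{S'} the transposed adjacency). The adjacency copies carry the raw
#' association signal and make the two column layouts conformable, so the
#' row inner products in [score_associations()] pair drug blocks with
#' microbe blocks of matching width.
#'
#' @param DR,MR \code{mda_profile} (or bare square matrix) for drugs
#'   (\code{Nr x Nr}) and microbes (\code{Nm x Nm}).
#' @param SAEr1,SAEr2 drug attribute features (\code{mda_features} or
#'   matrix, \code{Nr x Nr}).
#' @param SAEm1,SAEm2 microbe attribute features (\code{Nm x Nm}).
#' @param S binary adjacency matrix (\code{Nr x Nm}).
#' @return object of class \code{mda_integrated}: \code{IFMr}, \code{IFMm},
#'   and \code{block_layout} (data.frame of block names, widths and column
#'   spans for both matrices).
#' @export
integrate_features <- function(DR, MR, SAEr1, SAEr2, SAEm1, SAEm2, S) {
  as_vals <- function(x) {
    if (inherits(x, c("mda_profile", "mda_features"))) x$values else x
  }
  DR <- as_vals(DR); MR <- as_vals(MR)
  SAEr1 <- as_vals(SAEr1); SAEr2 <- as_vals(SAEr2)
  SAEm1 <- as_vals(SAEm1); SAEm2 <- as_vals(SAEm2)
  stopifnot(is.matrix(S))
  Nr <- nrow(S); Nm <- ncol(S)
  check <- function(m, nr, nc, name) {
    if (!is.matrix(m) || nrow(m) != nr || ncol(m) != nc) {
      stop_mdassoc(sprintf(
        "block %s has shape %sx%s, expected %dx%d", name,
        if (is.matrix(m)) nrow(m) else "?", if (is.matrix(m)) ncol(m) else "?",
        nr, nc), "mdassoc_validation_error")
    }
  }
  check(DR, Nr, Nr, "DR"); check(SAEr1, Nr, Nr, "SAEr1")
  check(SAEr2, Nr, Nr, "SAEr2")
  check(MR, Nm, Nm, "MR"); check(SAEm1, Nm, Nm, "SAEm1")
  check(SAEm2, Nm, Nm, "SAEm2")

  St <- t(S)
  IFMr <- cbind(DR, S, SAEr1, S, SAEr2, S)
  IFMm <- cbind(St, MR, St, SAEm1, St, SAEm2)
  widths <- c(Nr, Nm, Nr, Nm, Nr, Nm)
  ends <- cumsum(widths)
  layout <- data.frame(
    block = 1:6,
    drug_side = c("DR", "S", "SAEr1", "S", "SAEr2", "S"),
    microbe_side = c("St", "MR", "St", "SAEm1", "St", "SAEm2"),
    width = widths, start = ends - widths + 1L, end = ends
  )
  structure(list(IFMr = IFMr, IFMm = IFMm, block_layout = layout,
                 Nr = Nr, Nm = Nm),
            class = "mda_integrated")
}

#' Score all drug-microbe pairs
#'
#' Computes the raw logits \code{IFMr \%*\% t(IFMm)} and the reported scores
#' \code{logistic(logits)}. With thousands of nonnegative feature columns
#' the logistic saturates to 1 in floating point, so downstream ranking and
#' AUC always use \code{raw_logits} -- the ordering is identical because the
#' logistic is strictly monotone.
#'
#' @param IF \code{mda_integrated}.
#' @param standardize z-score each feature column of both matrices before
#'   the product (off by default).
#' @return object of class \code{mda_scores}: \code{values} (Nr x Nm, in
#'   (0,1)) and \code{raw_logits}.
#' @export
score_associations <- function(IF, standardize = FALSE) {
  stopifnot(inherits(IF, "mda_integrated"))
  A <- IF$IFMr; B <- IF$IFMm
  if (standardize) {
    zs <- function(M) {
      mu <- colMeans(M)
      sd <- apply(M, 2, stats::sd)
      sd[sd == 0] <- 1
      sweep(sweep(M, 2, mu, "-"), 2, sd, "/")
    }
    A <- zs(A); B <- zs(B)
  }
  logits <- tcrossprod(A, B)
  if (any(!is.finite(logits))) {
    stop_mdassoc(paste0("non-finite logits; max |feature| = ",
                        signif(max(abs(A), abs(B)), 4)),
                 "mdassoc_numeric_error")
  }
  structure(list(values = logistic(logits), raw_logits = logits),
            class = "mda_scores")
}

#' Per-block decomposition of the score logits
#'
#' Diagnostic: by block alignment the logits decompose as
#' \code{DR.S + S.MR' + SAEr1.S + S.SAEm1' + SAEr2.S + S.SAEm2'}; returns
#' the six addend matrices, whose sum equals \code{raw_logits}.
#'
#' @param IF \code{mda_integrated}.
#' @return named list of six Nr x Nm matrices.
#' @export
score_block_decomposition <- function(IF) {
  stopifnot(inherits(IF, "mda_integrated"))
  lay <- IF$block_layout
  out <- vector("list", nrow(lay))
  for (i in seq_len(nrow(lay))) {
    cols <- lay$start[i]:lay$end[i]
    out[[i]] <- tcrossprod(IF$IFMr[, cols, drop = FALSE],
                           IF$IFMm[, cols, drop = FALSE])
    names(out)[i] <- paste0(lay$drug_side[i], ".", lay$microbe_side[i])
  }
  out
}

#' Ranked candidate pair list from a score matrix
#'
#' @param scores \code{mda_scores}.
#' @param dataset \code{mda_dataset} supplying identifiers.
#' @param exclude_known drop pairs already known in \code{dataset$S}.
#' @param top_n keep the first \code{top_n} rows (NULL = all).
#' @return data.frame (drug, microbe, score, logit, rank) sorted by
#'   decreasing logit.
#' @export
rank_pairs <- function(scores, dataset, exclude_known = TRUE, top_n = NULL) {
  stopifnot(inherits(scores, "mda_scores"), inherits(dataset, "mda_dataset"))
  lg <- scores$raw_logits
  idx <- which(if (exclude_known) dataset$S == 0 else TRUE, arr.ind = TRUE)
  if (!is.matrix(idx)) idx <- which(array(TRUE, dim(lg)), arr.ind = TRUE)
  df <- data.frame(
    drug = dataset$drug_ids[idx[, 1]],
    microbe = dataset$microbe_ids[idx[, 2]],
    score = scores$values[idx],
    logit = lg[idx]
  )
  df <- df[order(-df$logit, df$drug, df$microbe), ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  if (!is.null(top_n)) df <- df[seq_len(min(top_n, nrow(df))), ]
  df
}
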