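#' Similarity matrix container
#'
#' Square symmetric matrix of pairwise similarities over one entity type
#' (drugs or microbes), tagged by the measure that produced it. Values lie
#' in [0, 1]; symmetry is enforced to 1e-10 at construction.
#'
#' @param values square numeric matrix.
#' @param entity \code{"drug"} or \code{"microbe"}.
#' @param measure one of \code{"gaussian"}, \code{"cosine"},
#'   \code{"structural"}, \code{"functional"}.
#' @return object of class \code{mda_similarity} wrapping \code{values}.
#' @export
similarity_matrix <- function(values,
                              entity = c("drug", "microbe"),
                              measure = c("gaussian", "cosine",
                                          "structural", "functional")) {
  entity <- match.arg(entity)
  measure <- match.arg(measure)
  if (!is_square(values)) {
    stop_mdassoc("similarity values must be a square matrix",
                 "mdassoc_validation_error")
  }
  if (any(!is.finite(values))) {
    stop_mdassoc("similarity values must be finite", "mdassoc_validation_error")
  }
  if (max(abs(values - t(values))) > 1e-10) {
    stop_mdassoc("similarity matrix is asymmetric beyond 1e-10",
                 "mdassoc_validation_error")
  }
  if (min(values) < 0 || max(values) > 1) {
    stop_mdassoc("similarity values outside [0, 1]", "mdassoc_validation_error")
  }
  structure(list(values = values, entity = entity, measure = measure),
            class = "mda_similarity")
}

#' @export
print.mda_similarity <- function(x, ...) {
  cat("<mda_similarity> ", x$entity, "/", x$measure, ", ",
      nrow(x$values), "x", ncol(x$values), "\n", sep = "")
  invisible(x)
}

profiles_along <- function(S, axis) {
  # rows: drug interaction profiles Rs(i); columns: microbe profiles Cs(i),
  # handled as rows of t(S) so both cases share one code path
  if (axis == "rows") S else t(S)
}

#' Gaussian interaction-profile kernel similarity
#'
#' Computes \code{exp(-mu * ||p_i - p_j||^2)} between the binary interaction
#' profiles of two entities, with the kernel bandwidth \code{mu} set to the
#' reciprocal of the mean squared profile norm:
#' \code{mu = 1 / (mean_i ||p_i||^2)}. Profiles are the rows of \code{S} for
#' drugs (\code{axis = "rows"}) and the columns for microbes
#' (\code{axis = "columns"}).
#'
#' @param S binary adjacency matrix (drugs x microbes).
#' @param axis \code{"rows"} (drug profiles) or \code{"columns"} (microbe
#'   profiles).
#' @return \code{mda_similarity} with measure \code{"gaussian"}; symmetric,
#'   unit diagonal, entries in (0, 1].
#' @export
gaussian_kernel_similarity <- function(S, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(S))
  P <- profiles_along(S, axis)
  sq <- rowSums(P^2)
  denom <- mean(sq)
  if (denom == 0) {
    stop_mdassoc("bandwidth undefined: adjacency matrix has no associations",
                 "mdassoc_numeric_error")
  }
  mu <- 1 / denom
  # ||p_i - p_j||^2 = ||p_i||^2 + ||p_j||^2 - 2 p_i . p_j
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
  d2[d2 < 0] <- 0  # guard tiny negative rounding
  G <- exp(-mu * d2)
  G <- (G + t(G)) / 2
  diag(G) <- 1
  dimnames(G) <- list(rownames(P), rownames(P))
  similarity_matrix(G, entity = if (axis == "rows") "drug" else "microbe",
                    measure = "gaussian")
}

#' Cosine similarity of interaction profiles
#'
#' \code{p_i . p_j / (||p_i|| ||p_j||)}. Any pair involving an all-zero
#' profile -- an entity with no known associations -- is assigned similarity
#' 0, including that entity's own diagonal: an isolated node carries no
#' profile evidence.
#'
#' @inheritParams gaussian_kernel_similarity
#' @return \code{mda_similarity} with measure \code{"cosine"}; entries in
#'   [0, 1] for binary input.
#' @export
cosine_similarity <- function(S, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(S))
  P <- profiles_along(S, axis)
  nrm <- sqrt(rowSums(P^2))
  dots <- tcrossprod(P)
  denom <- outer(nrm, nrm)
  C <- matrix(0, nrow(P), nrow(P))
  nz <- denom > 0
  C[nz] <- dots[nz] / denom[nz]
  C[C > 1] <- 1  # rounding guard
  C[C < 0] <- 0
  C <- (C + t(C)) / 2
  diag(C)[nrm > 0] <- 1
  dimnames(C) <- list(rownames(P), rownames(P))
  similarity_matrix(C, entity = if (axis == "rows") "drug" else "microbe",
                    measure = "cosine")
}

#' Write a similarity matrix as labeled CSV
#' @param sim \code{mda_similarity}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_similarity <- function(sim, path) {
  stopifnot(inherits(sim, "mda_similarity"))
  utils::write.csv(sim$values, path, row.names = TRUE)
  invisible(path)
}
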