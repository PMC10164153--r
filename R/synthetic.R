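#' Specification for a synthetic association dataset
#'
#' Planted co-cluster (stochastic block) model of a sparse bipartite
#' association matrix: drugs and microbes are partitioned into blocks, a
#' pair inside a co-cluster associates with probability
#' \code{within_block_prob}, any other pair with \code{background_prob},
#' and every cell is then flipped independently with
#' \code{noise_flip_prob}.
#'
#' @param n_drugs,n_microbes entity counts.
#' @param n_blocks number of co-clusters.
#' @param within_block_prob association probability inside a co-cluster.
#' @param background_prob association probability elsewhere; must be below
#'   \code{within_block_prob} so planted signal exists.
#' @param noise_flip_prob independent flip probability applied after
#'   planting.
#' @param seed RNG seed.
#' @return list of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_drugs = 200, n_microbes = 60, n_blocks = 4,
                           within_block_prob = 0.3, background_prob = 0.01,
                           noise_flip_prob = 0, seed = 1) {
  stopifnot(n_drugs >= 1, n_microbes >= 1, n_blocks >= 1,
            within_block_prob > 0, within_block_prob <= 1,
            background_prob >= 0, background_prob < 1,
            noise_flip_prob >= 0, noise_flip_prob < 1)
  if (within_block_prob <= background_prob) {
    stop_mdassoc("within_block_prob must exceed background_prob",
                 "mdassoc_validation_error")
  }
  structure(list(n_drugs = as.integer(n_drugs),
                 n_microbes = as.integer(n_microbes),
                 n_blocks = as.integer(n_blocks),
                 within_block_prob = within_block_prob,
                 background_prob = background_prob,
                 noise_flip_prob = noise_flip_prob,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic association dataset with planted block structure
#'
#' @param spec \code{synthetic_spec}.
#' @return list: \code{dataset} (\code{mda_dataset}), \code{drug_blocks},
#'   \code{microbe_blocks} (integer block labels in entity order),
#'   \code{spec}.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nd <- spec$n_drugs; nm <- spec$n_microbes; nb <- spec$n_blocks
  # zero-padded ids sort lexicographically in construction order
  drug_ids <- sprintf("drug%0*d", nchar(nd), seq_len(nd))
  microbe_ids <- sprintf("microbe%0*d", nchar(nm), seq_len(nm))
  with_seed(spec$seed, {
    drug_blocks <- sample(rep_len(seq_len(nb), nd))
    microbe_blocks <- sample(rep_len(seq_len(nb), nm))
    same <- outer(drug_blocks, microbe_blocks, "==")
    p <- ifelse(same, spec$within_block_prob, spec$background_prob)
    expected <- sum(p)
    if (expected == 0) {
      stop_mdassoc("expected positive count is zero under this spec",
                   "mdassoc_validation_error")
    }
    S <- matrix(as.numeric(stats::rbinom(nd * nm, 1, as.vector(p))), nd, nm)
    if (spec$noise_flip_prob > 0) {
      flip <- matrix(stats::rbinom(nd * nm, 1, spec$noise_flip_prob), nd, nm)
      S <- abs(S - flip)
    }
    if (sum(S) == 0) {
      stop_mdassoc("generated dataset has no associations; raise the rates",
                   "mdassoc_validation_error")
    }
    dimnames(S) <- list(drug_ids, microbe_ids)
    dataset <- structure(list(drug_ids = drug_ids, microbe_ids = microbe_ids,
                              S = S),
                         class = "mda_dataset")
    list(dataset = dataset, drug_blocks = drug_blocks,
         microbe_blocks = microbe_blocks, spec = spec)
  })
}

#' Synthetic stand-ins for external similarity matrices
#'
#' Builds synthetic drug structural and microbe functional similarity
#' matrices from the planted block labels: the exact block indicator (1
#' within a block, 0 across) mixed convexly with symmetric uniform noise,
#' \code{reliability * indicator + (1 - reliability) * noise}; diagonal set
#' to 1. At reliability 1 the matrices carry perfect block information, at
#' 0 none.
#'
#' @param drug_blocks,microbe_blocks integer block labels from
#'   [generate_synthetic()].
#' @param reliability mixing weight in [0, 1].
#' @param seed RNG seed for the noise.
#' @return list with \code{Sr} (drug, measure \code{"structural"}) and
#'   \code{Fm} (microbe, measure \code{"functional"}), both
#'   \code{mda_similarity}.
#' @export
make_external_similarities <- function(drug_blocks, microbe_blocks,
                                       reliability = 0.9, seed = 1) {
  stopifnot(reliability >= 0, reliability <= 1)
  mk <- function(blocks, entity, measure, s) {
    n <- length(blocks)
    ind <- outer(blocks, blocks, "==") * 1
    noise <- with_seed(s, {
      U <- matrix(stats::runif(n * n), n, n)
      (U + t(U)) / 2
    })
    V <- reliability * ind + (1 - reliability) * noise
    diag(V) <- 1
    similarity_matrix(V, entity = entity, measure = measure)
  }
  list(Sr = mk(drug_blocks, "drug", "structural", seed),
       Fm = mk(microbe_blocks, "microbe", "functional", seed + 1L))
}
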