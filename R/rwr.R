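#' Restart random walk configuration
#'
#' @param restart_lambda walk/restart mixing weight in [0, 1); default 0.1.
#'   As written, the update is \code{q <- lambda * M q + (1 - lambda) * e},
#'   i.e. \code{lambda} weights the walk term. Set \code{swap_lambda = TRUE}
#'   for the conventional reading in which \code{lambda} is the restart mass
#'   on \code{e}.
#' @param max_iter iteration cap; default 1000.
#' @param tol L1 convergence threshold on successive iterates; default 1e-6.
#' @param normalization \code{"column"} (default; walk steps push probability
#'   along columns) or \code{"row"}.
#' @param swap_lambda see \code{restart_lambda}.
#' @return list of class \code{rwr_config}.
#' @export
rwr_config <- function(restart_lambda = 0.1, max_iter = 1000, tol = 1e-6,
                       normalization = c("column", "row"),
                       swap_lambda = FALSE) {
  normalization <- match.arg(normalization)
  stopifnot(restart_lambda >= 0, restart_lambda < 1, max_iter >= 1, tol > 0)
  structure(list(restart_lambda = restart_lambda, max_iter = max_iter,
                 tol = tol, normalization = normalization,
                 swap_lambda = swap_lambda),
            class = "rwr_config")
}

#' Normalize a similarity matrix into a transition probability matrix
#'
#' @param G \code{mda_similarity} or nonnegative square matrix.
#' @param normalization \code{"column"} or \code{"row"}: which margin sums
#'   to one.
#' @return square matrix whose chosen margin sums to 1 within 1e-12.
#' @export
transition_matrix <- function(G, normalization = c("column", "row")) {
  normalization <- match.arg(normalization)
  V <- if (inherits(G, "mda_similarity")) G$values else G
  stopifnot(is_square(V))
  if (min(V) < 0) {
    stop_mdassoc("similarity must be nonnegative", "mdassoc_validation_error")
  }
  margins <- if (normalization == "column") colSums(V) else rowSums(V)
  if (any(margins == 0)) {
    stop_mdassoc(paste0("all-zero ", substr(normalization, 1, 3),
                        " in similarity; transition matrix undefined"),
                 "mdassoc_numeric_error")
  }
  if (normalization == "column") {
    sweep(V, 2, margins, "/")
  } else {
    V / margins
  }
}

#' Diffusion profiles by restart random walk
#'
#' Iterates \code{q_i <- lambda * M q_i + (1 - lambda) * e_i} for every node
#' jointly (all unit-basis restarts as one matrix iteration, identical to
#' per-node iteration by linearity) until the largest per-node L1 change
#' falls below \code{cfg$tol}. The fixed point is the closed form
#' \code{q_i = (1 - lambda) (I - lambda M)^{-1} e_i}.
#'
#' @param M stochastic matrix from [transition_matrix()].
#' @param cfg \code{rwr_config}.
#' @param entity \code{"drug"} or \code{"microbe"} tag.
#' @return object of class \code{mda_profile}: list with \code{values}
#'   (square matrix, row i = converged profile of node i), \code{entity},
#'   \code{iterations}, \code{converged}.
#' @export
rwr_profile <- function(M, cfg = rwr_config(), entity = c("drug", "microbe")) {
  entity <- match.arg(entity)
  stopifnot(is_square(M))
  lam <- cfg$restart_lambda
  walk_w <- if (cfg$swap_lambda) 1 - lam else lam
  restart_w <- 1 - walk_w
  n <- nrow(M)
  Q <- diag(n)            # columns are q_i, started at e_i
  E <- diag(n)
  converged <- FALSE
  iters <- 0L
  for (l in seq_len(cfg$max_iter)) {
    Qn <- walk_w * (M %*% Q) + restart_w * E
    delta <- max(colSums(abs(Qn - Q)))
    Q <- Qn
    iters <- l
    if (delta < cfg$tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("restart random walk did not converge in ", cfg$max_iter,
            " iterations; returning last iterate", call. = FALSE)
  }
  vals <- t(Q)            # row i is node i's profile
  dimnames(vals) <- dimnames(M)
  structure(list(values = vals, entity = entity, iterations = iters,
                 converged = converged),
            class = "mda_profile")
}

#' Closed-form diffusion profiles
#'
#' Dense linear solve of the restart random walk fixed point,
#' \code{(1 - w) (I - w M)^{-1}} with \code{w} the walk weight; used as the
#' reference against which the iterative solver is checked.
#'
#' @inheritParams rwr_profile
#' @return matrix, row i = profile of node i.
#' @export
rwr_closed_form <- function(M, cfg = rwr_config()) {
  stopifnot(is_square(M))
  lam <- cfg$restart_lambda
  walk_w <- if (cfg$swap_lambda) 1 - lam else lam
  n <- nrow(M)
  Q <- (1 - walk_w) * solve(diag(n) - walk_w * M)
  t(Q)
}

#' @export
print.mda_profile <- function(x, ...) {
  cat("<mda_profile> ", x$entity, ", ", nrow(x$values), " nodes, ",
      x$iterations, " iterations",
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  invisible(x)
}
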