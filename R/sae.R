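#' Stacked-autoencoder configuration
#'
#' Defaults follow the model's tuned operating point: three stacked
#' autoencoders with hidden widths 128/64/32, four attention heads and Adam
#' at learning rate 0.01.
#'
#' @param hidden_sizes integer vector of encoder widths, one per stacked
#'   autoencoder (innermost last).
#' @param heads number of self-attention heads.
#' @param learning_rate Adam step size.
#' @param epochs end-to-end fine-tuning epochs (full-batch).
#' @param pretrain_epochs greedy layer-wise pretraining epochs per layer.
#' @param seed integer seed fixing weight initialization; \code{NULL} leaves
#'   the session RNG in charge.
#' @param use_attention attach the multi-head attention block to the output
#'   layer (\code{FALSE} gives the plain-SAE ablation arm).
#' @param hidden_activation,output_activation \code{"relu"} /
#'   \code{"sigmoid"} / \code{"identity"}. The sigmoid output matches the
#'   [0, 1] range of similarity inputs.
#' @return list of class \code{sae_config}; \code{n_stacked} is the length
#'   of \code{hidden_sizes}.
#' @export
sae_config <- function(hidden_sizes = c(128, 64, 32), heads = 4,
                       learning_rate = 0.01, epochs = 200,
                       pretrain_epochs = 50, seed = NULL,
                       use_attention = TRUE,
                       hidden_activation = "relu",
                       output_activation = "sigmoid") {
  stopifnot(length(hidden_sizes) >= 1, all(hidden_sizes >= 1),
            heads >= 1, learning_rate > 0, epochs >= 1, pretrain_epochs >= 0)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 n_stacked = length(hidden_sizes),
                 heads = as.integer(heads),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 seed = seed, use_attention = isTRUE(use_attention),
                 hidden_activation = hidden_activation,
                 output_activation = output_activation),
            class = "sae_config")
}

activate <- function(Z, act) {
  switch(act,
         relu = relu(Z),
         sigmoid = logistic(Z),
         identity = Z,
         stop_mdassoc(paste0("unknown activation: ", act)))
}

activate_grad <- function(Z, A, act) {
  # derivative wrt pre-activation, using cached Z (pre) and A (post)
  switch(act,
         relu = (Z > 0) * 1,
         sigmoid = A * (1 - A),
         identity = array(1, dim(Z)),
         stop_mdassoc(paste0("unknown activation: ", act)))
}

glorot <- function(n_in, n_out) {
  limit <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -limit, limit), n_in, n_out)
}

#' Build an untrained stacked autoencoder
#'
#' Lays out \code{n_stacked} encoder/decoder pairs (encoder i maps
#' \code{d[i-1] -> hidden_sizes[i]}, decoders mirror back to the input
#' dimension) plus, when \code{cfg$use_attention}, a multi-head
#' self-attention block applied to the final decoder output with a residual
#' connection. Weights are Glorot-uniform, biases zero, all drawn under
#' \code{cfg$seed}.
#'
#' @param input_dim number of input features (= number of nodes for a
#'   square similarity input).
#' @param cfg \code{sae_config}.
#' @return list of class \code{sae_model} holding parameter matrices and
#'   layer dimensions.
#' @export
build_sae <- function(input_dim, cfg = sae_config()) {
  stopifnot(input_dim >= 1)
  if (any(cfg$hidden_sizes > input_dim)) {
    warning("hidden layer wider than input (", input_dim,
            "): over-complete autoencoder", call. = FALSE)
  }
  dims <- c(input_dim, cfg$hidden_sizes)
  L <- cfg$n_stacked
  with_seed(cfg$seed, {
    enc <- lapply(seq_len(L), function(i) {
      list(W = glorot(dims[i], dims[i + 1]), b = numeric(dims[i + 1]))
    })
    # decoder i maps dims[L + 2 - i] -> dims[L + 1 - i]; last emits input_dim
    dec <- lapply(seq_len(L), function(i) {
      list(W = glorot(dims[L + 2 - i], dims[L + 1 - i]),
           b = numeric(dims[L + 1 - i]),
           act = if (i == L) cfg$output_activation else cfg$hidden_activation)
    })
    att <- if (cfg$use_attention) mha_init(input_dim, cfg$heads) else NULL
    structure(list(enc = enc, dec = dec, attention = att, dims = dims,
                   input_dim = input_dim, cfg = cfg),
              class = "sae_model")
  })
}

# ---- multi-head self-attention -------------------------------------------

mha_init <- function(d, heads) {
  dp <- as.integer(ceiling(d / heads) * heads)
  if (dp != d) {
    msg_info("attention dimension ", d, " padded to ", dp, " for ", heads,
             " heads (truncated after output projection)")
  }
  list(Wq = glorot(d, dp), Wk = glorot(d, dp), Wv = glorot(d, dp),
       Wo = glorot(dp, d), heads = as.integer(heads), d = as.integer(d),
       dp = dp, dk = dp %/% heads)
}

softmax_rows <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

mha_forward <- function(H, p) {
  Q <- H %*% p$Wq; K <- H %*% p$Wk; V <- H %*% p$Wv
  n <- nrow(H)
  O <- matrix(0, n, p$dp)
  A_list <- vector("list", p$heads)
  for (h in seq_len(p$heads)) {
    idx <- ((h - 1) * p$dk + 1):(h * p$dk)
    A <- softmax_rows(tcrossprod(Q[, idx, drop = FALSE],
                                 K[, idx, drop = FALSE]) / sqrt(p$dk))
    A_list[[h]] <- A
    O[, idx] <- A %*% V[, idx, drop = FALSE]
  }
  out <- H + O %*% p$Wo
  list(out = out, cache = list(H = H, Q = Q, K = K, V = V, O = O, A = A_list))
}

mha_backward <- function(dOut, p, cache) {
  H <- cache$H
  dH <- dOut                      # residual path
  dWo <- crossprod(cache$O, dOut)
  dO <- dOut %*% t(p$Wo)
  dQ <- matrix(0, nrow(H), p$dp)
  dK <- matrix(0, nrow(H), p$dp)
  dV <- matrix(0, nrow(H), p$dp)
  for (h in seq_len(p$heads)) {
    idx <- ((h - 1) * p$dk + 1):(h * p$dk)
    A <- cache$A[[h]]
    dOh <- dO[, idx, drop = FALSE]
    Vh <- cache$V[, idx, drop = FALSE]
    dA <- tcrossprod(dOh, Vh)
    dV[, idx] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(dA * A))          # softmax Jacobian, row-wise
    dS <- dS / sqrt(p$dk)
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE]
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE])
  }
  dH <- dH + dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(dH = dH, grads = list(Wq = crossprod(H, dQ), Wk = crossprod(H, dK),
                             Wv = crossprod(H, dV), Wo = dWo))
}

#' Multi-head self-attention over node feature rows
#'
#' Standard scaled dot-product self-attention where each node's feature row
#' is one token: per head, queries/keys/values are learned linear maps of
#' width \code{d/heads} (zero-padded to the next multiple when \code{d} is
#' not divisible), head outputs are concatenated, projected back to
#' \code{d}, and added residually to the input.
#'
#' @param H numeric matrix (nodes x features).
#' @param heads number of heads.
#' @param params optional parameter list from a trained model; freshly
#'   initialized under \code{seed} when \code{NULL}.
#' @param seed RNG seed for fresh initialization.
#' @param return_weights also return the per-head attention weight matrices
#'   (rows sum to 1).
#' @return matrix of the same shape as \code{H}, or a list with elements
#'   \code{out} and \code{weights} when \code{return_weights}.
#' @export
multi_head_attention <- function(H, heads = 4, params = NULL, seed = NULL,
                                 return_weights = FALSE) {
  stopifnot(is.matrix(H), heads >= 1)
  if (is.null(params)) params <- with_seed(seed, mha_init(ncol(H), heads))
  fw <- mha_forward(H, params)
  if (return_weights) list(out = fw$out, weights = fw$cache$A) else fw$out
}

# ---- Adam ----------------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- full-stack forward / backward ---------------------------------------

# Flatten model parameters into a named list for the optimizer.
sae_params_flatten <- function(model) {
  out <- list()
  for (i in seq_along(model$enc)) {
    out[[paste0("eW", i)]] <- model$enc[[i]]$W
    out[[paste0("eb", i)]] <- model$enc[[i]]$b
  }
  for (i in seq_along(model$dec)) {
    out[[paste0("dW", i)]] <- model$dec[[i]]$W
    out[[paste0("db", i)]] <- model$dec[[i]]$b
  }
  if (!is.null(model$attention)) {
    for (k in c("Wq", "Wk", "Wv", "Wo")) out[[paste0("a", k)]] <- model$attention[[k]]
  }
  out
}

sae_params_unflatten <- function(model, flat) {
  for (i in seq_along(model$enc)) {
    model$enc[[i]]$W <- flat[[paste0("eW", i)]]
    model$enc[[i]]$b <- flat[[paste0("eb", i)]]
  }
  for (i in seq_along(model$dec)) {
    model$dec[[i]]$W <- flat[[paste0("dW", i)]]
    model$dec[[i]]$b <- flat[[paste0("db", i)]]
  }
  if (!is.null(model$attention)) {
    for (k in c("Wq", "Wk", "Wv", "Wo")) model$attention[[k]] <- flat[[paste0("a", k)]]
  }
  model
}

#' Forward pass of a stacked autoencoder
#'
#' @param model \code{sae_model}.
#' @param X input matrix (rows are node samples).
#' @return list: \code{output} (reconstruction, post-attention), \code{loss}
#'   (mean squared reconstruction error against \code{X}), plus internal
#'   caches.
#' @export
sae_forward <- function(model, X) {
  cfg <- model$cfg
  L <- cfg$n_stacked
  H <- X
  enc_cache <- vector("list", L)
  for (i in seq_len(L)) {
    Z <- sweep(H %*% model$enc[[i]]$W, 2, model$enc[[i]]$b, "+")
    A <- activate(Z, cfg$hidden_activation)
    enc_cache[[i]] <- list(input = H, Z = Z, A = A)
    H <- A
  }
  dec_cache <- vector("list", L)
  for (i in seq_len(L)) {
    Z <- sweep(H %*% model$dec[[i]]$W, 2, model$dec[[i]]$b, "+")
    A <- activate(Z, model$dec[[i]]$act)
    dec_cache[[i]] <- list(input = H, Z = Z, A = A)
    H <- A
  }
  att_cache <- NULL
  out <- H
  if (!is.null(model$attention)) {
    fw <- mha_forward(H, model$attention)
    out <- fw$out
    att_cache <- fw$cache
  }
  loss <- mean((X - out)^2)
  list(output = out, loss = loss,
       enc_cache = enc_cache, dec_cache = dec_cache, att_cache = att_cache)
}

sae_backward <- function(model, X, fw) {
  cfg <- model$cfg
  L <- cfg$n_stacked
  grads <- list()
  dOut <- 2 * (fw$output - X) / length(X)
  if (!is.null(model$attention)) {
    bk <- mha_backward(dOut, model$attention, fw$att_cache)
    dH <- bk$dH
    for (k in c("Wq", "Wk", "Wv", "Wo")) grads[[paste0("a", k)]] <- bk$grads[[k]]
  } else {
    dH <- dOut
  }
  for (i in rev(seq_len(L))) {
    cc <- fw$dec_cache[[i]]
    dZ <- dH * activate_grad(cc$Z, cc$A, model$dec[[i]]$act)
    grads[[paste0("dW", i)]] <- crossprod(cc$input, dZ)
    grads[[paste0("db", i)]] <- colSums(dZ)
    dH <- dZ %*% t(model$dec[[i]]$W)
  }
  for (i in rev(seq_len(L))) {
    cc <- fw$enc_cache[[i]]
    dZ <- dH * activate_grad(cc$Z, cc$A, cfg$hidden_activation)
    grads[[paste0("eW", i)]] <- crossprod(cc$input, dZ)
    grads[[paste0("eb", i)]] <- colSums(dZ)
    dH <- dZ %*% t(model$enc[[i]]$W)
  }
  grads
}

# Train one autoencoder (W_e, b_e, W_d, b_d) on target T for greedy
# layer-wise pretraining. Returns updated weights.
pretrain_layer <- function(We, be, Wd, bd, Tmat, dec_act, hid_act,
                           epochs, lr) {
  params <- list(We = We, be = be, Wd = Wd, bd = bd)
  st <- adam_state(params)
  for (e in seq_len(epochs)) {
    Ze <- sweep(Tmat %*% params$We, 2, params$be, "+")
    Ae <- activate(Ze, hid_act)
    Zd <- sweep(Ae %*% params$Wd, 2, params$bd, "+")
    Ad <- activate(Zd, dec_act)
    dOut <- 2 * (Ad - Tmat) / length(Tmat)
    dZd <- dOut * activate_grad(Zd, Ad, dec_act)
    gWd <- crossprod(Ae, dZd); gbd <- colSums(dZd)
    dAe <- dZd %*% t(params$Wd)
    dZe <- dAe * activate_grad(Ze, Ae, hid_act)
    gWe <- crossprod(Tmat, dZe); gbe <- colSums(dZe)
    upd <- adam_step(params, list(We = gWe, be = gbe, Wd = gWd, bd = gbd),
                     st, lr)
    params <- upd$params; st <- upd$state
  }
  params
}

#' Train a stacked autoencoder with attention on a similarity matrix
#'
#' Two stages: (1) greedy layer-wise pretraining -- each autoencoder is
#' trained to reconstruct the previous encoder's output for
#' \code{pretrain_epochs}; (2) end-to-end fine-tuning of the full stack plus
#' the attention block for \code{epochs}, minimizing the squared
#' reconstruction error \code{||X - X'||^2} with full-batch Adam. The
#' returned attribute features are the final output-layer reconstruction
#' (post-attention), same shape as the input -- the shape the downstream
#' feature integration requires.
#'
#' @param X square similarity matrix (rows are node samples) or
#'   \code{mda_similarity}.
#' @param cfg \code{sae_config}.
#' @param entity \code{"drug"} or \code{"microbe"} tag carried to the output.
#' @param source_measure measure tag of the input similarity.
#' @return object of class \code{mda_features}: \code{values} (matrix, same
#'   shape as input), \code{loss_curve} (fine-tuning loss per epoch,
#'   element 1 = loss before the first update), \code{model}, \code{entity},
#'   \code{source_measure}.
#' @export
train_sae <- function(X, cfg = sae_config(), entity = c("drug", "microbe"),
                      source_measure = "cosine") {
  entity <- match.arg(entity)
  if (inherits(X, "mda_similarity")) {
    source_measure <- X$measure
    X <- X$values
  }
  stopifnot(is_square(X))
  model <- build_sae(ncol(X), cfg)

  # stage 1: greedy layer-wise pretraining (decoder i mirrors encoder L+1-i)
  if (cfg$pretrain_epochs > 0) {
    L <- cfg$n_stacked
    Tmat <- X
    for (i in seq_len(L)) {
      j <- L + 1 - i                       # mirrored decoder index
      p <- pretrain_layer(model$enc[[i]]$W, model$enc[[i]]$b,
                          model$dec[[j]]$W, model$dec[[j]]$b,
                          Tmat, dec_act = model$dec[[j]]$act,
                          hid_act = cfg$hidden_activation,
                          epochs = cfg$pretrain_epochs,
                          lr = cfg$learning_rate)
      model$enc[[i]]$W <- p$We; model$enc[[i]]$b <- p$be
      model$dec[[j]]$W <- p$Wd; model$dec[[j]]$b <- p$bd
      Tmat <- activate(sweep(Tmat %*% p$We, 2, p$be, "+"),
                       cfg$hidden_activation)
    }
  }

  # stage 2: end-to-end fine-tuning of stack + attention
  flat <- sae_params_flatten(model)
  st <- adam_state(flat)
  loss_curve <- numeric(cfg$epochs + 1L)
  fw <- sae_forward(model, X)
  loss_curve[1L] <- fw$loss
  for (e in seq_len(cfg$epochs)) {
    if (!is.finite(fw$loss)) {
      stop_mdassoc(paste0("non-finite reconstruction loss at epoch ", e - 1L,
                          "; try a lower learning_rate than ",
                          cfg$learning_rate), "mdassoc_numeric_error")
    }
    grads <- sae_backward(model, X, fw)
    upd <- adam_step(flat, grads, st, cfg$learning_rate)
    flat <- upd$params; st <- upd$state
    model <- sae_params_unflatten(model, flat)
    fw <- sae_forward(model, X)
    loss_curve[e + 1L] <- fw$loss
  }
  msg_info("SAE (", entity, "/", source_measure, "): loss ",
           signif(loss_curve[1L], 4), " -> ", signif(fw$loss, 4),
           " over ", cfg$epochs, " epochs")
  vals <- fw$output
  dimnames(vals) <- dimnames(X)
  structure(list(values = vals, entity = entity,
                 source_measure = source_measure,
                 loss_curve = loss_curve, model = model),
            class = "mda_features")
}

#' @export
print.mda_features <- function(x, ...) {
  cat("<mda_features> ", x$entity, "/", x$source_measure, ", ",
      nrow(x$values), "x", ncol(x$values), ", final loss ",
      signif(x$loss_curve[length(x$loss_curve)], 4), "\n", sep = "")
  invisible(x)
}
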