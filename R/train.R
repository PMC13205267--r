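#' Training configuration
#'
#' Collects every tunable of the joint objective and the optimization
#' loop. The loss for V views is
#' `sum_v [ (1/2n)||X^v - Xrec^v||_F^2 + alpha ||W1^v||_{2,1}
#'   + lambda1 ||Z^v - C^v Z^v||_F^2 + lambda2 ||C^v||_F^2
#'   + lambda3 ||A^v - C^v||_F^2 ] + tnn_weight * TNN(C') + beta * KL(P, S)`
#' where A^v is the hybrid motif/first-order graph, C' the rotated stack of
#' the symmetrized C^v and S the f1-normalized attention consensus.
#'
#' @param alpha weight of the L2,1 penalty on the first encoder layer.
#' @param lambda1 self-expression residual weight.
#' @param lambda2 Frobenius penalty on C^v.
#' @param lambda3 high-order alignment weight.
#' @param beta weight of the KL refinement term.
#' @param tnn_weight scale of the tensor nuclear-norm regularization (the
#'   threshold handed to [tsvt_prox()] and the strength of the quadratic
#'   pull toward the low-rank surrogate).
#' @param eta hybrid-similarity trade-off in [0, 1].
#' @param sigma Gaussian kernel bandwidth or `"auto"`.
#' @param p1,p2 encoder hidden widths (1024/512 for cohort-scale data;
#'   shrink for desk-scale runs).
#' @param pretrain_lr,train_lr Adam learning rates for the pretraining and
#'   joint phases (defaults 1e-4 and 1e-3).
#' @param pretrain_epochs,train_epochs epoch counts for the two phases.
#' @param prox_every epochs between refreshes of the tensor low-rank
#'   surrogate via [tsvt_prox()].
#' @param target_refresh epochs between recomputations of the self-training
#'   target P (held fixed in between).
#' @param leaky_slope LeakyReLU negative slope in the attention module.
#' @param graph_mode which graph anchors the alignment term:
#'   `"hybrid"`, `"first_order"` or `"motif"` (the similarity ablation).
#' @param seed integer seed controlling all randomness.
#' @return object of class `train_config`.
#' @export
train_config <- function(alpha = 0.01, lambda1 = 1, lambda2 = 1,
                         lambda3 = 1, beta = 0.1, tnn_weight = 0.1,
                         eta = 0.5, sigma = "auto",
                         p1 = 1024, p2 = 512,
                         pretrain_lr = 1e-4, train_lr = 1e-3,
                         pretrain_epochs = 50, train_epochs = 100,
                         prox_every = 10, target_refresh = 10,
                         leaky_slope = 0.01,
                         graph_mode = c("hybrid", "first_order", "motif"),
                         seed = 1) {
  graph_mode <- match.arg(graph_mode)
  if (pretrain_epochs < 1 || train_epochs < 1) stop("epochs must be >= 1")
  if (pretrain_lr <= 0 || train_lr <= 0) stop("learning rates must be positive")
  if (any(c(alpha, lambda1, lambda2, lambda3, beta, tnn_weight) < 0))
    stop("loss weights must be nonnegative")
  structure(as.list(environment()), class = "train_config")
}

view_params <- function(state) {
  state[c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")]
}

set_view_params <- function(state, params) {
  state[names(params)] <- params
  state
}

#' Pretrain the per-view autoencoders
#'
#' Minimizes reconstruction + L2,1 only (no self-expression) per view with
#' full-batch Adam at `pretrain_lr`. Deterministic given `config$seed`.
#'
#' @param dataset an aligned [multi_omics_dataset()].
#' @param config a [train_config()].
#' @return list of `encoder_state` objects, one per view, with an attached
#'   `pretrain_loss` trace (matrix epoch x view).
#' @export
pretrain <- function(dataset, config) {
  stopifnot(inherits(dataset, "multi_omics_dataset"),
            inherits(config, "train_config"))
  # each view's weights are drawn from the same seeded stream, so views
  # with identical data (and dims) start identically and the objective's
  # symmetry under view exchange is preserved exactly
  states <- lapply(dataset$views, function(v) {
    set.seed(config$seed)
    init_encoder_state(ncol(v$values), config$p1, config$p2)
  })
  loss_trace <- matrix(NA_real_, config$pretrain_epochs, length(states))
  colnames(loss_trace) <- names(dataset$views)
  for (v in seq_along(states)) {
    X <- dataset$views[[v]]$values
    n <- nrow(X)
    params <- view_params(states[[v]])
    opt <- adam_init(params)
    for (ep in seq_len(config$pretrain_epochs)) {
      st <- set_view_params(states[[v]], params)
      fwd <- encode_decode(X, st, C = NULL)
      loss <- reconstruction_loss(X, fwd$Xrec, n) +
        config$alpha * l21_norm(st$W1)
      if (!is.finite(loss))
        stop("pretraining diverged at epoch ", ep, " (view ", v, ")")
      loss_trace[ep, v] <- loss
      grads <- backprop_view(X, st, fwd, config$alpha, n, C = NULL)
      stepped <- adam_step(params, grads[names(params)], opt,
                           config$pretrain_lr)
      params <- stepped$params
      opt <- stepped$opt
    }
    states[[v]] <- set_view_params(states[[v]], params)
  }
  attr(states, "pretrain_loss") <- loss_trace
  states
}

# Evaluate every term of the joint objective from current state.
# Returns a named numeric vector; `total` is their sum.
joint_loss_terms <- function(Xs, states, Cs, A_list, att_W, P, config) {
  V <- length(Xs)
  recon <- l21 <- selfe <- cfrob <- align <- 0
  Zs <- vector("list", V)
  Csym <- lapply(Cs, symmetrize_affinity)
  for (v in seq_len(V)) {
    fwd <- encode_decode(Xs[[v]], states[[v]], C = Cs[[v]])
    Zs[[v]] <- fwd$Z
    n <- nrow(Xs[[v]])
    recon <- recon + reconstruction_loss(Xs[[v]], fwd$Xrec, n)
    l21 <- l21 + config$alpha * l21_norm(states[[v]]$W1)
    selfe <- selfe + config$lambda1 * sum((fwd$Z - Cs[[v]] %*% fwd$Z)^2)
    cfrob <- cfrob + config$lambda2 * sum(Cs[[v]]^2)
    align <- align + config$lambda3 * sum((A_list[[v]] - Cs[[v]])^2)
  }
  tnn <- if (config$tnn_weight > 0)
    config$tnn_weight * tensor_nuclear_norm(stack_and_rotate(Csym)) else 0
  kl <- if (config$beta > 0 && !is.null(P)) {
    att <- attention_weights(Csym, att_W, slope = config$leaky_slope)
    cons <- normalize_f1(fuse_graphs(Csym, att))
    config$beta * kl_refinement(P, cons)
  } else 0
  terms <- c(reconstruction = recon, l21 = l21, self_expression = selfe,
             c_frobenius = cfrob, alignment = align, tnn = tnn, kl = kl)
  c(terms, total = sum(terms))
}

#' Jointly train the similarity graphs and fuse them
#'
#' Runs the full joint phase: per epoch, one full-batch Adam step on the
#' encoder/decoder weights, the self-expressive matrices C^v (zero
#' diagonal enforced) and the attention weight matrix against the smooth
#' terms; the self-training target P is refreshed every `target_refresh`
#' epochs; and every `prox_every` epochs the rotated stack of symmetrized
#' C^v is passed through [tsvt_prox()] to refresh a low-rank surrogate
#' toward which each C^v is quadratically pulled (realizing the tensor
#' nuclear-norm constraint by inexact proximal regularization).
#'
#' @param dataset an aligned [multi_omics_dataset()].
#' @param config a [train_config()].
#' @param states pretrained encoder states (from [pretrain()]); computed
#'   on the fly when `NULL`.
#' @param graphs precomputed per-view graph constructions (from
#'   [build_view_graph()], one per view); computed on the fly when `NULL`.
#' @return object of class `mhsgtr_fit` with elements `C` (raw
#'   self-expressive matrices), `C_sym` (symmetrized affinities), `CF`,
#'   `S_cons`, `attention` (N x V weights), `trace` (per-epoch loss terms),
#'   `states`, `graphs`, `config`.
#' @export
mhsgtr_fit <- function(dataset, config = train_config(), states = NULL,
                       graphs = NULL) {
  stopifnot(inherits(dataset, "multi_omics_dataset"),
            inherits(config, "train_config"))
  if (is.null(states)) states <- pretrain(dataset, config)
  if (is.null(graphs)) {
    graphs <- lapply(dataset$views, function(v)
      build_view_graph(v$values, sigma = config$sigma, eta = config$eta,
                       mode = config$graph_mode))
  }
  Xs <- lapply(dataset$views, function(v) v$values)
  V <- length(Xs)
  n <- nrow(Xs[[1]])
  A_list <- lapply(graphs, function(g) {
    A <- g$A
    diag(A) <- 0  # C^v has zero diagonal; align off-diagonal structure only
    A
  })
  set.seed(config$seed + 1L)
  # warm-start C^v at the (zero-diagonal) anchor graph when the alignment
  # term is active; cold-start at zero otherwise (pure self-expression)
  Cs <- if (config$lambda3 > 0) lapply(A_list, identity)
        else lapply(A_list, function(a) a * 0)
  att_W <- matrix(1, n * V, V)
  params <- list()
  for (v in seq_len(V)) {
    pv <- view_params(states[[v]])
    names(pv) <- paste0(names(pv), "_v", v)
    params <- c(params, pv)
    params[[paste0("C_v", v)]] <- Cs[[v]]
  }
  params$att_W <- att_W
  opt <- adam_init(params)
  L_surr <- NULL   # low-rank surrogate slices
  P <- NULL
  trace <- matrix(NA_real_, config$train_epochs, 8)
  colnames(trace) <- c("reconstruction", "l21", "self_expression",
                       "c_frobenius", "alignment", "tnn", "kl", "total")
  get_C <- function(params, v) params[[paste0("C_v", v)]]
  for (ep in seq_len(config$train_epochs)) {
    Cs <- lapply(seq_len(V), function(v) get_C(params, v))
    Csym <- lapply(Cs, symmetrize_affinity)
    for (v in seq_len(V))
      states[[v]] <- set_view_params(
        states[[v]],
        stats::setNames(params[paste0(
          c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4"), "_v", v)],
          c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")))
    # refresh the tensor low-rank surrogate
    if (config$tnn_weight > 0 &&
        (ep == 1 || (ep - 1) %% config$prox_every == 0)) {
      L_surr <- unrotate(tsvt_prox(stack_and_rotate(Csym),
                                   tau = config$tnn_weight))
    }
    # refresh the self-training target
    if (config$beta > 0) {
      att <- attention_weights(Csym, params$att_W, slope = config$leaky_slope)
      cons <- normalize_f1(fuse_graphs(Csym, att))
      if (ep == 1 || (ep - 1) %% config$target_refresh == 0)
        P <- target_distribution_f2(cons)
    }
    # ---- gradients ----
    grads <- vector("list", length(params))
    names(grads) <- names(params)
    # KL chain: dKL/dCF -> per-view symmetrized graphs + attention weights
    dCsym <- lapply(seq_len(V), function(v) matrix(0, n, n))
    if (config$beta > 0) {
      DCF <- kl_grad_wrt_cf(P, cons, config$beta)
      fb <- fusion_backprop(DCF, Csym, att)
      dCsym <- fb$dGraphs
      grads$att_W <- fb$dW
    } else {
      grads$att_W <- matrix(0, n * V, V)
    }
    for (v in seq_len(V)) {
      X <- Xs[[v]]
      C <- Cs[[v]]
      st <- states[[v]]
      fwd <- encode_decode(X, st, C = C)
      E <- fwd$Z - C %*% fwd$Z
      dZ_extra <- 2 * config$lambda1 * (E - t(C) %*% E)
      g <- backprop_view(X, st, fwd, config$alpha, nrow(X), C = C,
                         dZ_extra = dZ_extra)
      dC <- g$dC -
        2 * config$lambda1 * E %*% t(fwd$Z) +
        2 * config$lambda2 * C -
        2 * config$lambda3 * (A_list[[v]] - C)
      if (config$tnn_weight > 0)
        dC <- dC + 2 * config$tnn_weight * (C - L_surr[[v]])
      # chain the KL gradient through Csym = (|C| + |C^T|)/2
      Dv <- dCsym[[v]]
      dC <- dC + sign(C) * (Dv + t(Dv)) / 2
      diag(dC) <- 0
      for (nm in c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4"))
        grads[[paste0(nm, "_v", v)]] <- g[[nm]]
      grads[[paste0("C_v", v)]] <- dC
    }
    stepped <- adam_step(params, grads, opt, config$train_lr)
    params <- stepped$params
    opt <- stepped$opt
    for (v in seq_len(V)) {
      Cv <- params[[paste0("C_v", v)]]
      diag(Cv) <- 0
      params[[paste0("C_v", v)]] <- Cv
    }
    # bookkeeping: every objective term at the post-step state, against the
    # target P in effect this epoch (so the last row is recomputable from
    # the returned fit)
    Cs_post <- lapply(seq_len(V), function(v) get_C(params, v))
    states_post <- states
    for (v in seq_len(V))
      states_post[[v]] <- set_view_params(
        states_post[[v]],
        stats::setNames(params[paste0(
          c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4"), "_v", v)],
          c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")))
    terms <- joint_loss_terms(Xs, states_post, Cs_post, A_list,
                              params$att_W, P, config)
    if (!all(is.finite(terms)))
      stop("non-finite loss term at epoch ", ep)
    trace[ep, ] <- terms
  }
  # final artifacts
  Cs <- lapply(seq_len(V), function(v) get_C(params, v))
  Csym <- lapply(Cs, symmetrize_affinity)
  if (any(vapply(Csym, function(cc) any(rowSums(cc) == 0), logical(1))))
    warning("all-zero row in a learned affinity matrix")
  for (v in seq_len(V))
    states[[v]] <- set_view_params(
      states[[v]],
      stats::setNames(params[paste0(
        c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4"), "_v", v)],
        c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")))
  att <- attention_weights(Csym, params$att_W, slope = config$leaky_slope)
  CF <- fuse_graphs(Csym, att)
  cons <- normalize_f1(CF)
  ids <- dataset$views[[1]]$sample_ids
  dimnames(cons$S) <- dimnames(CF) <- list(ids, ids)
  rownames(att$weights) <- ids
  structure(list(
    C = Cs, C_sym = Csym, CF = CF, S_cons = cons$S,
    attention = att$weights, att_W = params$att_W,
    trace = trace, states = states, graphs = graphs,
    A = A_list, P = P, config = config
  ), class = "mhsgtr_fit")
}

#' Recompute the objective terms of a fitted model
#'
#' Re-evaluates every term of the joint objective from the state stored in
#' a fit (encoder weights, C matrices, attention weights, target P). The
#' result matches the final row of `fit$trace`, which guards against
#' silent drift between the logged trace and the optimized objective.
#'
#' @param fit an `mhsgtr_fit`.
#' @param dataset the dataset the fit was trained on.
#' @return named numeric vector of loss terms plus their `total`.
#' @export
loss_terms <- function(fit, dataset) {
  stopifnot(inherits(fit, "mhsgtr_fit"),
            inherits(dataset, "multi_omics_dataset"))
  Xs <- lapply(dataset$views, function(v) v$values)
  joint_loss_terms(Xs, fit$states, fit$C, fit$A, fit$att_W, fit$P,
                   fit$config)
}

#' @export
print.mhsgtr_fit <- function(x, ...) {
  cat(sprintf(
    "<mhsgtr_fit: %d view(s), %d samples, %d joint epochs, final loss %.4g>\n",
    length(x$C), nrow(x$S_cons), nrow(x$trace),
    x$trace[nrow(x$trace), "total"]))
  invisible(x)
}
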