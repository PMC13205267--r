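leaky_relu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)

row_softmax <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

#' Per-sample omics attention weights
#'
#' The per-omics affinity graphs are concatenated column-wise into an
#' N x (N V) matrix, multiplied by a trainable (N V) x V weight matrix
#' (initialized all-ones), passed through a LeakyReLU (negative slope 0.01
#' by default) and row-softmaxed over the V omics. Row i of the result is
#' sample i's weight over the omics layers (a point on the V-simplex).
#'
#' @param graphs list of V equally shaped N x N affinity matrices.
#' @param weight_matrix (N V) x V matrix; defaults to all-ones.
#' @param slope LeakyReLU negative slope.
#' @return list of class `attention_state` with `concat`, `weight_matrix`,
#'   `pre` (pre-activation scores), `weights` (N x V simplex rows).
#' @export
attention_weights <- function(graphs, weight_matrix = NULL, slope = 0.01) {
  if (is.matrix(graphs)) graphs <- list(graphs)
  V <- length(graphs)
  n <- nrow(graphs[[1]])
  if (!all(vapply(graphs, function(g) all(dim(g) == c(n, n)), logical(1))))
    stop("all graphs must share the same N x N shape")
  concat <- do.call(cbind, graphs)
  if (is.null(weight_matrix)) weight_matrix <- matrix(1, n * V, V)
  if (!all(dim(weight_matrix) == c(n * V, V)))
    stop("weight_matrix must be (N*V) x V")
  pre <- concat %*% weight_matrix
  m <- row_softmax(leaky_relu(pre, slope))
  structure(list(concat = concat, weight_matrix = weight_matrix,
                 pre = pre, weights = m, slope = slope),
            class = "attention_state")
}

#' Attention-weighted graph fusion
#'
#' `CF = sum_v diag(m_v) %*% C^v`: row i of each omics graph is scaled by
#' sample i's attention weight for that omics, then summed. Uniform weights
#' reduce to the elementwise mean of the graphs.
#'
#' @param graphs list of V equally shaped N x N matrices.
#' @param M_att N x V matrix of per-sample omics weights (rows on the
#'   simplex), or an `attention_state`.
#' @return N x N fused matrix CF.
#' @export
fuse_graphs <- function(graphs, M_att) {
  if (inherits(M_att, "attention_state")) M_att <- M_att$weights
  if (is.matrix(graphs)) graphs <- list(graphs)
  V <- length(graphs)
  if (ncol(M_att) != V || nrow(M_att) != nrow(graphs[[1]]))
    stop("attention weights must be N x V")
  cf <- graphs[[1]] * 0
  for (v in seq_len(V)) cf <- cf + M_att[, v] * graphs[[v]]
  cf
}

#' Row-normalize the consensus graph (f1)
#'
#' `s_ij = (cf_ij + cf_ji) / (2 * csum_i)` for i != j, where `csum_i` is
#' the sum of the off-diagonal entries of row i of CF, and `s_ii = 1`.
#' Negative off-diagonal entries of CF are clipped to zero first (the
#' symmetrized self-expressive affinities are already nonnegative; clipping
#' guards arbitrary input). For symmetric CF every off-diagonal row of the
#' result sums to exactly 1.
#'
#' @param CF N x N fused similarity matrix.
#' @return list of class `consensus_graph` with `CF` (clipped input),
#'   `S` (the normalized matrix) and `row_sums` (the csum vector).
#' @export
normalize_f1 <- function(CF) {
  CF <- pmax(CF, 0)
  n <- nrow(CF)
  off <- CF
  diag(off) <- 0
  rs <- rowSums(off)
  if (any(rs <= 0)) {
    bad <- which(rs <= 0)[1]
    nm <- rownames(CF)[bad]
    stop("row ", if (!is.null(nm)) nm else bad,
         " of the consensus graph has no off-diagonal mass")
  }
  S <- (off + t(off)) / (2 * rs)
  diag(S) <- 1
  structure(list(CF = CF, S = S, row_sums = rs), class = "consensus_graph")
}

#' Self-training target distribution (f2)
#'
#' Sharpened, frequency-normalized transform of the consensus similarity:
#' `p_ij = (s_ij^2 / f_j) / sum_j' (s_ij'^2 / f_j')` with
#' `f_j = sum_i s_ij` the column mass. Squaring emphasizes confident
#' similarities; dividing by the column mass prevents large clusters from
#' dominating the target. Rows of P sum to 1.
#'
#' @param S_cons consensus similarity matrix (a `consensus_graph` or a
#'   nonnegative matrix with positive row sums).
#' @return N x N target matrix P with simplex rows.
#' @export
target_distribution_f2 <- function(S_cons) {
  if (inherits(S_cons, "consensus_graph")) S_cons <- S_cons$S
  if (any(S_cons < 0)) stop("S must be nonnegative")
  f <- colSums(S_cons)
  if (any(f <= 0)) stop("zero column mass in S")
  num <- sweep(S_cons^2, 2, f, `/`)
  den <- rowSums(num)
  if (any(den <= 0)) stop("zero row in the target numerator")
  num / den
}

#' Kullback-Leibler refinement term
#'
#' `KL(P || Q) = sum_ij p_ij log(p_ij / q_ij)` with `0 log 0 := 0`, where Q
#' is the row-renormalized consensus similarity (rows of S, including the
#' unit diagonal, rescaled to sum to 1 so both arguments are row
#' distributions). Minimizing this pulls the consensus graph toward the
#' sharpened target.
#'
#' @param P target distribution (rows on the simplex).
#' @param S_cons consensus similarity (a `consensus_graph` or matrix).
#' @return nonnegative real.
#' @export
kl_refinement <- function(P, S_cons) {
  if (inherits(S_cons, "consensus_graph")) S_cons <- S_cons$S
  if (!all(dim(P) == dim(S_cons))) stop("shape mismatch")
  Q <- S_cons / rowSums(S_cons)
  if (any(P > 0 & Q == 0)) stop("support violation: P > 0 where S is 0")
  terms <- ifelse(P > 0, P * log(P / Q), 0)
  sum(terms)
}

# Gradient of beta * KL(P || rownorm(f1(CF))) with respect to CF (P fixed).
# Returns the N x N gradient; the diagonal of CF does not enter f1 and gets
# zero gradient. `clip_mask` should be 1 where CF entered f1 unclipped.
kl_grad_wrt_cf <- function(P, cons, beta) {
  S <- cons$S
  t_i <- rowSums(S)
  Q <- S / t_i
  ratio <- P / Q
  ratio[P == 0] <- 0               # p log(p/q) is identically 0 where p = 0
  G <- (1 - ratio) / t_i           # dKL/dS (off-diagonal and diagonal alike)
  diag(G) <- 0                     # s_ii fixed at 1: no gradient path
  r <- cons$row_sums
  Soff <- S
  diag(Soff) <- 0
  u <- rowSums(G * Soff)           # sum_j g_ij s_ij
  D <- G / (2 * r) + t(G / (2 * r)) - u / r
  diag(D) <- 0
  beta * D
}

# Backpropagate DCF (gradient wrt CF) through fusion + attention to the
# per-view symmetrized affinities and the attention weight matrix.
# Returns list(dGraphs = list of N x N, dW = (N V) x V).
fusion_backprop <- function(DCF, graphs, att) {
  V <- length(graphs)
  n <- nrow(DCF)
  M <- att$weights
  dM <- matrix(0, n, V)
  dGraphs <- vector("list", V)
  for (v in seq_len(V)) {
    dM[, v] <- rowSums(DCF * graphs[[v]])
    dGraphs[[v]] <- DCF * M[, v]
  }
  # softmax rows backprop
  dPre_act <- M * (dM - rowSums(dM * M))
  # leaky relu backprop
  dPre <- dPre_act * ifelse(att$pre > 0, 1, att$slope)
  dW <- t(att$concat) %*% dPre
  dConcat <- dPre %*% t(att$weight_matrix)
  for (v in seq_len(V)) {
    dGraphs[[v]] <- dGraphs[[v]] + dConcat[, (v - 1) * n + seq_len(n)]
  }
  list(dGraphs = dGraphs, dW = dW)
}
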