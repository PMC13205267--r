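#' L2,1 norm of a matrix
#'
#' Sum over rows of the Euclidean norm of each row. Penalizing the first
#' encoder layer with this norm shrinks the weights of irrelevant input
#' features jointly across all hidden units (row-wise sparsity, i.e.
#' feature-level selection).
#'
#' @param W numeric matrix.
#' @return nonnegative real.
#' @export
l21_norm <- function(W) {
  if (!all(is.finite(W))) stop("W must be finite")
  sum(sqrt(rowSums(W^2)))
}

# Subgradient of the L2,1 norm; zero rows get subgradient 0.
l21_grad <- function(W) {
  rn <- sqrt(rowSums(W^2))
  scale <- ifelse(rn > 0, 1 / rn, 0)
  W * scale
}

#' Autoencoder reconstruction loss
#'
#' `(1 / (2 n)) * ||X - Xrec||_F^2` with `n` the number of samples.
#'
#' @param X,Xrec matrices of identical shape.
#' @param n sample count (defaults to `nrow(X)`).
#' @return nonnegative real.
#' @export
reconstruction_loss <- function(X, Xrec, n = nrow(X)) {
  if (!all(dim(X) == dim(Xrec))) stop("shape mismatch")
  sum((X - Xrec)^2) / (2 * n)
}

#' Self-expression loss
#'
#' `l1 * ||Z - C Z||_F^2 + l2 * ||C||_F^2`: each sample's latent code is
#' approximated as a linear combination of the other samples' codes, and
#' the coefficient matrix C doubles as an affinity graph. Row i of C holds
#' the coefficients reconstructing sample i; the diagonal is constrained to
#' zero elsewhere in the package to rule out the trivial solution C = I.
#'
#' @param Z N x p latent matrix (samples in rows).
#' @param C N x N self-expressive coefficient matrix.
#' @param l1,l2 nonnegative weights.
#' @return nonnegative real.
#' @export
self_expression_loss <- function(Z, C, l1, l2) {
  if (nrow(C) != nrow(Z) || ncol(C) != nrow(Z)) stop("shape mismatch")
  l1 * sum((Z - C %*% Z)^2) + l2 * sum(C^2)
}

#' High-order graph alignment loss
#'
#' `l3 * ||A - C||_F^2`, pulling the self-expressive graph toward the
#' hybrid motif/first-order similarity so that high-order connectivity
#' patterns inform the learned affinities.
#'
#' @param A hybrid similarity matrix (or a `hybrid_graph`).
#' @param C self-expressive coefficient matrix.
#' @param l3 nonnegative weight.
#' @return nonnegative real.
#' @export
high_order_alignment_loss <- function(A, C, l3) {
  if (inherits(A, "hybrid_graph")) A <- A$hybrid
  if (!all(dim(A) == dim(C))) stop("shape mismatch")
  l3 * sum((A - C)^2)
}

relu <- function(x) pmax(x, 0)

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize a per-view encoder/decoder state
#'
#' Three-layer perceptron encoder d -> p1 -> p2 (ReLU on the first hidden
#' layer, linear latent output) mirrored by the decoder p2 -> p1 -> d.
#' Hidden widths default to 1024/512; desk-scale analyses shrink them via
#' the training configuration.
#'
#' @param d input feature dimension.
#' @param p1,p2 hidden widths.
#' @return list of class `encoder_state` with weight matrices `W1,b1,W2,b2`
#'   (encoder) and `W3,b3,W4,b4` (decoder). Uses the current RNG stream.
#' @export
init_encoder_state <- function(d, p1 = 1024, p2 = 512) {
  structure(list(
    d = d, p1 = p1, p2 = p2,
    W1 = glorot(d, p1), b1 = rep(0, p1),
    W2 = glorot(p1, p2), b2 = rep(0, p2),
    W3 = glorot(p2, p1), b3 = rep(0, p1),
    W4 = glorot(p1, d), b4 = rep(0, d)
  ), class = "encoder_state")
}

#' Forward pass through the autoencoder and self-expressive layer
#'
#' Computes the latent codes `Z = enc(X)`, the self-expressed codes
#' `C %*% Z` (the linear, activation-free layer between encoder and
#' decoder), and the reconstruction. During pretraining (`C = NULL`) the
#' decoder consumes Z directly; during joint training it consumes the
#' self-expressed codes, so the reconstruction path exercises C.
#'
#' @param X sample-by-feature matrix or [omics_matrix()].
#' @param state an `encoder_state`.
#' @param C optional N x N self-expressive matrix.
#' @return list with `Z`, `Zc` (self-expressed codes or Z when `C` is
#'   NULL), `Xrec`, and cached pre-activations for backpropagation.
#' @export
encode_decode <- function(X, state, C = NULL) {
  if (inherits(X, "omics_matrix")) X <- X$values
  if (ncol(X) != state$d) stop("feature dimension mismatch")
  pre1 <- sweep(X %*% state$W1, 2, state$b1, `+`)
  H1 <- relu(pre1)
  Z <- sweep(H1 %*% state$W2, 2, state$b2, `+`)
  Zc <- if (is.null(C)) Z else C %*% Z
  pre3 <- sweep(Zc %*% state$W3, 2, state$b3, `+`)
  H2 <- relu(pre3)
  Xrec <- sweep(H2 %*% state$W4, 2, state$b4, `+`)
  list(Z = Z, Zc = Zc, Xrec = Xrec, H1 = H1, H2 = H2,
       pre1 = pre1, pre3 = pre3)
}

# Backpropagate the reconstruction + L2,1 path for one view.
# Returns gradients for all encoder/decoder weights plus dZ and dC
# contributions arising from the reconstruction path (decoder input Zc).
# `dZ_extra` carries gradients flowing into Z from other loss terms.
backprop_view <- function(X, state, fwd, alpha, n, C = NULL,
                          dZ_extra = NULL) {
  dXrec <- -(X - fwd$Xrec) / n              # d recon / d Xrec
  gW4 <- t(fwd$H2) %*% dXrec
  gb4 <- colSums(dXrec)
  dH2 <- dXrec %*% t(state$W4)
  dpre3 <- dH2 * (fwd$pre3 > 0)
  gW3 <- t(fwd$Zc) %*% dpre3
  gb3 <- colSums(dpre3)
  dZc <- dpre3 %*% t(state$W3)
  if (is.null(C)) {
    dZ <- dZc
    dC <- NULL
  } else {
    dZ <- t(C) %*% dZc
    dC <- dZc %*% t(fwd$Z)
  }
  if (!is.null(dZ_extra)) dZ <- dZ + dZ_extra
  gW2 <- t(fwd$H1) %*% dZ
  gb2 <- colSums(dZ)
  dH1 <- dZ %*% t(state$W2)
  dpre1 <- dH1 * (fwd$pre1 > 0)
  gW1 <- t(X) %*% dpre1 + alpha * l21_grad(state$W1)
  gb1 <- colSums(dpre1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4, dC = dC)
}

#' Symmetrize a self-expressive coefficient matrix into an affinity
#'
#' `(|C| + |C^T|) / 2`: spectral methods and the fusion stage need a
#' symmetric nonnegative affinity, while the raw (possibly signed,
#' asymmetric) coefficients are retained for the losses.
#'
#' @param C N x N matrix.
#' @return symmetric nonnegative matrix with zero diagonal.
#' @export
symmetrize_affinity <- function(C) {
  A <- (abs(C) + t(abs(C))) / 2
  diag(A) <- 0
  A
}

# --- Adam optimizer ---------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, opt, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}
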