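#' Gaussian-kernel first-order similarity
#'
#' Pairwise similarity `s_ij = exp(-||x_i - x_j||^2 / (2 sigma^2))` between
#' sample rows of `X`. With `sigma = "auto"` the bandwidth is the median
#' pairwise Euclidean distance, a scale-free default in keeping with the
#' median-based edge threshold applied downstream.
#'
#' @param X numeric matrix, samples in rows (or an [omics_matrix()]).
#' @param sigma positive bandwidth, or `"auto"`.
#' @return list of class `first_order_similarity` with `values` (N x N
#'   symmetric matrix, unit diagonal) and `sigma`.
#' @export
gaussian_similarity <- function(X, sigma = "auto") {
  if (inherits(X, "omics_matrix")) X <- X$values
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 samples")
  d2 <- as.matrix(stats::dist(X))^2
  if (identical(sigma, "auto")) {
    sigma <- stats::median(sqrt(d2[upper.tri(d2)]))
    if (!is.finite(sigma) || sigma <= 0)
      stop("auto bandwidth failed: median pairwise distance is not positive")
  }
  sigma <- as.numeric(sigma)
  if (sigma <= 0) stop("sigma must be positive")
  s <- exp(-d2 / (2 * sigma^2))
  diag(s) <- 1
  rownames(s) <- colnames(s) <- rownames(X)
  structure(list(values = s, sigma = sigma),
            class = "first_order_similarity")
}

#' Threshold a similarity matrix at its median
#'
#' The edge threshold is the median of the off-diagonal upper-triangle
#' similarities (the unit diagonal is not an inter-sample similarity and is
#' excluded). Edges with `s_ij >= threshold` are retained; ties at the
#' threshold are kept. The diagonal of both outputs is forced to zero.
#'
#' @param S a `first_order_similarity` or a symmetric numeric matrix.
#' @return list of class `thresholded_graph` with `binary` (0/1 adjacency),
#'   `weighted` (retained similarities, 0 elsewhere) and `threshold`.
#' @export
threshold_graph <- function(S) {
  s <- if (inherits(S, "first_order_similarity")) S$values else as.matrix(S)
  n <- nrow(s)
  if (n < 3) warning("fewer than 3 samples: no triangles are possible")
  eps <- stats::median(s[upper.tri(s)])
  b <- (s >= eps) * 1
  diag(b) <- 0
  w <- s * b
  structure(list(binary = b, weighted = w, threshold = eps),
            class = "thresholded_graph")
}

#' Count triangle motifs shared by each node pair
#'
#' For an undirected graph, entry (i, j) counts the triangles (closed
#' triplets, motif M4) that the adjacent pair i–j jointly participates in:
#' the number of common neighbours k with all three edges present. For a
#' 0/1 adjacency W this is `(W %*% W) * W`. Two samples that close many
#' triangles with common neighbours are treated as high-order similar.
#'
#' @param W01 symmetric binary adjacency matrix with zero diagonal, or a
#'   `thresholded_graph`.
#' @return list of class `motif_count_matrix` with `values` (N x N integer
#'   counts) and `triangle_count` (total number of distinct triangles).
#' @export
count_triangle_motifs <- function(W01) {
  if (inherits(W01, "thresholded_graph")) W01 <- W01$binary
  W01 <- as.matrix(W01)
  if (!all(W01 %in% c(0, 1))) stop("adjacency must be binary")
  if (!isTRUE(all.equal(W01, t(W01)))) stop("adjacency must be symmetric")
  if (any(diag(W01) != 0)) stop("adjacency must have zero diagonal")
  wm <- (W01 %*% W01) * W01
  diag(wm) <- 0
  tri <- sum(wm[upper.tri(wm)]) / 3
  structure(list(values = wm, triangle_count = as.integer(round(tri))),
            class = "motif_count_matrix")
}

#' Motif-weighted similarity
#'
#' Hadamard product of the triangle-count matrix with the weighted
#' adjacency: high-order similarity is nonzero only on retained edges and
#' grows with the number of jointly closed triangles.
#'
#' @param WM a `motif_count_matrix` or nonnegative integer matrix.
#' @param W weighted adjacency of the same shape.
#' @return numeric matrix `M = WM * W` (elementwise).
#' @export
motif_weighted_similarity <- function(WM, W) {
  if (inherits(WM, "motif_count_matrix")) WM <- WM$values
  if (inherits(W, "thresholded_graph")) W <- W$weighted
  if (!all(dim(WM) == dim(W))) stop("shape mismatch between WM and W")
  WM * W
}

#' Blend first-order and motif similarity into a hybrid graph
#'
#' `A = eta * S + (1 - eta) * M_rescaled`, where the motif similarity is
#' min-max rescaled to [0, 1] first so that `eta` acts as a genuine convex
#' weight (raw triangle counts are unbounded and would otherwise swamp S).
#'
#' @param S first-order similarity matrix (entries in (0, 1]).
#' @param M motif similarity matrix (output of
#'   [motif_weighted_similarity()]).
#' @param eta trade-off in [0, 1]; 1 = pure first-order, 0 = pure motif.
#' @return list of class `hybrid_graph` with `motif_sim` (rescaled M),
#'   `hybrid` (the blend A) and `eta`.
#' @export
hybrid_similarity <- function(S, M, eta = 0.5) {
  if (inherits(S, "first_order_similarity")) S <- S$values
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]")
  if (!all(dim(S) == dim(M))) stop("shape mismatch between S and M")
  rng <- range(M)
  Mr <- if (rng[2] > rng[1]) (M - rng[1]) / (rng[2] - rng[1]) else M * 0
  A <- eta * S + (1 - eta) * Mr
  structure(list(motif_sim = Mr, hybrid = A, eta = eta),
            class = "hybrid_graph")
}

#' Build the per-view similarity graphs for one omics layer
#'
#' Runs the full high-order graph construction for one view: Gaussian
#' similarity, median thresholding, triangle-motif counting, motif
#' weighting and the hybrid blend. `mode` substitutes the graph that is
#' used downstream as the high-order anchor A: `"hybrid"` is the full
#' construction, `"first_order"` uses S alone (equivalently eta = 1) and
#' `"motif"` uses the rescaled motif similarity alone (eta = 0), which is
#' what the similarity ablation compares.
#'
#' @param X sample-by-feature matrix or [omics_matrix()].
#' @param sigma Gaussian bandwidth or `"auto"`.
#' @param eta hybrid trade-off in [0, 1].
#' @param mode one of `"hybrid"`, `"first_order"`, `"motif"`.
#' @return list with `S`, `threshold_graph`, `WM`, `M` (rescaled), `A`
#'   (the anchor graph for the chosen mode) and `eta_effective`.
#' @export
build_view_graph <- function(X, sigma = "auto", eta = 0.5,
                             mode = c("hybrid", "first_order", "motif")) {
  mode <- match.arg(mode)
  fo <- gaussian_similarity(X, sigma = sigma)
  tg <- threshold_graph(fo)
  wm <- count_triangle_motifs(tg)
  m <- motif_weighted_similarity(wm, tg)
  eta_eff <- switch(mode, hybrid = eta, first_order = 1, motif = 0)
  hy <- hybrid_similarity(fo$values, m, eta = eta_eff)
  list(S = fo$values, sigma = fo$sigma, threshold_graph = tg,
       WM = wm, M = hy$motif_sim, A = hy$hybrid, eta_effective = eta_eff)
}

#' Export a graph as a weighted edge list
#'
#' @param A symmetric matrix.
#' @param path output TSV path with columns `i`, `j`, `weight` (upper
#'   triangle, nonzero entries only).
#' @export
write_edge_list <- function(A, path) {
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  ids <- rownames(A)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(A)))
  df <- data.frame(i = ids[idx[, 1]], j = ids[idx[, 2]],
                   weight = A[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
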