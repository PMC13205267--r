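#' Stack per-omics graphs into a rotated third-order tensor
#'
#' The V similarity graphs are stacked into an N x N x V tensor with
#' frontal slices C^v, then rotated so that the omics mode becomes a matrix
#' dimension of the slices: entry (i, j, v) of the native tensor becomes
#' entry (i, v, j) of the rotated tensor (shape N x V x N). The rotation is
#' a lossless permutation; with the tensor nuclear norm applied along the
#' third (sample) mode of the rotated tensor, low-rankness couples
#' inter-omics structure rather than within-graph structure.
#'
#' @param graphs list of V equally shaped N x N matrices.
#' @return list of class `graph_tensor` with `values` (the rotated
#'   N x V x N array), `dims_native` and `rotated = TRUE`.
#' @export
stack_and_rotate <- function(graphs) {
  if (inherits(graphs, "matrix")) graphs <- list(graphs)
  if (!length(graphs)) stop("need at least one graph")
  n <- nrow(graphs[[1]])
  if (!all(vapply(graphs, function(g) all(dim(g) == c(n, n)), logical(1))))
    stop("all graphs must be square with identical shape")
  V <- length(graphs)
  native <- array(0, dim = c(n, n, V))
  for (v in seq_len(V)) native[, , v] <- graphs[[v]]
  rotated <- aperm(native, c(1, 3, 2))  # (i, j, v) -> (i, v, j)
  structure(list(values = rotated, dims_native = c(n, n, V), rotated = TRUE),
            class = "graph_tensor")
}

#' Undo [stack_and_rotate()]
#'
#' @param tensor a `graph_tensor`.
#' @return list of the V original N x N matrices.
#' @export
unrotate <- function(tensor) {
  stopifnot(inherits(tensor, "graph_tensor"))
  native <- aperm(tensor$values, c(1, 3, 2))
  V <- dim(native)[3]
  lapply(seq_len(V), function(v) native[, , v])
}

# FFT of an order-3 array along its third mode; returns a complex array of
# the same shape. inverse = TRUE applies the (normalized) inverse transform.
fft_mode3 <- function(a, inverse = FALSE) {
  d <- dim(a)
  out <- array(complex(real = 0), dim = d)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      z <- stats::fft(a[i, j, ], inverse = inverse)
      if (inverse) z <- z / d[3]
      out[i, j, ] <- z
    }
  }
  out
}

#' t-SVD tensor nuclear norm
#'
#' The discrete Fourier transform is applied along the third mode of the
#' (rotated) tensor; the tensor nuclear norm is the mean over the n3
#' transformed frontal slices of their matrix nuclear norms (sum of
#' singular values). The 1/n3 scaling makes the norm coincide with the
#' ordinary matrix nuclear norm when n3 = 1.
#'
#' @param tensor a `graph_tensor`, or a numeric order-3 array.
#' @return nonnegative real.
#' @export
tensor_nuclear_norm <- function(tensor) {
  a <- if (inherits(tensor, "graph_tensor")) tensor$values else tensor
  if (!all(is.finite(a))) stop("tensor contains non-finite values")
  d <- dim(a)
  af <- fft_mode3(a)
  total <- 0
  for (k in seq_len(d[3])) {
    sv <- svd(af[, , k], nu = 0, nv = 0)$d
    total <- total + sum(sv)
  }
  total / d[3]
}

#' Tensor singular-value thresholding (proximal map of the TNN)
#'
#' Exact proximal operator of `tau * TNN(.)`: in the Fourier domain each
#' frontal slice's singular values are soft-thresholded by `tau` (under the
#' 1/n3 norm convention the Frobenius term also picks up a 1/n3 factor
#' through Parseval, so the per-slice threshold is `tau` itself), the
#' slices are reconstructed and inverse-transformed. The output minimizes
#' `tau * TNN(X) + 0.5 * ||X - T||_F^2` and is exactly real for real input
#' (conjugate symmetry is preserved; any numerical imaginary residue is
#' discarded after verification).
#'
#' @param tensor a `graph_tensor` or numeric order-3 array.
#' @param tau nonnegative threshold.
#' @return object of the same kind as the input with shrunk values.
#' @export
tsvt_prox <- function(tensor, tau) {
  is_gt <- inherits(tensor, "graph_tensor")
  a <- if (is_gt) tensor$values else tensor
  if (tau < 0) stop("tau must be nonnegative")
  if (!all(is.finite(a))) stop("tensor contains non-finite values")
  if (tau == 0) return(tensor)
  d <- dim(a)
  af <- fft_mode3(a)
  out <- array(complex(real = 0), dim = d)
  for (k in seq_len(d[3])) {
    sv <- svd(af[, , k])
    shrunk <- pmax(sv$d - tau, 0)
    out[, , k] <- sv$u %*% (shrunk * Conj(t(sv$v)))
  }
  res <- fft_mode3(out, inverse = TRUE)
  imag_resid <- max(abs(Im(res)))
  if (imag_resid > 1e-8)
    stop("tsvt_prox lost conjugate symmetry (imaginary residue ",
         format(imag_resid), ")")
  real_res <- Re(res)
  if (is_gt) {
    tensor$values <- real_res
    tensor
  } else {
    real_res
  }
}
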