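# Independent oracles used across the suite. These deliberately avoid the
# code paths they check (triple loops instead of matrix products, explicit
# DFT matrices instead of fft, risk-set tabulation instead of survdiff).

# O(N^3) triangle enumeration: counts, per pair, the triangles it closes.
triangle_oracle <- function(W01) {
  n <- nrow(W01)
  wm <- matrix(0, n, n)
  n_tri <- 0
  if (n >= 3) {
    for (i in seq_len(n - 2)) {
      for (j in (i + 1):(n - 1)) {
        if (W01[i, j] == 0) next
        for (k in (j + 1):n) {
          if (W01[i, k] == 1 && W01[j, k] == 1) {
            n_tri <- n_tri + 1
            wm[i, j] <- wm[i, j] + 1
            wm[i, k] <- wm[i, k] + 1
            wm[j, k] <- wm[j, k] + 1
          }
        }
      }
    }
  }
  wm <- wm + t(wm)
  list(values = wm, triangle_count = n_tri)
}

# Multi-group log-rank chi-square by explicit risk-set tabulation.
logrank_oracle <- function(time, event, group) {
  group <- as.factor(group)
  G <- nlevels(group)
  ev_times <- sort(unique(time[event == 1]))
  O <- E <- rep(0, G)
  V <- matrix(0, G, G)
  for (t in ev_times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(event == 1 & time == t)
    n_g <- vapply(levels(group), function(g) sum(at_risk & group == g),
                  numeric(1))
    d_g <- vapply(levels(group), function(g)
      sum(event == 1 & time == t & group == g), numeric(1))
    O <- O + d_g
    E <- E + d_t * n_g / n_t
    if (n_t > 1) {
      frac <- n_g / n_t
      V <- V + d_t * (n_t - d_t) / (n_t - 1) *
        (diag(frac, G) - outer(frac, frac))
    }
  }
  oe <- (O - E)[-G]
  vv <- V[-G, -G, drop = FALSE]
  chi2 <- drop(t(oe) %*% solve(vv) %*% oe)
  list(chi2 = chi2, df = G - 1,
       p = stats::pchisq(chi2, df = G - 1, lower.tail = FALSE))
}

# Dense DFT matrix (for the fft-free tensor oracle).
dft_matrix <- function(n) {
  w <- exp(-2i * pi / n)
  outer(0:(n - 1), 0:(n - 1), function(a, b) w^(a * b))
}

# Tensor nuclear norm via explicit DFT-matrix transform along mode 3.
tnn_oracle <- function(a) {
  d <- dim(a)
  Fm <- dft_matrix(d[3])
  total <- 0
  for (k in seq_len(d[3])) {
    slice <- matrix(0i, d[1], d[2])
    for (l in seq_len(d[3])) slice <- slice + Fm[k, l] * a[, , l]
    total <- total + sum(svd(slice, nu = 0, nv = 0)$d)
  }
  total / d[3]
}

# Prox of tau * TNN via explicit DFT matrices and slice-wise SVT.
tsvt_oracle <- function(a, tau) {
  d <- dim(a)
  Fm <- dft_matrix(d[3])
  Fi <- Conj(Fm) / d[3]
  hat <- array(0i, dim = d)
  for (k in seq_len(d[3]))
    for (l in seq_len(d[3]))
      hat[, , k] <- hat[, , k] + Fm[k, l] * a[, , l]
  shr <- array(0i, dim = d)
  for (k in seq_len(d[3])) {
    sv <- svd(hat[, , k])
    shr[, , k] <- sv$u %*% ((pmax(sv$d - tau, 0)) * Conj(t(sv$v)))
  }
  out <- array(0i, dim = d)
  for (k in seq_len(d[3]))
    for (l in seq_len(d[3]))
      out[, , k] <- out[, , k] + Fi[k, l] * shr[, , l]
  Re(out)
}

# Small random symmetric nonnegative affinity with zero diagonal.
random_affinity <- function(n) {
  A <- abs(matrix(stats::rnorm(n * n), n, n))
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}

# Tiny two-view dataset for fast training tests.
tiny_dataset <- function(n = 40, seed = 7, separation = 3) {
  spec <- synthetic_spec(n_samples = n, n_clusters = 2,
                         view_dims = c(20, 15), separation = separation,
                         hazard_rates = c(1, 0.25), seed = seed)
  generate_dataset(spec)
}

tiny_config <- function(seed = 7, ...) {
  train_config(p1 = 16, p2 = 8, pretrain_epochs = 10, train_epochs = 15,
               seed = seed, ...)
}
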