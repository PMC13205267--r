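#' Specification of a synthetic multi-omics cohort
#'
#' Describes a cohort of `n_samples` patients drawn from `k` latent
#' subtypes. Each omics view is a Gaussian feature matrix in which an
#' `informative_fraction` of features carries cluster-specific means
#' separated by `separation` within-cluster standard deviations; the
#' remaining features are pure noise. Survival times are exponential with
#' a cluster-specific hazard and independent exponential censoring, and the
#' clinical table carries one cluster-associated categorical column
#' (positive control) plus one independent column (negative control).
#'
#' Defaults correspond to a desk-scale cohort of 150 samples in three
#' balanced subtypes over three views, strongly separated (3 within-cluster
#' standard deviations) with hazards 1.0 / 0.5 / 0.25 and 20% censoring.
#'
#' @param n_samples number of samples N.
#' @param n_clusters number of planted subtypes k (>= 2).
#' @param cluster_proportions simplex vector of length k.
#' @param view_dims integer vector of per-view feature counts d_v.
#' @param separation between-cluster mean distance, in units of the
#'   within-cluster standard deviation, per informative feature.
#' @param noise_sd per-view within-cluster standard deviation (recycled).
#' @param informative_fraction per-view fraction of features carrying
#'   cluster signal (recycled).
#' @param hazard_rates per-cluster exponential event rates.
#' @param censor_rate rate of the independent exponential censoring time;
#'   0 disables censoring.
#' @param seed integer seed; the dataset is a pure function of the spec.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 150, n_clusters = 3,
                           cluster_proportions = rep(1 / n_clusters, n_clusters),
                           view_dims = c(120, 100, 80),
                           separation = 3, noise_sd = 1,
                           informative_fraction = 0.3,
                           hazard_rates = c(1.0, 0.5, 0.25)[seq_len(n_clusters)],
                           censor_rate = 0.2, seed = 1) {
  if (n_clusters < 2) stop("n_clusters must be >= 2")
  if (abs(sum(cluster_proportions) - 1) > 1e-8 || any(cluster_proportions <= 0))
    stop("cluster_proportions must be positive and sum to 1")
  if (length(cluster_proportions) != n_clusters)
    stop("cluster_proportions must have length n_clusters")
  if (any(view_dims < 1)) stop("view_dims must be positive")
  if (separation < 0) stop("separation must be nonnegative")
  if (any(hazard_rates <= 0)) stop("hazard_rates must be positive")
  if (length(hazard_rates) != n_clusters)
    stop("hazard_rates must have length n_clusters")
  if (censor_rate < 0) stop("censor_rate must be nonnegative")
  V <- length(view_dims)
  structure(list(
    n_samples = n_samples, n_clusters = n_clusters,
    cluster_proportions = cluster_proportions,
    view_dims = view_dims,
    separation = separation,
    noise_sd = rep_len(noise_sd, V),
    informative_fraction = rep_len(informative_fraction, V),
    hazard_rates = hazard_rates, censor_rate = censor_rate,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# Cluster mean vectors for one view: informative features get means placed
# at scaled random unit directions so that the expected pairwise distance
# between cluster centroids is `separation` noise-sd per informative feature
# axis; implemented as +/- separation/2 sign patterns, which gives exactly
# `separation`*sd mean difference per informative feature between any two
# clusters that disagree on that feature's sign.
cluster_means <- function(k, d, n_inf, separation, sd) {
  mu <- matrix(0, k, d)
  if (n_inf > 0 && separation > 0) {
    signs <- matrix(sample(c(-1, 1), k * n_inf, replace = TRUE), k, n_inf)
    # ensure no two clusters share an identical sign pattern
    while (anyDuplicated(apply(signs, 1, paste, collapse = ""))) {
      dup <- which(duplicated(apply(signs, 1, paste, collapse = "")))
      signs[dup, ] <- sample(c(-1, 1), length(dup) * n_inf, replace = TRUE)
    }
    mu[, seq_len(n_inf)] <- signs * (separation * sd / 2)
  }
  mu
}

#' Generate a synthetic multi-omics dataset with planted subtypes
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `dataset` (a [multi_omics_dataset()], aligned,
#'   with survival and clinical tables) and `labels` (integer vector of the
#'   planted subtype per sample, named by sample ID).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  k <- spec$n_clusters
  labels <- sample(seq_len(k), n, replace = TRUE,
                   prob = spec$cluster_proportions)
  # guarantee every cluster is populated
  for (g in seq_len(k)) {
    if (!any(labels == g)) labels[sample(n, 1)] <- g
  }
  ids <- sprintf("s%03d", seq_len(n))
  views <- vector("list", length(spec$view_dims))
  for (v in seq_along(spec$view_dims)) {
    d <- spec$view_dims[v]
    n_inf <- round(spec$informative_fraction[v] * d)
    sd_v <- spec$noise_sd[v]
    mu <- cluster_means(k, d, n_inf, spec$separation, sd_v)
    x <- mu[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * d, sd = sd_v), n, d)
    rownames(x) <- ids
    colnames(x) <- sprintf("v%d_f%04d", v, seq_len(d))
    views[[v]] <- omics_matrix(x, view_name = paste0("view", v))
  }
  event_time <- stats::rexp(n, rate = spec$hazard_rates[labels])
  if (spec$censor_rate > 0) {
    cens_time <- stats::rexp(n, rate = spec$censor_rate)
    time <- pmin(event_time, cens_time)
    event <- as.numeric(event_time <= cens_time)
  } else {
    time <- event_time
    event <- rep(1, n)
  }
  surv <- survival_table(ids, time, event)
  # positive control: categorical label correlated with the subtype
  # (80% concordant, 20% uniform relabel); negative control: independent.
  assoc <- ifelse(stats::runif(n) < 0.8, labels,
                  sample(seq_len(k), n, replace = TRUE))
  indep <- sample(c("A", "B"), n, replace = TRUE)
  clin <- clinical_table(
    ids,
    list(subtype_marker = paste0("L", assoc), unrelated = indep),
    types = c(subtype_marker = "categorical", unrelated = "categorical")
  )
  dataset <- multi_omics_dataset(views, survival = surv, clinical = clin)
  names(labels) <- ids
  list(dataset = dataset, labels = labels)
}

#' Generate a stochastic-block-model adjacency matrix
#'
#' Symmetric zero-diagonal binary adjacency with `n_blocks` planted
#' communities of `n_per_block` nodes each; within-block edges appear with
#' probability `p_in` and between-block edges with probability `p_out`.
#' Used as a fixture for motif counting and the similarity ablation.
#'
#' @param n_per_block nodes per block.
#' @param n_blocks number of blocks.
#' @param p_in within-block edge probability.
#' @param p_out between-block edge probability (`p_out <= p_in`).
#' @param seed integer seed.
#' @return list with `adjacency` (0/1 matrix) and `blocks` (integer
#'   block membership).
#' @export
generate_block_graph <- function(n_per_block, n_blocks, p_in, p_out, seed = 1) {
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1)
    stop("edge probabilities must lie in [0, 1]")
  if (p_out > p_in) stop("p_out must not exceed p_in")
  set.seed(seed)
  n <- n_per_block * n_blocks
  blocks <- rep(seq_len(n_blocks), each = n_per_block)
  a <- matrix(0, n, n)
  same <- outer(blocks, blocks, `==`)
  up <- upper.tri(a)
  prob <- ifelse(same[up], p_in, p_out)
  a[up] <- as.numeric(stats::runif(sum(up)) < prob)
  a <- a + t(a)
  list(adjacency = a, blocks = blocks)
}
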