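#' Spectral clustering of a similarity graph
#'
#' Symmetric-normalized graph Laplacian, the k eigenvectors belonging to
#' its smallest eigenvalues, row normalization of the embedding, then
#' k-means with a fixed seed and 20 restarts.
#'
#' @param S symmetric nonnegative similarity matrix (symmetrized if not).
#' @param k number of clusters (2 <= k < N).
#' @param seed integer seed for the k-means restarts.
#' @param nstart k-means restarts (default 20).
#' @return list of class `cluster_result` with integer `labels` in 1..k,
#'   `k`, and `eigenvalues` (the smallest k + 1 Laplacian eigenvalues).
#' @export
spectral_cluster <- function(S, k, seed = 1, nstart = 20) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (k < 2) stop("k must be >= 2")
  if (k >= n) stop("k must be smaller than the number of samples")
  S <- (S + t(S)) / 2
  S[S < 0] <- 0
  diag(S) <- 0
  deg <- rowSums(S)
  if (any(deg <= 0)) {
    warning("isolated sample(s) in the similarity graph")
    deg[deg <= 0] <- .Machine$double.eps
  }
  dinv <- 1 / sqrt(deg)
  L <- diag(n) - (dinv * S) * rep(dinv, each = n)  # D^-1/2 S D^-1/2
  ev <- eigen(L, symmetric = TRUE)
  vals <- rev(ev$values)                            # ascending
  n_comp <- sum(vals < 1e-10)
  if (n_comp > k)
    warning("graph has more connected components (", n_comp,
            ") than clusters (", k, ")")
  U <- ev$vectors[, n:(n - k + 1), drop = FALSE]    # smallest k eigenvectors
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn
  set.seed(seed)
  km <- stats::kmeans(U, centers = k, nstart = nstart, iter.max = 100)
  labels <- as.integer(km$cluster)
  names(labels) <- rownames(S)
  structure(list(labels = labels, k = k,
                 eigenvalues = vals[seq_len(min(k + 1, n))]),
            class = "cluster_result")
}

#' Choose the number of clusters by the largest Laplacian eigengap
#'
#' Returns the k in `[k_min, k_max]` maximizing the gap between the k-th
#' and (k+1)-th smallest eigenvalues of the symmetric-normalized Laplacian.
#'
#' @param S similarity matrix.
#' @param k_min,k_max search range (defaults 2..6).
#' @return integer k.
#' @export
select_k <- function(S, k_min = 2, k_max = 6) {
  S <- as.matrix(S)
  n <- nrow(S)
  k_max <- min(k_max, n - 1)
  S <- (S + t(S)) / 2
  S[S < 0] <- 0
  diag(S) <- 0
  deg <- rowSums(S)
  deg[deg <= 0] <- .Machine$double.eps
  dinv <- 1 / sqrt(deg)
  L <- diag(n) - (dinv * S) * rep(dinv, each = n)
  vals <- rev(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  gaps <- vals[(k_min + 1):(k_max + 1)] - vals[k_min:k_max]
  if (max(gaps) <= 1e-12)
    warning("flat eigenvalue spectrum; defaulting to k_min")
  as.integer(k_min + which.max(gaps) - 1)
}

#' Multi-group log-rank test for survival separation between subtypes
#'
#' Standard log-rank statistic over the shared risk sets, with
#' `#groups - 1` degrees of freedom. Reported both as a p-value and as
#' `-log10(p)`, the scale on which subtype survival separation is usually
#' summarized.
#'
#' @param survival a [survival_table()].
#' @param labels integer/factor cluster labels, one per sample (aligned
#'   with `survival$sample_ids`).
#' @return list with `chi2`, `df`, `p` and `neg_log10_p`.
#' @export
logrank_test <- function(survival, labels) {
  stopifnot(inherits(survival, "survival_table"))
  labels <- as.factor(labels)
  if (length(labels) != length(survival$sample_ids))
    stop("one label per survival row required")
  if (nlevels(droplevels(labels)) < 2)
    stop("log-rank test needs at least two nonempty groups")
  if (sum(survival$event) == 0) stop("no events observed")
  fit <- survival::survdiff(
    survival::Surv(survival$time, survival$event) ~ labels
  )
  df <- length(fit$n) - 1
  p <- stats::pchisq(fit$chisq, df = df, lower.tail = FALSE)
  list(chi2 = unname(fit$chisq), df = df, p = p,
       neg_log10_p = -log10(p))
}

#' Clinical-label enrichment across subtypes
#'
#' For every clinical covariate, tests association with the cluster labels:
#' chi-square (without continuity correction) for categorical columns,
#' Kruskal-Wallis for numeric columns. Missing values are dropped per test.
#' Raw p-values are Benjamini-Hochberg adjusted across the columns that
#' were actually testable, and a covariate counts as enriched when its
#' adjusted p < `alpha`.
#'
#' @param clinical a [clinical_table()].
#' @param labels cluster labels aligned with `clinical$sample_ids`.
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return list of class `enrichment_report` with a `table` data frame
#'   (column, test, statistic, p, p_adjusted, significant) and
#'   `n_significant`.
#' @export
clinical_enrichment <- function(clinical, labels, alpha = 0.05) {
  stopifnot(inherits(clinical, "clinical_table"))
  labels <- as.factor(labels)
  if (length(labels) != length(clinical$sample_ids))
    stop("one label per clinical row required")
  rows <- list()
  for (nm in names(clinical$columns)) {
    col <- clinical$columns[[nm]]
    keep <- !is.na(col)
    lab <- droplevels(labels[keep])
    val <- col[keep]
    if (nlevels(lab) < 2) {
      warning("column '", nm, "': fewer than 2 clusters after missing-drop; skipped")
      next
    }
    if (clinical$types[[nm]] == "categorical") {
      val <- as.factor(val)
      if (nlevels(droplevels(val)) < 2) {
        warning("column '", nm, "' has a single level; skipped")
        next
      }
      tab <- table(lab, droplevels(val))
      expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expd < 5))
        warning("column '", nm, "': expected counts < 5; chi-square approximation may be poor")
      tst <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      rows[[nm]] <- data.frame(column = nm, test = "chi-square",
                               statistic = unname(tst$statistic),
                               p = tst$p.value)
    } else {
      if (length(unique(val)) < 2) {
        warning("column '", nm, "' is constant; skipped")
        next
      }
      tst <- stats::kruskal.test(val ~ lab)
      rows[[nm]] <- data.frame(column = nm, test = "kruskal-wallis",
                               statistic = unname(tst$statistic),
                               p = tst$p.value)
    }
  }
  if (!length(rows)) stop("no testable clinical columns")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$p_adjusted <- stats::p.adjust(tab$p, method = "BH")
  tab$significant <- tab$p_adjusted < alpha
  structure(list(table = tab, n_significant = sum(tab$significant),
                 alpha = alpha),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("<enrichment_report: %d/%d label(s) enriched at adjusted p < %g>\n",
              x$n_significant, nrow(x$table), x$alpha))
  print(x$table, digits = 4)
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement: 1 for identical partitions (up to label
#' renaming), about 0 for independent ones.
#'
#' @param labels_a,labels_b label vectors of equal length.
#' @return real in [-1, 1].
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("length mismatch")
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
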