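#' Run the full subtyping pipeline on a dataset
#'
#' Alignment, per-view graph construction (first-order, motif, hybrid),
#' autoencoder pretraining, joint training of the self-expressive graphs
#' with tensor and KL regularization, attention fusion, spectral clustering
#' of the consensus graph, and — when survival/clinical tables are present
#' — the log-rank and clinical-enrichment evaluation.
#'
#' @param dataset a [multi_omics_dataset()] (aligned automatically).
#' @param k number of clusters; `NULL` selects k by the Laplacian eigengap
#'   within `k_range`.
#' @param config a [train_config()].
#' @param k_range search range for [select_k()] when `k` is `NULL`.
#' @param output_dir optional directory; when given, labels, the consensus
#'   graph, attention weights, loss trace, evaluation report and a manifest
#'   of all effective parameters are written there as TSV/YAML.
#' @return list of class `mhsgtr_result` with `labels`, `k`, `fit`,
#'   `logrank` (or NULL), `enrichment` (or NULL), `dataset` (aligned).
#' @export
run_pipeline <- function(dataset, k = NULL, config = train_config(),
                         k_range = c(2, 6), output_dir = NULL) {
  dataset <- align_samples(dataset)
  fit <- tryCatch(
    mhsgtr_fit(dataset, config),
    error = function(e) stop("training stage failed: ", conditionMessage(e))
  )
  if (is.null(k)) k <- select_k(fit$S_cons, k_range[1], k_range[2])
  cl <- spectral_cluster(fit$S_cons, k = k, seed = config$seed)
  lr <- NULL
  if (!is.null(dataset$survival)) {
    lr <- tryCatch(logrank_test(dataset$survival, cl$labels),
                   error = function(e) {
                     message("survival evaluation skipped: ",
                             conditionMessage(e))
                     NULL
                   })
  } else {
    message("no survival table: survival evaluation skipped")
  }
  enr <- NULL
  if (!is.null(dataset$clinical)) {
    enr <- tryCatch(clinical_enrichment(dataset$clinical, cl$labels),
                    error = function(e) {
                      message("clinical evaluation skipped: ",
                              conditionMessage(e))
                      NULL
                    })
  }
  res <- structure(list(labels = cl$labels, k = k, fit = fit,
                        logrank = lr, enrichment = enr,
                        cluster = cl, dataset = dataset),
                   class = "mhsgtr_result")
  if (!is.null(output_dir)) write_result(res, output_dir)
  res
}

#' @export
print.mhsgtr_result <- function(x, ...) {
  cat(sprintf("<mhsgtr_result: %d samples in %d subtypes>\n",
              length(x$labels), x$k))
  print(table(subtype = x$labels))
  if (!is.null(x$logrank))
    cat(sprintf("log-rank: chi2 = %.3f, p = %.3g (-log10 p = %.2f)\n",
                x$logrank$chi2, x$logrank$p, x$logrank$neg_log10_p))
  if (!is.null(x$enrichment))
    cat(sprintf("enriched clinical labels: %d\n",
                x$enrichment$n_significant))
  invisible(x)
}

write_result <- function(res, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(res$labels)
  utils::write.table(
    data.frame(sample = ids, subtype = unname(res$labels)),
    file.path(output_dir, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = ids, as.data.frame(res$fit$S_cons)),
    file.path(output_dir, "consensus_graph.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  att <- res$fit$attention
  utils::write.table(
    data.frame(sample = ids,
               stats::setNames(as.data.frame(att),
                               paste0("view", seq_len(ncol(att))))),
    file.path(output_dir, "attention_weights.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(epoch = seq_len(nrow(res$fit$trace)), res$fit$trace),
    file.path(output_dir, "loss_trace.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$logrank)) {
    utils::write.table(
      data.frame(chi2 = res$logrank$chi2, df = res$logrank$df,
                 p = res$logrank$p,
                 neg_log10_p = res$logrank$neg_log10_p),
      file.path(output_dir, "logrank.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$enrichment)) {
    utils::write.table(res$enrichment$table,
                       file.path(output_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- res$fit$config
  manifest <- c(list(k = res$k, n_samples = length(res$labels),
                     views = names(res$dataset$views),
                     package_version =
                       as.character(utils::packageVersion("mhsgtr"))),
                unclass(cfg))
  yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))
  invisible(output_dir)
}

#' Similarity ablation: first-order vs motif vs hybrid anchor graphs
#'
#' Re-runs the pipeline with the alignment anchor A^v substituted by the
#' pure first-order similarity (eta = 1), the pure rescaled motif
#' similarity (eta = 0) or the hybrid blend, holding everything else —
#' including the pretrained encoders — fixed. With planted labels the
#' modes are compared by ARI; with a survival table by -log10(p) of the
#' log-rank test.
#'
#' @param dataset a [multi_omics_dataset()].
#' @param k number of clusters.
#' @param config a [train_config()]; its `graph_mode` is overridden per
#'   mode.
#' @param modes subset of `c("first_order", "motif", "hybrid")`.
#' @param true_labels optional planted labels for ARI scoring.
#' @return data frame with one row per mode: `mode`, `ari` (if labels
#'   given), `logrank_neg_log10_p` (if survival present), plus the list of
#'   per-mode results as attribute `"results"`.
#' @export
run_ablation <- function(dataset, k, config = train_config(),
                         modes = c("first_order", "motif", "hybrid"),
                         true_labels = NULL) {
  modes <- match.arg(modes, c("first_order", "motif", "hybrid"),
                     several.ok = TRUE)
  dataset <- align_samples(dataset)
  states <- pretrain(dataset, config)
  base_graphs <- lapply(dataset$views, function(v)
    build_view_graph(v$values, sigma = config$sigma, eta = config$eta,
                     mode = "hybrid"))
  if (!is.null(true_labels)) {
    ids <- dataset$views[[1]]$sample_ids
    if (!is.null(names(true_labels))) true_labels <- true_labels[ids]
  }
  results <- list()
  rows <- list()
  for (mode in modes) {
    # substitute the anchor graph while keeping S/M fixed per view
    graphs <- lapply(base_graphs, function(g) {
      eta_eff <- switch(mode, hybrid = config$eta, first_order = 1, motif = 0)
      A <- eta_eff * g$S + (1 - eta_eff) * g$M
      g$A <- A
      g$eta_effective <- eta_eff
      g
    })
    cfg <- config
    cfg$graph_mode <- mode
    fit <- mhsgtr_fit(dataset, cfg, states = states, graphs = graphs)
    cl <- spectral_cluster(fit$S_cons, k = k, seed = config$seed)
    row <- data.frame(mode = mode)
    if (!is.null(true_labels))
      row$ari <- adjusted_rand_index(true_labels, cl$labels)
    if (!is.null(dataset$survival)) {
      lr <- tryCatch(logrank_test(dataset$survival, cl$labels),
                     error = function(e) NULL)
      row$logrank_neg_log10_p <- if (is.null(lr)) NA_real_ else lr$neg_log10_p
    }
    rows[[mode]] <- row
    results[[mode]] <- list(fit = fit, labels = cl$labels)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `views` (named list of paths), `survival`,
#' `clinical` (paths), `orientation`, `k`, `k_range`, `output_dir`, and any
#' argument of [train_config()] under `train`.
#'
#' @param path YAML file path.
#' @return list with `dataset`-loading info and a `config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  train_args <- cfg$train
  if (is.null(train_args)) train_args <- list()
  config <- do.call(train_config, train_args)
  list(views = cfg$views, survival = cfg$survival, clinical = cfg$clinical,
       orientation = if (is.null(cfg$orientation)) "samples" else cfg$orientation,
       k = cfg$k, k_range = if (is.null(cfg$k_range)) c(2, 6) else cfg$k_range,
       output_dir = cfg$output_dir, config = config)
}

#' Load a dataset from the paths in a pipeline configuration
#'
#' @param pc output of [read_pipeline_config()].
#' @return a [multi_omics_dataset()] (not yet aligned).
#' @export
load_dataset_from_config <- function(pc) {
  if (is.null(pc$views) || !length(pc$views))
    stop("configuration lists no omics views")
  views <- lapply(seq_along(pc$views), function(i) {
    nm <- names(pc$views)[i]
    read_omics_matrix(pc$views[[i]], orientation = pc$orientation,
                      view_name = if (is.null(nm) || nm == "")
                        paste0("view", i) else nm)
  })
  surv <- if (!is.null(pc$survival)) read_survival_table(pc$survival)
  clin <- if (!is.null(pc$clinical)) read_clinical_table(pc$clinical)
  multi_omics_dataset(views, survival = surv, clinical = clin)
}
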