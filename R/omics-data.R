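#' Construct an omics matrix
#'
#' An `omics_matrix` holds one omics layer as a samples-in-rows numeric
#' matrix with unique sample and feature identifiers. All downstream stages
#' (similarity graphs, embedding, fusion) consume this container.
#'
#' @param values numeric matrix, samples in rows. `dimnames` are used as
#'   sample/feature identifiers unless overridden.
#' @param view_name short label for the omics layer (e.g. `"mrna"`).
#' @param sample_ids,feature_ids optional character vectors overriding the
#'   matrix dimnames.
#' @return an object of class `omics_matrix` with elements `view_name`,
#'   `sample_ids`, `feature_ids` and `values`.
#' @export
omics_matrix <- function(values, view_name = "view",
                         sample_ids = rownames(values),
                         feature_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("omics values must be numeric")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature IDs: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  }
  if (nrow(values) < 2) stop("an omics matrix needs at least 2 samples")
  if (length(sample_ids) != nrow(values) ||
      length(feature_ids) != ncol(values)) {
    stop("ID lengths do not match matrix dimensions")
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(
    list(view_name = view_name, sample_ids = sample_ids,
         feature_ids = feature_ids, values = values),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix '%s': %d samples x %d features>\n",
              x$view_name, length(x$sample_ids), length(x$feature_ids)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Construct a survival table
#'
#' @param sample_ids character vector of sample identifiers.
#' @param time nonnegative follow-up times (one unit for all rows).
#' @param event event indicator in \{0, 1\} (1 = event observed).
#' @return object of class `survival_table`.
#' @export
survival_table <- function(sample_ids, time, event) {
  sample_ids <- as.character(sample_ids)
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs in survival table")
  if (length(time) != length(sample_ids) || length(event) != length(sample_ids))
    stop("survival columns must have one row per sample")
  ok <- !is.na(time) & !is.na(event)
  if (any(time[ok] < 0)) stop("survival time must be nonnegative")
  if (!all(event[ok] %in% c(0, 1))) stop("event indicator must be 0 or 1")
  structure(list(sample_ids = sample_ids, time = time, event = event),
            class = "survival_table")
}

#' Construct a clinical covariate table
#'
#' Each column is tagged `"categorical"` or `"numeric"`; missing values are
#' allowed and are dropped per-test by [clinical_enrichment()].
#'
#' @param sample_ids character vector of sample identifiers.
#' @param columns named list of covariate vectors, one value per sample.
#' @param types named character vector tagging each column
#'   (`"categorical"` or `"numeric"`). Untagged columns are inferred from
#'   their storage mode.
#' @return object of class `clinical_table`.
#' @export
clinical_table <- function(sample_ids, columns, types = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs in clinical table")
  if (is.null(names(columns)) || any(names(columns) == ""))
    stop("clinical columns must be named")
  columns <- lapply(columns, function(col) {
    if (length(col) != length(sample_ids))
      stop("each clinical column needs one value per sample")
    col
  })
  inferred <- vapply(columns, function(col) {
    if (is.numeric(col)) "numeric" else "categorical"
  }, character(1))
  if (!is.null(types)) {
    unknown <- setdiff(names(types), names(columns))
    if (length(unknown)) stop("type tags for unknown columns: ",
                              paste(unknown, collapse = ", "))
    inferred[names(types)] <- types
  }
  if (!all(inferred %in% c("categorical", "numeric")))
    stop("column types must be 'categorical' or 'numeric'")
  for (nm in names(columns)) {
    if (inferred[[nm]] == "numeric" && !is.numeric(columns[[nm]]))
      stop("column '", nm, "' tagged numeric but stored non-numeric")
  }
  missingness <- vapply(columns, function(col) mean(is.na(col)), numeric(1))
  structure(list(sample_ids = sample_ids, columns = columns,
                 types = inferred, missingness = missingness),
            class = "clinical_table")
}

#' Bundle omics views with optional survival and clinical tables
#'
#' @param views list of [omics_matrix()] objects.
#' @param survival optional [survival_table()].
#' @param clinical optional [clinical_table()].
#' @return object of class `multi_omics_dataset`.
#' @export
multi_omics_dataset <- function(views, survival = NULL, clinical = NULL) {
  if (inherits(views, "omics_matrix")) views <- list(views)
  if (!length(views)) stop("at least one omics view is required")
  if (!all(vapply(views, inherits, logical(1), "omics_matrix")))
    stop("all views must be omics_matrix objects")
  nm <- vapply(views, function(v) v$view_name, character(1))
  if (is.null(names(views))) names(views) <- nm
  structure(list(views = views, survival = survival, clinical = clinical),
            class = "multi_omics_dataset")
}

#' @export
print.multi_omics_dataset <- function(x, ...) {
  cat(sprintf("<multi_omics_dataset: %d view(s)>\n", length(x$views)))
  for (v in x$views) {
    cat(sprintf("  %s: %d x %d\n", v$view_name,
                nrow(v$values), ncol(v$values)))
  }
  if (!is.null(x$survival)) cat("  + survival table\n")
  if (!is.null(x$clinical)) cat("  + clinical table\n")
  invisible(x)
}

sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a delimited omics matrix
#'
#' Reads a TSV/CSV table with one header row and one leading ID column and
#' returns it in samples-in-rows orientation. IDs are preserved verbatim.
#'
#' @param path file path to a delimited text table.
#' @param orientation `"samples"` if rows of the file are samples,
#'   `"features"` if rows are features (the table is transposed on read).
#' @param view_name label for the view; defaults to the file stem.
#' @param sep field separator; by default sniffed from the header line.
#' @return an [omics_matrix()].
#' @export
read_omics_matrix <- function(path, orientation = c("samples", "features"),
                              view_name = NULL, sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep)) sep <- sniff_sep(path)
  if (is.null(view_name))
    view_name <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), comment.char = "",
                          quote = "\"")
  mat <- as.matrix(df)
  if (!is.numeric(mat)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))[1]
    row <- which(is.na(suppressWarnings(as.numeric(df[[bad]]))) &
                   !is.na(df[[bad]]))[1]
    stop(sprintf("non-numeric value in column '%s'%s of %s",
                 colnames(df)[bad],
                 if (!is.na(row)) sprintf(", row '%s'", rownames(df)[row]) else "",
                 path))
  }
  if (orientation == "features") mat <- t(mat)
  omics_matrix(mat, view_name = view_name)
}

#' Write an omics matrix as a delimited table
#'
#' Round-trips exactly with [read_omics_matrix()] (full double precision).
#'
#' @param m an [omics_matrix()].
#' @param path output path.
#' @param sep field separator, tab by default.
#' @export
write_omics_matrix <- function(m, path, sep = "\t") {
  stopifnot(inherits(m, "omics_matrix"))
  df <- data.frame(sample_id = m$sample_ids,
                   format(m$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival table (`sample`, `time`, `event` columns)
#'
#' @param path delimited text file with columns `sample`, `time`, `event`.
#' @param sep separator, sniffed by default.
#' @return a [survival_table()].
#' @export
read_survival_table <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  if (!all(need %in% colnames(df)))
    stop("survival table needs columns: ", paste(need, collapse = ", "))
  survival_table(df$sample, df$time, df$event)
}

#' Read a clinical table
#'
#' First column is the sample ID; remaining columns are covariates. Types
#' may be declared explicitly, otherwise numeric storage implies a numeric
#' covariate.
#'
#' @param path delimited text file; first column `sample`.
#' @param types optional named character vector of column types.
#' @param sep separator, sniffed by default.
#' @return a [clinical_table()].
#' @export
read_clinical_table <- function(path, types = NULL, sep = NULL) {
  if (is.null(sep)) sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (!"sample" %in% colnames(df))
    stop("clinical table needs a 'sample' column")
  ids <- as.character(df$sample)
  cols <- as.list(df[setdiff(colnames(df), "sample")])
  clinical_table(ids, cols, types = types)
}

subset_view <- function(v, ids) {
  omics_matrix(v$values[ids, , drop = FALSE], view_name = v$view_name)
}

#' Restrict a dataset to the samples shared by every view and table
#'
#' Keeps the intersection of sample IDs across all omics views, in a single
#' deterministic (lexicographic) order, and restricts the survival and
#' clinical tables to the same samples. When a survival table is present,
#' samples with missing survival entries are removed, mirroring the usual
#' cohort-assembly rule for survival-evaluated subtyping.
#'
#' @param dataset a [multi_omics_dataset()].
#' @return the aligned dataset; idempotent.
#' @export
align_samples <- function(dataset) {
  stopifnot(inherits(dataset, "multi_omics_dataset"))
  ids <- Reduce(intersect, lapply(dataset$views, function(v) v$sample_ids))
  if (!is.null(dataset$survival)) {
    sv <- dataset$survival
    complete <- sv$sample_ids[!is.na(sv$time) & !is.na(sv$event)]
    ids <- intersect(ids, complete)
  }
  if (!is.null(dataset$clinical)) {
    ids <- intersect(ids, dataset$clinical$sample_ids)
  }
  ids <- sort(ids, method = "radix")
  if (!length(ids)) stop("no samples shared by all views and tables")
  if (length(ids) < 2) stop("fewer than 2 samples after alignment")
  views <- lapply(dataset$views, subset_view, ids = ids)
  surv <- dataset$survival
  if (!is.null(surv)) {
    idx <- match(ids, surv$sample_ids)
    surv <- survival_table(ids, surv$time[idx], surv$event[idx])
  }
  clin <- dataset$clinical
  if (!is.null(clin)) {
    idx <- match(ids, clin$sample_ids)
    clin <- clinical_table(ids, lapply(clin$columns, `[`, idx),
                           types = clin$types)
  }
  multi_omics_dataset(views, survival = surv, clinical = clin)
}

#' Filter expression features by missingness and zero fraction
#'
#' Drops any feature with at least one missing value, any feature whose
#' fraction of zero entries exceeds `max_zero_fraction` (strictly greater:
#' a feature at exactly the boundary is kept), then any zero-variance
#' feature. Feature order is otherwise preserved. Intended for count-like
#' expression layers (mRNA, miRNA) before [log2_transform()].
#'
#' @param m an [omics_matrix()].
#' @param max_zero_fraction maximum tolerated fraction of zeros (default 0.30).
#' @return the filtered [omics_matrix()].
#' @export
filter_expression_features <- function(m, max_zero_fraction = 0.30) {
  stopifnot(inherits(m, "omics_matrix"))
  x <- m$values
  keep <- colSums(is.na(x)) == 0
  zf <- colMeans(x == 0, na.rm = TRUE)
  keep <- keep & (zf <= max_zero_fraction)
  v <- apply(x, 2, stats::var)
  keep <- keep & !is.na(v) & v > 0
  if (!any(keep)) stop("all features removed by expression filtering")
  omics_matrix(x[, keep, drop = FALSE], view_name = m$view_name)
}

#' Log2-transform an expression matrix
#'
#' Elementwise `log2(x + pseudocount)`. The default pseudocount of 1 keeps
#' the transform defined at zero, which the zero-fraction filter allows
#' through.
#'
#' @param m an [omics_matrix()] with nonnegative entries.
#' @param pseudocount added before taking logs (default 1).
#' @return the transformed [omics_matrix()].
#' @export
log2_transform <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "omics_matrix"))
  if (any(m$values < 0, na.rm = TRUE))
    stop("log2_transform requires nonnegative values")
  omics_matrix(log2(m$values + pseudocount), view_name = m$view_name)
}

#' Variance filter with optional duplicate-probe averaging
#'
#' For methylation-style layers: rows of the platform that map to the same
#' gene are averaged (arithmetic mean per sample), then features with zero
#' variance are dropped.
#'
#' @param m an [omics_matrix()].
#' @param feature_groups optional character vector, one entry per feature,
#'   mapping each feature (probe) to a group (gene); features sharing a
#'   group are averaged into a single feature named after the group. When
#'   `NULL` no collapsing is performed.
#' @return the filtered [omics_matrix()].
#' @export
filter_variance <- function(m, feature_groups = NULL) {
  stopifnot(inherits(m, "omics_matrix"))
  x <- m$values
  if (!is.null(feature_groups)) {
    if (length(feature_groups) != ncol(x))
      stop("feature_groups must have one entry per feature")
    groups <- unique(feature_groups)
    x <- vapply(groups, function(g) {
      rowMeans(x[, feature_groups == g, drop = FALSE])
    }, numeric(nrow(x)))
    colnames(x) <- groups
  }
  v <- apply(x, 2, stats::var)
  keep <- !is.na(v) & v > 0
  if (!any(keep)) stop("all features removed by variance filtering")
  omics_matrix(x[, keep, drop = FALSE], view_name = m$view_name)
}
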