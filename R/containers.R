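#' Expression dataset container
#'
#' Bundles one study's genes x samples expression matrix with an identifier
#' and optional per-sample annotations.  Expression values are assumed to be
#' normalized upstream (e.g. MAS5 on microarrays), on whatever scale the
#' study provides; all downstream correlation statistics are scale-free
#' per gene.
#'
#' @param dataset_id Single string identifying the study.
#' @param values Numeric matrix, genes in rows, samples in columns.  Row
#'   names are gene identifiers, column names sample identifiers.
#' @param annotations Optional data.frame with one row per sample (aligned
#'   with the columns of `values`).  Conventional columns: `subtype`,
#'   `er_status`, `tp53_status`, `tp53_expression`, `node_status`,
#'   `tumor_size`, `grade` -- all optional.
#' @return An object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(dataset_id, values, annotations = NULL) {
  stopifnot(is.character(dataset_id), length(dataset_id) == 1L)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(rownames(values))) stop("expression matrix must have gene row names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers in dataset '", dataset_id, "'")
  if (is.null(colnames(values)))
    colnames(values) <- paste0(dataset_id, "_s", seq_len(ncol(values)))
  if (anyNA(values))
    stop("missing expression values in dataset '", dataset_id,
         "'; complete matrices are required")
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    if (nrow(annotations) != ncol(values))
      stop("annotation rows (", nrow(annotations), ") do not match samples (",
           ncol(values), ") in dataset '", dataset_id, "'")
    rownames(annotations) <- colnames(values)
  }
  structure(
    list(dataset_id = dataset_id, gene_ids = rownames(values),
         values = values, annotations = annotations),
    class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset '", x$dataset_id, "': ",
      nrow(x$values), " genes x ", ncol(x$values), " samples",
      if (!is.null(x$annotations)) paste0(" (", ncol(x$annotations), " annotation columns)"),
      "\n", sep = "")
  invisible(x)
}

#' Multi-study cohort container
#'
#' An ordered list of [expression_dataset()] objects sharing an identical
#' gene list, the unit on which leave-one-out correlations are computed.
#' At least two datasets are required for leave-one-out operations; use
#' [align_datasets()] to build a cohort from studies with differing gene
#' coverage.
#'
#' @param datasets List of `ExpressionDataset` objects with identical
#'   `gene_ids` in identical order.
#' @return An object of class `Cohort`.
#' @export
cohort <- function(datasets) {
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  if (!all(vapply(datasets, inherits, logical(1), "ExpressionDataset")))
    stop("all cohort members must be ExpressionDataset objects")
  ids <- vapply(datasets, `[[`, character(1), "dataset_id")
  if (anyDuplicated(ids)) stop("duplicate dataset ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  ref <- datasets[[1]]$gene_ids
  for (d in datasets)
    if (!identical(d$gene_ids, ref))
      stop("dataset '", d$dataset_id,
           "' gene list differs from the first dataset; run align_datasets() first")
  names(datasets) <- ids
  structure(list(datasets = datasets, gene_ids = ref), class = "Cohort")
}

#' @export
print.Cohort <- function(x, ...) {
  ns <- vapply(x$datasets, function(d) ncol(d$values), integer(1))
  cat("Cohort: ", length(x$datasets), " datasets, ",
      length(x$gene_ids), " genes, ", sum(ns), " samples (",
      paste(ns, collapse = "+"), ")\n", sep = "")
  invisible(x)
}

#' Pool a cohort's samples into one matrix
#'
#' Column-binds all member datasets (genes x total samples), preserving
#' dataset order.  Used internally by correlation and filtering steps.
#'
#' @param coh A `Cohort`.
#' @return Numeric matrix, genes x pooled samples.
#' @export
pool_cohort <- function(coh) {
  stopifnot(inherits(coh, "Cohort"))
  do.call(cbind, lapply(coh$datasets, `[[`, "values"))
}

#' Pool a cohort's sample annotations
#'
#' Row-binds the per-dataset annotation tables in dataset order, adding a
#' `dataset_id` column.  Datasets without annotations contribute rows of NA.
#'
#' @param coh A `Cohort`.
#' @return A data.frame with one row per pooled sample.
#' @export
pool_annotations <- function(coh) {
  stopifnot(inherits(coh, "Cohort"))
  cols <- unique(unlist(lapply(coh$datasets, function(d) colnames(d$annotations))))
  rows <- lapply(coh$datasets, function(d) {
    n <- ncol(d$values)
    out <- data.frame(dataset_id = rep(d$dataset_id, n),
                      sample_id = colnames(d$values),
                      stringsAsFactors = FALSE)
    for (cc in cols)
      out[[cc]] <- if (!is.null(d$annotations) && cc %in% colnames(d$annotations))
        d$annotations[[cc]] else NA
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation matrix container
#'
#' Symmetric gene x gene matrix of edge weights.  After leave-one-out
#' minimisation and positivity filtering, retained entries lie in (0, 1];
#' filtered (absent) pairs are stored as `NA`, never as zero, so that
#' "no edge" and "zero correlation" stay distinct.  The diagonal is `NA`
#' and ignored by all consumers.
#'
#' @param values Symmetric numeric matrix with gene ids as dimnames.
#' @param n_datasets Number of datasets that entered the computation.
#' @return An object of class `CorrelationMatrix`.
#' @export
correlation_matrix <- function(values, n_datasets = 1L) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("correlation matrix needs gene dimnames")
  if (nrow(values) != ncol(values)) stop("correlation matrix must be square")
  if (!isTRUE(all.equal(values, t(values), check.attributes = FALSE)))
    stop("correlation matrix must be symmetric")
  diag(values) <- NA_real_
  structure(list(gene_ids = rownames(values), values = values,
                 n_datasets = as.integer(n_datasets)),
            class = "CorrelationMatrix")
}

#' @export
print.CorrelationMatrix <- function(x, ...) {
  present <- sum(!is.na(x$values[upper.tri(x$values)]))
  cat("CorrelationMatrix: ", length(x$gene_ids), " genes, ",
      present, " retained pairs, n_datasets = ", x$n_datasets, "\n", sep = "")
  invisible(x)
}

# Accept a CorrelationMatrix or a bare symmetric matrix wherever pairwise
# weights are consumed.
corr_values <- function(corr) {
  if (inherits(corr, "CorrelationMatrix")) return(corr$values)
  m <- as.matrix(corr)
  if (nrow(m) != ncol(m) || is.null(rownames(m)))
    stop("expected a CorrelationMatrix or a square matrix with gene dimnames")
  diag(m) <- NA_real_
  m
}

#' Gene module container
#'
#' @param module_id Single string.
#' @param gene_ids Character vector of member genes (non-empty, unique).
#' @param label Free-text biological annotation (e.g. "stroma",
#'   "mitotic checkpoint"); defaults to the module id.
#' @param source_cutoff Correlation cutoff of the network the module was
#'   extracted from, or `NA`.
#' @return An object of class `GeneModule`.
#' @export
gene_module <- function(module_id, gene_ids, label = module_id,
                        source_cutoff = NA_real_) {
  stopifnot(is.character(module_id), length(module_id) == 1L)
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) == 0L) stop("a module must contain at least one gene")
  if (anyDuplicated(gene_ids)) stop("duplicate genes in module '", module_id, "'")
  structure(list(module_id = module_id, gene_ids = gene_ids,
                 label = label, source_cutoff = source_cutoff),
            class = "GeneModule")
}

#' @export
print.GeneModule <- function(x, ...) {
  cat("GeneModule '", x$module_id, "' (", x$label, "): ",
      length(x$gene_ids), " genes", sep = "")
  if (!is.na(x$source_cutoff)) cat(", cutoff ", x$source_cutoff, sep = "")
  cat("\n")
  invisible(x)
}
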