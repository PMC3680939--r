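#' Collapse probe-level expression to gene level
#'
#' Removes cross-hybridizing probes (probes flagged as cross-hybridizing or
#' mapping to more than one gene identifier) and merges the remaining probes
#' by taking, for each gene, the arithmetic mean of its surviving probes in
#' every sample.  This is the standard probe-to-Entrez collapsing step for
#' microarray meta-analysis.
#'
#' @param probes Numeric matrix, probes x samples, with probe ids as row
#'   names and sample ids as column names.
#' @param probe_map A data.frame with columns `probe_id`, `gene_ids`
#'   (semicolon-separated when a probe maps to several genes) and `crosshyb`
#'   (0/1 or logical), as returned by [read_probe_map_tsv()].
#' @param dataset_id Identifier for the resulting dataset.
#' @param annotations Optional per-sample annotation data.frame.
#' @return An [expression_dataset()] with one row per gene that retained at
#'   least one probe.  Gene order follows the first appearance of each gene
#'   among the surviving probes.
#' @export
merge_probes_to_genes <- function(probes, probe_map, dataset_id = "dataset",
                                  annotations = NULL) {
  probes <- as.matrix(probes)
  if (is.null(rownames(probes))) stop("probe matrix must have probe ids as row names")
  pm <- as.data.frame(probe_map)
  need <- c("probe_id", "gene_ids", "crosshyb")
  if (!all(need %in% colnames(pm)))
    stop("probe map must have columns: ", paste(need, collapse = ", "))
  idx <- match(rownames(probes), pm$probe_id)
  if (anyNA(idx)) {
    missing <- rownames(probes)[is.na(idx)]
    stop("probe(s) absent from the probe map: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  }
  pm <- pm[idx, , drop = FALSE]
  genes_per_probe <- strsplit(as.character(pm$gene_ids), ";", fixed = TRUE)
  genes_per_probe <- lapply(genes_per_probe, function(g) unique(g[nzchar(g)]))
  if (any(lengths(genes_per_probe) == 0L))
    stop("probe(s) with empty gene mapping: ",
         paste(rownames(probes)[lengths(genes_per_probe) == 0L], collapse = ", "))
  crosshyb <- as.logical(as.integer(as.logical(pm$crosshyb)))
  keep <- !crosshyb & lengths(genes_per_probe) == 1L
  if (!any(keep))
    stop("no probes survive cross-hybridization filtering; cannot build a gene matrix")
  probes <- probes[keep, , drop = FALSE]
  gene_of_probe <- vapply(genes_per_probe[keep], `[[`, character(1), 1L)
  genes <- unique(gene_of_probe)
  grp <- factor(gene_of_probe, levels = genes)
  # rowsum aggregates probe rows per gene; divide by probe counts for the mean
  sums <- rowsum(probes, grp, reorder = FALSE)
  counts <- as.vector(table(grp))
  values <- sums / counts
  rownames(values) <- genes
  expression_dataset(dataset_id, values, annotations)
}

#' Preprocessing configuration
#'
#' @param sd_cutoff Standard-deviation threshold for [variance_filter()];
#'   genes are kept only when their pooled-sample SD is strictly greater
#'   than this value.  Default 1.
#' @param center_mode How [mean_center()] centers gene rows:
#'   `"per_gene_global"` subtracts each gene's mean over all pooled samples,
#'   `"per_gene_within_dataset"` centers each dataset separately, `"none"`
#'   leaves values untouched.  Pearson correlations within a dataset are
#'   unaffected by either centering; the choice matters only for pooled-SD
#'   filtering and exported values.
#' @return A list of class `PreprocessConfig`.
#' @export
preprocess_config <- function(sd_cutoff = 1,
                              center_mode = c("per_gene_global",
                                              "per_gene_within_dataset",
                                              "none")) {
  stopifnot(is.numeric(sd_cutoff), length(sd_cutoff) == 1L, sd_cutoff >= 0)
  center_mode <- match.arg(center_mode)
  structure(list(sd_cutoff = sd_cutoff, center_mode = center_mode),
            class = "PreprocessConfig")
}

#' Mean-center gene expression rows
#'
#' Subtracts per-gene means so each gene row has mean zero.  For a
#' `Cohort` in `per_gene_global` mode the mean is taken over all samples
#' pooled across datasets; in `per_gene_within_dataset` mode each dataset
#' is centered on its own; `none` returns the input unchanged.
#'
#' @param x An `ExpressionDataset` or `Cohort`.
#' @param cfg A [preprocess_config()].
#' @return Object of the same class with centered values; annotations are
#'   untouched.
#' @export
mean_center <- function(x, cfg = preprocess_config()) UseMethod("mean_center")

#' @export
mean_center.ExpressionDataset <- function(x, cfg = preprocess_config()) {
  if (cfg$center_mode == "none") return(x)
  x$values <- x$values - rowMeans(x$values)
  x
}

#' @export
mean_center.Cohort <- function(x, cfg = preprocess_config()) {
  if (cfg$center_mode == "none") return(x)
  if (cfg$center_mode == "per_gene_within_dataset") {
    x$datasets <- lapply(x$datasets, mean_center, cfg = cfg)
    return(cohort(x$datasets))
  }
  pooled_mean <- rowMeans(pool_cohort(x))
  x$datasets <- lapply(x$datasets, function(d) {
    d$values <- d$values - pooled_mean
    d
  })
  cohort(x$datasets)
}

#' Filter genes by pooled standard deviation
#'
#' Retains genes whose sample standard deviation (n - 1 denominator),
#' computed over all samples pooled across the cohort's datasets, is
#' strictly greater than `cfg$sd_cutoff`.  Gene order is preserved.  With
#' the default cutoff of 1 this is the classic "most varying genes" filter
#' applied before network construction.
#'
#' @param coh A `Cohort`.
#' @param cfg A [preprocess_config()].
#' @return The filtered `Cohort`, with attribute `"n_dropped"` recording how
#'   many genes were removed.
#' @export
variance_filter <- function(coh, cfg = preprocess_config()) {
  stopifnot(inherits(coh, "Cohort"))
  pooled <- pool_cohort(coh)
  n <- ncol(pooled)
  if (n < 2L) stop("variance filtering needs at least 2 pooled samples")
  sds <- sqrt(rowSums((pooled - rowMeans(pooled))^2) / (n - 1))
  keep <- sds > cfg$sd_cutoff
  if (!any(keep))
    stop(sprintf(
      "no gene exceeds SD cutoff %.3g (observed SD range [%.3g, %.3g])",
      cfg$sd_cutoff, min(sds), max(sds)))
  out <- coh
  out$datasets <- lapply(coh$datasets, function(d) {
    d$values <- d$values[keep, , drop = FALSE]
    d$gene_ids <- rownames(d$values)
    d
  })
  out <- cohort(out$datasets)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Align datasets on their common gene set
#'
#' Restricts every dataset to the intersection of all datasets' gene ids,
#' in a single shared order (the first dataset's order restricted to the
#' intersection), and returns the resulting [cohort()].
#'
#' @param datasets List of two or more `ExpressionDataset` objects.
#' @return A `Cohort`; attribute `"dropped_per_dataset"` gives, per dataset,
#'   how many of its genes fell outside the intersection.
#' @export
align_datasets <- function(datasets) {
  stopifnot(is.list(datasets))
  if (length(datasets) < 2L)
    stop("alignment requires at least 2 datasets")
  gene_sets <- lapply(datasets, `[[`, "gene_ids")
  common <- Reduce(intersect, gene_sets)
  if (length(common) == 0L)
    stop("datasets share no genes; cannot align")
  common <- gene_sets[[1]][gene_sets[[1]] %in% common]
  dropped <- vapply(gene_sets, function(g) length(g) - length(common), integer(1))
  names(dropped) <- vapply(datasets, `[[`, character(1), "dataset_id")
  aligned <- lapply(datasets, function(d) {
    d$values <- d$values[common, , drop = FALSE]
    d$gene_ids <- common
    d
  })
  out <- cohort(aligned)
  attr(out, "dropped_per_dataset") <- dropped
  out
}
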