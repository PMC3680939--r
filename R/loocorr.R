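#' Leave-one-out minimum pairwise Pearson correlations
#'
#' For a cohort of D datasets, computes D full gene-gene Pearson correlation
#' matrices, each on the pooled samples of the D - 1 datasets retained after
#' excluding one dataset, and stores for every gene pair the minimum of the
#' D values.  Pairs whose minimum is not strictly positive are marked absent
#' (`NA`).  Requiring a positive correlation in every leave-one-out
#' calculation removes edges driven by a confounder inherent to a single
#' dataset (a batch artifact): excluding the offending dataset collapses the
#' correlation, and the minimum with it.
#'
#' A gene that is constant within some leave-one-out pool has undefined
#' correlations there; all its pairs are marked absent with a warning.
#'
#' @param coh A `Cohort` with at least two datasets.
#' @param min_samples Minimum pooled sample count required in every
#'   leave-one-out pool (default 30); smaller pools make single-pool
#'   correlation estimates too noisy for a minimum statistic.
#' @return A [correlation_matrix()] whose retained entries lie in (0, 1].
#' @export
loo_min_correlation <- function(coh, min_samples = 30L) {
  stopifnot(inherits(coh, "Cohort"))
  D <- length(coh$datasets)
  if (D < 2L)
    stop("leave-one-out correlations need at least 2 datasets, got ", D)
  ns <- vapply(coh$datasets, function(d) ncol(d$values), integer(1))
  total <- sum(ns)
  if (any(total - ns < min_samples))
    stop("leave-one-out pool(s) below min_samples = ", min_samples,
         " (smallest pool: ", min(total - ns), " samples)")
  min_r <- NULL
  degenerate <- rep(FALSE, length(coh$gene_ids))
  for (d in seq_len(D)) {
    pooled <- do.call(cbind, lapply(coh$datasets[-d], `[[`, "values"))
    sds <- apply(pooled, 1L, stats::sd)
    if (any(sds == 0)) degenerate <- degenerate | (sds == 0)
    r <- suppressWarnings(stats::cor(t(pooled)))
    min_r <- if (is.null(min_r)) r else pmin(min_r, r)
  }
  if (any(degenerate))
    warning("gene(s) constant within a leave-one-out pool, pairs marked absent: ",
            paste(utils::head(coh$gene_ids[degenerate], 5), collapse = ", "))
  min_r[is.na(min_r) | min_r <= 0] <- NA_real_
  dimnames(min_r) <- list(coh$gene_ids, coh$gene_ids)
  correlation_matrix(min_r, n_datasets = D)
}

#' Plain Pearson correlation matrix for a sample subset
#'
#' Convenience wrapper producing a [correlation_matrix()] from a single
#' dataset (or pooled cohort) restricted to selected samples, without
#' leave-one-out minimisation or positivity filtering.  Used by the
#' subgroup interconnectivity tests, which recompute correlations within
#' sample strata of one dataset.
#'
#' @param x An `ExpressionDataset`, `Cohort`, or bare genes x samples matrix.
#' @param samples Optional sample selector (indices or column names);
#'   default uses all samples.
#' @return A `CorrelationMatrix` with `n_datasets = 1`; entries may be
#'   negative (no filtering is applied).
#' @export
sample_correlation <- function(x, samples = NULL) {
  values <- if (inherits(x, "ExpressionDataset")) x$values
            else if (inherits(x, "Cohort")) pool_cohort(x)
            else as.matrix(x)
  if (is.null(rownames(values))) stop("expression matrix must have gene row names")
  if (!is.null(samples)) values <- values[, samples, drop = FALSE]
  if (ncol(values) < 3L) stop("need at least 3 samples to estimate correlations")
  r <- suppressWarnings(stats::cor(t(values)))
  correlation_matrix(r, n_datasets = 1L)
}

#' Permutation null for the correlation significance threshold
#'
#' Destroys all gene-gene correlation while preserving each gene's marginal
#' distribution by independently permuting every gene's values across the
#' pooled samples, then records the maximum pairwise Pearson correlation of
#' the permuted matrix.  Repeating this `n_perm` times yields a null
#' distribution of maxima; the overall maximum across repetitions is the
#' significance threshold -- any observed correlation above it exceeds
#' everything seen under the null.
#'
#' The permutation stream is fully determined by `seed`: repetitions are
#' processed in order and within each repetition genes are permuted in row
#' order, one `sample.int()` draw per gene.
#'
#' @param coh A `Cohort` (or a bare genes x samples matrix) already filtered
#'   to the analysis genes.
#' @param n_perm Number of repetitions (>= 1).
#' @param seed Integer seed.
#' @return A list of class `PermutationNull` with elements `n_perm`, `seed`,
#'   `per_perm_max` (one maximum per repetition) and `threshold`
#'   (`max(per_perm_max)`).
#' @export
permutation_threshold <- function(coh, n_perm = 1000L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  values <- if (inherits(coh, "Cohort")) pool_cohort(coh) else as.matrix(coh)
  n <- ncol(values)
  G <- nrow(values)
  if (G < 2L) stop("need at least 2 genes")
  per_perm_max <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm <- values
      for (g in seq_len(G)) perm[g, ] <- perm[g, sample.int(n)]
      r <- stats::cor(t(perm))
      diag(r) <- NA_real_
      max(r, na.rm = TRUE)
    }, numeric(1))
  })
  structure(list(n_perm = as.integer(n_perm), seed = seed,
                 per_perm_max = per_perm_max,
                 threshold = max(per_perm_max)),
            class = "PermutationNull")
}

#' @export
print.PermutationNull <- function(x, ...) {
  cat("PermutationNull: ", x$n_perm, " repetition(s), threshold = ",
      format(x$threshold, digits = 4),
      " (per-repetition max range [",
      format(min(x$per_perm_max), digits = 4), ", ",
      format(max(x$per_perm_max), digits = 4), "])\n", sep = "")
  invisible(x)
}
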