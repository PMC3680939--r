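#' Module co-expression versus random gene sets
#'
#' Measures how tightly a module's genes are co-expressed in a target
#' dataset as the average pairwise Pearson correlation over all gene pairs
#' of the module, and compares it to `n_random` gene sets of the same size
#' drawn uniformly from the dataset's gene universe.  The empirical p-value
#' uses the add-one (resample-inclusive) estimator, so it is never zero.
#'
#' @param module A [gene_module()].
#' @param ds An `ExpressionDataset` (or `Cohort`, pooled).
#' @param n_random Number of random gene sets for the null (default 1000);
#'   0 skips the null.
#' @param seed Integer seed for the random draws.
#' @return List of class `CoexpressionSummary`: `module_id`,
#'   `mean_pairwise_r`, `n_genes_used`, `null_mean_r` (vector), `empirical_p`.
#' @export
module_coexpression <- function(module, ds, n_random = 1000L, seed = 1L) {
  stopifnot(inherits(module, "GeneModule"), n_random >= 0)
  values <- if (inherits(ds, "Cohort")) pool_cohort(ds) else ds$values
  present <- intersect(module$gene_ids, rownames(values))
  if (length(present) < 2L) {
    missing <- setdiff(module$gene_ids, rownames(values))
    stop("fewer than 2 module genes present in the dataset; missing: ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  mean_pair_r <- function(genes) {
    r <- stats::cor(t(values[genes, , drop = FALSE]))
    mean(r[upper.tri(r)])
  }
  observed <- mean_pair_r(present)
  null_mean_r <- numeric(0)
  empirical_p <- NA_real_
  if (n_random > 0L) {
    universe <- rownames(values)
    null_mean_r <- withr::with_seed(seed,
      vapply(seq_len(n_random), function(i)
        mean_pair_r(sample(universe, length(present))), numeric(1)))
    empirical_p <- (1 + sum(null_mean_r >= observed)) / (1 + n_random)
  }
  structure(list(module_id = module$module_id,
                 mean_pairwise_r = observed,
                 n_genes_used = length(present),
                 null_mean_r = null_mean_r,
                 empirical_p = empirical_p),
            class = "CoexpressionSummary")
}

#' @export
print.CoexpressionSummary <- function(x, ...) {
  cat("Module '", x$module_id, "': mean pairwise r = ",
      format(x$mean_pairwise_r, digits = 3), " over ", x$n_genes_used,
      " genes", sep = "")
  if (!is.na(x$empirical_p))
    cat("; empirical p = ", format(x$empirical_p, digits = 3),
        " (", length(x$null_mean_r), " random sets)", sep = "")
  cat("\n")
  invisible(x)
}

#' Network average clustering coefficient (NACC)
#'
#' The fraction of realized connections within a gene set at a correlation
#' cutoff: the number of gene pairs whose weight is strictly above the
#' cutoff, divided by the maximum possible number of pairs m(m-1)/2.
#' Absent (`NA`) pairs never qualify.
#'
#' @param genes Character vector of at least two genes present in `corr`.
#' @param corr A [correlation_matrix()] or square weight matrix.
#' @param cutoff Correlation cutoff.
#' @return A value in \[0, 1\].
#' @export
nacc <- function(genes, corr, cutoff) {
  w <- corr_values(corr)
  genes <- unique(as.character(genes))
  missing <- setdiff(genes, rownames(w))
  if (length(missing) > 0L)
    stop("gene(s) absent from the correlation matrix: ",
         paste(utils::head(missing, 10), collapse = ", "))
  m <- length(genes)
  if (m < 2L) stop("NACC needs at least 2 genes")
  sub <- w[genes, genes]
  qualifying <- sum(!is.na(sub) & sub > cutoff) / 2
  qualifying / (m * (m - 1) / 2)
}

# Cross-only variant: qualifying A-B pairs over |A| * |B| possible.
nacc_cross <- function(genesA, genesB, corr, cutoff) {
  w <- corr_values(corr)
  if (length(intersect(genesA, genesB)) > 0L)
    stop("gene sets overlap; cross-only NACC requires disjoint sets")
  missing <- setdiff(c(genesA, genesB), rownames(w))
  if (length(missing) > 0L)
    stop("gene(s) absent from the correlation matrix: ",
         paste(utils::head(missing, 10), collapse = ", "))
  sub <- w[genesA, genesB, drop = FALSE]
  sum(!is.na(sub) & sub > cutoff) / (length(genesA) * length(genesB))
}

#' NACC profile over a cutoff grid
#'
#' Evaluates the interconnectivity of one gene set, or of a pair of sets,
#' at each cutoff of an ascending grid.  With two sets, `combine_mode`
#' `"union"` treats them as one module (the classic clustering-coefficient
#' reading), while `"cross_only"` counts only between-set pairs over
#' |A| x |B| possible -- a sharper measure of the coupling between two
#' modules.  Profiles are non-increasing in the cutoff by construction.
#'
#' @param genesA Character vector of genes.
#' @param genesB Optional second gene set; `NULL` for a single-set profile.
#' @param corr A [correlation_matrix()] or weight matrix.
#' @param cutoffs Ascending cutoff grid.
#' @param combine_mode `"union"` or `"cross_only"` (two-set calls only).
#' @return List of class `NACCProfile` with `cutoffs`, `nacc` (one value per
#'   cutoff), `combine_mode`, and the gene sets used.
#' @export
nacc_profile <- function(genesA, genesB = NULL, corr,
                         cutoffs = c(0.3, 0.4, 0.5, 0.6, 0.7),
                         combine_mode = c("union", "cross_only")) {
  if (is.unsorted(cutoffs, strictly = TRUE)) stop("cutoffs must be ascending")
  combine_mode <- match.arg(combine_mode)
  f <- if (is.null(genesB)) {
    function(cutoff) nacc(genesA, corr, cutoff)
  } else if (combine_mode == "union") {
    function(cutoff) nacc(union(genesA, genesB), corr, cutoff)
  } else {
    function(cutoff) nacc_cross(genesA, genesB, corr, cutoff)
  }
  values <- vapply(cutoffs, f, numeric(1))
  if (is.unsorted(rev(values)))
    stop("internal error: NACC profile must be non-increasing in the cutoff")
  structure(list(cutoffs = cutoffs, nacc = values,
                 combine_mode = if (is.null(genesB)) "single" else combine_mode,
                 genesA = genesA, genesB = genesB),
            class = "NACCProfile")
}

#' @export
print.NACCProfile <- function(x, ...) {
  cat("NACCProfile (", x$combine_mode, "):\n", sep = "")
  tab <- data.frame(cutoff = x$cutoffs, nacc = round(x$nacc, 4))
  if (!is.null(x$p_values)) tab$p <- signif(x$p_values, 3)
  if (!is.null(x$null_mean)) {
    tab$null_mean <- round(x$null_mean, 4)
    tab$null_sd <- round(x$null_sd, 4)
  }
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Subgroup interconnectivity test by subsampling
#'
#' Tests whether two modules are more interconnected in a small sample
#' subgroup (e.g. TP53-mutated tumors) than expected from the large
#' reference subgroup (e.g. TP53 wildtype).  The observed NACC profile is
#' computed on a correlation matrix estimated from the small group's
#' samples; the null redraws `n_resample` subsets of the large group of the
#' same size, recomputing correlations and NACC each time.  One-sided
#' p-values (high interconnectivity) use the add-one estimator; the null
#' mean and SD per cutoff are reported for plotting reference bands.
#'
#' @param genesA,genesB Module gene sets.
#' @param ds An `ExpressionDataset` (or `Cohort`; samples are pooled).
#' @param group_small Sample selector (indices or names) for the tested
#'   subgroup; must not be larger than `group_large`.
#' @param group_large Sample selector for the reference subgroup.
#' @param cutoffs Ascending cutoff grid.
#' @param n_resample Number of reference subsamples (default 10000).
#' @param seed Integer seed.
#' @param combine_mode Passed to [nacc_profile()].
#' @return A `NACCProfile` for the small group with extra fields
#'   `p_values`, `null_mean`, `null_sd` (per cutoff), `n_resample`,
#'   `n_small`, `n_large`.
#' @export
subgroup_nacc_test <- function(genesA, genesB, ds, group_small, group_large,
                               cutoffs = c(0.3, 0.4, 0.5, 0.6, 0.7),
                               n_resample = 10000L, seed = 1L,
                               combine_mode = c("union", "cross_only")) {
  combine_mode <- match.arg(combine_mode)
  values <- if (inherits(ds, "Cohort")) pool_cohort(ds) else ds$values
  idx <- function(sel) if (is.character(sel)) match(sel, colnames(values)) else sel
  small <- idx(group_small); large <- idx(group_large)
  if (anyNA(small) || anyNA(large)) stop("unknown sample id in group selector")
  if (length(small) == 0L || length(large) == 0L)
    stop("both sample groups must be non-empty")
  if (length(small) > length(large))
    stop("the tested subgroup (", length(small),
         ") may not be larger than the reference subgroup (", length(large), ")")
  genes <- union(genesA, genesB)
  sub_values <- values[genes, , drop = FALSE]
  profile_for <- function(cols) {
    corr <- sample_correlation(sub_values, cols)
    nacc_profile(genesA, genesB, corr, cutoffs, combine_mode)$nacc
  }
  observed <- profile_for(small)
  null_mat <- withr::with_seed(seed,
    vapply(seq_len(n_resample), function(i)
      profile_for(sample(large, length(small))), numeric(length(cutoffs))))
  null_mat <- matrix(null_mat, nrow = length(cutoffs))
  p <- (1 + rowSums(null_mat >= observed)) / (1 + n_resample)
  out <- nacc_profile(genesA, genesB,
                      sample_correlation(sub_values, small),
                      cutoffs, combine_mode)
  out$p_values <- p
  out$null_mean <- rowMeans(null_mat)
  out$null_sd <- apply(null_mat, 1L, stats::sd)
  out$n_resample <- as.integer(n_resample)
  out$n_small <- length(small)
  out$n_large <- length(large)
  out
}

#' NACC profiles within expression quartiles of a stratifier gene
#'
#' Splits the samples into four equal-size groups by the expression of a
#' stratifier gene (e.g. TP53), using rank order with ties broken by input
#' sample order, and computes the between-module NACC profile within each
#' quartile plus an all-sample reference.  Quartile sizes differ by at most
#' one sample.
#'
#' @param genesA,genesB Module gene sets.
#' @param ds An `ExpressionDataset` (or `Cohort`, pooled).
#' @param stratifier_gene Gene whose expression defines the quartiles.
#' @param cutoffs Ascending cutoff grid.
#' @param combine_mode Passed to [nacc_profile()].
#' @return List with `quartiles` (list of 4 `NACCProfile`s, Q1 = lowest
#'   expression), `reference` (all samples), and `quartile_samples`.
#' @export
quartile_nacc <- function(genesA, genesB, ds, stratifier_gene,
                          cutoffs = c(0.3, 0.4, 0.5, 0.6, 0.7),
                          combine_mode = c("union", "cross_only")) {
  combine_mode <- match.arg(combine_mode)
  values <- if (inherits(ds, "Cohort")) pool_cohort(ds) else ds$values
  if (!stratifier_gene %in% rownames(values))
    stop("stratifier gene '", stratifier_gene, "' not present in the dataset")
  n <- ncol(values)
  if (n < 32L) stop("need at least 8 samples per quartile (32 total), got ", n)
  ord <- order(values[stratifier_gene, ])  # stable: ties keep input order
  qsize <- rep(n %/% 4L, 4L)
  extra <- n %% 4L
  if (extra > 0L) qsize[seq_len(extra)] <- qsize[seq_len(extra)] + 1L
  bounds <- cumsum(c(0L, qsize))
  quart_samples <- lapply(1:4, function(q) ord[(bounds[q] + 1L):bounds[q + 1L]])
  genes <- union(genesA, genesB)
  sub_values <- values[genes, , drop = FALSE]
  prof <- function(cols) nacc_profile(genesA, genesB,
                                      sample_correlation(sub_values, cols),
                                      cutoffs, combine_mode)
  list(quartiles = lapply(quart_samples, prof),
       reference = prof(seq_len(n)),
       quartile_samples = lapply(quart_samples, function(i) colnames(values)[i]))
}

#' Rank-based module activity scores
#'
#' Summarizes each module's expression per sample.  In `rank_mean` mode all
#' G genes are ranked ascending within each sample (average ranks on ties)
#' and the score is the mean rank of the module's genes divided by G,
#' giving a value in (0, 1] that is invariant to any strictly increasing
#' transform of that sample's expression vector.  `expression_sum` mode
#' returns the plain per-sample sum of the module genes' values.
#'
#' Modules with some genes absent from the dataset are scored on the
#' present subset with a warning, provided at least half the genes are
#' present.
#'
#' @param modules List of [gene_module()] objects (a single module is
#'   accepted).
#' @param ds An `ExpressionDataset` (or `Cohort`, pooled).
#' @param mode `"rank_mean"` or `"expression_sum"`.
#' @return A list of class `ModuleActivityScores`: `scores` (modules x
#'   samples matrix), `scoring_mode`, `n_genes_used`.
#' @export
activity_scores <- function(modules, ds,
                            mode = c("rank_mean", "expression_sum")) {
  mode <- match.arg(mode)
  if (inherits(modules, "GeneModule")) modules <- list(modules)
  values <- if (inherits(ds, "Cohort")) pool_cohort(ds) else ds$values
  G <- nrow(values)
  ranks <- if (mode == "rank_mean") apply(values, 2L, rank) else NULL
  rows <- lapply(modules, function(mod) {
    present <- intersect(mod$gene_ids, rownames(values))
    frac <- length(present) / length(mod$gene_ids)
    if (frac < 0.5)
      stop("module '", mod$module_id, "': only ",
           length(present), "/", length(mod$gene_ids),
           " genes present (< 50%); cannot score")
    if (frac < 1)
      warning("module '", mod$module_id, "': scoring on ",
              length(present), "/", length(mod$gene_ids), " present genes")
    if (mode == "rank_mean")
      colMeans(ranks[present, , drop = FALSE]) / G
    else
      colSums(values[present, , drop = FALSE])
  })
  scores <- do.call(rbind, rows)
  rownames(scores) <- vapply(modules, `[[`, character(1), "module_id")
  colnames(scores) <- colnames(values)
  structure(list(scores = scores, scoring_mode = mode,
                 n_genes_used = vapply(modules, function(m)
                   length(intersect(m$gene_ids, rownames(values))), integer(1))),
            class = "ModuleActivityScores")
}

#' @export
print.ModuleActivityScores <- function(x, ...) {
  cat("ModuleActivityScores (", x$scoring_mode, "): ",
      nrow(x$scores), " module(s) x ", ncol(x$scores), " samples\n", sep = "")
  invisible(x)
}

#' Spearman correlation between a module score and a single gene
#'
#' @param scores A [activity_scores()] result.
#' @param module_id Module row to use.
#' @param gene Gene whose expression is correlated with the score.
#' @param ds The `ExpressionDataset` (or `Cohort`) the scores refer to.
#' @return Spearman's rho (single number).
#' @export
gene_module_correlation <- function(scores, module_id, gene, ds) {
  stopifnot(inherits(scores, "ModuleActivityScores"))
  values <- if (inherits(ds, "Cohort")) pool_cohort(ds) else ds$values
  if (!module_id %in% rownames(scores$scores))
    stop("unknown module id '", module_id, "'")
  if (!gene %in% rownames(values)) stop("gene '", gene, "' not in dataset")
  s <- scores$scores[module_id, ]
  g <- values[gene, colnames(scores$scores)]
  if (stats::sd(g) == 0 || stats::sd(s) == 0)
    stop("Spearman correlation undefined: constant ",
         if (stats::sd(g) == 0) "gene expression" else "module scores")
  stats::cor(s, g, method = "spearman")
}

#' Cross-dataset conserved module core
#'
#' Identifies the part of a module whose co-expression survives in a second
#' correlation matrix (e.g. the same genes in another cancer type).
#' Conserved edges are module-internal gene pairs with weight strictly
#' above `cutoff` in BOTH matrices; the core is the largest connected
#' component of the conserved-edge graph (empty when there are no conserved
#' edges).
#'
#' @param module A [gene_module()].
#' @param corr_source Correlation matrix of the cohort the module came from.
#' @param corr_other Correlation matrix of the validation cohort.
#' @param cutoff Correlation cutoff.
#' @return List of class `ConservedCore`: `source_module`,
#'   `conserved_edges` (data.frame gene_a/gene_b), `core_genes`.
#' @export
module_conservation <- function(module, corr_source, corr_other, cutoff) {
  stopifnot(inherits(module, "GeneModule"))
  ws <- corr_values(corr_source)
  wo <- corr_values(corr_other)
  genes <- intersect(module$gene_ids, intersect(rownames(ws), rownames(wo)))
  if (length(genes) < length(module$gene_ids))
    warning("module '", module$module_id, "': ",
            length(module$gene_ids) - length(genes),
            " gene(s) absent from one of the matrices, dropped")
  if (length(genes) < 2L)
    return(structure(list(source_module = module,
                          conserved_edges = data.frame(gene_a = character(0),
                                                       gene_b = character(0)),
                          core_genes = character(0)),
                     class = "ConservedCore"))
  ss <- ws[genes, genes]; so <- wo[genes, genes]
  conserved <- !is.na(ss) & ss > cutoff & !is.na(so) & so > cutoff
  conserved[lower.tri(conserved, diag = TRUE)] <- FALSE
  idx <- which(conserved, arr.ind = TRUE)
  edges <- data.frame(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                      stringsAsFactors = FALSE)
  core <- character(0)
  if (nrow(edges) > 0L) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    comp <- igraph::components(g)
    core <- sort(igraph::V(g)$name[comp$membership == which.max(comp$csize)])
  }
  structure(list(source_module = module, conserved_edges = edges,
                 core_genes = core),
            class = "ConservedCore")
}

#' @export
print.ConservedCore <- function(x, ...) {
  cat("ConservedCore of '", x$source_module$module_id, "': ",
      length(x$core_genes), " core genes, ",
      nrow(x$conserved_edges), " conserved edges\n", sep = "")
  invisible(x)
}

#' Dichotomize activity scores at the module mean
#'
#' Labels each sample `"above"` when its score is strictly greater than the
#' module's mean score, `"below"` otherwise (so all-equal scores are all
#' "below").  Labels are invariant to affine transforms of the score
#' vector and are the standard export for external survival tooling.
#'
#' @param scores A [activity_scores()] result.
#' @param module_id Module row to dichotomize.
#' @return Named character vector (`"above"`/`"below"`) over samples.
#' @export
dichotomize_scores <- function(scores, module_id) {
  stopifnot(inherits(scores, "ModuleActivityScores"))
  if (!module_id %in% rownames(scores$scores))
    stop("unknown module id '", module_id, "'")
  s <- scores$scores[module_id, ]
  if (length(s) < 2L) stop("need at least 2 samples to dichotomize")
  ifelse(s > mean(s), "above", "below")
}
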