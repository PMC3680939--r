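#' Configuration for the synthetic multi-dataset cohort generator
#'
#' Describes a Gaussian factor-model cohort: each planted module m has one
#' standard-normal factor per sample, and a member gene's value is
#' `sqrt(rho) * factor + sqrt(1 - rho) * noise`, giving expected
#' within-module pairwise correlation exactly `rho`.  Coupled module pairs
#' share factor correlation `tau` (`tau_alt` for samples carrying the
#' alternative covariate label), giving expected cross-module gene
#' correlation `tau * sqrt(rho_i * rho_j)`.  Background genes are
#' independent noise.  Optional per-(dataset, gene) additive batch shifts
#' and a single-dataset artifact module emulate study-specific confounding.
#'
#' The default scenario is a compact multi-study cohort: 4 datasets of 150
#' samples each, 500 genes, and 8 modules of sizes 10-30 with within-module
#' correlations between 0.65 and 0.85.  Correlation strength is paired
#' inversely with size: a small module is detectable at a stringent network
#' cutoff only if its members are very tightly correlated (each gene in a
#' 10-gene module has just 9 potential neighbors from which it must keep 5),
#' whereas large modules tolerate looser correlations -- so the defaults give
#' every planted module a comparable recovery margin.
#'
#' @param n_datasets Number of studies (default 4).
#' @param samples_per_dataset Samples per study; scalar or length
#'   `n_datasets` vector (default 150).
#' @param n_genes Total gene count (default 500).
#' @param modules Data.frame (or list coercible to one) with columns `size`
#'   and `rho`; module genes are allocated from the start of the gene list.
#' @param cross_couplings Optional data.frame with columns `module_i`,
#'   `module_j` (1-based module indices), `tau_base`, `tau_alt`: factor
#'   correlation for base- and alternative-covariate samples.
#' @param covariate_name Annotation column carrying the coupling covariate
#'   (default `"tp53_status"`).
#' @param base_label,alt_label Covariate labels (defaults `"wildtype"`,
#'   `"mutant"`).
#' @param alt_fraction Fraction of samples carrying `alt_label`
#'   (default 0.25).
#' @param batch_shift_sd SD of additive per-(dataset, gene) mean shifts
#'   (default 0 = no batch structure).
#' @param artifact_module Optional list `(size, rho, dataset)`: a gene set
#'   sharing a factor ONLY inside the named/indexed dataset, independent
#'   noise elsewhere -- the planted input for leave-one-out batch-defense
#'   tests.  Its genes are taken from the background pool.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A list of class `SyntheticCohortConfig`.
#' @export
synthetic_cohort_config <- function(n_datasets = 4L,
                                    samples_per_dataset = 150L,
                                    n_genes = 500L,
                                    modules = data.frame(
                                      size = c(30L, 28L, 24L, 20L, 16L, 14L, 12L, 10L),
                                      rho = seq(0.65, 0.85, length.out = 8)),
                                    cross_couplings = NULL,
                                    covariate_name = "tp53_status",
                                    base_label = "wildtype",
                                    alt_label = "mutant",
                                    alt_fraction = 0.25,
                                    batch_shift_sd = 0,
                                    artifact_module = NULL,
                                    seed = 1L) {
  modules <- as.data.frame(modules)
  stopifnot(all(c("size", "rho") %in% colnames(modules)),
            all(modules$size >= 1), all(modules$rho >= 0), all(modules$rho < 1),
            n_datasets >= 1, n_genes >= 1,
            alt_fraction >= 0, alt_fraction <= 1, batch_shift_sd >= 0)
  samples_per_dataset <- rep_len(as.integer(samples_per_dataset), n_datasets)
  n_art <- if (is.null(artifact_module)) 0L else artifact_module$size
  if (sum(modules$size) + n_art > n_genes)
    stop("module sizes (plus artifact module) exceed n_genes")
  if (!is.null(cross_couplings)) {
    cross_couplings <- as.data.frame(cross_couplings)
    stopifnot(all(c("module_i", "module_j", "tau_base", "tau_alt") %in%
                    colnames(cross_couplings)),
              all(abs(cross_couplings$tau_base) < 1),
              all(abs(cross_couplings$tau_alt) < 1))
  }
  if (!is.null(artifact_module))
    stopifnot(all(c("size", "rho", "dataset") %in% names(artifact_module)),
              artifact_module$rho >= 0, artifact_module$rho < 1)
  structure(list(n_datasets = as.integer(n_datasets),
                 samples_per_dataset = samples_per_dataset,
                 n_genes = as.integer(n_genes),
                 modules = modules,
                 cross_couplings = cross_couplings,
                 covariate_name = covariate_name,
                 base_label = base_label, alt_label = alt_label,
                 alt_fraction = alt_fraction,
                 batch_shift_sd = batch_shift_sd,
                 artifact_module = artifact_module,
                 seed = as.integer(seed)),
            class = "SyntheticCohortConfig")
}

# Factor correlation matrix for one covariate stratum; errors before any
# sampling when the requested coupling structure is not positive definite.
factor_sigma <- function(K, couplings, tau_col) {
  sigma <- diag(K)
  if (!is.null(couplings) && nrow(couplings) > 0L) {
    for (r in seq_len(nrow(couplings))) {
      i <- couplings$module_i[r]; j <- couplings$module_j[r]
      if (i < 1 || j < 1 || i > K || j > K || i == j)
        stop("invalid module indices in cross_couplings: ", i, ", ", j)
      sigma[i, j] <- sigma[j, i] <- couplings[[tau_col]][r]
    }
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("requested cross-coupling structure is not positive definite ",
         "(smallest eigenvalue ", format(min(ev), digits = 3), ")")
  sigma
}

#' Generate a synthetic multi-dataset expression cohort
#'
#' Samples a cohort from the factor model described in
#' [synthetic_cohort_config()], together with a ground-truth object for
#' parameter-recovery tests.
#'
#' @param cfg A [synthetic_cohort_config()].
#' @return List with elements `cohort` (a [cohort()]) and `truth` (class
#'   `SyntheticTruth`): `module_genes` (named list), `factors` (pooled
#'   samples x modules matrix; each column doubles as the per-sample
#'   activity amplitude of that module), `covariate` (named vector over
#'   pooled samples), `artifact_genes`, `artifact_dataset`, `config`.
#' @export
generate_cohort <- function(cfg = synthetic_cohort_config()) {
  stopifnot(inherits(cfg, "SyntheticCohortConfig"))
  K <- nrow(cfg$modules)
  n_per <- cfg$samples_per_dataset
  n_total <- sum(n_per)
  G <- cfg$n_genes
  gene_ids <- sprintf("g%04d", seq_len(G))
  module_ids <- sprintf("mod%02d", seq_len(K))
  sizes <- cfg$modules$size
  stops <- cumsum(sizes)
  starts <- c(1L, utils::head(stops, -1L) + 1L)
  module_genes <- lapply(seq_len(K), function(k) gene_ids[starts[k]:stops[k]])
  names(module_genes) <- module_ids
  art <- cfg$artifact_module
  artifact_genes <- character(0)
  art_ds <- NA_integer_
  if (!is.null(art)) {
    artifact_genes <- gene_ids[(stops[K] + 1L):(stops[K] + art$size)]
    art_ds <- if (is.character(art$dataset))
      match(art$dataset, paste0("D", seq_len(cfg$n_datasets)))
    else as.integer(art$dataset)
    if (is.na(art_ds) || art_ds < 1L || art_ds > cfg$n_datasets)
      stop("artifact_module$dataset does not name a cohort dataset")
  }
  sigma_base <- factor_sigma(K, cfg$cross_couplings, "tau_base")
  sigma_alt <- factor_sigma(K, cfg$cross_couplings, "tau_alt")
  dataset_of <- rep(seq_len(cfg$n_datasets), times = n_per)
  sample_ids <- sprintf("d%d_s%03d", dataset_of,
                        unlist(lapply(n_per, seq_len)))
  out <- withr::with_seed(cfg$seed, {
    covariate <- ifelse(stats::runif(n_total) < cfg$alt_fraction,
                        cfg$alt_label, cfg$base_label)
    z <- matrix(stats::rnorm(n_total * K), n_total, K)
    factors <- matrix(NA_real_, n_total, K,
                      dimnames = list(sample_ids, module_ids))
    is_alt <- covariate == cfg$alt_label
    if (any(!is_alt))
      factors[!is_alt, ] <- z[!is_alt, , drop = FALSE] %*% chol(sigma_base)
    if (any(is_alt))
      factors[is_alt, ] <- z[is_alt, , drop = FALSE] %*% chol(sigma_alt)
    values <- matrix(stats::rnorm(G * n_total), G, n_total,
                     dimnames = list(gene_ids, sample_ids))
    for (k in seq_len(K)) {
      rows <- starts[k]:stops[k]
      values[rows, ] <- sqrt(cfg$modules$rho[k]) *
        matrix(factors[, k], length(rows), n_total, byrow = TRUE) +
        sqrt(1 - cfg$modules$rho[k]) * values[rows, , drop = FALSE]
    }
    if (!is.null(art)) {
      in_ds <- dataset_of == art_ds
      art_factor <- stats::rnorm(sum(in_ds))
      rows <- match(artifact_genes, gene_ids)
      values[rows, in_ds] <- sqrt(art$rho) *
        matrix(art_factor, length(rows), sum(in_ds), byrow = TRUE) +
        sqrt(1 - art$rho) * values[rows, in_ds, drop = FALSE]
    }
    if (cfg$batch_shift_sd > 0) {
      for (d in seq_len(cfg$n_datasets)) {
        shift <- stats::rnorm(G, sd = cfg$batch_shift_sd)
        values[, dataset_of == d] <- values[, dataset_of == d] + shift
      }
    }
    list(values = values, factors = factors, covariate = covariate)
  })
  datasets <- lapply(seq_len(cfg$n_datasets), function(d) {
    cols <- which(dataset_of == d)
    ann <- data.frame(row.names = sample_ids[cols])
    ann[[cfg$covariate_name]] <- out$covariate[cols]
    expression_dataset(paste0("D", d), out$values[, cols, drop = FALSE], ann)
  })
  truth <- structure(
    list(module_genes = module_genes,
         factors = out$factors,
         covariate = stats::setNames(out$covariate, sample_ids),
         artifact_genes = artifact_genes,
         artifact_dataset = art_ds,
         config = cfg),
    class = "SyntheticTruth")
  list(cohort = cohort(datasets), truth = truth)
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat("SyntheticTruth: ", length(x$module_genes), " planted modules (sizes ",
      paste(lengths(x$module_genes), collapse = ", "), ")",
      if (length(x$artifact_genes) > 0)
        paste0("; artifact module of ", length(x$artifact_genes),
               " genes in dataset ", x$artifact_dataset),
      "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic siRNA knockdown screen
#'
#' Emulates an arrayed knockdown screen read out by one log-intensity per
#' targeted gene: `intensity = baseline + shift(gene) + Normal(0, noise_sd)`,
#' with planted per-module shifts and flagged non-specific controls offset
#' by `control_shift`.
#'
#' @param n_genes Number of library genes, or a character vector of gene ids.
#' @param effect_modules List of `list(genes = <character>, shift = <numeric>)`
#'   entries with disjoint gene sets; genes named by id (ids outside the
#'   library are an error).
#' @param noise_sd Intensity noise SD (default 1).
#' @param n_controls Number of flagged non-specific controls (default 5).
#' @param control_shift Additive offset of the controls relative to
#'   `baseline` (default 0).
#' @param baseline Baseline log intensity (default 0).
#' @param seed Integer seed.
#' @return A [screen_data()] object; planted shifts are recorded in
#'   attribute `"planted_shifts"`.
#' @export
generate_screen <- function(n_genes = 5000L, effect_modules = list(),
                            noise_sd = 1, n_controls = 5L,
                            control_shift = 0, baseline = 0, seed = 1L) {
  gene_ids <- if (is.character(n_genes)) n_genes
              else sprintf("g%04d", seq_len(n_genes))
  all_effect <- unlist(lapply(effect_modules, `[[`, "genes"))
  if (anyDuplicated(all_effect))
    stop("effect module gene sets must be disjoint")
  if (!all(all_effect %in% gene_ids))
    stop("effect module gene(s) outside the screen library")
  shift <- stats::setNames(rep(0, length(gene_ids)), gene_ids)
  for (em in effect_modules) shift[em$genes] <- em$shift
  ctrl_ids <- if (n_controls > 0L) sprintf("ctrl%02d", seq_len(n_controls))
              else character(0)
  ids <- c(gene_ids, ctrl_ids)
  mu <- c(baseline + shift, rep(baseline + control_shift, n_controls))
  intensity <- withr::with_seed(seed,
    mu + stats::rnorm(length(ids), sd = noise_sd))
  out <- screen_data(ids, intensity,
                     is_control = c(rep(FALSE, length(gene_ids)),
                                    rep(TRUE, n_controls)))
  attr(out, "planted_shifts") <- shift
  out
}
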