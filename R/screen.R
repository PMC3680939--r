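#' siRNA screen data container
#'
#' One log-transformed Ki-67 staining intensity per targeted gene, with
#' non-specific control siRNAs flagged.  Replicate entries for the same
#' gene are collapsed by the median before testing.
#'
#' @param gene_ids Character vector of targeted genes.
#' @param intensity Numeric vector of log-transformed Ki-67 intensities.
#' @param is_control Logical (or 0/1) vector flagging non-specific controls.
#' @return A list of class `ScreenData`.
#' @export
screen_data <- function(gene_ids, intensity, is_control = FALSE) {
  gene_ids <- as.character(gene_ids)
  intensity <- as.numeric(intensity)
  is_control <- rep_len(as.logical(is_control), length(gene_ids))
  stopifnot(length(intensity) == length(gene_ids))
  if (any(!is.finite(intensity))) stop("screen intensities must be finite")
  if (anyDuplicated(gene_ids)) {
    agg <- tapply(intensity, gene_ids, stats::median)
    ctl <- tapply(is_control, gene_ids, any)
    ord <- unique(gene_ids)
    gene_ids <- ord
    intensity <- as.numeric(agg[ord])
    is_control <- as.logical(ctl[ord])
  }
  structure(list(gene_ids = gene_ids,
                 intensity = stats::setNames(intensity, gene_ids),
                 is_control = stats::setNames(is_control, gene_ids)),
            class = "ScreenData")
}

#' @export
print.ScreenData <- function(x, ...) {
  cat("ScreenData: ", length(x$gene_ids), " genes (",
      sum(x$is_control), " controls), intensity range [",
      format(min(x$intensity), digits = 3), ", ",
      format(max(x$intensity), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Module-level knockdown effect test
#'
#' Tests whether knocking down a module's genes reduces proliferation
#' (Ki-67 intensity) more than random gene groups of the same size.  The
#' observed statistic is the mean intensity over the module's screened
#' genes; the null draws `n_samples` gene groups of the same size, each
#' sampled uniformly without replacement from the screened library genes
#' (controls excluded by default).  The one-sided p-value for reduced
#' intensity is `(1 + #\{null <= observed\}) / (1 + n_samples)`;
#' `two_sided = TRUE` doubles the smaller tail (capped at 1).
#' `centered_mean` is the observed mean minus the null mean, the quantity
#' conventionally plotted against the null density.
#'
#' @param screen A [screen_data()] object.
#' @param module A [gene_module()].
#' @param n_samples Number of null gene groups (default 10000).
#' @param seed Integer seed.
#' @param exclude_controls Drop flagged controls from the null universe
#'   (default TRUE).
#' @param two_sided Report a two-sided p instead of the one-sided
#'   reduced-intensity p.
#' @return List of class `ScreenResult`: `module_id`, `observed_mean`,
#'   `centered_mean`, `null` (vector of null means), `p_one_sided`,
#'   `n_genes_used`.
#' @export
module_knockdown_test <- function(screen, module, n_samples = 10000L,
                                  seed = 1L, exclude_controls = TRUE,
                                  two_sided = FALSE) {
  stopifnot(inherits(screen, "ScreenData"), inherits(module, "GeneModule"),
            n_samples >= 1)
  present <- intersect(module$gene_ids, screen$gene_ids)
  if (length(present) == 0L)
    stop("no gene of module '", module$module_id, "' was screened")
  absent <- setdiff(module$gene_ids, screen$gene_ids)
  if (length(absent) > 0L)
    warning("module '", module$module_id, "': ", length(absent),
            " gene(s) not screened: ",
            paste(utils::head(absent, 10), collapse = ", "))
  universe <- if (exclude_controls)
    screen$gene_ids[!screen$is_control] else screen$gene_ids
  m <- length(present)
  if (m > length(universe))
    stop("module larger than the null universe (", length(universe), " genes)")
  observed <- mean(screen$intensity[present])
  null <- withr::with_seed(seed,
    vapply(seq_len(n_samples), function(i)
      mean(screen$intensity[sample(universe, m)]), numeric(1)))
  p_lower <- (1 + sum(null <= observed)) / (1 + n_samples)
  p_upper <- (1 + sum(null >= observed)) / (1 + n_samples)
  p <- if (two_sided) min(1, 2 * min(p_lower, p_upper)) else p_lower
  structure(list(module_id = module$module_id,
                 observed_mean = observed,
                 centered_mean = observed - mean(null),
                 null = null,
                 p_one_sided = p,
                 two_sided = two_sided,
                 n_genes_used = m),
            class = "ScreenResult")
}

#' @export
print.ScreenResult <- function(x, ...) {
  cat("ScreenResult '", x$module_id, "': observed mean = ",
      format(x$observed_mean, digits = 4), ", centered = ",
      format(x$centered_mean, digits = 4), ", ",
      if (x$two_sided) "two-sided" else "one-sided", " p = ",
      format(x$p_one_sided, digits = 3),
      " (", length(x$null), " null groups, ", x$n_genes_used, " genes)\n",
      sep = "")
  invisible(x)
}

#' Knockdown test for the non-specific control group
#'
#' Treats the screen's flagged control siRNAs as a module and runs
#' [module_knockdown_test()] against the library-gene null.  On screens
#' where most library genes themselves reduce proliferation, the controls
#' sit above the bulk and the centered mean is positive.
#'
#' @param screen A [screen_data()] object with at least one flagged control.
#' @param n_samples,seed,two_sided Passed to [module_knockdown_test()].
#' @return A `ScreenResult` for the control group.
#' @export
control_group_test <- function(screen, n_samples = 10000L, seed = 1L,
                               two_sided = FALSE) {
  stopifnot(inherits(screen, "ScreenData"))
  controls <- screen$gene_ids[screen$is_control]
  if (length(controls) == 0L) stop("screen has no flagged controls")
  ctl_module <- gene_module("controls", sort(controls),
                            label = "non-specific siRNA controls")
  # controls stay excluded from the null universe; they are not library genes
  module_knockdown_test(screen, ctl_module, n_samples = n_samples,
                        seed = seed, exclude_controls = TRUE,
                        two_sided = two_sided)
}
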