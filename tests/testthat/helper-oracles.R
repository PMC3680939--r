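# Independent brute-force oracles and small fixture builders shared by the
# suite.  The oracles deliberately avoid the package's code paths: the
# k-core oracle scans exhaustively over an adjacency matrix, the NACC
# oracle counts pairs in a double loop, and correlations are recomputed
# from the definition where needed.

# Exhaustive k-core: repeatedly delete nodes of degree < k from a logical
# adjacency matrix until a full scan removes nothing.
brute_kcore_nodes <- function(adj, k) {
  stopifnot(is.logical(adj), nrow(adj) == ncol(adj))
  diag(adj) <- FALSE
  alive <- rep(TRUE, nrow(adj))
  repeat {
    deg <- sapply(seq_len(nrow(adj)), function(i)
      if (alive[i]) sum(adj[i, alive]) else 0L)
    drop <- alive & deg < max(k, 1L)
    if (!any(drop)) break
    alive[drop] <- FALSE
  }
  rownames(adj)[alive]
}

# Pair-counting NACC from the definition.
brute_nacc <- function(genes, w, cutoff) {
  m <- length(genes)
  hits <- 0L
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    r <- w[genes[i], genes[j]]
    if (!is.na(r) && r > cutoff) hits <- hits + 1L
  }
  hits / (m * (m - 1) / 2)
}

# Random symmetric weight matrix with gene dimnames; density of present
# entries controlled by p_na.
random_weight_matrix <- function(n_genes, p_na = 0.2) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  w <- matrix(stats::runif(n_genes^2), n_genes, n_genes)
  w[stats::runif(n_genes^2) < p_na] <- NA_real_
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  diag(w) <- NA_real_
  dimnames(w) <- list(genes, genes)
  w
}

# Minimal multi-dataset cohort from a list of genes x samples matrices.
tiny_cohort <- function(mats, gene_ids = NULL) {
  if (is.null(gene_ids))
    gene_ids <- sprintf("g%02d", seq_len(nrow(mats[[1]])))
  ds <- lapply(seq_along(mats), function(i) {
    m <- mats[[i]]
    rownames(m) <- gene_ids
    colnames(m) <- sprintf("d%d_s%d", i, seq_len(ncol(m)))
    expression_dataset(paste0("D", i), m)
  })
  cohort(ds)
}

# Integer labelling of genes by module membership (0 = unassigned),
# for adjusted-Rand comparisons of partitions.
module_labels <- function(modules, genes) {
  lab <- stats::setNames(rep(0L, length(genes)), genes)
  for (i in seq_along(modules)) {
    gs <- if (inherits(modules[[i]], "GeneModule"))
      modules[[i]]$gene_ids else modules[[i]]
    lab[intersect(gs, genes)] <- i
  }
  lab
}
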