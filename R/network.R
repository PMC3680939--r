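#' Network construction configuration
#'
#' @param cutoff Correlation threshold; edges require weight strictly above
#'   it.  The landscape grid conventionally spans 0.3-0.7.
#' @param min_neighbors Minimum node degree k kept after pruning (default 5).
#' @param prune_mode `"iterative_kcore"` repeatedly removes nodes of degree
#'   < k until none remain (the k-core); `"single_pass"` removes low-degree
#'   nodes once, using degrees of the unpruned thresholded graph.  Isolated
#'   nodes are removed in both modes.
#' @return A list of class `NetworkConfig`.
#' @export
network_config <- function(cutoff = 0.6, min_neighbors = 5L,
                           prune_mode = c("iterative_kcore", "single_pass")) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0, cutoff < 1,
            min_neighbors >= 0)
  prune_mode <- match.arg(prune_mode)
  structure(list(cutoff = cutoff, min_neighbors = as.integer(min_neighbors),
                 prune_mode = prune_mode),
            class = "NetworkConfig")
}

#' Build a thresholded, degree-pruned co-expression network
#'
#' Connects gene pairs whose stored correlation weight is strictly greater
#' than `cfg$cutoff`, then prunes low-degree genes.  In `iterative_kcore`
#' mode pruning repeats until every remaining node has at least
#' `cfg$min_neighbors` neighbors (the k-core); `single_pass` removes
#' under-connected nodes once.  An empty network is a valid result.
#'
#' @param corr A [correlation_matrix()] (or square weight matrix with gene
#'   dimnames; `NA` entries mean "no pair").
#' @param cfg A [network_config()].
#' @return A list of class `CoexpressionNetwork` with elements `graph`
#'   (an undirected [igraph::graph] with edge attribute `weight`), `nodes`,
#'   `edges` (data.frame: gene_a, gene_b, weight), `cutoff`, `prune_mode`.
#' @export
build_network <- function(corr, cfg = network_config()) {
  w <- corr_values(corr)
  genes <- rownames(w)
  adj <- !is.na(w) & w > cfg$cutoff
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = genes[idx[, 1]], to = genes[idx[, 2]],
               weight = w[idx]),
    directed = FALSE,
    vertices = data.frame(name = genes))
  k <- cfg$min_neighbors
  if (cfg$prune_mode == "iterative_kcore") {
    keep <- igraph::coreness(g) >= max(k, 1L)
  } else {
    keep <- igraph::degree(g) >= max(k, 1L)
  }
  g <- igraph::induced_subgraph(g, which(keep))
  # single-pass removal can strand nodes; isolated nodes go in both modes
  g <- igraph::induced_subgraph(g, which(igraph::degree(g) > 0))
  el <- igraph::as_data_frame(g, what = "edges")
  names(el) <- c("gene_a", "gene_b", "weight")
  structure(list(graph = g,
                 nodes = igraph::V(g)$name,
                 edges = el,
                 cutoff = cfg$cutoff,
                 prune_mode = cfg$prune_mode),
            class = "CoexpressionNetwork")
}

#' @export
print.CoexpressionNetwork <- function(x, ...) {
  cat("CoexpressionNetwork: ", length(x$nodes), " genes, ",
      nrow(x$edges), " edges (cutoff ", x$cutoff, ", ",
      x$prune_mode, ")\n", sep = "")
  invisible(x)
}

#' Extract gene modules as connected components
#'
#' Modules are operationalized as the connected components of the pruned
#' network with at least `min_size` genes (default 6, the smallest possible
#' 5-core), ordered by decreasing size with ties broken by the smallest
#' contained gene id.  At stringent cutoffs the network fragments into its
#' tightly co-expressed neighborhoods, so components are the natural
#' mechanization of visually distinct modules.
#'
#' @param net A [build_network()] result.
#' @param min_size Minimum module size.
#' @return List of [gene_module()] objects, ids `"M1"`, `"M2"`, ...
#' @export
extract_modules <- function(net, min_size = 6L) {
  stopifnot(inherits(net, "CoexpressionNetwork"))
  comp <- igraph::components(net$graph)
  if (comp$no == 0L) return(list())
  members <- split(igraph::V(net$graph)$name, comp$membership)
  members <- members[lengths(members) >= min_size]
  if (length(members) == 0L) return(list())
  first_gene <- vapply(members, function(g) min(sort(g)), character(1))
  ord <- order(-lengths(members), first_gene)
  members <- members[ord]
  lapply(seq_along(members), function(i)
    gene_module(paste0("M", i), sort(members[[i]]),
                source_cutoff = net$cutoff))
}

#' Landscape z-values: highest cutoff of network membership
#'
#' For each gene, z is the highest cutoff in `grid` at which the gene is
#' still a member of the pruned network; genes absent from every network get
#' the sentinel 0.  Because raising the cutoff only removes edges and the
#' k-core is monotone under edge removal, membership at a cutoff implies
#' membership at every smaller one, so the maximum is well defined.
#'
#' @param corr A [correlation_matrix()].
#' @param grid Ascending cutoffs (default `c(0.3, 0.4, 0.5, 0.6, 0.7)`).
#' @param cfg A [network_config()]; its `cutoff` is ignored in favor of the
#'   grid.
#' @return Named numeric vector of z-values over all genes of `corr`.
#' @export
landscape_z <- function(corr, grid = c(0.3, 0.4, 0.5, 0.6, 0.7),
                        cfg = network_config()) {
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly ascending")
  genes <- if (inherits(corr, "CorrelationMatrix")) corr$gene_ids else rownames(corr)
  z <- stats::setNames(rep(0, length(genes)), genes)
  for (cutoff in grid) {
    cfg$cutoff <- cutoff
    net <- build_network(corr, cfg)
    z[net$nodes] <- cutoff
  }
  z
}

#' Spring-embedded layout coordinates
#'
#' Places network genes in the plane with a weighted force-directed
#' (Fruchterman-Reingold) layout using the pairwise correlations as spring
#' weights, so strongly correlated genes land close together.  Coordinates
#' are centered and rescaled to a unit bounding box; a single node sits at
#' the origin.  Deterministic given `seed`.
#'
#' @param net A non-empty [build_network()] result.
#' @param seed Integer seed for the layout's random initialisation.
#' @return Data.frame with columns `gene`, `x`, `y`.
#' @export
layout_xy <- function(net, seed = 1L) {
  stopifnot(inherits(net, "CoexpressionNetwork"))
  if (length(net$nodes) == 0L) stop("cannot lay out an empty network")
  xy <- withr::with_seed(seed,
    igraph::layout_with_fr(net$graph,
                           weights = igraph::E(net$graph)$weight))
  xy <- sweep(xy, 2L, colMeans(xy))
  span <- max(apply(xy, 2L, function(v) diff(range(v))))
  if (span > 0) xy <- xy / span
  data.frame(gene = net$nodes, x = xy[, 1], y = xy[, 2],
             stringsAsFactors = FALSE)
}

#' Full landscape coordinate table
#'
#' Combines the x/y layout of the base-cutoff network with per-gene z-values
#' over the cutoff grid.  Genes of the base network always have x/y; genes
#' outside it have z only (x, y = NA).
#'
#' @param corr A [correlation_matrix()].
#' @param grid Ascending cutoff grid; the first element is the base cutoff
#'   used for the layout.
#' @param cfg A [network_config()].
#' @param seed Layout seed.
#' @return Data.frame with columns `gene`, `x`, `y`, `z`.
#' @export
landscape_coordinates <- function(corr, grid = c(0.3, 0.4, 0.5, 0.6, 0.7),
                                  cfg = network_config(), seed = 1L) {
  z <- landscape_z(corr, grid, cfg)
  cfg$cutoff <- grid[1]
  base <- build_network(corr, cfg)
  out <- data.frame(gene = names(z), x = NA_real_, y = NA_real_,
                    z = unname(z), stringsAsFactors = FALSE)
  if (length(base$nodes) > 0L) {
    xy <- layout_xy(base, seed)
    m <- match(xy$gene, out$gene)
    out$x[m] <- xy$x
    out$y[m] <- xy$y
  }
  out
}
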