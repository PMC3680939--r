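#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene (or probe)
#' identifiers and whose header row holds sample identifiers.
#'
#' @param path File path.
#' @param dataset_id Dataset identifier; defaults to the file name without
#'   extension.
#' @param annotations Optional annotation data.frame, or a path to a TSV
#'   keyed by sample id in its first column.
#' @return An [expression_dataset()].
#' @export
read_expression_tsv <- function(path, dataset_id = NULL, annotations = NULL) {
  if (is.null(dataset_id))
    dataset_id <- sub("\\.[^.]*$", "", basename(path))
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- as.character(tab[[1]])
  if (is.character(annotations) && length(annotations) == 1L)
    annotations <- read_annotations_tsv(annotations, colnames(values))
  expression_dataset(dataset_id, values, annotations)
}

#' Read a sample annotation table from TSV
#'
#' First column is the sample id; remaining columns are annotations
#' (subtype, er_status, tp53_status, ...).  Rows are reordered to match
#' `sample_ids` when given; samples without a row get NA annotations.
#'
#' @param path File path.
#' @param sample_ids Optional sample ordering to align to.
#' @return A data.frame keyed by sample id.
#' @export
read_annotations_tsv <- function(path, sample_ids = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  ann <- tab[, -1, drop = FALSE]
  rownames(ann) <- ids
  if (!is.null(sample_ids)) ann <- ann[sample_ids, , drop = FALSE]
  ann
}

#' Read a probe-to-gene map from TSV
#'
#' Columns: `probe_id`, `gene_ids` (semicolon-separated for multi-gene
#' probes), `crosshyb` (0/1).
#'
#' @param path File path.
#' @return Data.frame suitable for [merge_probes_to_genes()].
#' @export
read_probe_map_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "integer"))
  need <- c("probe_id", "gene_ids", "crosshyb")
  if (!all(need %in% colnames(tab)))
    stop("probe map must have columns: ", paste(need, collapse = ", "))
  tab
}

#' Read an siRNA screen table from TSV
#'
#' Columns: `gene_id`, `intensity` (log-transformed Ki-67 staining),
#' `is_control` (0/1).
#'
#' @param path File path.
#' @return A [screen_data()] object.
#' @export
read_screen_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("gene_id", "intensity", "is_control")
  if (!all(need %in% colnames(tab)))
    stop("screen table must have columns: ", paste(need, collapse = ", "))
  screen_data(tab$gene_id, tab$intensity, as.logical(tab$is_control))
}

#' Write a correlation matrix as an edge list TSV
#'
#' Emits one row per retained gene pair with weight above `floor`, columns
#' `gene_a`, `gene_b`, `min_r`.
#'
#' @param corr A [correlation_matrix()].
#' @param path Output file.
#' @param floor Minimum weight to export (default 0: all retained pairs).
#' @return Invisibly, the number of edges written.
#' @export
write_edges_tsv <- function(corr, path, floor = 0) {
  w <- corr_values(corr)
  genes <- rownames(w)
  sel <- !is.na(w) & w > floor
  sel[lower.tri(sel, diag = TRUE)] <- FALSE
  idx <- which(sel, arr.ind = TRUE)
  out <- data.frame(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                    min_r = w[idx])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(nrow(out))
}

#' Write gene modules in GMT format
#'
#' One line per module: id, label, then the member genes, tab-separated --
#' the conventional gene-set exchange format.
#'
#' @param modules List of [gene_module()] objects.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_modules_gmt <- function(modules, path) {
  lines <- vapply(modules, function(m)
    paste(c(m$module_id, m$label, m$gene_ids), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene modules from GMT format
#'
#' @param path GMT file: per line, module id, label, then member genes.
#' @return List of [gene_module()] objects.
#' @export
read_modules_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(l, 1, 60))
    gene_module(parts[1], parts[-(1:2)], label = parts[2])
  })
}

#' Write landscape coordinates as TSV
#'
#' @param coords A [landscape_coordinates()] data.frame (`gene`, `x`, `y`,
#'   `z`).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_coordinates_tsv <- function(coords, path) {
  utils::write.table(coords, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write module activity scores as TSV
#'
#' Modules in rows, samples in columns, with a leading `module_id` column.
#'
#' @param scores A [activity_scores()] result.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_scores_tsv <- function(scores, path) {
  stopifnot(inherits(scores, "ModuleActivityScores"))
  out <- data.frame(module_id = rownames(scores$scores),
                    scores$scores, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network in GraphML format
#'
#' @param net A [build_network()] result.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "CoexpressionNetwork"))
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}
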