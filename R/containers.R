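#' Construct a count matrix with sample roles
#'
#' The central expression container: a nonnegative integer gene-by-sample
#' matrix together with a role (`"tumor"` or `"reference"`) per sample.
#' Library sizes (column sums) are computed on construction and revalidated
#' on read.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param roles character vector of `"tumor"`/`"reference"`, one per sample,
#'   named by sample id or in column order.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `roles` and `library_sizes`.
#' @export
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' cm <- count_matrix(m, c(s1 = "tumor", s2 = "reference"))
#' library_sizes(cm)
count_matrix <- function(counts, roles) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    format_error("count matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    format_error("duplicate gene id: %s",
                 rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    format_error("duplicate sample id: %s",
                 colnames(counts)[duplicated(colnames(counts))][1])
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    format_error("counts must be finite nonnegative integers")
  storage.mode(counts) <- "integer"
  if (!is.null(names(roles))) {
    missing <- setdiff(colnames(counts), names(roles))
    if (length(missing))
      format_error("no role given for sample %s", missing[1])
    roles <- roles[colnames(counts)]
  }
  if (length(roles) != ncol(counts))
    format_error("need one role per sample")
  if (!all(roles %in% c("tumor", "reference")))
    format_error("roles must be 'tumor' or 'reference'")
  structure(
    list(counts = counts,
         roles = setNames(unname(roles), colnames(counts)),
         library_sizes = colSums(counts)),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples (%d tumor, %d reference)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$roles == "tumor"), sum(x$roles == "reference")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Gene, sample and library-size accessors
#' @param x a `count_matrix`.
#' @return Character vector of ids, or numeric library sizes.
#' @export
gene_ids <- function(x) rownames(x$counts)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$counts)

#' @rdname gene_ids
#' @export
library_sizes <- function(x) x$library_sizes

#' @rdname gene_ids
#' @export
tumor_ids <- function(x) names(x$roles)[x$roles == "tumor"]

#' @rdname gene_ids
#' @export
reference_ids <- function(x) names(x$roles)[x$roles == "reference"]

#' @export
tidy.count_matrix <- function(x, ...) {
  tibble::as_tibble(x$counts, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "count") |>
    dplyr::mutate(role = unname(x$roles[.data$sample]))
}

#' Construct a directed signed network
#'
#' Edge-table representation of a signalling network: one row per directed
#' edge with sign +1 (activation) or -1 (inhibition).  Duplicate identical
#' triples are collapsed with a warning; a node list (superset of edge
#' endpoints, e.g. isolated proteins) may be supplied.
#'
#' @param edges data frame with columns `from`, `to`, `sign`.
#' @param nodes optional character vector of node ids.
#' @return A tibble of class `signed_network` with columns `from`, `to`,
#'   `sign` and a `nodes` attribute.
#' @export
#' @examples
#' signed_network(data.frame(from = "A", to = "B", sign = 1))
signed_network <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)[, c("from", "to", "sign")]
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (!all(edges$sign %in% c(-1, 1)))
    format_error("edge signs must be +1 or -1")
  edges$sign <- as.integer(edges$sign)
  dup <- duplicated(edges)
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate edge triple(s)", sum(dup)),
            call. = FALSE)
    edges <- edges[!dup, ]
  }
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  structure(edges, nodes = nodes,
            class = c("signed_network", class(edges)))
}

#' @rdname signed_network
#' @param x a `signed_network`.
#' @export
network_nodes <- function(x) attr(x, "nodes")

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("<signed_network> %d nodes, %d signed edges\n",
              length(network_nodes(x)), nrow(x)))
  NextMethod()
}

# internal: adjacency list of (to, sign) pairs keyed by source node
adjacency_list <- function(network) {
  nodes <- network_nodes(network)
  adj <- split(
    data.frame(to = network$to, sign = network$sign,
               stringsAsFactors = FALSE),
    factor(network$from, levels = nodes))
  adj
}

# internal: igraph view (signs as edge attribute)
as_igraph_signed <- function(network) {
  igraph::graph_from_data_frame(
    as.data.frame(network), directed = TRUE,
    vertices = network_nodes(network))
}

#' Construct a regulon set
#'
#' A regulon is the target set of one transcription factor, each target with
#' a regulation mode: +1 (stimulation) or -1 (repression).
#'
#' @param tbl data frame with columns `tf`, `target`, `mode`.
#' @return A tibble of class `regulon_set`.
#' @export
regulon_set <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)[, c("tf", "target", "mode")]
  tbl$tf <- as.character(tbl$tf)
  tbl$target <- as.character(tbl$target)
  if (!all(tbl$mode %in% c(-1, 1)))
    format_error("regulon modes must be +1 or -1")
  tbl$mode <- as.integer(tbl$mode)
  if (nrow(tbl) == 0) format_error("empty regulon table")
  dup <- duplicated(tbl[, c("tf", "target")])
  if (any(dup))
    format_error("target %s appears twice in regulon of %s",
                 tbl$target[dup][1], tbl$tf[dup][1])
  structure(tbl, class = c("regulon_set", class(tbl)))
}

#' @export
print.regulon_set <- function(x, ...) {
  cat(sprintf("<regulon_set> %d TFs, %d TF-target interactions\n",
              length(unique(x$tf)), nrow(x)))
  NextMethod()
}

#' Construct a gene set collection
#'
#' @param sets named list of character vectors (member genes per set).
#' @param descriptions optional character vector parallel to `sets`.
#' @return A long tibble of class `gene_sets` with columns `set`,
#'   `description`, `gene`.
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    format_error("gene sets need unique names")
  if (any(lengths(sets) == 0)) format_error("empty gene set")
  descriptions <- descriptions %||% rep("", length(sets))
  out <- tibble::tibble(
    set = rep(names(sets), lengths(sets)),
    description = rep(descriptions, lengths(sets)),
    gene = unlist(sets, use.names = FALSE))
  structure(out, class = c("gene_sets", class(out)))
}

# internal: gene_sets tibble -> named list
gene_set_list <- function(gs) split(gs$gene, gs$set)

#' Construct a discrete state matrix
#'
#' Proteins-by-samples matrix over \{-1, 0, +1\}: +1 "active", -1 "inactive",
#' 0 not identified.  The central intermediate of the pipeline.
#'
#' @param m integer matrix with protein rownames and sample colnames, values
#'   in \{-1, 0, 1\}.
#' @param provenance one of `"TF"`, `"MR"`, `"merged"`.
#' @return An integer matrix of class `state_matrix`.
#' @export
state_matrix <- function(m, provenance = c("TF", "MR", "merged")) {
  provenance <- match.arg(provenance)
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    format_error("state matrix needs protein rownames and sample colnames")
  if (!all(m %in% c(-1L, 0L, 1L)))
    format_error("state matrix values must be in {-1, 0, 1}")
  storage.mode(m) <- "integer"
  structure(m, provenance = provenance,
            class = c("state_matrix", "matrix", "array"))
}

#' @export
print.state_matrix <- function(x, ...) {
  cat(sprintf("<state_matrix:%s> %d proteins x %d samples (%d nonzero)\n",
              attr(x, "provenance"), nrow(x), ncol(x), sum(x != 0)))
  invisible(x)
}

#' @export
tidy.state_matrix <- function(x, ...) {
  m <- unclass(x)
  attr(m, "provenance") <- NULL
  tibble::as_tibble(m, rownames = "protein") |>
    tidyr::pivot_longer(-"protein", names_to = "sample", values_to = "state")
}

#' Construct a single-cell expression matrix
#'
#' @param tpm nonnegative matrix of transcripts-per-million, genes in rows,
#'   cells in columns.
#' @param cell_types character vector, one type label per cell.
#' @return A list of class `single_cell_matrix`.
#' @export
single_cell_matrix <- function(tpm, cell_types) {
  tpm <- as.matrix(tpm)
  if (any(!is.finite(tpm)) || any(tpm < 0))
    format_error("tpm values must be finite and >= 0")
  if (length(cell_types) != ncol(tpm) || anyNA(cell_types))
    format_error("every cell needs a type label")
  structure(list(tpm = tpm, cell_types = as.character(cell_types)),
            class = "single_cell_matrix")
}

#' @export
print.single_cell_matrix <- function(x, ...) {
  cat(sprintf("<single_cell_matrix> %d genes x %d cells (%d types)\n",
              nrow(x$tpm), ncol(x$tpm), length(unique(x$cell_types))))
  invisible(x)
}
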