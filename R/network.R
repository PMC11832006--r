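# MR subnetwork structure: induced subgraph and its largest weakly
# connected component, a random-subnetwork null, structural controllability
# via maximum matching (minimum driver node set), directed centralities, and
# the bulk TF-target network built from state/DEG cosine agreement.

#' Induce the master regulator subnetwork
#'
#' Induced subgraph of the signed network on `mr_ids`; connectivity is weak
#' (edge orientation ignored when forming components).
#'
#' @param network a [signed_network()].
#' @param mr_ids protein ids.
#' @return A list: `subnetwork` ([signed_network()] on `mr_ids` in the
#'   network), `stats` (tibble: `n_nodes_in_network`, `n_connected_in_lcc`,
#'   `n_edges_in_lcc`, `n_edges_induced`), `lcc_nodes`.
#' @export
induce_mr_subnetwork <- function(network, mr_ids) {
  present <- intersect(mr_ids, network_nodes(network))
  if (!length(present)) format_error("no mr_ids present in the network")
  sel <- network$from %in% present & network$to %in% present
  sub <- signed_network(as.data.frame(network[sel, ]), nodes = present)
  g <- as_igraph_signed(sub)
  comp <- igraph::components(g, mode = "weak")
  lcc_id <- which.max(comp$csize)
  lcc_nodes <- names(comp$membership)[comp$membership == lcc_id]
  n_edges_lcc <- sum(sub$from %in% lcc_nodes & sub$to %in% lcc_nodes)
  list(subnetwork = sub,
       stats = tibble::tibble(n_nodes_in_network = length(present),
                              n_connected_in_lcc = length(lcc_nodes),
                              n_edges_in_lcc = n_edges_lcc,
                              n_edges_induced = nrow(sub)),
       lcc_nodes = sort(lcc_nodes))
}

#' Random-subnetwork null for induced connectivity
#'
#' Draws `n_draws` uniform node subsets of size `k` without replacement and
#' records, per draw, the size of the largest weakly connected component of
#' the induced subgraph and the induced edge count.
#'
#' @param network a [signed_network()].
#' @param k subset size.
#' @param n_draws number of draws (default 1000).
#' @param seed integer seed.
#' @return A list: `draws` (tibble `lcc_size`, `n_edges`) and `summary`
#'   (tibble of median and max for both).
#' @export
random_subnetwork_null <- function(network, k, n_draws = 1000, seed = 1) {
  nodes <- network_nodes(network)
  if (k > length(nodes)) format_error("k exceeds the node count")
  g <- as_igraph_signed(network)
  res <- with_seed(sub_seed(seed, "subnetwork-null"), {
    vapply(seq_len(n_draws), function(i) {
      sub <- igraph::induced_subgraph(g, sample(nodes, k))
      comp <- igraph::components(sub, mode = "weak")
      c(max(comp$csize), igraph::ecount(sub))
    }, numeric(2))
  })
  draws <- tibble::tibble(lcc_size = res[1, ], n_edges = res[2, ])
  list(draws = draws,
       summary = tibble::tibble(
         statistic = c("lcc_size", "n_edges"),
         median = c(median(draws$lcc_size), median(draws$n_edges)),
         max = c(max(draws$lcc_size), max(draws$n_edges))))
}

#' Minimum driver node set by maximum matching
#'
#' Structural controllability: the minimum number of externally driven
#' nodes equals `max(1, N - M)` where `M` is the size of a maximum matching
#' of the bipartite graph with an out-copy and an in-copy per node and one
#' bipartite edge per network edge.  Drivers are the nodes whose in-copy is
#' unmatched (any node may serve when the matching is perfect).
#'
#' @param network a [signed_network()].
#' @return A list of class `controllability_result`: `n_drivers`,
#'   `matching_size`, `witness_driver_set`.
#' @export
mds_drivers <- function(network) {
  nodes <- network_nodes(network)
  if (!length(nodes)) format_error("empty network")
  n <- length(nodes)
  if (nrow(network) == 0)
    return(structure(list(n_drivers = n, matching_size = 0L,
                          witness_driver_set = nodes),
                     class = "controllability_result"))
  idx <- setNames(seq_len(n), nodes)
  pairs <- rbind(idx[network$from], n + idx[network$to])
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, n), rep(TRUE, n)), edges = as.vector(pairs),
    directed = FALSE)
  igraph::V(g)$name <- c(paste0("out::", nodes), paste0("in::", nodes))
  mm <- igraph::max_bipartite_match(g)
  matching_size <- mm$matching_size
  matched_in <- !is.na(mm$matching[paste0("in::", nodes)])
  unmatched <- nodes[!matched_in]
  n_drivers <- max(1L, n - matching_size)
  witness <- if (length(unmatched)) sort(unmatched) else sort(nodes)[1]
  structure(list(n_drivers = as.integer(n_drivers),
                 matching_size = as.integer(matching_size),
                 witness_driver_set = witness),
            class = "controllability_result")
}

#' @export
print.controllability_result <- function(x, ...) {
  cat(sprintf("<controllability> %d driver node(s), matching size %d\n",
              x$n_drivers, x$matching_size))
  invisible(x)
}

#' @export
glance.controllability_result <- function(x, ...) {
  tibble::tibble(n_drivers = x$n_drivers, matching_size = x$matching_size)
}

#' Outdegree and directed closeness centralities
#'
#' Outdegree counts distinct out-neighbours (parallel opposite-sign edges
#' count once).  Closeness is the inverse of the summed directed
#' shortest-path lengths from a node to the nodes reachable from it, and 0
#' when nothing is reachable.
#'
#' @param network a [signed_network()].
#' @return A tibble: `node`, `outdegree`, `closeness`.
#' @export
centralities <- function(network) {
  nodes <- network_nodes(network)
  outdeg <- vapply(nodes, function(u)
    length(unique(network$to[network$from == u])), 0L)
  g <- as_igraph_signed(network)
  d <- igraph::distances(g, mode = "out")
  closeness <- vapply(seq_along(nodes), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (!length(di)) 0 else 1 / sum(di)
  }, 0)
  tibble::tibble(node = nodes, outdegree = unname(outdeg),
                 closeness = closeness)
}

#' Build the bulk TF-target network
#'
#' For every regulon interaction with both profiles available, the cosine
#' similarity between the TF's state profile and the target gene's DEG-call
#' profile is computed with a bootstrap CI.  A stimulating interaction
#' (mode +1) is kept when the cosine exceeds `cos_threshold` with a
#' positive CI lower limit; a repressing one (mode -1) when the cosine is
#' below `-cos_threshold` and - under the default symmetric rule - the CI
#' upper limit is negative (`repression_rule = "literal"` instead requires
#' a negative lower limit).
#'
#' @param tf_states a [state_matrix()] (TF x samples).
#' @param deg_calls DEG call matrix (genes x samples).
#' @param regulons a [regulon_set()].
#' @param cos_threshold cosine cutoff (default 0.3).
#' @param B,seed bootstrap parameters.
#' @param mr_genes optional gene list for the restricted outdegree.
#' @param repression_rule `"symmetric"` (default) or `"literal"`.
#' @return A list: `edges` (tibble `tf`, `target`, `mode`, `cosine`,
#'   `ci_low`, `ci_high`, `included`), `network` (a [signed_network()] of
#'   included edges), `outdegree` (tibble `tf`, `outdegree_all`,
#'   `outdegree_mr`).
#' @export
build_tf_target_network <- function(tf_states, deg_calls, regulons,
                                    cos_threshold = 0.3, B = 1000,
                                    seed = 1, mr_genes = character(),
                                    repression_rule = c("symmetric",
                                                        "literal")) {
  repression_rule <- match.arg(repression_rule)
  samples <- intersect(colnames(tf_states), colnames(deg_calls))
  if (!length(samples)) format_error("no shared samples")
  avail <- regulons$tf %in% rownames(tf_states) &
    regulons$target %in% rownames(deg_calls)
  reg <- regulons[avail, ]
  rows <- lapply(seq_len(nrow(reg)), function(i) {
    tf <- reg$tf[i]; target <- reg$target[i]; mode <- reg$mode[i]
    u <- as.numeric(tf_states[tf, samples])
    v <- as.numeric(deg_calls[target, samples])
    cs <- cosine(u, v)
    ci <- bootstrap_ci(u, v, B = B,
                       seed = sub_seed(seed, paste(tf, target)))
    included <- if (mode == 1) {
      cs > cos_threshold && ci[["low"]] > 0
    } else if (repression_rule == "symmetric") {
      cs < -cos_threshold && ci[["high"]] < 0
    } else {
      cs < -cos_threshold && ci[["low"]] < 0
    }
    tibble::tibble(tf = tf, target = target, mode = mode, cosine = cs,
                   ci_low = ci[["low"]], ci_high = ci[["high"]],
                   included = included)
  })
  edges <- dplyr::bind_rows(rows)
  inc <- edges[edges$included, ]
  net <- if (nrow(inc))
    signed_network(data.frame(from = inc$tf, to = inc$target,
                              sign = inc$mode))
  else signed_network(data.frame(from = character(), to = character(),
                                 sign = integer()),
                      nodes = unique(reg$tf))
  outdeg <- inc |>
    dplyr::group_by(tf = .data$tf) |>
    dplyr::summarise(
      outdegree_all = dplyr::n_distinct(.data$target),
      outdegree_mr = dplyr::n_distinct(.data$target[
        .data$target %in% mr_genes])) |>
    dplyr::ungroup()
  missing_tfs <- setdiff(unique(reg$tf), outdeg$tf)
  if (length(missing_tfs))
    outdeg <- dplyr::bind_rows(
      outdeg, tibble::tibble(tf = missing_tfs, outdegree_all = 0L,
                             outdegree_mr = 0L)) |>
      dplyr::arrange(.data$tf)
  list(edges = edges, network = net, outdegree = outdeg)
}
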