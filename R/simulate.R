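# Synthetic study generator: a layered signed signalling network (upstream
# regulators -> intermediate signalling proteins -> TFs), signed regulons for
# the TF layer, planted per-sample regulator activities propagated with the
# same signed shortest-path semantics the causal stage uses, and negative
# binomial counts whose expression shifts realise the planted activities.
# Every protein's encoding gene shares its identifier, and each planted
# regulator up-/down-regulates its own gene, closing the positive feedback
# loop the pipeline is designed to detect.

#' Configuration for the synthetic study
#'
#' Defaults describe the benchmark condition used throughout the test suite:
#' 30 tumour plus 5 reference samples, 10 upstream regulators, 10
#' intermediate signalling proteins, 20 TFs, a planted log2 effect of 2 and
#' negative binomial dispersion 0.05.
#'
#' @param n_mr_layer upstream regulator (top layer) count.
#' @param n_intermediate middle signalling layer count.
#' @param n_tf TF (bottom layer) count; only TFs carry regulons.
#' @param n_genes total measured genes, network-node encoding genes included.
#' @param n_tumor,n_reference sample counts.
#' @param regulon_size_range integer interval for regulon sizes.
#' @param edge_density probability of each possible between-layer edge.
#' @param inhibitory_fraction probability that an edge (or regulon mode) is
#'   inhibitory.
#' @param planted_lfc log2 fold change applied to affected genes (>= 0).
#' @param nb_dispersion negative binomial dispersion phi (variance
#'   `mu * (1 + phi * mu)`); 0 means Poisson.
#' @param base_mean_range positive interval for log-uniform baseline means.
#' @param active_fraction,inactive_fraction per-sample probability that each
#'   top-layer regulator is planted active (+1) / inactive (-1).
#' @param seed integer seed; identical configs give bit-identical studies.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_mr_layer = 10, n_intermediate = 10, n_tf = 20,
                       n_genes = 2000, n_tumor = 30, n_reference = 5,
                       regulon_size_range = c(20, 40),
                       edge_density = 0.27, inhibitory_fraction = 0.3,
                       planted_lfc = 2, nb_dispersion = 0.05,
                       base_mean_range = c(20, 2000),
                       active_fraction = 0.18, inactive_fraction = 0.18,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    n_mr_layer >= 1, n_intermediate >= 1, n_tf >= 1, n_genes >= 1,
    n_tumor >= 1, n_reference >= 1,
    length(regulon_size_range) == 2,
    regulon_size_range[1] >= 1,
    regulon_size_range[1] <= regulon_size_range[2],
    edge_density >= 0, edge_density <= 1,
    inhibitory_fraction >= 0, inhibitory_fraction <= 1,
    planted_lfc >= 0, nb_dispersion >= 0,
    base_mean_range[1] > 0, base_mean_range[1] <= base_mean_range[2],
    active_fraction >= 0, inactive_fraction >= 0,
    active_fraction + inactive_fraction <= 1)
  n_nodes <- n_mr_layer + n_intermediate + n_tf
  if (n_genes <= n_nodes)
    format_error("n_genes (%d) must exceed the %d network nodes",
                 n_genes, n_nodes)
  if (regulon_size_range[2] > n_genes - n_nodes)
    format_error("regulon_size_range exceeds the background gene universe")
  structure(cfg, class = "sim_config")
}

sim_node_ids <- function(config) {
  list(mr = sprintf("MR%02d", seq_len(config$n_mr_layer)),
       mid = sprintf("SIG%02d", seq_len(config$n_intermediate)),
       tf = sprintf("TF%02d", seq_len(config$n_tf)))
}

sim_gene_ids <- function(config) {
  ids <- sim_node_ids(config)
  n_bg <- config$n_genes - length(unlist(ids))
  c(unlist(ids, use.names = FALSE), sprintf("G%05d", seq_len(n_bg)))
}

# layer-to-layer random bipartite edges; each source gets >= min_out
# out-edges and each sink >= 1 in-edge so no layer is disconnected from the
# next and every source has a non-trivial downstream footprint
layer_edges <- function(from, to, density, inhibitory_fraction,
                        min_out = 1) {
  grid <- expand.grid(from = from, to = to, stringsAsFactors = FALSE)
  keep <- runif(nrow(grid)) < density
  for (f in from) {
    have <- which(keep & grid$from == f)
    need <- min(min_out, length(to)) - length(have)
    if (need > 0)
      keep[sample(setdiff(which(grid$from == f), have), need)] <- TRUE
  }
  for (t in to)
    if (!any(keep[grid$to == t]))
      keep[sample(which(grid$to == t), 1)] <- TRUE
  edges <- grid[keep, ]
  # signs stratified per source: each node gets the configured fraction of
  # inhibitory out-edges (stochastic rounding), so every regulator's
  # downstream footprint mixes activation and inhibition
  edges$sign <- 1L
  for (f in unique(edges$from)) {
    i <- which(edges$from == f)
    n_inh <- floor(length(i) * inhibitory_fraction)
    if (runif(1) < length(i) * inhibitory_fraction - n_inh)
      n_inh <- n_inh + 1
    if (n_inh > 0) edges$sign[sample(i, n_inh)] <- -1L
  }
  edges
}

#' Generate the layered signed network and TF regulons
#'
#' @param config a [sim_config()].
#' @return A list: `network` ([signed_network()]), `regulons`
#'   ([regulon_set()]), `layers` (named character vector node -> layer).
#' @export
generate_network_and_regulons <- function(config) {
  ids <- sim_node_ids(config)
  with_seed(sub_seed(config$seed, "network"), {
    edges <- rbind(
      layer_edges(ids$mr, ids$mid, config$edge_density,
                  config$inhibitory_fraction, min_out = 3),
      layer_edges(ids$mid, ids$tf, config$edge_density,
                  config$inhibitory_fraction, min_out = 3))
    network <- signed_network(edges, nodes = unlist(ids, use.names = FALSE))
    # regulon targets come from background genes only: the planted feedback
    # edge is then the single route from a protein's state to its own gene,
    # keeping the recovery benchmark identifiable
    background <- setdiff(sim_gene_ids(config), unlist(ids))
    size_pool <- seq(config$regulon_size_range[1],
                     config$regulon_size_range[2])
    sizes <- size_pool[sample.int(length(size_pool), config$n_tf,
                                  replace = TRUE)]
    regulons <- regulon_set(do.call(rbind, lapply(seq_len(config$n_tf),
      function(i) data.frame(
        tf = ids$tf[i],
        target = sample(background, sizes[i]),
        mode = ifelse(runif(sizes[i]) < config$inhibitory_fraction,
                      -1L, 1L)))))
    layers <- setNames(rep(c("mr", "intermediate", "tf"),
                           c(length(ids$mr), length(ids$mid),
                             length(ids$tf))),
                       unlist(ids, use.names = FALSE))
    list(network = network, regulons = regulons, layers = layers)
  })
}

# internal: propagate planted top-layer states to all nodes.  Each planted
# regulator contributes state * shortest-path sign to every node it reaches
# unambiguously; contributions from different regulators are combined by
# sign majority (ties and empty -> 0).
propagate_states <- function(network, planted, reaches = NULL) {
  nodes <- network_nodes(network)
  contrib <- setNames(numeric(length(nodes)), nodes)
  active <- planted[planted != 0]
  for (m in names(active)) {
    reach <- if (is.null(reaches)) {
      signed_shortest_paths(network, m, delta = length(nodes))
    } else reaches[[m]]
    ok <- !is.na(reach$sign) & reach$node != m
    contrib[reach$node[ok]] <- contrib[reach$node[ok]] +
      active[[m]] * reach$sign[ok]
  }
  states <- sign(contrib)
  states[names(active)] <- active          # planted values take precedence
  as.integer(states) |> setNames(nodes)
}

#' Plant per-sample truth states and expression shifts
#'
#' For each tumour sample every top-layer regulator is planted active (+1)
#' with probability `active_fraction`, inactive (-1) with
#' `inactive_fraction`, else 0.  States propagate downwards along signed
#' shortest paths (ambiguous sign: no effect; several regulators: sign
#' majority).  A TF in state sigma shifts each regulon target by
#' `sigma * mode * planted_lfc` log2 units (conflicting TF influences cancel
#' to 0), and every planted regulator's own encoding gene is shifted by
#' `state * planted_lfc` - the positive feedback loop.
#'
#' @param network,regulons from [generate_network_and_regulons()].
#' @param config a [sim_config()].
#' @return A list of class `truth_table`: `node_states` (nodes x tumour
#'   samples), `mr_states`, `tf_states` (layer slices), `lfc` (genes x
#'   tumour samples planted log2 fold changes), `feedback_mrs` (top-layer
#'   regulators planted nonzero in >= 1 sample).
#' @export
plant_truth <- function(network, regulons, config) {
  ids <- sim_node_ids(config)
  genes <- sim_gene_ids(config)
  samples <- sprintf("T%03d", seq_len(config$n_tumor))
  nodes <- network_nodes(network)
  reaches <- lapply(setNames(nodes, nodes), function(nd)
    signed_shortest_paths(network, nd, delta = length(nodes)))
  node_states <- matrix(0L, length(nodes), config$n_tumor,
                        dimnames = list(nodes, samples))
  lfc <- matrix(0, length(genes), config$n_tumor,
                dimnames = list(genes, samples))
  reg_by_tf <- split(regulons[, c("target", "mode")], regulons$tf)
  with_seed(sub_seed(config$seed, "truth"), {
    for (j in seq_len(config$n_tumor)) {
      u <- runif(config$n_mr_layer)
      planted <- setNames(ifelse(u < config$active_fraction, 1L,
                          ifelse(u < config$active_fraction +
                                   config$inactive_fraction, -1L, 0L)),
                          ids$mr)
      st <- propagate_states(network, planted, reaches)
      node_states[, j] <- st[nodes]
      # regulon-driven shifts, sign-combined across TFs
      shift_sign <- setNames(numeric(length(genes)), genes)
      for (tf in ids$tf) {
        sigma <- st[[tf]]
        if (sigma == 0 || is.null(reg_by_tf[[tf]])) next
        r <- reg_by_tf[[tf]]
        shift_sign[r$target] <- shift_sign[r$target] + sigma * r$mode
      }
      delta <- sign(shift_sign) * config$planted_lfc
      # feedback: a planted regulator's own gene follows its state
      fb <- planted[planted != 0]
      delta[names(fb)] <- fb * config$planted_lfc
      lfc[, j] <- delta[genes]
    }
  })
  structure(list(node_states = state_matrix(node_states, "merged"),
                 mr_states = state_matrix(node_states[ids$mr, , drop = FALSE],
                                          "MR"),
                 tf_states = state_matrix(node_states[ids$tf, , drop = FALSE],
                                          "TF"),
                 lfc = lfc,
                 feedback_mrs = ids$mr[rowSums(
                   node_states[ids$mr, , drop = FALSE] != 0) > 0]),
            class = "truth_table")
}

#' Simulate negative binomial counts from a planted truth
#'
#' Baseline means are log-uniform over `base_mean_range`; network-node
#' encoding genes draw from the upper part of the range (above the 30th
#' percentile on the log scale) so that, as in real studies where the
#' network is restricted to genes expressed in the tissue, regulator genes
#' survive the low-expression filter.  Reference samples follow
#' `NB(mu_g, phi)`; tumour sample s follows `NB(mu_g * 2^Delta_gs, phi)`.
#'
#' @param truth a `truth_table` from [plant_truth()].
#' @param regulons the matching [regulon_set()] (recorded for provenance).
#' @param config a [sim_config()].
#' @return A [count_matrix()] with reference samples first.
#' @export
simulate_counts <- function(truth, regulons, config) {
  genes <- rownames(truth$lfc)
  n_nodes <- length(unlist(sim_node_ids(config)))
  samples <- c(sprintf("N%02d", seq_len(config$n_reference)),
               colnames(truth$lfc))
  roles <- setNames(rep(c("reference", "tumor"),
                        c(config$n_reference, config$n_tumor)), samples)
  lo <- log(config$base_mean_range[1]); hi <- log(config$base_mean_range[2])
  phi <- config$nb_dispersion
  with_seed(sub_seed(config$seed, "counts"), {
    mu <- exp(runif(length(genes), lo, hi))
    mu[seq_len(n_nodes)] <- exp(runif(n_nodes, lo + 0.3 * (hi - lo), hi))
    draw <- function(mean_vec) {
      if (phi == 0) rpois(length(mean_vec), mean_vec)
      else rnbinom(length(mean_vec), mu = mean_vec, size = 1 / phi)
    }
    counts <- matrix(0L, length(genes), length(samples),
                     dimnames = list(genes, samples))
    for (j in seq_len(config$n_reference)) counts[, j] <- draw(mu)
    for (j in seq_len(config$n_tumor))
      counts[, config$n_reference + j] <-
        draw(mu * 2^truth$lfc[, j])
    count_matrix(counts, roles)
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining [generate_network_and_regulons()],
#' [plant_truth()] and [simulate_counts()].
#'
#' @param config a [sim_config()].
#' @return A list: `config`, `network`, `regulons`, `layers`, `truth`,
#'   `counts`.
#' @export
#' @examples
#' study <- simulate_mr_study(sim_config(n_genes = 300, n_tumor = 4,
#'                                       regulon_size_range = c(5, 10)))
#' study$counts
simulate_mr_study <- function(config = sim_config()) {
  net <- generate_network_and_regulons(config)
  truth <- plant_truth(net$network, net$regulons, config)
  counts <- simulate_counts(truth, net$regulons, config)
  c(list(config = config), net, list(truth = truth, counts = counts))
}

#' Simulate a labelled single-cell tpm matrix
#'
#' Per cell type each gene is expressed with a Bernoulli probability; the
#' nonzero magnitudes are exponential with the given mean tpm.
#'
#' @param genes character vector of gene ids.
#' @param cells named integer vector: cells per type.
#' @param expr_prob genes x types matrix (or scalar) of expression
#'   probabilities.
#' @param mean_tpm genes x types matrix (or scalar) of mean tpm of
#'   expressing cells.
#' @param seed integer seed.
#' @return A [single_cell_matrix()].
#' @export
simulate_single_cell <- function(genes, cells, expr_prob = 0.5,
                                 mean_tpm = 10, seed = 1L) {
  types <- names(cells)
  if (is.null(types)) format_error("cells must be named by cell type")
  expand <- function(x) {
    if (length(x) == 1) matrix(x, length(genes), length(types),
                               dimnames = list(genes, types))
    else x
  }
  expr_prob <- expand(expr_prob); mean_tpm <- expand(mean_tpm)
  with_seed(sub_seed(seed, "single-cell"), {
    cols <- lapply(seq_along(types), function(t) {
      n <- cells[[t]]
      on <- matrix(runif(length(genes) * n) < expr_prob[, t], ncol = n)
      mag <- matrix(rexp(length(genes) * n, 1 / mean_tpm[, t]), ncol = n)
      on * mag
    })
    tpm <- do.call(cbind, cols)
    rownames(tpm) <- genes
    colnames(tpm) <- sprintf("C%05d", seq_len(ncol(tpm)))
    single_cell_matrix(tpm, rep(types, cells))
  })
}
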