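# Signed shortest-path causal reasoning: which upstream nodes, set "active"
# (+1) or "inactive" (-1), best explain the observed TF states of one sample.
# The sign of a path is the product of its edge signs; when two shortest
# paths to the same node disagree, the net effect is ambiguous and the node
# is non-informative for that hypothesis.

#' Signed shortest-path reach of one node
#'
#' Breadth-first exploration of the signed network from `source` to depth
#' `delta`.  For every reached node the shortest directed distance and the
#' sign product along shortest paths are reported; if two shortest paths
#' carry unequal sign products the sign is ambiguous (`NA`).  The source
#' itself is reached at distance 0 with sign +1.
#'
#' @param network a [signed_network()].
#' @param source node id.
#' @param delta maximum path length (>= 0).
#' @return A tibble with columns `node`, `distance`, `sign` (integer; `NA`
#'   for ambiguous).
#' @export
#' @examples
#' net <- signed_network(data.frame(from = c("A", "B"), to = c("B", "C"),
#'                                  sign = c(1, -1)))
#' signed_shortest_paths(net, "A", delta = 2)
signed_shortest_paths <- function(network, source, delta) {
  nodes <- network_nodes(network)
  if (!source %in% nodes) format_error("source '%s' not in network", source)
  stopifnot(delta >= 0)
  n <- length(nodes)
  idx <- setNames(seq_len(n), nodes)
  dist <- rep(NA_integer_, n)
  can_plus <- logical(n)
  can_minus <- logical(n)
  s0 <- idx[[source]]
  dist[s0] <- 0L
  can_plus[s0] <- TRUE
  # edge arrays grouped by source for fast frontier expansion
  ef <- idx[network$from]
  et <- idx[network$to]
  es <- network$sign
  frontier <- s0
  d <- 0L
  while (length(frontier) && d < delta) {
    d <- d + 1L
    sel <- ef %in% frontier
    if (!any(sel)) break
    u <- ef[sel]; v <- et[sel]; sg <- es[sel]
    new_nodes <- integer(0)
    for (k in seq_along(u)) {
      vu <- v[k]
      if (!is.na(dist[vu]) && dist[vu] < d) next
      if (is.na(dist[vu])) {
        dist[vu] <- d
        new_nodes <- c(new_nodes, vu)
      }
      if (sg[k] == 1L) {
        if (can_plus[u[k]]) can_plus[vu] <- TRUE
        if (can_minus[u[k]]) can_minus[vu] <- TRUE
      } else {
        if (can_plus[u[k]]) can_minus[vu] <- TRUE
        if (can_minus[u[k]]) can_plus[vu] <- TRUE
      }
    }
    frontier <- unique(new_nodes)
  }
  reached <- which(!is.na(dist))
  sign_out <- ifelse(can_plus[reached] & can_minus[reached], NA_integer_,
                     ifelse(can_plus[reached], 1L, -1L))
  tibble::tibble(node = nodes[reached],
                 distance = dist[reached],
                 sign = sign_out)[order(dist[reached], nodes[reached]), ]
}

# internal: sign propagation is computed once per source at delta_max; a
# smaller delta is the subset with distance <= delta ONLY when sign sets are
# recomputed, because ambiguity at delta_max may involve longer paths?  No:
# shortest-path signs depend only on paths of exactly the shortest length,
# which is <= delta for every retained node, so subsetting is exact.
restrict_reach <- function(reach, delta) reach[reach$distance <= delta, ]

#' Score one causal hypothesis against observed TF states
#'
#' The hypothesis "node has sign `s`" predicts state `s * sign(path)` for
#' every observed TF it reaches with an unambiguous sign.  The score counts
#' explained minus contradicted observations; ambiguous or unreachable TFs
#' are non-informative.
#'
#' @param reach output of [signed_shortest_paths()].
#' @param observations named integer vector of TF states in \{-1, +1\}.
#' @param s hypothesis sign, +1 ("active") or -1 ("inactive").
#' @return A one-row tibble: `score`, `n_explained`, `n_contradicted`,
#'   `n_ambiguous`.
#' @export
score_hypothesis <- function(reach, observations, s) {
  stopifnot(s %in% c(-1, 1), length(observations) > 0)
  obs <- observations[observations != 0]
  m <- match(names(obs), reach$node)
  sigma <- reach$sign[m]                     # NA: unreachable or ambiguous
  informative <- !is.na(m) & !is.na(sigma)
  pred <- s * sigma[informative]
  n_exp <- sum(pred == obs[informative])
  n_con <- sum(pred == -obs[informative])
  tibble::tibble(score = n_exp - n_con,
                 n_explained = n_exp,
                 n_contradicted = n_con,
                 n_ambiguous = length(obs) - n_exp - n_con)
}

# internal: null distribution of the unsigned statistic T = sum(w * o) under
# reassignment of the observed state multiset across observed positions.
# Returns list(T = numeric vector of null draws, exhaustive = logical).
null_statistic <- function(w, obs, n_perm, seed, exhaustive_limit = 1e4) {
  n <- length(obs)
  k <- sum(obs == 1)
  n_assign <- choose(n, k)
  if (n_assign <= exhaustive_limit) {
    if (k == 0 || k == n) return(list(T = sum(w * obs), exhaustive = TRUE))
    cmb <- combn(n, k)
    Tn <- 2 * colSums(matrix(w[cmb], nrow = k)) - sum(w)
    list(T = Tn, exhaustive = TRUE)
  } else {
    Tn <- with_seed(seed, vapply(seq_len(n_perm),
                                 function(i) sum(w * sample(obs)), 0))
    list(T = Tn, exhaustive = FALSE)
  }
}

#' Permutation p-value for a causal hypothesis score
#'
#' The null reassigns the observed state multiset uniformly across the
#' observed TF positions.  All distinct assignments are enumerated when
#' there are at most `exhaustive_limit` of them; otherwise `n_perm` Monte
#' Carlo reassignments are drawn and the add-one estimator
#' `(1 + #\{perm >= obs\}) / (1 + n_perm)` is used.
#'
#' @inheritParams score_hypothesis
#' @param n_perm Monte Carlo permutations (default 1000).
#' @param seed integer seed for the Monte Carlo path.
#' @param exhaustive_limit enumeration cutoff (default 1e4 assignments).
#' @return The p-value for `P(score_perm >= score_obs)`.
#' @export
permutation_pvalue <- function(reach, observations, s, n_perm = 1000,
                               seed = 1, exhaustive_limit = 1e4) {
  obs <- observations[observations != 0]
  m <- match(names(obs), reach$node)
  w <- ifelse(is.na(m), 0, reach$sign[m])
  w[is.na(w)] <- 0
  T_obs <- sum(w * obs)
  nd <- null_statistic(w, unname(obs), n_perm, seed, exhaustive_limit)
  hits <- if (s == 1) sum(nd$T >= T_obs) else sum(nd$T <= T_obs)
  if (nd$exhaustive) hits / length(nd$T)
  else (1 + hits) / (1 + length(nd$T))
}

#' Call master regulators for one sample
#'
#' Every network node is a candidate hypothesis with sign +1 or -1.  For
#' each path-length limit in `deltas` a hypothesis is significant when its
#' permutation p-value is below `alpha` and its score is positive; per node
#' the significant calls are merged by union over deltas, and nodes that are
#' significant with both signs (at any deltas) are controversial and
#' dropped.
#'
#' @param network a [signed_network()].
#' @param tf_states named integer vector of observed TF states for one
#'   sample (\{-1, 0, +1\}; zeros are ignored).
#' @param deltas path-length limits to merge over (default `1:3`).
#' @param alpha significance cutoff (default 0.05).
#' @param n_perm Monte Carlo permutations when enumeration is infeasible.
#' @param seed integer seed.
#' @param candidates optional candidate node subset (default: all nodes).
#' @param reaches optional precomputed list of reaches at `max(deltas)`
#'   keyed by candidate node (as built internally; used by [call_mrs()]).
#' @return A list with `states` (named integer vector of surviving calls)
#'   and `hypotheses` (tibble of all significant (node, sign, delta) rows
#'   before controversy removal).
#' @export
call_mrs_per_sample <- function(network, tf_states, deltas = 1:3,
                                alpha = 0.05, n_perm = 1000, seed = 1,
                                candidates = NULL, reaches = NULL) {
  obs <- tf_states[tf_states != 0]
  if (!length(obs))
    return(list(states = integer(0), hypotheses = empty_hypotheses()))
  candidates <- candidates %||% network_nodes(network)
  delta_max <- max(deltas)
  if (is.null(reaches))
    reaches <- lapply(setNames(candidates, candidates), function(nd)
      signed_shortest_paths(network, nd, delta_max))
  rows <- list()
  for (nd in candidates) {
    full <- reaches[[nd]]
    for (dl in sort(deltas)) {
      reach <- restrict_reach(full, dl)
      m <- match(names(obs), reach$node)
      w <- ifelse(is.na(m), 0, reach$sign[m])
      w[is.na(w)] <- 0
      if (all(w == 0)) next
      T_obs <- sum(w * obs)
      ndist <- null_statistic(w, unname(obs), n_perm,
                              sub_seed(seed, paste(nd, dl)))
      for (s in c(1L, -1L)) {
        score <- s * T_obs
        if (score <= 0) next
        hits <- if (s == 1) sum(ndist$T >= T_obs) else sum(ndist$T <= T_obs)
        p <- if (ndist$exhaustive) hits / length(ndist$T)
             else (1 + hits) / (1 + length(ndist$T))
        if (p < alpha)
          rows[[length(rows) + 1]] <- tibble::tibble(
            node = nd, sign = s, delta = dl, score = score, p_value = p)
      }
    }
  }
  hyp <- if (length(rows)) dplyr::bind_rows(rows) else empty_hypotheses()
  if (!nrow(hyp)) return(list(states = integer(0), hypotheses = hyp))
  by_node <- split(hyp$sign, hyp$node)
  keep <- vapply(by_node, function(s) length(unique(s)) == 1, TRUE)
  states <- vapply(by_node[keep], `[[`, 0L, 1)
  list(states = states, hypotheses = hyp)
}

empty_hypotheses <- function() {
  tibble::tibble(node = character(), sign = integer(), delta = integer(),
                 score = numeric(), p_value = numeric())
}

#' Call master regulators for every tumour sample
#'
#' Runs [call_mrs_per_sample()] over the columns of a TF state matrix,
#' reusing one set of precomputed signed reaches.
#'
#' @param network a [signed_network()].
#' @param tf_states a [state_matrix()] (TF-by-sample).
#' @inheritParams call_mrs_per_sample
#' @return A list with `states` (a `state_matrix` with provenance `"MR"`,
#'   nodes-by-samples) and `hypotheses` (tibble with a `sample` column).
#' @export
call_mrs <- function(network, tf_states, deltas = 1:3, alpha = 0.05,
                     n_perm = 1000, seed = 1, candidates = NULL) {
  candidates <- candidates %||% network_nodes(network)
  delta_max <- max(deltas)
  reaches <- lapply(setNames(candidates, candidates), function(nd)
    signed_shortest_paths(network, nd, delta_max))
  samples <- colnames(tf_states)
  out <- matrix(0L, nrow = length(candidates), ncol = length(samples),
                dimnames = list(candidates, samples))
  hyp <- vector("list", length(samples))
  for (j in seq_along(samples)) {
    res <- call_mrs_per_sample(
      network, tf_states[, j], deltas = deltas, alpha = alpha,
      n_perm = n_perm, seed = sub_seed(seed, samples[j]),
      candidates = candidates, reaches = reaches)
    if (length(res$states)) out[names(res$states), j] <- res$states
    hyp[[j]] <- dplyr::mutate(res$hypotheses, sample = samples[j],
                              .before = 1)
  }
  list(states = state_matrix(out, "MR"), hypotheses = dplyr::bind_rows(hyp))
}
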