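# Annotation of the identified regulators: hypergeometric
# over-representation of MR genes in gene sets, a single-sample
# rank-weighted immune infiltration score, the dual-level Kendall
# correlation screen, and single-cell expression summaries.

#' Over-representation analysis of a gene list
#'
#' One-sided hypergeometric upper-tail test of each set's overlap with the
#' query, both restricted to the universe; BH adjustment across sets.  A
#' set passes the reporting filter when it overlaps the query in at least
#' two genes with raw `p < 0.05`.
#'
#' @param query_genes character vector (violating genes outside the
#'   universe are dropped with a message).
#' @param universe character vector of measurable genes.
#' @param sets a [gene_sets()] collection.
#' @return A tibble: `set`, `n_overlap`, `n_set`, `n_query`, `n_universe`,
#'   `p_value`, `p_adjusted`, `passes_filter`.
#' @export
ora_enrich <- function(query_genes, universe, sets) {
  universe <- unique(universe)
  if (!length(universe)) format_error("empty universe")
  outside <- setdiff(query_genes, universe)
  if (length(outside))
    message(sprintf("dropped %d query gene(s) outside the universe",
                    length(outside)))
  query <- unique(intersect(query_genes, universe))
  sl <- gene_set_list(sets)
  rows <- purrr::imap(sl, function(members, nm) {
    in_uni <- intersect(unique(members), universe)
    k <- length(intersect(in_uni, query))
    K <- length(in_uni)
    p <- if (K == 0) 1 else
      phyper(k - 1, K, length(universe) - K, length(query),
             lower.tail = FALSE)
    tibble::tibble(set = nm, n_overlap = k, n_set = K,
                   n_query = length(query),
                   n_universe = length(universe), p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out$passes_filter <- out$n_overlap >= 2 & out$p_value < 0.05
  dplyr::arrange(out, .data$p_value)
}

#' Single-sample immune infiltration score
#'
#' Rank-weighted single-sample enrichment of a signature in each sample's
#' expression profile: genes are ranked by expression, and the score is the
#' summed difference between the `rank^exponent`-weighted cumulative
#' distribution of signature genes and the unweighted one of the remainder,
#' walking the ranking from the most to the least expressed gene.  A rank
#' statistic: invariant under any strictly monotone transform of the
#' profile.
#'
#' @param expression normalised genes x samples matrix.
#' @param signature character vector of signature genes (>= 10 measured).
#' @param exponent rank weight exponent (default 0.25).
#' @return Named numeric vector of per-sample scores.
#' @export
immune_score <- function(expression, signature, exponent = 0.25) {
  sig <- intersect(signature, rownames(expression))
  if (length(sig) < 10)
    format_error("signature too small: %d measured gene(s), need >= 10",
                 length(sig))
  in_sig <- rownames(expression) %in% sig
  n <- nrow(expression)
  apply(expression, 2, function(x) {
    r <- rank(x, ties.method = "average")
    ord <- order(x, decreasing = TRUE)
    w <- r[ord]^exponent * in_sig[ord]
    ecdf_sig <- cumsum(w) / sum(w)
    ecdf_rest <- cumsum(!in_sig[ord]) / sum(!in_sig)
    sum(ecdf_sig - ecdf_rest)
  })
}

# internal: Kendall tau-b and a two-sided p-value.  Exact permutation
# enumeration for n <= 8 (handles ties, unlike cor.test's exact path);
# otherwise the tie-corrected normal approximation on the S statistic.
kendall_tau_test <- function(x, y) {
  n <- length(x)
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    return(list(tau = NA_real_, p = NA_real_))
  tau <- suppressWarnings(cor(x, y, method = "kendall"))
  if (n <= 8) {
    # tau's denominator is permutation-invariant, so |tau| ordering equals
    # |S| ordering with S = sum_{i<j} sign(x_i - x_j) sign(y_i - y_j)
    perms <- all_permutations(n)
    sx <- sign(outer(x, x, "-"))
    sy <- sign(outer(y, y, "-"))
    S_perm <- numeric(nrow(perms))
    S_obs <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (sx[i, j] == 0) next
      S_obs <- S_obs + sx[i, j] * sy[i, j]
      S_perm <- S_perm + sx[i, j] * sy[cbind(perms[, i], perms[, j])]
    }
    return(list(tau = tau,
                p = mean(abs(S_perm) >= abs(S_obs) - 1e-9)))
  }
  xt <- outer(x, x, "-"); yt <- outer(y, y, "-")
  S <- sum(sign(xt[lower.tri(xt)]) * sign(yt[lower.tri(yt)]))
  tie_terms <- function(v) {
    t <- table(v); t <- t[t > 1]
    c(v0 = sum(t * (t - 1) * (2 * t + 5)),
      v1 = sum(t * (t - 1)) ,
      v2 = sum(t * (t - 1) * (t - 2)))
  }
  tx <- tie_terms(x); ty <- tie_terms(y)
  n0 <- n * (n - 1) * (2 * n + 5)
  var_S <- (n0 - tx[["v0"]] - ty[["v0"]]) / 18 +
    tx[["v1"]] * ty[["v1"]] / (2 * n * (n - 1)) +
    tx[["v2"]] * ty[["v2"]] / (9 * n * (n - 1) * (n - 2))
  z <- S / sqrt(var_S)
  list(tau = tau, p = 2 * pnorm(-abs(z)))
}

# internal: all permutations of 1..n as a matrix (rows), n <= 8
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

#' Dual-level Kendall correlation screen
#'
#' Correlates a per-sample score vector (e.g. immune infiltration) with a
#' protein's discrete state profile and with its encoding gene's
#' normalised expression, both by Kendall tau-b.  Correlation is declared
#' only when both coefficients are positive with `p < 0.05`.
#'
#' @param states integer vector of per-sample states (\{-1, 0, 1\}).
#' @param expression numeric vector of per-sample expression.
#' @param scores numeric per-sample scores (same samples, same order).
#' @param protein protein id recorded in the output.
#' @return A one-row tibble: `protein`, `tau_discrete`, `p_discrete`,
#'   `tau_expression`, `p_expression`, `correlated`.
#' @export
kendall_screen <- function(states, expression, scores, protein = NA) {
  stopifnot(length(states) == length(scores),
            length(expression) == length(scores))
  kd <- kendall_tau_test(as.numeric(states), scores)
  ke <- kendall_tau_test(as.numeric(expression), scores)
  if (is.na(kd$tau) || is.na(ke$tau))
    message(sprintf("constant profile for %s: tau undefined", protein))
  tibble::tibble(
    protein = protein,
    tau_discrete = kd$tau, p_discrete = kd$p,
    tau_expression = ke$tau, p_expression = ke$p,
    correlated = isTRUE(kd$tau > 0 && kd$p < 0.05 &&
                          ke$tau > 0 && ke$p < 0.05))
}

#' Per-gene, per-cell-type single-cell expression summaries
#'
#' @param sc a [single_cell_matrix()].
#' @param genes optional gene subset (default all).
#' @param cell_types optional cell-type subset; a requested type with no
#'   cells is an error.
#' @return A list: `summary` (tibble `gene`, `cell_type`, `mean_tpm`,
#'   `pct_nonzero`) and `bins` (tibble of decile bins of `pct_nonzero` per
#'   cell type).
#' @export
single_cell_summary <- function(sc, genes = NULL, cell_types = NULL) {
  genes <- genes %||% rownames(sc$tpm)
  missing <- setdiff(genes, rownames(sc$tpm))
  if (length(missing))
    format_error("gene(s) absent from the tpm matrix: %s",
                 paste(head(missing, 5), collapse = ", "))
  types <- cell_types %||% unique(sc$cell_types)
  tab <- table(factor(sc$cell_types, levels = types))
  if (any(tab == 0))
    format_error("cell type with 0 cells: %s", names(tab)[tab == 0][1])
  rows <- lapply(types, function(ct) {
    cols <- sc$cell_types == ct
    m <- sc$tpm[genes, cols, drop = FALSE]
    tibble::tibble(gene = genes, cell_type = ct,
                   mean_tpm = unname(rowMeans(m)),
                   pct_nonzero = unname(100 * rowMeans(m > 0)))
  })
  summary <- dplyr::bind_rows(rows)
  bins <- summary |>
    dplyr::mutate(bin = cut(.data$pct_nonzero,
                            breaks = seq(0, 100, 10),
                            include.lowest = TRUE, right = TRUE)) |>
    dplyr::count(.data$cell_type, .data$bin, name = "n_genes")
  list(summary = summary, bins = bins)
}
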