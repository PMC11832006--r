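# Independent brute-force oracles.  These deliberately share no code with
# the package implementations they check.

# --- signed reach: enumerate every simple directed path up to max_len ----
oracle_signed_reach <- function(edges, nodes, source, max_len) {
  # edges: data.frame(from, to, sign)
  paths <- list()
  walk <- function(node, visited, sgn, len) {
    paths[[length(paths) + 1]] <<- list(node = node, sign = sgn, len = len)
    if (len == max_len) return()
    out <- edges[edges$from == node, , drop = FALSE]
    for (i in seq_len(nrow(out))) {
      if (out$to[i] %in% visited) next
      walk(out$to[i], c(visited, out$to[i]), sgn * out$sign[i], len + 1L)
    }
  }
  walk(source, source, 1L, 0L)
  df <- do.call(rbind, lapply(paths, as.data.frame))
  res <- lapply(split(df, df$node), function(d) {
    dmin <- min(d$len)
    signs <- unique(d$sign[d$len == dmin])
    data.frame(node = d$node[1], distance = as.integer(dmin),
               sign = if (length(signs) > 1) NA_integer_
                      else as.integer(signs))
  })
  out <- do.call(rbind, res)
  out[order(out$distance, out$node), , drop = FALSE]
}

# --- hypothesis score straight from the definition ----------------------
oracle_score <- function(reach, obs, s) {
  n_exp <- n_con <- 0
  for (t in names(obs)) {
    i <- match(t, reach$node)
    if (is.na(i) || is.na(reach$sign[i])) next
    pred <- s * reach$sign[i]
    if (pred == obs[[t]]) n_exp <- n_exp + 1
    else n_con <- n_con + 1
  }
  list(score = n_exp - n_con, n_explained = n_exp, n_contradicted = n_con)
}

# --- exhaustive permutation p over all distinct assignments -------------
oracle_exhaustive_p <- function(reach, obs, s) {
  k <- sum(obs == 1)
  n <- length(obs)
  obs_score <- oracle_score(reach, obs, s)$score
  plus_sets <- combn(n, max(k, 1), simplify = FALSE)
  if (k == 0) plus_sets <- list(integer(0))
  scores <- vapply(plus_sets, function(ps) {
    o <- setNames(rep(-1L, n), names(obs))
    o[ps] <- 1L
    oracle_score(reach, o, s)$score
  }, 0)
  mean(scores >= obs_score)
}

# --- maximum bipartite matching by exhaustive search --------------------
oracle_max_matching <- function(edges) {
  # edges: data.frame(from, to); matching in the out/in bipartite graph
  if (nrow(edges) == 0) return(0L)
  best <- 0L
  recurse <- function(i, used_out, used_in, size) {
    if (size + (nrow(edges) - i + 1) <= best) return()
    if (i > nrow(edges)) { best <<- max(best, size); return() }
    f <- edges$from[i]; t <- edges$to[i]
    if (!(f %in% used_out) && !(t %in% used_in))
      recurse(i + 1, c(used_out, f), c(used_in, t), size + 1L)
    recurse(i + 1, used_out, used_in, size)
  }
  recurse(1L, character(0), character(0), 0L)
  best
}

# --- BH step-up from the definition -------------------------------------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# --- hypergeometric upper tail by direct summation ----------------------
oracle_hyper_p <- function(k, K, N, q) {
  i <- k:min(K, q)
  sum(choose(K, i) * choose(N - K, q - i)) / choose(N, q)
}

# --- Kendall tau-b by explicit pair counting ----------------------------
oracle_kendall_tau <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1
    if (s < 0) disc <- disc + 1
  }
  tx <- sum(sapply(split(seq_along(x), x), function(g)
    choose(length(g), 2)))
  ty <- sum(sapply(split(seq_along(y), y), function(g)
    choose(length(g), 2)))
  n0 <- choose(n, 2)
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# --- directed closeness via Floyd-Warshall ------------------------------
oracle_closeness <- function(edges, nodes) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(edges)))
    d[edges$from[i], edges$to[i]] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (!length(di)) 0 else 1 / sum(di)
  }, 0)
}

# --- random signed digraph ----------------------------------------------
random_signed_digraph <- function(n_nodes, p_edge = 0.3) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  grid <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, ]
  keep <- runif(nrow(grid)) < p_edge
  edges <- grid[keep, , drop = FALSE]
  edges$sign <- sample(c(-1L, 1L), nrow(edges), replace = TRUE)
  list(edges = edges, nodes = nodes)
}
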