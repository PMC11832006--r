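test_that("hypergeometric enrichment matches the exact tail sum", {
  universe <- sprintf("g%03d", 1:100)
  sets <- gene_sets(list(S = universe[1:10]))
  query <- c(universe[1:3], universe[50:51])   # overlap 3, query 5
  res <- ora_enrich(query, universe, sets)
  expect_equal(res$p_value, oracle_hyper_p(3, 10, 100, 5))
  # sum_{i=3..5} C(10,i) C(90,5-i) / C(100,5) = 499752 / 75287520
  expect_equal(res$p_value, 499752 / 75287520, tolerance = 1e-12)
  expect_true(res$passes_filter)
})

test_that("the reporting filter needs two regulator genes regardless of p", {
  universe <- sprintf("g%03d", 1:200)
  sets <- gene_sets(list(tiny = universe[1]))
  res <- ora_enrich(universe[1], universe, sets)
  expect_lt(res$p_value, 0.01)
  expect_false(res$passes_filter)  # single-gene overlap
})

test_that("degenerate queries behave: full query, out-of-universe genes", {
  universe <- sprintf("g%03d", 1:50)
  sets <- gene_sets(list(S = universe[1:10]))
  res <- ora_enrich(universe, universe, sets)
  expect_equal(res$n_overlap, 10)
  expect_equal(res$p_value, 1)
  expect_message(res2 <- ora_enrich(c(universe[1:2], "absent"), universe,
                                    sets),
                 "outside the universe")
  expect_equal(res2$n_query, 2)
  expect_error(ora_enrich("g", character(0), sets), "empty universe")
})

test_that("hypergeometric p agrees with brute-force enumeration on small universes", {
  set.seed(6)
  for (i in 1:200) {
    N <- sample(5:20, 1)
    K <- sample(1:N, 1)
    q <- sample(1:N, 1)
    universe <- sprintf("u%02d", 1:N)
    members <- sample(universe, K)
    query <- sample(universe, q)
    k <- length(intersect(members, query))
    res <- ora_enrich(query, universe, gene_sets(list(S = members)))
    expect_equal(res$p_value, oracle_hyper_p(k, K, N, q),
                 tolerance = 1e-12)
  }
})

test_that("immune score ranks signature placement and ignores scale", {
  genes <- sprintf("g%03d", 1:200)
  sig_genes <- genes[1:20]
  top <- matrix(c(rep(100, 20), rep(1, 180)), ncol = 1,
                dimnames = list(genes, "s1"))
  bottom <- matrix(c(rep(0.01, 20), rep(10, 180)), ncol = 1,
                   dimnames = list(genes, "s1"))
  expect_gt(immune_score(top, sig_genes)[["s1"]], 0)
  expect_lt(immune_score(bottom, sig_genes)[["s1"]], 0)
  # invariance under strictly monotone transforms
  set.seed(2)
  x <- matrix(rexp(200), ncol = 1, dimnames = list(genes, "s1"))
  expect_equal(immune_score(x, sig_genes),
               immune_score(log1p(x), sig_genes))
  expect_error(immune_score(x, genes[1:5]), "signature too small")
})

test_that("immune score increases with the planted immune fraction", {
  set.seed(3)
  genes <- sprintf("g%03d", 1:300)
  sig_genes <- genes[1:30]
  # heavy-tailed baseline keeps signature and background ranks overlapping
  # at partial immune fractions, so the score moves gradually with f
  baseline <- setNames(rlnorm(300, log(20), 1.2), genes)
  immune_component <- setNames(c(rep(100, 30), rep(0, 270)), genes)
  scores <- sapply(c(0, 0.25, 0.5), function(f) {
    mix <- matrix(baseline + f * immune_component, ncol = 1,
                  dimnames = list(genes, "s"))
    immune_score(mix, sig_genes)[["s"]]
  })
  expect_true(all(diff(scores) > 0))
})

test_that("kendall tau matches hand values and the pair-count oracle", {
  r <- kendall_screen(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$tau_discrete, 1)
  r2 <- kendall_screen(c(1, 2, 3), c(1, 2, 3), c(3, 1, 2))
  expect_equal(r2$tau_discrete, -1 / 3)
  set.seed(9)
  for (i in 1:100) {
    n <- sample(5:20, 1)
    x <- sample(c(-1, 0, 1), n, TRUE)
    y <- rnorm(n)
    if (length(unique(x)) < 2) next
    expect_equal(kendall_screen(x, y, y)$tau_discrete,
                 oracle_kendall_tau(x, y), tolerance = 1e-12)
  }
})

test_that("kendall p agrees with cor.test on tie-free inputs", {
  set.seed(10)
  for (n in c(6, 8, 15, 40)) {
    x <- sample(seq_len(n))
    y <- sample(seq_len(n))
    mine <- kendall_screen(x, y, y)
    ct <- cor.test(x, y, method = "kendall", exact = n <= 8,
                   correct = FALSE)
    expect_equal(mine$tau_discrete, unname(ct$estimate))
    expect_equal(mine$p_discrete, ct$p.value, tolerance = 1e-9)
  }
})

test_that("correlation requires both levels positive and significant", {
  set.seed(4)
  s <- rnorm(30)
  up <- s + rnorm(30, sd = 0.1)
  down <- -s + rnorm(30, sd = 0.1)
  expect_true(kendall_screen(up, up, s)$correlated)
  expect_false(kendall_screen(up, down, s)$correlated)   # expression anti
  expect_false(kendall_screen(down, up, s)$correlated)   # discrete anti
  expect_message(r <- kendall_screen(rep(1, 30), up, s), "constant")
  expect_false(r$correlated)
})

test_that("single-cell summaries follow the definitions", {
  tpm <- matrix(c(0, 5, 10, 0, 0, 0), nrow = 2, byrow = TRUE,
                dimnames = list(c("gA", "gB"), sprintf("c%d", 1:3)))
  sc <- single_cell_matrix(tpm, rep("malignant", 3))
  s <- single_cell_summary(sc)$summary
  expect_equal(s$mean_tpm[s$gene == "gA"], 5)
  expect_equal(s$pct_nonzero[s$gene == "gA"], 100 * 2 / 3)
  expect_equal(s$mean_tpm[s$gene == "gB"], 0)
  expect_equal(s$pct_nonzero[s$gene == "gB"], 0)
  expect_error(single_cell_summary(sc, cell_types = c("malignant",
                                                      "tcell")),
               "tcell")
  # invariance under cell order permutation
  sc2 <- single_cell_matrix(tpm[, c(3, 1, 2)], rep("malignant", 3))
  expect_equal(single_cell_summary(sc2)$summary, s)
})
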