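test_that("induced subnetwork and component stats follow hand examples", {
  chain <- signed_network(data.frame(from = c("A", "B"), to = c("B", "C"),
                                     sign = 1L))
  res <- induce_mr_subnetwork(chain, c("A", "C"))
  expect_equal(nrow(res$subnetwork), 0)
  expect_equal(res$stats$n_connected_in_lcc, 1)

  res2 <- induce_mr_subnetwork(chain, c("A", "B", "C"))
  expect_equal(nrow(res2$subnetwork), 2)
  expect_equal(res2$stats$n_connected_in_lcc, 3)

  tri <- signed_network(data.frame(from = c("A", "B", "C"),
                                   to = c("B", "C", "A"), sign = 1L))
  res3 <- induce_mr_subnetwork(tri, c("A", "B"))
  expect_equal(nrow(res3$subnetwork), 1)
  expect_setequal(res3$lcc_nodes, c("A", "B"))
})

test_that("random subnetwork null reproduces degenerate cases", {
  tri <- signed_network(data.frame(from = c("A", "B", "C"),
                                   to = c("B", "C", "A"), sign = 1L))
  null <- random_subnetwork_null(tri, k = 3, n_draws = 20, seed = 1)
  expect_true(all(null$draws$lcc_size == 3))
  expect_true(all(null$draws$n_edges == 3))

  edgeless <- signed_network(
    data.frame(from = character(), to = character(), sign = integer()),
    nodes = sprintf("n%d", 1:6))
  null2 <- random_subnetwork_null(edgeless, k = 3, n_draws = 20, seed = 1)
  expect_true(all(null2$draws$lcc_size == 1))
  expect_true(all(null2$draws$n_edges == 0))

  expect_error(random_subnetwork_null(tri, k = 4), "exceeds")
  # determinism
  n1 <- random_subnetwork_null(tri, 2, n_draws = 50, seed = 5)
  n2 <- random_subnetwork_null(tri, 2, n_draws = 50, seed = 5)
  expect_identical(n1$draws, n2$draws)
})

test_that("a planted dense module exceeds the null maximum", {
  set.seed(13)
  # sparse background plus a dense 8-node module
  bg <- random_signed_digraph(40, 0.01)
  module <- sprintf("n%02d", 1:8)
  extra <- expand.grid(from = module, to = module,
                       stringsAsFactors = FALSE)
  extra <- extra[extra$from != extra$to, ]
  extra <- extra[runif(nrow(extra)) < 0.6, ]
  extra$sign <- 1L
  net <- signed_network(unique(rbind(bg$edges, extra)), nodes = bg$nodes)
  obs <- induce_mr_subnetwork(net, module)
  null <- random_subnetwork_null(net, 8, n_draws = 300, seed = 2)
  expect_gt(obs$stats$n_connected_in_lcc, null$summary$max[1])
})

test_that("driver counts match closed-form cases", {
  path <- signed_network(data.frame(from = c("A", "B"), to = c("B", "C"),
                                    sign = 1L))
  res <- mds_drivers(path)
  expect_equal(res$n_drivers, 1)
  expect_equal(res$matching_size, 2)
  expect_equal(res$witness_driver_set, "A")

  isolated <- signed_network(
    data.frame(from = character(), to = character(), sign = integer()),
    nodes = sprintf("n%d", 1:4))
  expect_equal(mds_drivers(isolated)$n_drivers, 4)

  star <- signed_network(data.frame(from = "H", to = c("L1", "L2", "L3"),
                                    sign = 1L))
  res3 <- mds_drivers(star)
  expect_equal(res3$matching_size, 1)
  expect_equal(res3$n_drivers, 3)

  # perfect matching (cycle): one driver by convention
  cyc <- signed_network(data.frame(from = c("A", "B", "C"),
                                   to = c("B", "C", "A"), sign = 1L))
  expect_equal(mds_drivers(cyc)$n_drivers, 1)
})

test_that("driver count equals N minus brute-force maximum matching", {
  set.seed(31)
  for (rep in 1:20) {
    g <- random_signed_digraph(sample(3:7, 1), 0.3)
    net <- signed_network(g$edges, nodes = g$nodes)
    res <- mds_drivers(net)
    mm <- oracle_max_matching(g$edges)
    expect_equal(res$matching_size, mm)
    expect_equal(res$n_drivers, max(1, length(g$nodes) - mm))
    expect_length(res$witness_driver_set, res$n_drivers)
  }
})

test_that("centralities match hand distances and the brute-force oracle", {
  path <- signed_network(data.frame(from = c("A", "B"), to = c("B", "C"),
                                    sign = 1L))
  cent <- centralities(path)
  expect_equal(cent$outdegree, c(1, 1, 0))
  expect_equal(cent$closeness[cent$node == "A"], 1 / 3)
  expect_equal(cent$closeness[cent$node == "C"], 0)

  # complete digraph: closeness 1/(n-1) everywhere
  n <- 5
  nodes <- sprintf("k%d", 1:n)
  grid <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, ]
  grid$sign <- 1L
  comp <- centralities(signed_network(grid))
  expect_true(all(comp$closeness == 1 / (n - 1)))

  # parallel opposite-sign edges count once towards outdegree
  par <- signed_network(data.frame(from = c("A", "A"), to = c("B", "B"),
                                   sign = c(1L, -1L)))
  expect_equal(centralities(par)$outdegree[1], 1)

  set.seed(17)
  for (rep in 1:10) {
    g <- random_signed_digraph(sample(4:12, 1), 0.25)
    net <- signed_network(g$edges, nodes = g$nodes)
    expect_equal(centralities(net)$closeness,
                 unname(oracle_closeness(g$edges, g$nodes)))
  }
})

test_that("TF-target edges follow the signed cosine inclusion rules", {
  samples <- sprintf("s%d", 1:30)
  up <- c(rep(1L, 12), rep(0L, 18))
  tf_states <- state_matrix(rbind(TF1 = up) |> `colnames<-`(samples), "TF")
  calls <- rbind(gPos = up,                  # concordant target
                 gNeg = -up,                 # anti-concordant target
                 gNull = rep(0L, 30))
  colnames(calls) <- samples
  reg <- regulon_set(data.frame(
    tf = "TF1", target = c("gPos", "gNeg", "gNull"),
    mode = c(1L, -1L, 1L)))
  res <- build_tf_target_network(tf_states, calls, reg, B = 500, seed = 2)
  e <- res$edges
  expect_true(e$included[e$target == "gPos"])    # stimulation kept
  expect_true(e$included[e$target == "gNeg"])    # repression kept
  expect_false(e$included[e$target == "gNull"])
  expect_equal(res$outdegree$outdegree_all, 2)
  expect_equal(
    res$outdegree$outdegree_mr, 0)
  # a stimulating mode with negative cosine is excluded
  reg2 <- regulon_set(data.frame(tf = "TF1", target = "gNeg", mode = 1L))
  res2 <- build_tf_target_network(tf_states, calls, reg2, B = 500,
                                  seed = 2)
  expect_false(res2$edges$included)
  # the literal repression reading admits a CI that touches zero
  weak <- c(-1L, -1L, -1L, rep(0L, 27))
  calls3 <- rbind(gWeak = weak); colnames(calls3) <- samples
  reg3 <- regulon_set(data.frame(tf = "TF1", target = "gWeak", mode = -1L))
  sym <- build_tf_target_network(tf_states, calls3, reg3, B = 2000,
                                 seed = 3)
  lit <- build_tf_target_network(tf_states, calls3, reg3, B = 2000,
                                 seed = 3, repression_rule = "literal")
  expect_lt(lit$edges$cosine, -0.3)
  expect_true(lit$edges$included)     # lower limit < 0 suffices
  expect_false(sym$edges$included)    # upper limit is not < 0
})
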