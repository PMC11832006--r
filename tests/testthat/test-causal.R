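test_that("signed reach on the two-edge chain matches hand enumeration", {
  net <- chain_network()   # A -(+)-> B -(-)-> C
  reach <- signed_shortest_paths(net, "A", delta = 2)
  expect_equal(reach$node, c("A", "B", "C"))
  expect_equal(reach$distance, c(0L, 1L, 2L))
  expect_equal(reach$sign, c(1L, 1L, -1L))
  # the depth limit drops C
  reach1 <- signed_shortest_paths(net, "A", delta = 1)
  expect_false("C" %in% reach1$node)
})

test_that("conflicting parallel paths are ambiguous", {
  net <- signed_network(data.frame(from = c("A", "A"), to = c("C", "C"),
                                   sign = c(1L, -1L)))
  reach <- signed_shortest_paths(net, "A", delta = 1)
  expect_true(is.na(reach$sign[reach$node == "C"]))
  # conflict at distance 2 through two intermediates
  net2 <- signed_network(data.frame(
    from = c("A", "A", "M1", "M2"), to = c("M1", "M2", "C", "C"),
    sign = c(1L, 1L, 1L, -1L)))
  reach2 <- signed_shortest_paths(net2, "A", delta = 2)
  expect_true(is.na(reach2$sign[reach2$node == "C"]))
  # a longer conflicting path does not make a shortest sign ambiguous
  net3 <- signed_network(data.frame(
    from = c("A", "A", "M1", "M2", "M3"),
    to = c("C", "M1", "M2", "M3", "C"),
    sign = c(1L, -1L, 1L, 1L, 1L)))
  reach3 <- signed_shortest_paths(net3, "A", delta = 4)
  expect_identical(reach3$sign[reach3$node == "C"], 1L)
})

test_that("hypothesis scores match hand evaluation and are antisymmetric", {
  net <- chain_network()
  reach <- signed_shortest_paths(net, "A", delta = 2)
  obs <- c(B = 1L, C = -1L)
  up <- score_hypothesis(reach, obs, 1)
  expect_equal(up$score, 2)
  expect_equal(up$n_explained, 2)
  down <- score_hypothesis(reach, obs, -1)
  expect_equal(down$score, -2)
  mixed <- score_hypothesis(reach, c(B = 1L, C = 1L), 1)
  expect_equal(mixed$score, 0)
  expect_equal(mixed$n_contradicted, 1)
  # global symmetry: negating observations and hypothesis leaves the score
  neg <- score_hypothesis(reach, -obs, -1)
  expect_equal(neg$score, up$score)
})

test_that("unreachable and ambiguous observations count as ambiguous", {
  net <- signed_network(data.frame(from = c("A", "A"), to = c("C", "C"),
                                   sign = c(1L, -1L)), nodes = c("A", "C", "Z"))
  reach <- signed_shortest_paths(net, "A", delta = 2)
  res <- score_hypothesis(reach, c(C = 1L, Z = -1L), 1)
  expect_equal(res$score, 0)
  expect_equal(res$n_ambiguous, 2)
})

test_that("exhaustive permutation p matches full enumeration", {
  net <- chain_network()
  reach <- signed_shortest_paths(net, "A", delta = 2)
  obs <- c(B = 1L, C = -1L)
  # two assignments of the multiset {+1, -1}: scores {2, -2} -> p = 1/2
  expect_equal(permutation_pvalue(reach, obs, 1), 0.5)
  # all observations identical: a single assignment, p = 1
  expect_equal(permutation_pvalue(reach, c(B = 1L, C = 1L), 1), 1)
})

test_that("Monte Carlo p stays within binomial error of the exhaustive p", {
  set.seed(11)
  for (rep in 1:10) {
    g <- random_signed_digraph(8, 0.35)
    net <- signed_network(g$edges, nodes = g$nodes)
    src <- sample(g$nodes, 1)
    reach <- signed_shortest_paths(net, src, delta = 3)
    obs_nodes <- sample(setdiff(g$nodes, src), 6)
    obs <- setNames(sample(c(-1L, 1L), 6, TRUE), obs_nodes)
    if (all(obs == obs[1])) obs[1] <- -obs[1]
    p_ex <- permutation_pvalue(reach, obs, 1)
    p_mc <- permutation_pvalue(reach, obs, 1, n_perm = 4000,
                               seed = rep, exhaustive_limit = 0)
    expect_lt(abs(p_mc - p_ex), 3 * sqrt(p_ex * (1 - p_ex) / 4000) + 5e-4)
  }
})

test_that("single-path regulator is called with exhaustive significance", {
  # A explains a mixed set of observed TFs it fully reaches
  edges <- data.frame(
    from = "A", to = sprintf("T%d", 1:7),
    sign = c(1L, 1L, 1L, 1L, -1L, -1L, -1L))
  net <- signed_network(edges)
  obs <- setNames(c(1L, 1L, 1L, 1L, -1L, -1L, -1L), sprintf("T%d", 1:7))
  res <- call_mrs_per_sample(net, obs, deltas = 1, alpha = 0.05)
  expect_identical(res$states[["A"]], 1L)
  # p for the perfect assignment is 1 / C(7, 4)
  expect_equal(res$hypotheses$p_value[res$hypotheses$node == "A"], 1 / 35)
})

test_that("regulators significant with both signs are controversial and dropped", {
  # + evidence at delta 1 (direct edge), - evidence only at delta 3
  edges <- data.frame(
    from = c("A", "A", "X", rep("Y", 6)),
    to = c("B", "X", "Y", sprintf("C%d", 1:6)),
    sign = 1L)
  net <- signed_network(edges, nodes = c(edges$from, edges$to, "F1", "F2"))
  obs <- setNames(c(1L, rep(-1L, 6), 1L, 1L),
                  c("B", sprintf("C%d", 1:6), "F1", "F2"))
  res <- call_mrs_per_sample(net, obs, deltas = c(1, 3), alpha = 0.4,
                             seed = 2)
  hyp_a <- res$hypotheses[res$hypotheses$node == "A", ]
  expect_setequal(hyp_a$sign, c(1L, -1L))          # both signs significant
  expect_false("A" %in% names(res$states))          # and therefore dropped
})

test_that("a sample without nonzero TF states yields no calls", {
  net <- chain_network()
  res <- call_mrs_per_sample(net, c(B = 0L, C = 0L))
  expect_length(res$states, 0)
  expect_equal(nrow(res$hypotheses), 0)
})

test_that("reach, scores and exhaustive p agree with the brute-force oracle", {
  set.seed(21)
  for (rep in 1:25) {
    g <- random_signed_digraph(sample(5:10, 1), 0.3)
    net <- signed_network(g$edges, nodes = g$nodes)
    src <- sample(g$nodes, 1)
    for (delta in 1:3) {
      mine <- signed_shortest_paths(net, src, delta)
      orac <- oracle_signed_reach(g$edges, g$nodes, src, delta)
      expect_equal(mine$node, orac$node)
      expect_equal(mine$distance, orac$distance)
      expect_equal(mine$sign, orac$sign)
    }
    reach <- signed_shortest_paths(net, src, 3)
    obs_nodes <- sample(setdiff(g$nodes, src),
                        min(5, length(g$nodes) - 1))
    obs <- setNames(sample(c(-1L, 1L), length(obs_nodes), TRUE), obs_nodes)
    for (s in c(1, -1)) {
      expect_equal(score_hypothesis(reach, obs, s)$score,
                   oracle_score(reach, obs, s)$score)
      expect_equal(permutation_pvalue(reach, obs, s),
                   oracle_exhaustive_p(reach, obs, s))
    }
  }
})
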