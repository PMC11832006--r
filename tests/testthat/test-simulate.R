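small_config <- function(...) {
  args <- list(n_mr_layer = 2, n_intermediate = 2, n_tf = 4, n_genes = 120,
               n_tumor = 6, n_reference = 4, regulon_size_range = c(5, 10))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

test_that("the whole study is bit-identical under a fixed seed", {
  s1 <- simulate_mr_study(small_config(seed = 7))
  s2 <- simulate_mr_study(small_config(seed = 7))
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(as.data.frame(s1$network), as.data.frame(s2$network))
  expect_identical(unclass(s1$truth$node_states),
                   unclass(s2$truth$node_states))
  s3 <- simulate_mr_study(small_config(seed = 8))
  expect_false(identical(s1$counts$counts, s3$counts$counts))
})

test_that("regulon sizes and edge signs follow the configuration", {
  cfg <- small_config(regulon_size_range = c(10, 10), seed = 3)
  net <- generate_network_and_regulons(cfg)
  expect_true(all(table(net$regulons$tf) == 10))
  cfg0 <- small_config(inhibitory_fraction = 0, seed = 3)
  net0 <- generate_network_and_regulons(cfg0)
  expect_true(all(net0$network$sign == 1))
  expect_true(all(net0$regulons$mode == 1))
  # layered structure: MR layer feeds the intermediate layer only
  lay <- net$layers
  for (i in seq_len(nrow(net$network))) {
    expect_equal(unname(lay[net$network$from[i]]) == "mr",
                 unname(lay[net$network$to[i]]) == "intermediate")
  }
})

test_that("impossible regulon sizes are a config error", {
  expect_error(sim_config(n_genes = 50, regulon_size_range = c(30, 30)),
               "regulon_size_range")
})

test_that("zero planting probabilities give an all-zero truth", {
  cfg <- small_config(active_fraction = 0, inactive_fraction = 0, seed = 2)
  net <- generate_network_and_regulons(cfg)
  truth <- plant_truth(net$network, net$regulons, cfg)
  expect_true(all(truth$node_states == 0))
  expect_true(all(truth$lfc == 0))
  expect_length(truth$feedback_mrs, 0)
})

test_that("truth states follow signed shortest-path propagation", {
  cfg <- small_config(seed = 41)
  net <- generate_network_and_regulons(cfg)
  truth <- plant_truth(net$network, net$regulons, cfg)
  # in samples with exactly one planted regulator, every downstream state
  # must equal planted state x unambiguous shortest-path sign
  mr_ids <- rownames(truth$mr_states)
  solo <- which(colSums(truth$mr_states != 0) == 1)
  skip_if(length(solo) == 0, "no single-regulator sample drawn")
  for (j in solo[1:min(3, length(solo))]) {
    m <- mr_ids[truth$mr_states[, j] != 0]
    s_m <- truth$mr_states[m, j]
    reach <- signed_shortest_paths(net$network, m,
                                   length(network_nodes(net$network)))
    for (i in seq_len(nrow(reach))) {
      nd <- reach$node[i]
      if (nd == m) next
      expected <- if (is.na(reach$sign[i])) 0L else s_m * reach$sign[i]
      expect_identical(truth$node_states[nd, j], expected)
    }
  }
})

test_that("a planted regulator's own gene carries the feedback shift", {
  cfg <- small_config(seed = 5)
  net <- generate_network_and_regulons(cfg)
  truth <- plant_truth(net$network, net$regulons, cfg)
  for (m in rownames(truth$mr_states)) {
    nz <- which(truth$mr_states[m, ] != 0)
    for (j in nz)
      expect_equal(truth$lfc[m, j],
                   truth$mr_states[m, j] * cfg$planted_lfc)
  }
})

test_that("negative binomial counts match the planted moments", {
  # many reference samples make per-gene moments estimable
  cfg <- sim_config(n_mr_layer = 2, n_intermediate = 2, n_tf = 4,
                    n_genes = 60, n_tumor = 1, n_reference = 1500,
                    regulon_size_range = c(5, 10), nb_dispersion = 0.1,
                    seed = 9)
  study <- simulate_mr_study(cfg)
  refs <- study$counts$counts[, reference_ids(study$counts)]
  m <- rowMeans(refs)
  v <- apply(refs, 1, var)
  # var = mu (1 + phi mu): implied phi close to the configured one
  phi_hat <- (v - m) / m^2
  expect_equal(median(phi_hat), 0.1, tolerance = 0.25)
  expect_true(all(refs >= 0))
  expect_true(all(refs == round(refs)))
})

test_that("a planted shift doubles the expected count at lfc 1, phi -> 0", {
  cfg <- sim_config(n_mr_layer = 1, n_intermediate = 1, n_tf = 1,
                    n_genes = 20, n_tumor = 1000, n_reference = 5,
                    regulon_size_range = c(2, 3), nb_dispersion = 0,
                    planted_lfc = 1, active_fraction = 1,
                    inactive_fraction = 0, seed = 10)
  study <- simulate_mr_study(cfg)
  # the single regulator is active in every tumour sample: its own gene is
  # shifted by +1 log2 unit in every tumour column
  mr <- rownames(study$truth$mr_states)[1]
  ref_mean <- mean(study$counts$counts[mr, reference_ids(study$counts)])
  tum_mean <- mean(study$counts$counts[mr, tumor_ids(study$counts)])
  expect_equal(tum_mean / ref_mean, 2, tolerance = 0.15)
})

test_that("single-cell simulation honours expression probabilities", {
  genes <- sprintf("g%d", 1:20)
  sc <- simulate_single_cell(genes, c(A = 50, B = 30),
                             expr_prob = matrix(c(rep(1, 20), rep(0, 20)),
                                                20, 2,
                                                dimnames = list(genes,
                                                                c("A", "B"))),
                             mean_tpm = 10, seed = 4)
  summ <- single_cell_summary(sc)$summary
  expect_true(all(summ$pct_nonzero[summ$cell_type == "A"] == 100))
  expect_true(all(summ$mean_tpm[summ$cell_type == "B"] == 0))
  sc2 <- simulate_single_cell(genes, c(A = 50, B = 30),
                              expr_prob = matrix(c(rep(1, 20), rep(0, 20)),
                                                 20, 2), seed = 4)
  expect_identical(sc$tpm, sc2$tpm)
})
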