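# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# the default benchmark study: 30 tumour + 5 reference, 10 regulators,
# 20 TFs, planted log2 effect 2
fixture_study <- function() memo("study", function()
  simulate_mr_study(sim_config()))

fixture_pipeline <- function() memo("pipeline", function() {
  s <- fixture_study()
  suppressMessages(run_mr_pipeline(s$counts, s$network, s$regulons))
})

# a small count matrix with known structure
fixture_counts <- function() {
  m <- matrix(c(10L, 20L, 5L, 100L,
                12L, 18L, 6L, 90L,
                11L, 22L, 4L, 110L,
                50L, 40L, 30L, 200L,
                9L, 21L, 5L, 95L,
                60L, 70L, 20L, 150L),
              nrow = 6, byrow = TRUE,
              dimnames = list(sprintf("g%d", 1:6),
                              c("t1", "t2", "n1", "n2")))
  count_matrix(m, c(t1 = "tumor", t2 = "tumor",
                    n1 = "reference", n2 = "reference"))
}

chain_network <- function() {
  signed_network(data.frame(from = c("A", "B"), to = c("B", "C"),
                            sign = c(1L, -1L)))
}
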