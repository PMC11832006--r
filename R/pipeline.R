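# End-to-end orchestration: counts -> per-sample DEGs -> TF activity ->
# causal MR calls -> merged states -> feedback selection -> discrete-score
# biclustering -> network analysis -> optional annotation, with one global
# seed, per-stage sub-seeds, TSV outputs and a JSON manifest per run.

#' Merge TF-activity calls with causal MR calls
#'
#' Row-wise union of the two state matrices over the shared samples; where
#' a protein carries conflicting nonzero states from the two stages the
#' merged state is 0.
#'
#' @param tf_states,mr_states [state_matrix()] objects.
#' @return A `state_matrix` with provenance `"merged"`.
#' @export
merge_state_matrices <- function(tf_states, mr_states) {
  samples <- intersect(colnames(tf_states), colnames(mr_states))
  proteins <- union(rownames(tf_states), rownames(mr_states))
  a <- matrix(0L, length(proteins), length(samples),
              dimnames = list(proteins, samples))
  b <- a
  a[rownames(tf_states), ] <- unclass(tf_states)[, samples]
  b[rownames(mr_states), ] <- unclass(mr_states)[, samples]
  merged <- ifelse(a == 0, b, ifelse(b == 0 | b == a, a, 0L))
  storage.mode(merged) <- "integer"
  state_matrix(merged, "merged")
}

#' Pipeline parameters
#'
#' Stage parameters of [run_mr_pipeline()] with the workflow defaults:
#' `|log2 FC| > 1` and BH-adjusted `p < 0.05` for DEGs, adjusted `p < 0.05`
#' for TF activity, path lengths 1-3 with permutation `p < 0.05` for causal
#' calls, cosine `> 0.3` with a positive bootstrap CI for feedback
#' selection.
#'
#' @param lfc_threshold,alpha,pseudocount,dispersion_shrink see
#'   [de_config()].
#' @param min_targets minimum measured regulon targets.
#' @param delta_max maximum causal path length (deltas `1:delta_max`).
#' @param n_perm causal Monte Carlo permutations.
#' @param cos_threshold feedback/TF-network cosine cutoff.
#' @param b_bootstrap bootstrap replicates.
#' @param n_draws random-subnetwork null draws.
#' @param seed global seed.
#' @return A list of class `pipeline_params`.
#' @export
pipeline_params <- function(lfc_threshold = 1, alpha = 0.05,
                            pseudocount = 0.5, dispersion_shrink = 0.7,
                            min_targets = 5, delta_max = 3, n_perm = 1000,
                            cos_threshold = 0.3, b_bootstrap = 1000,
                            n_draws = 1000, seed = 1L) {
  stopifnot(delta_max >= 1, n_perm >= 1, b_bootstrap >= 1, n_draws >= 1)
  structure(as.list(environment()), class = "pipeline_params")
}

#' Run the full master-regulator pipeline
#'
#' Executes every stage on in-memory inputs and, when `out_dir` is given,
#' writes each stage's TSV outputs plus a JSON manifest recording input
#' checksums, parameters, seed and package version.  Reruns with the same
#' inputs and seed are bit-identical.
#'
#' @param counts a [count_matrix()] with tumour and reference samples.
#' @param network a [signed_network()].
#' @param regulons a [regulon_set()].
#' @param params a [pipeline_params()].
#' @param out_dir optional run directory (created if needed).
#' @param gene_sets optional [gene_sets()] for over-representation.
#' @param immune_signature optional character vector for the immune score.
#' @param subtypes optional named character vector (sample -> subtype).
#' @return A list of class `mr_pipeline` with the per-stage results.
#' @export
run_mr_pipeline <- function(counts, network, regulons,
                            params = pipeline_params(), out_dir = NULL,
                            gene_sets = NULL, immune_signature = NULL,
                            subtypes = NULL) {
  t0 <- Sys.time()
  seed <- params$seed
  decfg <- de_config(params$lfc_threshold, params$alpha, params$pseudocount,
                     params$dispersion_shrink)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  filtered <- stage("filter", filter_low_expression(counts))
  degs <- stage("diffexpr", deg_matrix(filtered, decfg))
  scores <- stage("tf_activity",
                  score_regulons(degs$signatures, regulons,
                                 params$min_targets))
  tf <- stage("tf_activity", call_tf_states(scores, params$alpha))
  causal <- stage("causal",
                  call_mrs(network, tf$states,
                           deltas = seq_len(params$delta_max),
                           alpha = params$alpha, n_perm = params$n_perm,
                           seed = sub_seed(seed, "causal")))
  merged_states <- stage("merge", merge_state_matrices(tf$states,
                                                       causal$states))
  feedback <- stage("feedback",
                    select_feedback_mrs(merged_states, degs$calls,
                                        cos_threshold = params$cos_threshold,
                                        B = params$b_bootstrap,
                                        seed = sub_seed(seed, "feedback")))
  selected <- feedback$protein[feedback$selected]
  scorem <- stage("scores", merged_scores(merged_states, degs$calls))
  clustering <- NULL
  if (length(selected) >= 2 && ncol(scorem) >= 2 &&
      any(scorem[selected, ] != 0))
    clustering <- stage("scores",
                        bicluster(scorem[selected, , drop = FALSE]))
  netres <- stage("network", {
    mr_nodes <- intersect(rownames(merged_states)[
      rowSums(merged_states != 0) > 0], network_nodes(network))
    sub <- induce_mr_subnetwork(network, mr_nodes)
    null <- random_subnetwork_null(network, length(mr_nodes),
                                   n_draws = params$n_draws,
                                   seed = sub_seed(seed, "network-null"))
    ctrl <- mds_drivers(sub$subnetwork)
    cent <- centralities(sub$subnetwork)
    tfnet <- build_tf_target_network(tf$states, degs$calls, regulons,
                                     cos_threshold = params$cos_threshold,
                                     B = params$b_bootstrap,
                                     seed = sub_seed(seed, "tf-network"),
                                     mr_genes = selected)
    list(subnetwork = sub, null = null, controllability = ctrl,
         centralities = cent, tf_target = tfnet)
  })
  annot <- stage("annotation", {
    out <- list()
    universe <- gene_ids(filtered)
    if (!is.null(gene_sets))
      out$enrichment <- ora_enrich(intersect(selected, universe),
                                   universe, gene_sets)
    if (!is.null(immune_signature)) {
      sf <- estimate_size_factors(filtered)
      norm <- sweep(filtered$counts, 2, sf, "/")
      out$immune_scores <- immune_score(norm, immune_signature)
      tum <- intersect(colnames(merged_states), colnames(norm))
      out$kendall <- dplyr::bind_rows(lapply(
        intersect(rownames(merged_states), rownames(norm)),
        function(p) kendall_screen(merged_states[p, tum], norm[p, tum],
                                   out$immune_scores[tum], protein = p)))
    }
    if (!is.null(subtypes)) {
      tum <- intersect(colnames(merged_states), names(subtypes))
      out$containment <- subtype_containment(
        merged_states[, tum, drop = FALSE], subtypes[tum])
    }
    out
  })
  result <- structure(
    list(filtered = filtered, degs = degs, tf_scores = scores,
         tf_states = tf$states, tf_calls = tf$calls,
         mr_states = causal$states, hypotheses = causal$hypotheses,
         merged_states = merged_states, feedback = feedback,
         selected = selected, merged_scores = scorem,
         clustering = clustering, network = netres, annotation = annot,
         params = params, elapsed = as.numeric(Sys.time() - t0,
                                               units = "secs")),
    class = "mr_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(result, counts, out_dir)
  result
}

#' @export
print.mr_pipeline <- function(x, ...) {
  cat(sprintf(paste0("<mr_pipeline> %d genes kept, %d tumour samples, ",
                     "%d TFs scored, %d proteins with calls, ",
                     "%d feedback MRs selected\n"),
              nrow(x$filtered$counts), ncol(x$merged_states),
              length(unique(x$tf_calls$tf)),
              sum(rowSums(x$merged_states != 0) > 0), length(x$selected)))
  invisible(x)
}

#' @export
glance.mr_pipeline <- function(x, ...) {
  states_sel <- x$merged_states[x$selected, , drop = FALSE]
  tibble::tibble(
    n_genes = nrow(x$filtered$counts),
    n_samples = ncol(x$merged_states),
    n_tfs_called = sum(rowSums(x$tf_states != 0) > 0),
    n_mrs_called = sum(rowSums(x$merged_states != 0) > 0),
    n_feedback_mrs = length(x$selected),
    n_active = sum(apply(states_sel, 1, function(r) any(r == 1))),
    n_inactive = sum(apply(states_sel, 1, function(r) any(r == -1))),
    n_drivers = x$network$controllability$n_drivers,
    lcc_size = x$network$subnetwork$stats$n_connected_in_lcc)
}

# internal: write every stage's tables plus the manifest
write_pipeline_outputs <- function(result, counts, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_count_matrix(result$filtered, p("filtered_counts.tsv"),
                     metadata_path = p("sample_roles.tsv"))
  for (s in names(result$degs$signatures))
    write_results_table(result$degs$signatures[[s]],
                        p(sprintf("signature_%s.tsv", s)))
  write_results_table(
    tibble::as_tibble(result$degs$calls, rownames = "gene"),
    p("deg_calls.tsv"))
  write_results_table(result$tf_calls, p("tf_activity.tsv"))
  write_state_matrix(result$tf_states, p("tf_states.tsv"))
  write_state_matrix(result$mr_states, p("mr_states.tsv"))
  write_results_table(result$hypotheses, p("causal_hypotheses.tsv"))
  write_state_matrix(result$merged_states, p("merged_states.tsv"))
  write_results_table(result$feedback, p("feedback_records.tsv"))
  write_results_table(
    tibble::as_tibble(unclass(result$merged_scores), rownames = "protein"),
    p("merged_scores.tsv"))
  if (!is.null(result$clustering)) {
    write_results_table(
      tibble::tibble(protein = result$clustering$row_order),
      p("row_order.tsv"))
    write_results_table(
      tibble::tibble(sample = result$clustering$col_order),
      p("col_order.tsv"))
    write_dendrograms(result$clustering, p("row_dendrogram.nwk"),
                      p("col_dendrogram.nwk"))
  }
  write_signed_network(result$network$subnetwork$subnetwork,
                       p("mr_subnetwork.tsv"))
  write_results_table(result$network$subnetwork$stats,
                      p("subnetwork_stats.tsv"))
  write_results_table(result$network$null$summary, p("null_summary.tsv"))
  write_results_table(glance(result$network$controllability),
                      p("controllability.tsv"))
  write_results_table(result$network$centralities, p("centralities.tsv"))
  write_results_table(result$network$tf_target$edges,
                      p("tf_target_edges.tsv"))
  write_results_table(result$network$tf_target$outdegree,
                      p("tf_target_outdegree.tsv"))
  for (nm in names(result$annotation)) {
    obj <- result$annotation[[nm]]
    if (is.numeric(obj))
      obj <- tibble::tibble(sample = names(obj), score = unname(obj))
    write_results_table(obj, p(sprintf("annotation_%s.tsv", nm)))
  }
  stage_names <- c("filter", "diffexpr", "tf_activity", "causal",
                   "feedback", "scores", "network", "annotation")
  tsvs <- list.files(out_dir, pattern = "\\.tsv$|\\.nwk$",
                     full.names = TRUE)
  manifest <- list(
    package = "mrloop",
    version = as.character(utils::packageVersion("mrloop")),
    seed = result$params$seed,
    parameters = result$params[setdiff(names(result$params), "seed")],
    stages = stage_names,
    n_input_genes = nrow(counts$counts),
    n_input_samples = ncol(counts$counts),
    outputs = as.list(setNames(unname(tools::md5sum(tsvs)),
                               basename(tsvs))))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             p("manifest.json"))
  invisible(out_dir)
}

#' Read a pipeline configuration file
#'
#' YAML with `inputs:` (paths `counts`, `metadata`, `network`, `regulons`,
#' optional `gene_sets`), optional `parameters:` (fields of
#' [pipeline_params()]) and `out_dir`.
#'
#' @param path YAML config.
#' @return A list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("counts", "metadata", "network", "regulons")) {
    if (is.null(cfg$inputs[[f]]))
      format_error("config is missing inputs.%s", f)
    if (!file.exists(cfg$inputs[[f]]))
      format_error("input file not found: %s", cfg$inputs[[f]])
  }
  cfg$parameters <- do.call(pipeline_params, cfg$parameters %||% list())
  structure(cfg, class = "pipeline_config")
}

#' Run the pipeline from a configuration file
#'
#' @param config path to a YAML config or a `pipeline_config`.
#' @return The `mr_pipeline` result, invisibly.
#' @export
run_mr_pipeline_config <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  counts <- read_count_matrix(config$inputs$counts,
                              metadata = config$inputs$metadata)
  network <- read_signed_network(config$inputs$network)
  regulons <- read_regulons(config$inputs$regulons)
  gs <- if (!is.null(config$inputs$gene_sets))
    read_gene_sets(config$inputs$gene_sets)
  out_dir <- config$out_dir %||% "mrloop_run"
  invisible(run_mr_pipeline(counts, network, regulons,
                            params = config$parameters, out_dir = out_dir,
                            gene_sets = gs))
}
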