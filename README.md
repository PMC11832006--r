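# mrloop — per-sample master regulator inference from bulk transcriptomes

Bulk tumour cohorts are heterogeneous: the proteins that drive expression
changes differ from sample to sample, and cohort-averaged analyses blur
precisely that signal. `mrloop` identifies **master regulators (MRs)** —
proteins at or above the transcription-factor layer of a signed signalling
network whose activity change explains the expression changes of an
*individual* tumour sample against a small reference group — and singles
out the MRs that sit in **positive feedback loops**, i.e. whose own
encoding gene moves concordantly with their inferred activity. It is
written for computational biologists working with a gene × sample count
matrix, a signed signalling network (OmniPath-style), and a signed regulon
table (CollecTRI-style).

## The method in brief

For each tumour sample *s* against references with normalised mean
`mu_g`:

* **DEGs** — `logFC = log2((x_gs/f_s + 0.5)/(mu_g + 0.5))`; a two-sided
  negative binomial outlier test with moment-based, shrunk dispersion;
  call `d_gs = ±1` iff `|logFC| > 1` and BH-adjusted `p < 0.05`.
* **TF activity** — probit scores `z_g = Φ⁻¹((rank_g − ½)/n)` of the logFC
  signature; for a regulon with modes `m_g ∈ {±1}`,
  `NES = Σ m_g z_g / √|regulon|`, standard normal under the null; TF state
  `t = sign(NES)` iff adjusted `p < 0.05`, else 0.
* **Causal MRs** — for every network node and hypothesis sign
  `s ∈ {±1}`, signed shortest paths up to `delta ∈ {1,2,3}` predict each
  observed TF as `s·σ(path)`; score = explained − contradicted;
  keep hypotheses with positive score and permutation `p < 0.05`
  (observed-state multiset reassigned across TF positions, exhaustively
  enumerated when feasible); merge deltas by union and drop sign-conflicted
  nodes.
* **Feedback MRs** — cosine between a protein's state profile and its
  gene's DEG profile; selected iff `cos > 0.3` and the percentile
  bootstrap 95% CI lower limit is > 0.
* **Scores & structure** — merged scores in `{−3..3}` biclustered with
  Ward linkage on `1 − cosine` distances; the MR subnetwork is compared
  with 1000 random node subsets, its minimum driver node set computed via
  maximum bipartite matching (`n_drivers = max(1, N − matching)`), plus
  outdegree/closeness centralities and a cosine-gated bulk TF–target
  network.

A synthetic-data generator plants known per-sample MR activities through a
layered signed network, so the whole chain is testable without external
data. See `vignettes/mrloop-methods.Rmd` for models, parameter meanings,
defaults and limitations.

## Worked example

```r
library(mrloop)

study <- simulate_mr_study(sim_config())   # the default benchmark
study$counts
#> <count_matrix> 2000 genes x 35 samples (30 tumor, 5 reference)

res <- run_mr_pipeline(study$counts, study$network, study$regulons)
res
#> <mr_pipeline> 1500 genes kept, 30 tumour samples, 20 TFs scored,
#>   38 proteins with calls, 9 feedback MRs selected

res$feedback[res$feedback$selected, ]
#> # A tibble: 9 x 6
#>   protein cosine ci_low ci_high gene_measured selected
#> 1 MR02     0.404  0.115   0.640 TRUE          TRUE
#> 2 MR03     0.548  0.258   0.745 TRUE          TRUE
#> 3 MR04     0.756  0.408   1     TRUE          TRUE
#> ...

study$truth$feedback_mrs          # the planted truth: MR01..MR10
```

The selected rows are the proteins in positive feedback loops: `cosine`
measures how concordantly the protein's active/inactive profile tracks its
own gene's up/down calls across the 30 tumour samples, and selection
requires the bootstrap CI to stay above zero. Here the pipeline recovers 9
of the 10 planted regulators with no false positives. Downstream results
live in the same object: `res$merged_scores` and `res$clustering` (the
heatmap input and dendrograms — `autoplot(res$clustering)` draws it),
`res$network$controllability` (`22 driver node(s), matching size 16` on
this run — the number of MRs an intervention would have to touch), and
`res$network$null$summary` for the random-subnetwork comparison.
`glance(res)` condenses the run to one row; `tidy()` methods give long
tibbles of every matrix.

Passing `out_dir =` writes every stage's TSVs plus a `manifest.json`
(parameters, seed, output checksums); `inst/scripts/mrpipe.R` wraps
`simulate` and `run` for shell use with a YAML config.

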