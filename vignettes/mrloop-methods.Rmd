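---
title: "Per-sample master regulator inference: models and methods"
author: "mrloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-sample master regulator inference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrloop)
```

## The problem

Bulk tumour transcriptomes are heterogeneous: the regulators that drive
expression changes differ from patient to patient, and averaging profiles
over a cohort blurs exactly the signal a personalised analysis needs.
`mrloop` implements a per-sample workflow for identifying **master
regulators (MRs)** — proteins at or above the transcription-factor (TF)
layer of a signalling network whose activity change explains the expression
changes observed in *one* tumour sample relative to a small reference group.
The workflow runs in six stages, each of which consumes the previous
stage's discrete output:

1. per-sample differential expression against the reference group;
2. TF activity from signed regulon enrichment, binarised to
   active (+1) / inactive (−1) / not identified (0);
3. upstream causal reasoning on a signed signalling network;
4. positive-feedback selection: an MR whose own encoding gene moves
   concordantly with its inferred state;
5. merged −3..3 scoring and Ward biclustering of MRs × samples;
6. structural analysis of the MR subnetwork (connectivity, controllability,
   centralities) and of the bulk TF–target network.

The discrete state matrix over {−1, 0, +1} is the central intermediate: a
value records whether, in that sample, the protein's predicted activity
change explains (+1) or would reverse (−1) the observed signature.

## Stage models

### Per-sample differential expression

Each tumour sample is tested gene-by-gene against the reference group.
After median-of-ratios size-factor normalisation (geometric-mean-one
convention) and removal of genes whose mean normalised count falls strictly
below the lower quartile of all gene means (linear-interpolation
percentile), the per-gene statistic is a **negative binomial outlier
test**: the observed tumour count is compared with the null predictive
distribution `NB(mu_hat * f_s, phi_eff)`, where `mu_hat` is the normalised
reference mean and `f_s` the sample's size factor.

Two points make this test calibrated with as few as five reference
samples:

* the per-gene method-of-moments dispersion is shrunk towards the **mean**
  of the per-gene estimates with weight `dispersion_shrink` (default 0.7).
  The mean, unlike the median, is nearly unbiased under the strongly
  right-skewed sampling distribution of the moment estimator at small
  `n_ref`; the heavy default weight reflects how noisy a 4-df variance
  estimate is.
* the predictive variance adds the sampling variance of the estimated
  reference mean, `f_s^2 (mu_hat + phi mu_hat^2) / n_ref`.  Without this
  inflation a one-versus-few outlier test is anti-conservative by
  construction.

Two-sidedness under discreteness is defined as
`min(1, 2 min(P(X <= x), P(X >= x)))`, both tails including the observed
point mass.  The log-fold change uses a pseudocount of 0.5 on both sides;
a gene is called (±1) when `|logFC| > 1` (strictly) and the BH-adjusted p
is below 0.05.  These thresholds balance DEG counts against significance
and are the conventional choice for this analysis; both are configurable.
The DE stage sits behind `deg_matrix()`, so a table produced by an
external DE tool can be substituted as long as it provides per-gene
`log_fc` and discrete calls.

### TF activity

For each sample, the logFC signature is rank-transformed
(`r = (rank − 0.5)/n`, average ranks on ties) and probit-scored
(`z = qnorm(r)`).  A TF with regulon targets `g` and modes
`m_g ∈ {−1, +1}` scores

```
NES = sum(m_g * z_g) / sqrt(|regulon ∩ measured|),
```

which is standard normal when gene labels carry no signal — the test suite
verifies this to Kolmogorov–Smirnov precision at 10^4 permutations.  A TF
is called active when `NES > 0` with BH-adjusted `p < 0.05` (adjustment
across TFs *within* a sample; the alternative global adjustment is a
one-line change and was not chosen because each sample is an independent
analysis in this workflow), inactive when `NES < 0` under the same cutoff.
Regulons with fewer than `min_targets = 5` measured targets are skipped
with a message: below that size the normal approximation and the biology
are both unreliable.  Interaction-confidence weighting and pleiotropy
correction of richer activity-inference tools are deliberately out of
scope; with ±1 modes the two-tailed analytic rank enrichment above is the
faithful core, and the scorer sits behind an interface so a richer one can
be swapped in.

### Causal reasoning

Candidate hypotheses are all network nodes with sign `s ∈ {+1, −1}`.  The
signed reach of a candidate is computed by breadth-first search to depth
`delta`: each reached node gets the shortest-path distance and the product
of edge signs along shortest paths; two shortest paths with unequal
products make the node **ambiguous**, and ambiguous or unreachable
observations are non-informative (they contribute to neither explanation
nor contradiction — the conservative convention of causal-reasoning tools
in this field).  The hypothesis score is
`n_explained − n_contradicted` over the observed TF states.

Significance is assessed with a permutation test whose null reassigns the
observed state multiset uniformly across the observed TF positions.  All
distinct assignments are enumerated when there are at most 10^4 of them
(the common case: `C(n, k)` for n observed TFs with k active), giving
exact p-values; otherwise `n_perm` Monte Carlo draws are used with the
add-one estimator `(1 + #{perm ≥ obs})/(1 + n_perm)`.  A hypothesis is
accepted at a given `delta` when `p < 0.05` **and** the score is positive
— the score condition is an explicit assumption added here, because a
"regulator" that contradicts more observations than it explains is not an
explanation at all, whatever its p-value.

Path-length limits `delta = 1, 2, 3` are run and their significant calls
merged by **union** per (node, sign): intersection would make the longer
runs redundant, since the reach at `delta` contains the reach at
`delta − 1`.  Nodes significant with both signs at any deltas are
controversial and removed.  The per-hypothesis p-values are not adjusted
across candidates by default (a plain `p < 0.05` cut); a BH option exists.
TF-activity calls and causal calls are then merged by union, with
conflicting nonzero states zeroed — the same controversy principle at the
merge level.

### Positive-feedback selection

For every protein the pipeline compares two per-sample profiles of equal
length: its state profile and its encoding gene's DEG-call profile.  The
cosine similarity between them (zero-norm convention: cosine 0) is
bootstrapped by resampling sample positions with replacement
(`B = 1000`, percentile 95% interval; neither the replicate count nor the
interval type is canonical, and both are parameters).  A protein is a
**feedback-loop MR** when the cosine exceeds 0.3 and the lower CI limit is
positive.  Proteins whose gene is unmeasured are retained as unselected
records rather than dropped.  A practical consequence of the percentile
criterion: a protein needs roughly four concordant nonzero samples out of
30 before the 2.5% quantile of the bootstrap distribution leaves zero —
fewer, and the CI lower limit is 0 and the protein is (correctly, under
this criterion) rejected.

### Merged scores and biclustering

State `s` and call `d` merge to an integer score: `3s` when `d = s ≠ 0`
(state and expression agree — the strongest evidence of a feedback
regulator), `2s` when `s ≠ 0, d = 0`, `d` when `s = 0, d ≠ 0`, and 0
otherwise, including sign conflicts.  Rows (proteins) and columns
(samples) are clustered independently with Ward linkage on `1 − cosine`
distances.  Ward has two common conventions; the implementation uses
`ward.D2` (Lance–Williams on squared distances), recorded here because the
choice changes merge heights but rarely leaf orders.  An all-zero matrix
has no meaningful cosine geometry and is an error.

### Network structure

The MR subnetwork is the induced subgraph on the called regulators;
"connected" means *weakly* connected, since the analysis asks whether the
regulators interact at all, not whether they reach each other along
directed paths.  Its size and edge count are compared against a null of
1000 uniform node subsets of equal size.  Structural controllability uses
the minimum driver node set: `n_drivers = max(1, N − M)` with `M` the
maximum matching of the bipartite out-copy/in-copy graph; the witness set
is the set of unmatched in-copies from a deterministic matching
(reproducible, not canonical — driver sets are never unique).  Outdegree
counts distinct out-neighbours (parallel opposite-sign edges count once);
closeness is the inverse of summed directed shortest-path lengths to
reachable nodes, zero for sinks.

The bulk TF–target network keeps a regulon interaction when the cosine
between TF state profile and target DEG profile passes ±0.3 with a CI
clear of zero on the matching side.  For repression the symmetric rule
(`cosine < −0.3` and CI *upper* limit < 0) is the default; the literal
asymmetric reading (lower limit < 0, which admits intervals crossing
zero) is available as `repression_rule = "literal"`.

### Annotation

Over-representation uses the hypergeometric upper tail against the
measured-gene universe with BH adjustment; the reporting filter requires
an overlap of at least two MR genes with raw `p < 0.05`.  The immune
infiltration score is a single-sample rank-weighted enrichment
(`rank^0.25` weights, signature ECDF minus remainder ECDF summed along the
ranking) — a pure rank statistic, invariant under monotone transforms of
the profile.  The correlation screen declares a protein immune-associated
only when Kendall's tau-b against the immune score is positive with
`p < 0.05` at **both** the discrete-state level and the expression level;
normalised expression feeds the expression-level test.  Tau's p-value is
computed by exact permutation enumeration for n ≤ 8 (the normal
approximation is poor there, and the textbook exact method does not
handle ties) and by the tie-corrected normal approximation otherwise.

## The synthetic benchmark

Real studies of this kind rest on cohort-scale consortium data plus
curated network and regulon snapshots; none of that is reproducible at
package-test scale.  The generator therefore *plants the truth the
pipeline is supposed to find* and every stage is tested against it.

Structure: a three-layer signed digraph — `n_mr_layer = 10` upstream
regulators, `n_intermediate = 10` signalling proteins, `n_tf = 20` TFs —
with between-layer edge probability 0.27 and at least three out-edges per
node, each TF carrying a regulon of 20–40 targets drawn from the
background genes.  Per tumour sample (30 tumour, 5 reference), each
regulator is planted active/inactive with probability 0.18/0.18; states
propagate along signed shortest paths with the causal module's own
ambiguity rule, influences from several planted regulators combine by
sign-majority (ties give no effect — the causal module never combines
sources, so this rule is the generator's own and is stated here).  A TF
in state σ shifts each regulon target by `σ · mode · planted_lfc` log2
units (conflicting TF influences cancel), and each planted regulator's
own gene is shifted by `state · planted_lfc` — the feedback loop.  Counts
are negative binomial (`mu (1 + phi mu)` variance, `phi = 0.05`) with
log-uniform baseline means over 20–2000.

Three generator choices exist purely to keep the benchmark
*identifiable*, and are worth stating because each traces back to a
property of the method:

* **Stratified edge signs.**  Each node gets the configured fraction
  (0.3) of inhibitory out-edges exactly (stochastic rounding) rather than
  i.i.d. Bernoulli signs.  A regulator's downstream sign pattern is a
  fixed network property; if it happens to be all-activating, every
  sample that regulator drives alone produces a sign-uniform observed TF
  multiset, for which the reassignment permutation null is degenerate
  (`p_min = 1/n > 0.05` for n ≤ 20 observed TFs) and detection is
  *structurally impossible*.  Real signalling hubs drive both activating
  and inhibitory arms; the stratification encodes that.
* **Balanced planting with partial footprints.**  Several simultaneous
  regulators with balanced signs keep the observation multiset mixed,
  while the moderate edge density keeps their footprints only partially
  overlapping, so majority conflicts silence a TF (harmless) more often
  than they outvote a regulator (a contradiction that costs the score
  twice).
* **Expressed network genes, background-only regulon targets.**  Node
  encoding genes draw baseline means above the low-expression filter
  range — mirroring the practice of restricting the network to genes
  expressed in the tissue — and regulon targets exclude node genes so the
  planted feedback edge is the *only* route from a protein's state to its
  own gene.

What the generator does **not** emulate: GC/length biases, batch
effects, correlated dispersion structure, regulon overlap between TFs,
dropout beyond the Bernoulli single-cell model, or subtype structure.
Passing the recovery tests therefore shows the chain of inferences is
correct and calibrated under its own assumptions — not that those
assumptions hold in any particular cohort.

On this benchmark the pipeline's selected feedback MRs reach sensitivity
and precision of at least 0.8 against the planted truth at
`planted_lfc = 2`, with both metrics monotone in the effect size — the
acceptance suite computes these numbers on every run, and
`scripts/acceptance.R` reports them for any seed.

## Numerical and reproducibility choices

* One global seed; each stochastic stage draws from a sub-stream derived
  by hashing the stage name into the seed (`sub_seed()`), so adding draws
  to one stage never perturbs another, and identical configurations give
  bit-identical run directories (verified file-by-file in the tests).
* Permutation enumeration switches to Monte Carlo above 10^4 distinct
  assignments; bootstrap and null-subnetwork draws are plain Monte Carlo.
* Rank ties break by average rank everywhere; hierarchical clustering
  inherits `hclust`'s deterministic tie handling.
* Degenerate inputs have stated conventions rather than NaNs: zero-norm
  cosine is 0, closeness of a sink is 0, an empty-network driver set is
  all nodes, a protein without a measured gene is an unselected record,
  and a constant profile yields `tau = NA` with `correlated = FALSE`.
* Test-suite problem sizes: 100 random graphs (≤12 nodes) for the causal
  oracle, 120 graphs (≤8 nodes) for the matching oracle, 10^4
  permutations for the NES null, 500 simulations × 1000 replicates for
  bootstrap coverage, and the default 2000-gene benchmark for end-to-end
  recovery.  These sizes are the package's own choices for a
  desk-scale, deterministic test suite.

## Known limitations

* The DE stage is an outlier test against a small reference group, not an
  exact reproduction of any published cohort pipeline; with `n_ref = 5`
  its power at `|logFC| ~ 1` is limited, which is visible in the
  benchmark's recovery falling to ~0.5 at `planted_lfc = 1`.
* The permutation null permutes observed states across TF positions; it
  conditions on the observation multiset but not on network topology.  A
  topology-preserving null (e.g. observation sets drawn from degree-matched
  TFs) would be stricter and is not implemented.
* With a strictly layered network the causal stage cannot call terminal
  TFs (a self-path explains one observation, never enough for
  `p < 0.05`); TF calls enter the merged state matrix from the activity
  stage instead.  On a real, cyclic signalling network TFs compete as
  hypotheses like any other node.
* Biclustering treats the immune-score track as display-only; it never
  influences the distances.
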