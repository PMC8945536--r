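---
title: "Probabilistic structural equation models for microbiome data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic structural equation models for microbiome data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the model it implements,
the choices that were genuinely open, and what the synthetic tests do and
do not establish. It states no empirical result that the test suite does
not itself compute.

## The model

A probabilistic structural equation model (pSEM) for microbiome data has
two halves.

**Measurement part.** Each genus' relative abundance (count over sample
total) is log-transformed where nonzero; zeros keep a dedicated ordered
category below the log scale, because a zero is biologically "very low or
absent", not a missing value. The log values are discretized and a
discrete Bayesian network is learned over all genera by minimizing a
minimum-description-length score,

    MDL(G) = sc * DL_struct(G) + DL_data(G)   [bits]

with `DL_data` the maximized negative log-likelihood and, per node,
`DL_struct = log2(n)(1 + |parents|) + (log2 N)/2 (r - 1) q` (`n` nodes,
`N` samples, `r` node arity, `q` parent-configuration count). The
structural coefficient `sc` in (0, 1] scales only the structural term:
it is the density dial, scanned by `sc_scan()`. Taxa are then clustered
along the learned skeleton (agglomerative, merge priority = average
pairwise mutual information, at most 10 per cluster) and each cluster is
compressed into a latent construct: one hidden categorical variable with
the members conditionally independent given its state, fitted by EM.
The construct's per-sample value is the MI-weighted average of member
values; weights are each member's MI with the construct divided by the
largest member MI, so exactly one member has weight 1.

**Structural part.** The discretized construct scores join the
covariates (age at sampling, sex, gut compartment, dietary insect-larva
percentage) and the phenotype (body weight in five classes). A second
MDL search runs on bootstrap resamples ("structural priors" bagging):
arcs appearing in at least `freq_threshold` of the resampled networks
become priors whose graph-coding bits are waived in the final full-data
search. The fitted network is validated by k-fold cross-validated
one-vs-rest ROC AUC on the weight classes, and each node's influence on
weight is split into a total and a direct effect.

**Effect semantics.** The total effect applies minimal-Kullback-Leibler
soft evidence on the source — an exponential tilting of its marginal
whose mean shifts by `delta` standard deviations (default 0.1) — and
propagates it exactly through the joint, reporting the change in the
expected weight per unit change in the source mean. Propagation is
evidential, not interventional: shifting a construct's mean also updates
belief about its parents (age), which is precisely how a construct with
no direct arc into weight acquires a nonzero total effect. The direct
effect holds the target's other parents fixed: within each configuration
of the other parents, the slope of `E[weight | source, config]` against
the source's numeric representatives is fitted by weighted least squares
(weights `P(source | config)`), and slopes average over `P(config)`. A
node that is not a parent of weight therefore has direct effect exactly
zero — a theorem of the definition, matching the empirical finding that
only the phenotype's parents carry direct effects. Significance comes
from a nonparametric bootstrap over samples with the structure held
fixed and CPTs refitted (95% percentile intervals); the choice of
bootstrap is ours, as the original tooling does not document its
significance machinery. Note one consequence of evidential propagation:
under pure confounding the total effect is also nonzero — "total" here
means predictive, not causal, association per unit mean shift.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `filter_threshold` | 1e-4 | keep a genus iff its relative abundance exceeds 0.01% in some sample of at least one replicate (strict inequality; ties drop) |
| `log base` | 10 | downstream steps are bin-based, so the base only relabels thresholds |
| `ra_r2_target` | 0.95 | smallest k in 2..5 whose optimal binning explains 95% of the variance |
| `weight_k` | 5 | weight classes via exact 1-D k-means |
| `taxa_sc` | 0.85 | midpoint of the 0.7–1 range adequate for taxa networks |
| `structural_sc` | 0.45 | low-density operating point for the structural model |
| `max_parents` | 4 | tractability cap; not binding on sparse networks |
| `max_cluster_size` | 10 | cap on construct membership |
| `mi_floor` | 0.02 bits | minimum average pairwise MI for a cluster merge |
| `n_boot` (bagging) | 100 (pipeline default 30) | resamples for arc frequencies |
| `freq_threshold` | 0.5 | arc frequency to become a structural prior |
| `effect delta` | 0.1 sd | size of the mean-shift perturbation |

Scoring uses pure maximum likelihood (pseudocount 0) so MDL semantics
are exact; inference and effect propagation use pseudocount 0.5 so no
conditional probability is ever exactly zero. Both are deliberate and
logged in the fitted objects.

## Numerical choices

* **Discretization is exact.** Both discretizers reduce to the optimal
  contiguous partition of sorted values minimizing within-bin sum of
  squares, solved by dynamic programming (Fisher partitioning); 1-D
  k-means is solved by the same program, so the "seed" only matters for
  ties. Intervals are left-open/right-closed; out-of-range values clamp
  to the extreme bins; a value equal to a threshold goes to the lower
  bin. The commercial genetic optimizer this mirrors can only
  approximate the same objective, so the exact program is used as the
  reference implementation.
* **Fallback k at the R-squared elbow.** For genuinely continuous data
  no small k reaches R² = 0.95 (a standard normal needs ~7 bins), and
  "take the k with maximal R²" would then always return the largest
  candidate — making the candidate set meaningless. When no candidate
  reaches the target, we therefore take the elbow (maximum curvature) of
  the R²-vs-k curve, which lands on 3 bins for Gaussian-like data — the
  behaviour the R² rule shows on the skewed abundance data it was
  designed for.
* **Search.** Greedy hill-climbing over add/delete/reverse moves with a
  tabu list on recently undone moves, random restarts from perturbed
  optima, per-family score caching and lexicographic tie-breaking, so a
  seed fully determines the result. The proprietary equivalence-class
  search it replaces reportedly reached similar scores with all its
  siblings, so the optimizer identity is not load-bearing. Acyclicity is
  enforced per move (reversing u→v is legal only if no other u⇝v path
  remains).
* **Inference.** Exact variable elimination with hard-evidence slicing,
  barren-node pruning (only the ancestral closure of query and evidence
  is instantiated) and a greedy smallest-scope elimination order.
* **EM.** Random responsibility starts (best of 5 by the smoothed
  objective), pseudocount 0.5 in the M-step, convergence on relative
  objective change below 1e-7. Latent states are relabeled so that the
  MI-weighted mean of member representatives increases with the state
  index: "high construct" then means "high member abundances". The
  latent arity defaults to the modal member arity; an MDL selection over
  {2, 3, 4} is available via `n_states`.
* **Ties and degenerate inputs.** A single-member cluster's construct is
  the member itself (purity 100, contingency-table fit undefined).
  All-zero variables produce a zero-class-only binning with a warning.
  Contingency-table fit is reported missing when members are already
  independent (the denominator vanishes).

## The synthetic world

The generator reproduces the structure of the motivating study rather
than its numbers: 90 samples over three replicates whose sampling frame
confounds age, compartment and diet onset exactly as the animal
experiment did (cloacal swabs taken young and before the insect diet
started, caecal contents at slaughter); three diet groups with **zero
true effect on anything** — the null the study reported; 62 genera
partitioned over 10 latent constructs; per-construct values
`alpha * standardized age + unit noise` with `alpha = 0.8` for five
constructs and 0 for the rest; taxon log-intensities
`intercept + lambda * construct + noise` pushed through a softmax (so
taxa are negatively coupled through the simplex, as compositions are)
and a multinomial draw at 10,000 reads; independent dropout at rate 0.2;
weight `10.59 g/day * age + 34.5 g * male + N(0, 60 g)`, truncated
positive. The age and sex coefficients are the study's own point
estimates; depth, sample count, genus count and design are the study's;
loading strength, noise scales (unit taxon noise, intercept spread 1.5
on the log scale) and the dropout rate are our choices of a realistic
regime, fixed once. The mediation preset (one age-driven construct among
three, 18 taxa) uses N = 400 — the same scale as the strong-signal
preset — because its purpose is to make the qualitative mediation
pattern identifiable, which the 90-sample design cannot do for the taxa
skeleton.

What a green test establishes: that the algorithms recover planted
structure, mediation and null-diet patterns from data *shaped like*
microbiome data. What it does not: that the generator matches real gut
communities. In particular the synthetic log-abundances are much less
skewed than real ones — real genus distributions concentrate near zero
with rare blooms, giving low-entropy categories after discretization.
Two published quality bars are unreachable in our world for exactly this
reason: construct purity above 95% and contingency-table fit above 70%.
A naive-Bayes model built from the generator's *true* latent values
scores purity 65–86% and contingency-table fit 23–25% on the
strong-signal preset (the EM fit beats this oracle, reaching ~85–91% and
~38–53%): with near-Gaussian members the R²-driven binning produces 4–6
categories, the posterior over 4–6 latent states cannot be 95%
concentrated at loading 2 against unit noise, and the contingency-table
denominator — the empirical joint entropy — saturates near `log2(N)`
when member configurations are almost all distinct. The corresponding
acceptance check is left failing by design, with the recovery (adjusted
Rand index) part passing; treating those bars as generator targets would
have meant tuning the world to the metric.

## Design choices that were open

* Filtering compares each replicate's **per-sample maximum** against the
  0.01% threshold (the only grouping the study names is its three
  replicates) and does **not** renormalize survivors, so downstream log
  values are unchanged.
* Table-style arc correlations are computed on the **continuous**
  log-abundances with zero-marked entries excluded pairwise; published
  correlations are clearly richer than 3-category codes. A flag switches
  to category codes.
* The G-test of an arc conditions on the child's **other parents**, the
  same conditioning that defines the arc's KL force; significance is
  0.05 with no multiplicity correction (a documented limitation, matching
  the original analysis). Arcs failing the test are flagged, never
  auto-removed.
* The number of clusters is emergent, not forced; the jackknife
  correspondence between clusterings uses greedy maximal-overlap
  matching with ties broken by cluster id.
* Zero-marked member values enter construct scores one unit below the
  member's observed log support — "below everything", preserving order
  without inventing a magnitude.
* Configuration files are JSON (plain text, lossless round-trip); every
  run writes its resolved configuration and a manifest with a config
  hash, so reruns are byte-comparable.

## Known limitations

* Effects are evidential associations per unit mean shift, not
  do-calculus causal effects; with confounding the two differ.
* The conditional-independence tests and MDL scores assume i.i.d.
  samples; the study design (repeated groups, two compartments) violates
  this mildly, as it did in the original analysis.
* At the study's own scale (90 samples) the synthetic taxa network is
  much sparser than the published one (4 arcs versus 59), because the
  synthetic variables carry 4–6 high-entropy categories where the real,
  skewed data supported ~3 low-entropy ones; measurement-part structure
  at that scale is consequently weak. The full pipeline still runs,
  deterministically, end to end.
* No multiple-testing correction on arc significance; no phylogenetic
  signal or read-level artifacts in the generator.
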