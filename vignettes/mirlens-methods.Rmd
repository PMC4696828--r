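---
title: "Inferring miRNA-mRNA regulation from matched expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring miRNA-mRNA regulation from matched expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirlens)
```

## The problem

microRNAs (miRNAs) repress messenger RNAs post-transcriptionally, and a
central question in systems biology is which mRNAs each miRNA actually
regulates in a given condition. When miRNA and mRNA abundance are measured
on the *same* samples ("matched profiles"), the co-variation between a
miRNA and a candidate target carries information about regulation: a
genuine target tends to go down when its regulator goes up. `mirlens`
turns this idea into a complete dry lab: a battery of scoring methods that
each fill an mRNAs × miRNAs score matrix, rank-aggregation ensembles,
masking by sequence-predicted binding, and validation of top-k target
lists against two kinds of ground truth — experimentally confirmed
interactions and miRNA perturbation (transfection) experiments.

Because miRNAs predominantly *down*-regulate targets, every sign-carrying
method ranks the most negative associations first. Non-negative
dependence measures rank the largest values first. Each score matrix
therefore carries an explicit ordering tag (`ASC_SIGNED`, `DESC_VALUE`,
`ASC_RANK`), and all downstream machinery (ranking, top-k extraction,
ensembles, masking) respects it.

## The scoring methods

**Correlation and dependence measures** (per pair, one miRNA against one
mRNA): Pearson, Spearman (Pearson on mid-ranks) and Kendall's tau-b
(tie-corrected) capture monotone association with sign; distance
correlation (the biased V-statistic form, via double-centred distance
matrices), Hoeffding's D (the classical rank statistic, with mid-ranks
and the ¼/½ tie conventions in the bivariate rank), and the randomised
dependence coefficient (RDC) capture general dependence without sign. The
RDC maps each variable to its empirical copula, projects through random
sinusoidal features (`n_features = 20`, scale `1/6`, following the
original parameterisation on the intercept-augmented copula block) and
takes the largest canonical correlation; each pair derives its generator
seed deterministically from `(seed, miRNA index, mRNA index)`, so results
are reproducible and projections are not shared across pairs. Mutual
information uses equal-frequency binning on mid-ranks (default
`ceiling(n^(1/3))` bins) and the plug-in estimator in bits; ranks are
used for binning so the estimate is invariant to sample permutation and
monotone transformations.

**Penalised regression**: each mRNA is regressed on *all* miRNAs jointly
with the elastic net (glmnet's coordinate descent behind the module
surface); the standardised coefficient of each miRNA is its score, so a
miRNA is only credited for variation it explains beyond the other
miRNAs. `l1_ratio = 1` is the lasso; the default mixing is 0.5. The
penalty is chosen by 5-fold cross-validation at minimum MSE with a
deterministic, seeded fold assignment (seeded shuffle, then index mod
folds); `lambda = 0` is solved by exact least squares rather than the
path solver.

**Causal inference (PC-stable + IDA)**: a completed partially directed
acyclic graph (CPDAG) is learned over all features with the
order-independent PC-stable variant — neighbour sets are frozen per
level, so the output does not depend on column order. Conditional
independence is tested with Fisher's z transform of the partial
correlation at significance level `alpha = 0.01`. Unshielded colliders
are oriented from the recorded separating sets; conflicting collider
demands leave the edge undirected (conservative); Meek rules 1–4 are
iterated to a fixed point. For each (miRNA, mRNA) pair, local IDA
enumerates the miRNA's candidate parent sets — certain parents plus every
subset of undirected neighbours whose orientation toward the miRNA
creates no new collider — and estimates one possible causal effect per
parent set by an adjustment regression on the raw (unstandardised)
expression values. The multiset is summarised by its minimum-absolute
element with sign kept, the conservative lower bound that is standard
IDA practice. Two deliberate refinements: the effect is exactly 0 when
the mRNA is not reachable from the miRNA by any semi-directed path (it is
zero in every DAG of the equivalence class, so reporting the regression
noise would be strictly worse), and the default conditioning-set cap is
3 (configurable to `Inf`) because the search is exponential in that size.

**Pseudo-knockout Z-score**: the sample in which a miRNA is lowest is
treated as its knockout condition; the score of an mRNA is the absolute
deviation of its expression in that sample from its mean, in standard
deviations (first sample on ties; the signed deviation is available via
`signed = TRUE`).

## Ensembles, masking, validation

`borda()` averages the per-miRNA ranks that several methods assign to
each mRNA; `borda_topk()` first truncates each method's ranking at `k`,
replacing every rank beyond `k` by the maximal rank (the number of
mRNAs), so only agreement inside top lists counts, and reduces exactly to
`borda()` at `k = N`. Ties always share the mean rank with the mRNA name
as a deterministic secondary key. Externally computed score matrices
are ingested by name-based alignment (`read_external_result()`), so any
outside method can be validated or ensembled alongside the built-ins.

`apply_target_mask()` intersects expression-based predictions with a
sequence-based pair list (e.g. exported TargetScan predictions or
CLIP-derived pairs): unsupported pairs drop to the ordering-specific null
score (0, or the maximal rank for `ASC_RANK`) so they can never displace
a supported pair with signal; a `drop` mode removes them outright. The
mask is applied after scoring, matching the view that the two evidence
types are computed independently and intersected.

`validate_confirmed()` counts, per miRNA, how many top-k predictions
appear in the confirmed-interaction set. `validate_perturbation()`
derives a ground truth from transfection experiments: a gene is a target
of the transfected miRNA when its absolute log2 fold-change strictly
exceeds 1.0 (a gene at exactly the threshold is excluded).
`compare_methods()` retains the miRNAs with at least one confirmed
target under *every* method, ranks the M methods per miRNA by confirmed
count (mean rank on ties) and awards `M − rank + 1` points; a method's
ranking score is its point total. The per-miRNA point formula is this
package's choice — it is Borda-consistent and monotone in the confirmed
count; the comparison literature does not pin down a unique formula.

## The synthetic-data generator

`simulate_regulation()` emulates a matched expression study so every
stage runs offline: miRNAs are iid standard Normal; a planted edge set
drives regulated mRNAs through `mRNA = Σ β·miR + ε` with β drawn from
`beta_range = c(-1.5, -0.6)` (negative only — the down-regulation
emphasis; positive edges can be admitted for stress tests), residual sd
1, at most 3 regulators per mRNA. The default dimensions (300 samples,
20 miRNAs, 500 mRNAs, 100 edges) are the package's reference study
conditions. Edges are allocated as evenly as possible across miRNAs
(5 each at the defaults): the design keeps "top-k per miRNA" evaluation
meaningful, since under uniform pair sampling some miRNAs would carry
fewer planted targets than the evaluation window and cap attainable
precision regardless of method quality. A `nonlinear_fraction` of
regulated mRNAs passes the linear predictor through a monotone cubic
link (η + η³/3, rescaled to the predictor's variance), producing
monotone-decreasing but non-linear regulation that correlation methods
underrate and MI/RDC still detect.

The generator also emits both ground-truth files: the planted edges, and
a perturbation table in which each edge responds to a simulated two-unit
over-expression (`lfc = −β·2 + N(0, 0.1)`, so edges with |β| ≥ 0.6 clear
the |LFC| > 1 threshold except for rare noise excursions) and an equal
number of non-edges drifts by `N(0, 0.3)`. What the generator does *not*
emulate: count-based (RNA-seq) noise, miRNA–miRNA correlation, batch
effects, and the heavy annotation noise of real interaction databases —
so passing recovery tests here demonstrates correctness of the machinery,
not expected field performance on real tumour data.

## Numerical choices and degenerate inputs

* Zero-variance features score 0 with a warning instead of aborting a
  whole matrix (batch semantics of a lab tool).
* Undefined or non-finite scores are stored as 0 with a warning.
* The Fisher-z test refuses to run when `n − |S| − 3 ≤ 0`, naming the
  offending level.
* Rank-deficient adjustment regressions are dropped with a warning.
* The RDC's canonical-correlation system is ridge-regularised (1e-8)
  when a block covariance is singular.
* Quantile normalisation maps each sample to the mean order-statistic
  distribution; tied values receive the mean of the quantile values the
  tie run spans, so the map is well defined and rank-preserving.
* KNN imputation (default `k_neighbors = 10`) measures sample proximity
  over the features complete everywhere and averages each missing
  feature over the nearest samples where it is observed, falling back to
  the feature median; features missing in more than half the samples are
  dropped.
* Differential expression uses an empirical-Bayes moderated t: pooled
  within-group variances are shrunk toward a scaled-inverse-chi-square
  prior fitted by method of moments on the log variances (trigamma
  inversion by bisection). When the observed variances agree more than
  sampling noise allows, the prior degrees of freedom are taken as
  infinite and the statistic reduces exactly to the ordinary pooled t.
  A Welch t-test is available as `method = "welch"`.
* Ties in `top_n` selection break by original feature order; ties at a
  top-k boundary break by mRNA name. Every tie rule in the package is
  deterministic so that repeated seeded runs are byte-identical.

## Problem sizes used in the shipped checks

The automated checks run the oracle comparisons on 200 random instances
of up to 30 samples; causal recovery on 3-node structures at n = 2000
and effect recovery at n = 5000 over 20 seeds; the end-to-end recovery
study at the reference conditions (20 miRNAs, 500 mRNAs, 100 edges,
n = 300) over 20 generator seeds; and the IDA-versus-enumeration
equivalence on learned CPDAGs of up to 6 nodes, where exhaustive DAG
enumeration is feasible. These sizes were chosen so the whole suite runs
on a single desktop core in minutes while still exercising every code
path at realistic signal-to-noise.

## Known limitations

* PC-stable with thousands of features is practical only because the
  default conditioning-set cap is 3; raising the cap on dense graphs is
  exponential.
* The plug-in MI estimator is biased upward for small n; scores are used
  only for ranking, where the bias is common to all pairs.
* The minimum-absolute-value IDA summary is conservative: an undirected
  miRNA–mRNA edge always admits the reverse orientation and hence a zero
  effect, so such pairs rank low even when the forward effect is large.
* Validation counts carry no significance calibration; they are counts
  against an incomplete ground truth, as in the original dry-lab
  methodology.
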