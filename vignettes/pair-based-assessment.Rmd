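---
title: "Pair-based assessment of protein function annotation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pair-based assessment of protein function annotation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funpairs)
```

## The problem and the design

Assessing protein function prediction methods normally requires ground-truth
annotations, which barely exist for proteins without close homologs
("orphans"). `funpairs` implements an ontology-blind alternative: instead of
asking whether a method's terms are *correct*, it asks whether the method
assigns *similar* annotations to pairs of proteins that independently appear
to share a molecular function. Because only pairwise similarity is compared,
methods predicting GO terms, EC numbers, Pfam domains, ortholog groups, or
raw embeddings can all be scored on the same footing.

The reference labels come from a structure+function gate: a pair is labeled
a **sibling** when its structural alignment score (TM-score) is at least
`tm_min = 0.7` and its Siamese-network functional similarity score (SNN) is
at least `snn_min = 0.98`, both inclusive. Everything else is **unlabeled** —
a mixture dominated by non-siblings but certainly containing unrecognized
siblings. This is a positive-versus-unlabeled test design: unlabeled pairs
are counted as negatives throughout, and every report says so. The gate is
deliberately high-precision/low-recall; the metric suite below is chosen to
be informative under exactly that regime.

## From predictions to pair similarity

Per-method inputs are tables of (protein, term, score). Scores are
normalized to an internal higher-is-better scale; E-value-like inputs are
mapped through `-log10` with raw zeros floored at a configurable cap
(default 300). A prediction-score threshold $\tau_p$ (inclusive, `>=`)
turns the table into per-protein annotation sets; proteins left with no term
are *not annotatable* at that threshold, and only pairs with both proteins
annotated are scored.

Similarity kernels, all symmetric with values in $[0,1]$:

* **Jaccard**: $S = |F_1 \cap F_2| / |F_1 \cup F_2|$.
* **IA-weighted Jaccard** (GO-style vocabularies): sets are first
  ancestor-propagated through the ontology DAG (roots removed), then
  $S = \sum_{v \in \cap} I_a(v) / \sum_{v \in \cup} I_a(v)$, where the
  information accretion $I_a(v) = -\log_2 \Pr(v \mid \mathrm{Parents}(v))$
  is estimated from a reference annotation corpus. With uniform $I_a$ this
  reduces exactly to the unweighted Jaccard.
* **Binary shared-term**: $S = 1$ if any term is shared — the rule for
  EC/Pfam/ortholog vocabularies where one common annotation counts as
  shared function. EC codes can be truncated to a hierarchy level
  (EC1/EC3) before comparison.
* **Embedding kernels**: $S_{euc} = 0.5/(0.5 + d/2)$ on the Euclidean
  distance $d$, and $S_{cos} = (e_1 \cdot e_2 + 1)/2$ on L2-normalized
  vectors.

Design notes on the open choices here. The Euclidean kernel's denominator
admits a second reading, $0.5/(0.5+\sqrt{\sum \Delta^2/2})$; we default to
$d/2$ (which satisfies $S(0)=1$ and monotone decay) and expose the
alternative via `variant = "sqrt_half"`. Cosine inputs are L2-normalized
first so the mapped value is guaranteed to land in $[0,1]$. Information
accretion uses base-2 logarithms (bits) and additive smoothing
$\alpha = 1$ by default so corpus-absent terms stay finite; $\alpha = 0$
gives the exact plug-in estimate for hand-checked corpora. Roots are removed
from propagated sets: they carry $I_a = 0$ and are shared trivially, so
keeping them would only inflate the union.

## The metric suite

With sibling pairs as positives and a similarity threshold $\tau_s$
(inclusive) calling a pair functionally identical:

* **F1max**: maximum F1 over the joint $(\tau_p, \tau_s)$ grid. The
  $\tau_p$ grid is the sorted distinct internal scores plus a $-\infty$
  sentinel; the $\tau_s$ grid is the distinct observed similarities at each
  $\tau_p$. Ties in the argmax break toward smaller $\tau_p$, then smaller
  $\tau_s$, for determinism. Precision and recall are reported at the
  optimum. Grid points whose scored pairs are all one class are skipped:
  with unlabeled pairs as negatives, a positives-only subset makes
  precision trivially 1 and the remaining statistics undefined.
* **ΔS**: the difference in mean similarity between scored sibling and
  scored unlabeled pairs, weighted by *coverage recall* — the fraction of
  all dataset siblings the method can score at $\tau_p$. The weight
  penalizes methods that simply cannot annotate the test-set siblings, and
  keeps ΔS independent of $\tau_s$; an alternative weighting by recall at
  the optimal $\tau_s$ is available (`delta_s_recall = "at_opt"`). ΔS lies
  in $[-1,1]$. **ΔSmax** is its maximum over the $\tau_p$ grid.
* **RecallmaxPPf50**: maximum recall over both thresholds subject to the
  predicted-positive fraction being strictly below 50% of the scored pairs
  ("fewer than half"), guarding against trivial all-positive calls; 0 when
  the budget is infeasible (e.g. all similarities tied).
* **PR AUC / ROC AUC**: computed at the optimal $\tau_p$, sweeping $\tau_s$
  only. ROC AUC uses the tie-aware rank (Mann-Whitney) identity —
  equivalent to trapezoids through tied blocks; PR AUC uses step-wise
  summation over descending thresholds without interpolation. The
  conventions are stated because AUC implementations differ exactly here.

**Resampling.** Because unlabeled pairs vastly outnumber siblings, every
reported metric is aggregated over balanced under-samples: all siblings are
kept and an equal number of unlabeled pairs is drawn without replacement;
the default is 100 iterations with per-iteration seeds derived as
`seed + iteration`, so each iteration is reproducible in isolation. Means
and standard deviations over iterations populate the reports, and
per-iteration samples feed the pairwise significance tests (two-sided
Wilcoxon rank-sum and Student's t, Benjamini-Hochberg adjusted within each
metric family).

**Baselines.** Two empirical references are evaluated through the same
machinery: a *random classifier* (pair scores drawn Uniform(0,1)) and a
*random annotator* (a method's scores kept fixed, sibling/unlabeled labels
permuted). On balanced data the random classifier sits at ROC AUC 0.5 and
F1max near 2/3 (the all-positive call), which is what the test suite
asserts. A binary "ideal predictor" protocol is also provided: reference
same/different labels (e.g. matching third-level EC numbers) predicted
positive directly, without any threshold sweep.

**Enrichment.** To characterize *which* pairs a method calls siblings, the
predicted positives at the optimal thresholds are binned by sequence
identity (<40, 40–60, 60–80, 80–90%), TM-score (0–0.5, 0.5–0.7, 0.7–1) and
SNN score (0–0.5, 0.5–0.98, 0.98–1), and each bin is tested against the
full pair universe with a two-sided Fisher exact test. Bins are
left-closed/right-open with the last bin closed — the printed ranges are
ambiguous at shared edges, so one convention is fixed. Glyphs follow the
usual footnote style: `+`/`-` for adjusted p in [0.001, 0.05], `++`/`--`
below 0.001; we flag on BH-adjusted p-values (family = one variable's bins
for one method) and report raw p alongside.

## The synthetic world

`generate_world()` plants the ground truth that every stage is tested
against: `n_proteins = 200` proteins in `n_clusters = 20` equal function
clusters; a toy ontology with one root and one chain of `ont_depth = 3`
terms per cluster (so clusters share no non-root ancestor); and a complete
pair table where same-cluster pairs draw TM ~ N(0.82, 0.10) and
SNN ~ N(0.985, 0.012) (clamped to $[0,1]$) while cross-cluster pairs draw
TM ~ N(0.45, 0.12), SNN ~ N(0.55, 0.18). Under the standard gate these
defaults give roughly 2–3% gate-positive pairs — the same sparse-positive
regime the assessment is designed for — with the gate's precision against
the planted clusters above 90% and its recall well below 1. Pair sequence
identities are Beta-distributed so that about 90% of sibling pairs fall
under 40% identity. Protein metadata is drawn to pass the orphan filters
(identity to reference < 30%, length ≤ 400, pLDDT and pTM > 0.9, strict as
stated).

`simulate_predictor()` degrades the truth with four dials — term dropout,
spurious-term rate, score noise, and protein coverage — and
`simulate_embeddings()` places cluster centroids at a between-cluster scale
with member vectors jittered at a within-cluster scale. All randomness
flows from one master seed through named sub-streams, so worlds, predictors
and embeddings are individually reproducible.

What the generator deliberately does *not* emulate: real sequences or
structures, correlated errors between methods, heavy-tailed score
distributions, multi-function proteins (each protein has exactly one
cluster), or ontologies with multiple parents (diamond-shaped DAGs are
exercised by dedicated ontology tests instead). Passing the synthetic suite
therefore shows the machinery is correct and well-calibrated under planted
structure — not that any particular real method will behave the same way on
real data.

## Numerical conventions and degenerate inputs

* All threshold comparisons are inclusive (`>=`); the orphan identity
  filter is strict (`< 30%`), and pLDDT/pTM filters are strict (`> 0.9`),
  matching their stated definitions.
* Pairs are canonicalized (`id1 < id2`); self-pairs and duplicate unordered
  pairs are errors.
* Empty annotation sets are never stored; the Jaccard of two empty sets is
  an error rather than a convention.
* A pair whose IA-weighted union mass is zero is excluded with a warning.
* Precision with no predicted positives is reported as 0 with an explicit
  flag; F1 is 0 when precision and recall are both 0.
* OBO parsing uses `is_a` edges (optionally `part_of`), skips obsolete
  terms, and fails loudly on cycles, naming a member.
* EC codes truncated through a missing position are incomplete and compare
  equal to nothing.

## Problem sizes

The shipped test-suite and worked examples run on worlds of 30–200 proteins
(up to ~20k pairs), 4–100 resampling iterations, and 1000-configuration
property sweeps; these sizes were chosen so the full suite exercises every
code path, including the slow joint sweeps, while remaining comfortable to
run locally. All of them scale up by changing the generator and
`n_iter` arguments only.

## Known limitations

* Unlabeled pairs are treated as negatives; all "false positive" counts are
  upper bounds, and reports carry that caveat rather than attempting any
  positive-unlabeled correction.
* ΔS compares raw score distributions, so it is comparable only between
  methods with similar similarity-score scales.
* Cross-vocabulary comparisons inherit the usual caveat that ontologies
  cover different slices of function space; the harness makes methods
  comparable, not their vocabularies equivalent.
* The per-τp sweep recomputes pair similarities at each grid point; for
  very dense score grids on large pair sets, supply a coarser `tau_p_grid`.
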