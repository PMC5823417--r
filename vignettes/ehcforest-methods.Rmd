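---
title: "Cluster-augmented forests for hepatobiliary diagnosis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-augmented forests for hepatobiliary diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehcforest)
```

## The diagnostic pipeline

`ehcforest` classifies four hepatobiliary disorders — alcoholic liver
damage, primary hepatoma, liver cirrhosis, cholelithiasis — from nine
continuous laboratory measurements. The pipeline has two stages:

1. **Hierarchical clustering** groups the training records bottom-up from a
   pairwise proximity matrix; the dendrogram is cut at `k` clusters and each
   record's cluster index is appended to the feature table as a nominal
   attribute. Held-out records are assigned to the nearest cluster centroid
   under the same distance.
2. **A random decision forest** (forest-RI) is grown on the augmented
   table: F bootstrap trees, `mtry` random candidate attributes per node,
   full depth, no pruning; averaged probabilities and plurality hard votes.

The premise is that patient cohorts have latent structure (subpopulations,
comorbidity patterns) that a small cluster label can summarize more
compactly than axis-aligned splits can rediscover, especially for weak
learners. The five variants — RF, ERF, HC-RF, HC-ERF, EHC-ERF — differ only
in the learner (exhaustive CART vs. randomized thresholds) and the
clustering distance (none, Euclidean, variance-weighted).

## The variance-weighted distance

The enhanced distance divides the Euclidean norm by a variance weight,

$$d(p, q) = v^{-1} \sqrt{\textstyle\sum_j (p_j - q_j)^2},
\qquad v = \frac{\sum_j (p_j - \bar p)^2}{n - 1},$$

where $v$ is the sample variance of a *single record's* attribute values.
Records whose panel is internally heterogeneous (e.g. one enzyme wildly out
of proportion) are pulled closer together; flat profiles are pushed apart.
Two numerical points needed decisions:

* **Asymmetry.** As written, $d$ depends only on $p$'s variance, so
  $d(p,q) \ne d(q,p)$, which no agglomerative algorithm can consume. The
  default (`symmetrization = "mean_variance"`) replaces $v$ by
  $(v(p)+v(q))/2$, preserving the intent while producing a symmetric
  proximity matrix; the literal form is kept behind
  `symmetrization = "as_printed"` for fidelity and single-record queries.
  The weight multiplies the whole norm (outside the square root), by
  structural parallel with the unweighted form.
* **Zero variance.** A constant record has $v = 0$; instead of producing an
  infinite distance or crashing, the package falls back to the plain
  Euclidean distance with a warning. Constant records occur in degenerate
  and discretized data and must not abort clustering.

The weighted distance deliberately does *not* satisfy the triangle
inequality (the package never relies on it), and no per-attribute
(column-wise) rescaling is performed: that would be a different, more
conventional statistic, and it is not what the weighted form above says.

## Clustering choices

The agglomeration keeps inter-cluster distances with Lance-Williams updates
(single = min, complete = max, average = size-weighted mean, identical to
the mean over all cross pairs). Three things the two-stage design leaves
open were fixed as follows:

* **Linkage:** average by default — robust to outliers and chaining, and the
  natural reading when no rule is specified; single and complete are
  selectable.
* **k:** default equal to the number of classes (4). The cluster feature is
  meant to mirror the diagnostic structure; `k` is the primary tuning flag.
* **Bridge to the forest:** the cluster index is appended as one nominal
  attribute — training rows get their fitted labels, test rows their
  nearest-representative assignment. This is the simplest mechanism by
  which a hierarchy can "inform" a classifier, and it keeps the two stages
  separable and testable. Test records never participate in fitting the
  clusters or their centroids.
* **Ties:** when two pairs are equally close, the pair with the smallest
  `(left_id, right_id)` merges first; equidistant cluster assignment takes
  the lowest index. Everything is deterministic given a seed.

## Forest choices

* `mtry` defaults to ⌊√N⌋ (3 for the 9-attribute panel, likewise for the
  10-column augmented table) — the standard forest-RI convention; only
  `mtry < N` is inherent to the method.
* F defaults to 100 trees; predictions stabilize well before that at this
  problem size.
* The **ERF learner** draws one uniform-random threshold per candidate
  attribute inside the node's value range and keeps the Gini-best; this is
  the canonical randomized tree and retains the bootstrap.
* **Unsplittable draws:** when an impure node's `mtry` sampled attributes
  admit no valid split, the node scans the remaining attributes before
  giving up. Without this fallback a full-depth CART tree would not be
  guaranteed pure on its own sample, a property the package promises (and
  tests) whenever no two identical records carry different labels.
* **Nominal splits** (cluster feature, discretized bins) use
  single-level-vs-rest candidates; an unseen level at prediction time routes
  to the child that held the majority of the node's training mass.
* Split ties take the lowest attribute index, then the lowest threshold;
  vote ties take the larger averaged probability, then lexicographic class
  order.

Numeric-to-nominal conversion is supported as *optional* equal-frequency
discretization (default off, 10 bins when on) applied to forest inputs
only: the distance stage is undefined on nominal codes, so clustering always
sees the original continuous values. Missing values are a parse error by
design; the pipeline defines no imputation semantics.

## The synthetic cohort

The original hospital data (536 records) is not publicly deposited, so the
package generates matched-shape data: nine positive continuous attributes
at plausible clinical magnitudes (enzymes in tens-to-hundreds of units,
MCV ≈ 92 fl, creatinine ≈ 1 mg/dl), four classes with configurable priors,
diagonal-covariance Gaussians clipped at zero. Two dials shape the
difficulty:

* `separability` (δ): class means shift along fixed Hadamard-style ±1 sign
  patterns by δ standard deviations per attribute; any two classes differ in
  exactly 4 of 9 coordinates, so separation is symmetric across class
  pairs. δ = 0 removes all signal.
* `cluster_alignment`: with this probability a record's latent cluster
  equals its class (otherwise uniform at random); cluster membership adds a
  shared offset of 0.5 δ sd along the cluster's pattern. At alignment 1 the
  latent clusters coincide with the diagnoses — the regime in which
  clustering ought to help classification; at 0 the cluster offsets are
  class-independent noise.

The default δ = 0.85 was fixed once, from the pairwise Gaussian error bound,
so that the generator's Bayes-optimal accuracy sits in the high-0.97s —
about as hard as the clinical task appears to be (measured 0.985 by
`bayes_reference_accuracy()` at seed 1, Monte-Carlo over 20 000 draws).
`bayes_reference_accuracy()` classifies fresh draws with the true
class-conditional mixture densities; it ignores the at-zero clipping, whose
per-coordinate probability is below 1% under the defaults.

What the generator does **not** emulate: within-class covariance between
biomarkers, heavy-tailed laboratory error, class-dependent missingness, or
any real pathophysiology. Passing the simulation study therefore shows the
pipeline recovers structure of this *kind* at this noise level — not that
it reproduces the clinical cohort's numbers.

## Problem sizes used in the shipped studies

The test-suite and acceptance-script studies run at the full data shape
(n = 536, 70/30 split → 375/161) with these replicate/forest sizes, chosen
to estimate means tightly while keeping each study a few minutes on one
core:

* performance recovery: 10 replicate seeds, default forests (F = 100).
* informativeness study: 20 seeds, F = 30, depth capped at 3 — stunted
  trees make the cluster feature's contribution visible; full-depth forests
  on 9 informative Gaussians are near the ceiling with or without it.
* no-signal control: 20 seeds (10 in the script), F = 15, depth 6; at δ = 0
  accuracy is insensitive to forest size.
* OOB bootstrap fraction: 1000 resamples of M = 536 against the
  (1 − 1/M)^M ≈ e⁻¹ limit.

## Known limitations

* The variance weight is a per-record scalar: attributes on large scales
  (LDH) dominate both distances; the package intentionally does not
  standardize columns, matching the method as defined. Users wanting
  scale-invariance should transform inputs upstream.
* Agglomeration is O(n²) in memory and O(n³) worst-case in time; fine for
  cohorts of hundreds, not for tens of thousands.
* Kappa can exceed or trail accuracy depending on the marginal structure;
  it is reported unclipped (with a warning when negative).
* Average-linkage merge heights need not be monotone (inversions are
  possible in principle); single and complete linkage heights are monotone
  and tested as such.
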