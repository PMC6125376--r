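---
title: "Signature discovery with mRMR and incremental feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature discovery with mRMR and incremental feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oasig)
```

# The problem

Blood transcriptome profiling offers a noninvasive readout for diseases —
such as osteoarthritis — whose affected tissue is hard to sample. A
diagnostic signature, however, must be *compact*: a classifier over a
handful of genes, not the hundreds that a differential-expression screen
returns. `oasig` implements a feature-selection route to such signatures:
mutual-information-based mRMR ranking followed by incremental feature
selection (IFS) with a cross-validated SVM.

# The model and its assumptions

## Preprocessing

Array probes mapping to the same gene are collapsed by their per-sample
arithmetic mean, and the gene-level matrix is quantile-normalized across
**all** samples jointly (cases and controls together). Joint
normalization is the common choice when the class label is the object of
study; normalizing per group would build the label into the data.
Normalization operates on the gene-level matrix, after probe collapsing.
No log-transform is applied: values are used as read, so callers feeding
raw linear-scale intensities should transform beforehand if they want
log-scale behavior.

## Discretization at mean ± SD

Mutual information is estimated on categorical data, so each gene is
reduced to three ordered levels: below mean − SD (*low*), above mean + SD
(*high*), otherwise *mid*. Conventions fixed here:

* SD is the sample standard deviation (n − 1), the natural choice for
  cohorts of tens of samples; the statistic is switchable via the
  `sd_fun` argument of `discretize()`.
* Boundary values fall in *mid*, for determinism.
* A constant gene has SD 0 and becomes all *mid* — legal, and carrying
  zero information as it should.

Discretization statistics are computed per gene over **all** samples,
before any cross-validation. The same holds for the mRMR ranking itself:
feature selection precedes the LOOCV loop, and only the classifier is
refit per fold. This mirrors the classical construction of such
pipelines, but it means held-out samples have influenced feature choice —
the reported LOOCV metrics are optimistic relative to truly external
validation, and any signature found this way needs confirmation on an
independent cohort.

## Mutual information and the mRMR objective

`mutual_information()` is the plug-in estimator
I(X;Y) = Σ p̂(a,b) log₂ [ p̂(a,b) / (p̂(a) p̂(b)) ], in bits. The base is
irrelevant to the ranking — relevance and redundancy scale together — but
reported scores are labeled. The greedy step moves the candidate
maximizing *relevance − mean redundancy* into the selected set; the first
gene's score is pure relevance (the empty-set redundancy is defined as
0). Pairwise gene–gene MI values are accumulated incrementally across
greedy steps, which is algebraically identical to naive recomputation
(and is tested against a naive reimplementation).

Ties in the greedy objective are broken by input gene order (first
column wins). Exact ties are common on discrete data — identical
contingency tables arise easily at small n — so the comparison allows a
1e-9 slack: scores within 1e-9 of the maximum are treated as tied. This
keeps the documented tie-break stable under floating-point summation
order; genuinely distinct MI differences at these sample sizes are
orders of magnitude larger.

## The classifier and its evaluation

The IFS stage feeds the **continuous**, normalized expression of the
top-k ranked genes to a C-classification SVM with a radial basis
function kernel — discretization exists only for the information-theoretic
ranking. The SVM configuration is pinned to the defaults of the reference
R implementation (`e1071::svm`): cost C = 1, γ = 1/#features, and
per-feature centering/scaling computed from the training data of each
fold. No class weights are used even though cohorts are unbalanced;
instead the Matthews correlation coefficient, which uses all four
confusion-matrix cells, is the model-selection metric. Conventions:

* MCC with a zero factor in the denominator is defined as 0.
* Sensitivity (specificity) is reported as missing when there are no
  actual positives (negatives).
* The positive class is always *case*.

Leave-one-out cross-validation refits the SVM n times, recomputing
standardization per fold; predictions are returned in sample order, and
every fold must retain both classes (each class needs ≥ 2 samples).

## Signature selection

`select_optimal()` returns the smallest k attaining the maximal MCC.
Smallest-k favors compact signatures, which is the point of the exercise;
note that on strongly separated data the curve saturates at MCC = 1
early, so the selected signature can be much smaller than the number of
truly informative genes — the selection answers "how few genes suffice",
not "how many genes carry signal".

## Overlap enrichment

`overlap_test()` evaluates a signature against a reference gene list with
the one-sided upper-tail hypergeometric probability P(X ≥ k) — the
standard enrichment convention — and the sample odds ratio
(k·neither)/(a-only · b-only) of the implied 2 × 2 table, with zero
overlap giving an odds ratio of 0 and a zero denominator giving
infinity. The universe size defaults to the number of genes in the
analyzed matrix and is overridable. With a 23- and a 27-gene set sharing
4 genes in a 25,159-gene universe these definitions give an odds ratio of
229.87 and p = 9.2e-09, as the test suite verifies against exhaustive
enumeration on small universes.

# The synthetic-cohort generator

`generate_cohort()` emulates the statistical skeleton this pipeline
assumes: a two-class cohort (defaults mirror a 106-case / 33-control
study shape) with three gene populations —

* **informative** genes, normal with a class mean shift of
  `effect_size` × `base_sd` (default δ = 3 SD units: a strong, cleanly
  recoverable signal);
* **redundant** genes, each an informative parent plus independent
  N(0, `redundancy_noise_sd`) noise (default 0.2, giving parent–copy
  correlations above 0.95);
* **null** genes, identically distributed in both classes (default 200,
  so planted signal is a small minority as in real transcriptomes).

The baseline (`base_mean` 8, `base_sd` 1) sits on the log2-intensity
scale typical of normalized bead-array data. Draws use one pseudo-random
stream ordered genes-then-samples, so enlarging the null background does
not reshuffle previously generated genes, and the caller's RNG state is
left untouched. Identical spec + seed is bit-identical.

What the generator deliberately does **not** emulate: probe-level
bead-array noise, batch effects, skewed or heavy-tailed intensity
distributions, and realistic co-expression networks (redundancy here is
pairwise parent–copy only). Passing tests therefore demonstrate the
pipeline's correctness and its behavior under idealized planted signal —
not its performance on real cohorts, where correlated backgrounds and
weaker effects make both ranking and signature size harder.

One identifiability note: with noise SD an order of magnitude below the
biological SD, a redundant copy carries essentially the same label
information as its parent, and at n ≈ 60 the sampling fluctuation of the
plug-in MI estimate exceeds the copy's expected information loss. Which
member of a parent–copy pair ranks first is therefore effectively
arbitrary; what the method does guarantee — and what the tests assert —
is that the pair never occupies adjacent top ranks (the second member is
crushed by the redundancy penalty) and that every planted signal cluster
is represented at the top of the list.

# Problem sizes and defaults

* `top_n` defaults to 300 ranked genes, the conventional search space for
  IFS over mRMR lists; `K` defaults to the full ranking length.
* The packaged validation experiments use desk-scale cohorts — 30 + 30
  samples, 5 informative genes with one redundant copy each, 200 nulls,
  `top_n = K = 30` — chosen so the full five-seed pipeline sweep completes
  in well under a minute while leaving the peak of the IFS curve far from
  the search boundary.
* LOOCV cost grows as n × K SVM fits; for large cohorts users should cap
  `K` rather than subsample the cohort.

# Known limitations

* Feature selection outside the CV loop (see above): reported metrics are
  selection-biased; treat them as internal consistency measures.
* The plug-in MI estimator is biased upward at small n; since all genes
  share the same n the *ranking* is largely unaffected, but the absolute
  bit-values should not be compared across cohorts of different size.
* Only the MID (difference) form of mRMR is implemented, not the MIQ
  quotient variant.
* The hypergeometric test assumes both gene lists are drawn from the same
  well-defined universe; with case-normalized exact ID matching,
  identifier drift (aliases, retired symbols) silently shrinks overlaps.
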