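---
title: "Tissue-specific expression calling and genome-wide tissue prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-specific expression calling and genome-wide tissue prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissueome)
```

This vignette is the package's own account of the models it implements, the
choices made where the design was genuinely open, and what the synthetic-data
tests do and do not establish about real data.

## The problem

Bulk RNA-seq of isolated tissues from a small animal (the motivating setting
is the four major somatic tissues of the adult nematode — neurons, muscle,
hypodermis, intestine — profiled with replicate libraries) supports two kinds
of analysis:

1. **Rule-based calling**: which genes are *expressed* in each tissue, which
   are *tissue-enriched* (much higher in one tissue than the average of the
   rest), and which are *tissue-unique* (higher than every other tissue
   separately)?
2. **Genome-wide prediction**: most public expression data comes from whole
   animals, not isolated tissues, but tissue-specific signal leaves traces in
   whole-animal profiles. A per-tissue classifier trained on a large
   whole-animal compendium, with curated anatomy annotations as labels, can
   predict tissue-specific expression for every gene — including genes and
   tissues never profiled directly.

The package implements both, plus the supporting machinery: anatomy-ontology
propagation and hierarchy-aware gold standards, per-dataset standard-normal
compendium assembly, precision-recall evaluation, and hypergeometric overlap
statistics for cross-species tissue comparison.

## Calling rules

All `log(rpkm)` thresholds are interpreted as `log2(rpkm + 1)`. The base and
pseudocount are configurable in every calling function; log2 is the norm in
transcriptomics and the +1 pseudocount handles zeros. Strictness follows the
printed rules exactly: expression and fold-change cuts are strict (`>`), the
FDR cut is non-strict (`<=`).

* **Detection**: a gene is kept when its CPM (count per million mapped reads)
  is at least 1 in at least 5 samples.
* **Expressed** (per tissue): mean replicate `log2(rpkm+1)` > 2 *and* every
  replicate > 1. The second clause guards against a single hot replicate.
* **Enriched**: mean log-RPKM in the tissue > 5, BH-adjusted q ≤ 0.05 and
  log2 fold-change > 2 against the *average of the other tissues*. The
  contrast average is the mean of the other tissues' per-tissue means, not of
  their pooled samples, so unbalanced replicate counts do not bias it. The
  high-expression clause uses the candidate tissue's replicates only.
* **Unique**: the same thresholds applied against *each* other tissue
  separately (a universal quantifier, so three comparisons with four
  tissues).

Two containment conventions are enforced structurally rather than assumed:
enriched calls are intersected with the expressed set, and unique calls with
the enriched set. The thresholds nearly imply this chain on their own (a gene
with mean log-RPKM above 5 virtually always passes the expressed rule), but
the calling table's invariant — unique ⊆ enriched ⊆ expressed — should never
depend on noise, so it holds by construction.

The differential statistic is a Welch two-sample t-test on `log2(rpkm+1)`,
with Benjamini–Hochberg adjustment per contrast. A negative-binomial GLM
engine (edgeR-style) is deliberately *not* reimplemented: the scientific
content of the calling stage is the thresholding rules, and the Welch test on
log scale is a calibrated, assumption-light substitute (its type-I error on
null data is checked in the test suite, and sits near the nominal 0.05).
Degenerate inputs follow a documented convention: when both groups have zero
variance, p = 1 for equal means and p = 0 otherwise.

For pathway-target Venn partitioning the membership rule is the simpler
single-clause "mean log-RPKM > 2" (`expressed_by_mean()`), matching how
pathway-target tissue overlap is usually summarized; the partition assigns
each gene to the exact combination of tissues in which it is expressed, with
genes detected nowhere reported separately rather than silently dropped.

## Gold standards from an anatomy ontology

Annotations of genes to anatomy terms (only those from small-scale
experiments — single-gene reporters, in situs — when the evidence filter is
on) are propagated up the ontology through `is_a` *and* `part_of` edges; the
relation whitelist is configurable since curated anatomy DAGs mix both.
Terms are retained as modeling targets when they have strictly more than 50
directly annotated genes and strictly more than 150 after propagation (both
configurable; see below for why the demonstration scales these down).

System-level "slim" terms partition the anatomy coarsely (nervous system,
muscular system, ...). A term counts as its own ancestor for slim assignment,
so slim terms map to themselves, and a term may belong to several systems.
Labels for tissue t are then:

* **positive** — genes annotated (directly or through propagation) to t;
* **negative** — genes annotated somewhere, but to no term sharing any
  system with t (and not to t);
* **excluded** — genes annotated only within t's system(s) but not to t,
  and unannotated genes.

The exclusion rule is an interpretive choice: annotations are incomplete, so
a gene known only in the sister tissue of the same system is too likely to
also be expressed in t to serve as a trustworthy negative. The same
reasoning motivates modeling annotation noise in the generator as false
positives only: curated annotation sets are assumed incomplete but mostly
correct. The per-tissue *prior* — |positives| / (|positives| + |negatives|) —
is the expected precision of a random ranking, the natural baseline for the
precision-at-recall results below.

## Compendium assembly

Each dataset is processed independently: duplicate samples collapsed by
per-gene means, then every gene normalized *within the dataset* to the
standard normal distribution. The default is a rank-based inverse normal
transform — rank r of n values maps to Φ⁻¹((r − 0.5)/n), ties receiving
average ranks — because it produces standard-normal marginals regardless of
the platform's scale (microarray intensities and RNA-seq abundances mix in a
real compendium); a z-score variant is available as the cheaper alternative.
Normalization is per *gene* rather than per sample because the downstream
classifier's feature vector for a gene is its profile across samples;
per-gene normalization makes those features comparable across datasets. This
direction is not forced by the problem statement, so it is switchable.

Constant genes are set to 0 (their sd is undefined), and missing values are
imputed as 0 *after* normalization — zero is the neutral value on the
standard-normal scale, consistent with the zero-fill of genes entirely
absent from a dataset at assembly time. The assembled compendium is dense,
carries a measured/zero-filled provenance flag per cell, and contains no
non-finite values (a hard assertion).

## Per-tissue linear SVMs

For each tissue, a linear soft-margin SVM is trained on the compendium with
the gold-standard labels:

$$\min_{w,b,\xi}\ \tfrac12 w^\top w + c\sum_i \xi_i
\quad\text{s.t.}\quad y_i(w\cdot x_i - b) \ge 1 - \xi_i,\ \ \xi_i \ge 0,$$

where the feature vector $x_i$ of gene *i* is its row of the compendium and
the decision value of any gene g is $w\cdot x_g - b$ (the offset is
*subtracted*; the package keeps this sign convention everywhere). There is no
class weighting — the objective has a single c — and class imbalance is
handled by the evaluation metric instead.

The solver is a maximal-violating-pair SMO scheme on the dual: analytic
two-variable updates with LIBSVM-style working-set selection, run to a KKT
violation below 1e-8 by default. Correctness is defined behaviorally, not by
solver identity: the test suite checks decision values against an
independent quadratic-programming solution of the same primal (tolerance
1e-4), primal feasibility and slack consistency at every solution, duality-gap
closure, objective monotonicity in c, and invariance to example duplication
at rescaled cost.

**Model selection.** The regularization constant is chosen from
{0.01, 0.1, 1, 10} (the grid is a package default; a finer grid costs
proportionally more) by 5-fold cross-validation maximizing *precision at 10%
recall*: genes are ranked by decision value and precision is read at the
first threshold step whose recall reaches 0.10, with no interpolation and
tied scores entering together. Folds are stratified by class so the metric is
defined in every fold; ties between costs resolve to the smaller cost. Every
labeled gene receives exactly one held-out score, from the fold that excluded
it — a bookkeeping invariant the tests verify by refitting without the fold.

**Scores.** After refitting on all labeled genes at the selected cost, every
compendium gene is scored, and each tissue's genome-wide score vector is
z-transformed (mean 0, sd 1) so scores are comparable across tissues. The
transform is over *all* genes, not labeled genes only: cross-tissue
comparisons are exactly the place where unlabeled genes matter. Sample
contributions are ranked by signed weight (largest first, ties broken by
sample id): for a linear model a strongly positive weight marks a sample
whose high values vote for tissue membership, which is the sense in which
isolated-tissue samples should dominate their own tissue's model.

## The synthetic data, and what it can show

The generators produce data with the statistical structure the pipeline
assumes, plus full ground truth. They define fixed study conditions — they
are not tuned per experiment.

* **Tissue RNA-seq** (`simulate_tissue_rnaseq()`): negative-binomial counts
  (variance μ + φμ², the standard RNA-seq noise model) around tissue means
  planted in log2-RPKM space: per-gene baselines N(4, 1), a +4 log2 effect in
  the target tissue for enriched genes, background genes near zero. Gene
  lengths are log-normal with median 1 kb so RPKM and CPM genuinely differ.
  Enriched-but-not-unique genes carry half the effect in one other tissue, so
  the rest-average rule fires while the every-other-tissue rule does not.
  Default: 4 tissues × 6 replicates, 2,000 genes.
* **Anatomy** (`simulate_anatomy()`): 4 systems × 2 tissues with two
  cell-type children per tissue (so propagation is genuinely exercised),
  `is_a` and `part_of` edges mixed, 40% of true (gene, tissue) memberships
  annotated — at the tissue term or a cell-type descendant — plus 3%
  spurious annotations (false positives only) and a small high-throughput
  slice for the evidence filter.
* **Compendium** (`simulate_compendium()`): each sample is a Dirichlet
  (concentration 0.15) convex mixture of gene × tissue signatures, times a
  per-dataset log-normal scale factor, plus Gaussian noise (sd 0.4); each of
  12 datasets measures a random 85% of the 2,000-gene universe and
  contributes 20–30 samples (~300 total). The simulation lives on a log-like
  abundance scale rather than counts because a real compendium mixes
  platforms and is rank-normalized per dataset anyway. Signatures carry 200
  ubiquitous and 100 tissue-specific genes per tissue over 8 tissues.

The demonstration study retains tissues at >20 direct / >40 propagated
annotations: the retention thresholds scale with annotation volume, and the
synthetic world has on the order of 2,000 annotations where a real curated
corpus has over a hundred thousand. The 50/150 defaults remain on
`select_tissues()`.

Under these conditions the pipeline's end-to-end behavior is checked in the
test suite and recomputed by `scripts/acceptance.R`: median held-out
precision at 10% recall across the 8 tissue models ≥ 0.9 (observed ≈ 0.97–1.0
across seeds), each tissue's truth-enriched gene set scoring highest in its
own prediction column for at least 7 of 8 tissues, zero containment
violations across 20 seeded calling runs, Welch type-I error within
[0.03, 0.07], and a null enriched-call rate indistinguishable from zero.

**What this does not show.** The mixture model is an idealization: no
quantitative description of real whole-animal signal mixing informs its
parameters, and real compendia add platform-specific distortions, batch
structure beyond a scalar dataset effect, and annotation biases that the
generator does not emulate. Passing these tests demonstrates that the
machinery is correct and that the method recovers planted structure under
its own assumptions — not that a particular precision will be achieved on
real data. Headline numbers from real studies (tens of thousands of curated
annotations, thousands of samples, 76 tissue models) are not reproducible at
this scale by design.

## Numerical choices and degenerate inputs

* Welch zero-variance convention: p = 1 (equal means) / p = 0 (unequal).
* BH adjustment delegates to `stats::p.adjust(method = "BH")`; an
  independent textbook step-up implementation serves as the test oracle.
* Hypergeometric overlap uses the inclusive upper tail P(X ≥ k); the
  cross-species overlap matrix applies BH across the *flattened* matrix
  (shape-invariant) and masks cells with q ≥ 0.05.
* Ortholog mapping is many-to-many; a worm set maps to the deduplicated
  union of human partners, and an empty mapped set yields k = 0, p = 1
  rather than an error.
* Rank-inverse-normal of a single value is Φ⁻¹(0.5) = 0; constant genes and
  post-normalization missing values are 0.
* SMO: tolerance 1e-8 on the maximal KKT violation, iteration cap
  max(20000, 500 n) with a warning if reached, offset averaged over free
  support vectors (midpoint of the violation interval when none are free).
* One global seed drives everything; each stage derives its own 32-bit seed
  from (seed, stage name), so any stage can be reproduced in isolation.

## Known limitations

* The Welch substitute will be less powerful than a negative-binomial GLM at
  very low counts; the calling thresholds dominate in practice, but counts
  near the detection limit are better served by a dedicated DE engine.
* The ontology parser supports the minimal OBO subset it needs (`id`,
  `name`, `is_a`, `relationship`, `is_obsolete`); exotic OBO constructs are
  ignored with a warning at most.
* Gold-standard negatives inherit any systematic gaps in the annotation
  corpus; the same-system exclusion rule mitigates, but cannot remove,
  label noise from under-annotation.
* The SVM stage is linear by construction; no kernels, no probability
  calibration. Gene-gene similarity search over prediction profiles is
  provided as cosine similarity on normalized score rows, nothing more.
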