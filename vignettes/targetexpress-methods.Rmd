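---
title: "Context-specific miRNA target refinement: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-specific miRNA target refinement: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetexpress)
```

## The problem

Sequence-based miRNA target predictors (TargetScan, microT-CDS, MIRZA)
scan the whole transcriptome and therefore emit one target list per
miRNA, independent of cell type. But a miRNA cannot repress a transcript
that is not expressed in the cell at hand, and among expressed targets
the more abundant ones tend to respond more strongly to a perturbation.
This package refines an existing target list for one cellular context by
combining six sequence-based scores with a single expression profile in
a supervised model, so that the same miRNA yields different — and more
functionally coherent — target sets in different tissues.

## The model

Each candidate transcript is described by seven features: TargetScan
Total Context+ score (more negative = stronger predicted repression) and
P~CT~, microT-CDS miTG, the three MIRZA per-transcript aggregates
(canonical, target frequency, non-canonical), and the expression value
of the transcript in the context of interest.

**Rank + min-max scaling.** Within each matrix every feature column is
replaced by its average-tie ranks and affinely mapped to $[-1, +1]$.
Ranking makes the model invariant to any strictly increasing transform
of the inputs, which is what allows microarray intensities, RPKM or
qPCR values to be used interchangeably as the expression feature.
Missing scores map to the min-max centre 0, a neutral value, instead of
discarding the transcript — most transcripts are missing at least one
method's score. A constant column also maps to 0 rather than erroring,
since a small evaluation profile can legitimately be flat. Scaling is
per-matrix: no training-time minima/maxima are carried over, so a new
context's profile never needs to share units with the training data.

**Orientation.** Before ranking, each feature is signed so that larger
means stronger predicted targeting; concretely Total Context+ is negated
and everything else used as-is. The original description does not state
the orientation, so `build_matrix()` exposes it (`default_orientation()`)
for users who disagree.

**Training labels.** Labels come from miRNA-perturbation experiments
analysed with a standard differential-expression pipeline. True Targets
(TT) are predicted targets significantly repressed
($\log_2\mathrm{FC} < 0$, $\mathrm{FDR} < 0.1$); False Targets (FT) are
predicted targets clearly unchanged ($\mathrm{FDR} > 0.2$, direction
blind); everything in between is unlabeled and excluded from training,
as are predicted targets the experiment never measured. All
inequalities are strict. A second, top-$k$ mode (the $k=250$ most
down-regulated with $t<0$ vs the $k$ with $|t|<1$ closest to zero) is
used when comparing platforms of very different power; because the two
top-250 definitions can overlap, FT candidates exclude transcripts
already labeled TT so the label sets always partition the pool, and
ties at the $k$-th value break lexicographically on transcript id.

**Class-weighted RBF-SVM members.** One C-classification SVM with
radial kernel is trained per eligible experiment, with $\gamma = 1/7$
(one over the number of features — kept at $1/7$ even for single-method
variants, which zero out columns rather than remove them), cost 1, and
no internal rescaling. Perturbation data are heavily imbalanced (many
more FT than TT), so per-class penalties follow the inverse-frequency
scheme

$$C_1 = \frac{1/n_1}{1/n_1 + 1/n_2}, \qquad
  C_2 = \frac{1/n_2}{1/n_1 + 1/n_2},$$

with $n_1$ TT and $n_2$ FT, giving $C_1 + C_2 = 1$ and
$C_1 n_1 = C_2 n_2$: each class contributes equal total penalty mass.
An experiment is eligible when its seed-enrichment QC gate passes and it
yields at least 20 TT (inclusive boundary).

**Consensus.** A new context is scored by summing the signed continuous
decision values of all members; positive consensus = predicted
functional target. The original text's "sum the predictions" is read as
decision values rather than hard votes because the published score
distribution is continuous; a vote mode
(`svm_config(aggregate = "vote")`) is provided for comparison.

## Evaluation machinery

`roc_auc()` uses the Mann–Whitney convention (tied pairs count 1/2) and
reports an operating point minimizing the Euclidean distance to
(sensitivity = 1, specificity = 1), ties resolved toward higher
sensitivity. A 95% CI is computed by DeLong's method. The
expression-intersect baseline keeps targets whose expression strictly
exceeds the median of the whole profile (even-length median = midpoint
of the central order statistics).

`loocv()` implements experiment-level leave-one-out: hold out one
experiment, train members on the rest, evaluate every method on the
held-out labeled transcripts; SVM variants are re-fitted per fold so no
held-out row ever enters training. Methods are compared with a paired
one-sided Wilcoxon signed-rank test — the source text names a "Rank Sum
paired" test, which conflates the two Wilcoxon tests; the paired design
dictates signed-rank. The exact null distribution of the positive-rank
sum is computed by convolution for up to 25 non-zero pairs (handling
tied ranks exactly, which `stats::wilcox.test` does not); larger samples
use the tie-corrected normal approximation with continuity correction.

## Enrichment

The QC gate is a deliberately minimal re-implementation of the
seed-enrichment idea: word presence is binary per 3'UTR (so the null at
each leading-bin cutoff is exactly hypergeometric), 20 evenly spaced
cutoffs span the ranking, and the gate passes when the smallest
over-representation p, Bonferroni-corrected across cutoffs, falls below
`alpha` (default 0.001; the original inclusion decision was a visual
call, so the explicit level is this package's own). It does not model
per-occurrence counts or composition bias; any sound gate preserves the
pipeline's semantics because the gate only decides experiment inclusion.
Rankings should put the genes expected to respond first — with the
treatment-is-higher-miRNA convention used throughout, that is ascending
t (most repressed first). Because the corrected p caps at 1, `alpha >= 1`
explicitly disables the gate.

`gene_set_test()` is the rank-based (Wilcoxon) gene-set test on
prediction scores within a universe of all predicted targets; the exact
null is enumerated when the universe is small (and matches exhaustive
permutation in the tests), otherwise the tie-corrected normal
approximation — numerically identical to limma's rank-only
`geneSetTest` — is used. GO-style term lists are filtered to sizes
strictly between 5 and 100 after universe intersection.

## The synthetic-data generator

`simulate_experiment()` produces data with exactly the structure the
method assumes, so training, cross-validation, QC and enrichment are
testable end to end:

* expression is log10-normal (mean 1.5, SD 1 decade), so the bulk spans
  roughly four orders of magnitude, as in real transcriptomes;
* the six prediction scores share one latent per-transcript targeting
  affinity plus independent method noise (SD 0.8), giving realistic
  inter-method correlation, and are mapped onto each method's scale and
  orientation; per-method missingness (25–45%) mimics the partial
  overlap of real prediction databases, with every record keeping at
  least one score;
* a transcript is truly repressed with probability
  $\mathrm{logit}^{-1}(\alpha + 1.2\,z_{\text{score}} +
  1.2\,z_{\text{expr}})$, with $\alpha$ set from a 15% baseline — the
  two weights are the `effect_score` and `effect_expr` knobs;
* the differential-expression table models a well-powered perturbation
  assay: 6 replicates per group (10 residual df), per-sample log2 SD
  0.35, repressed transcripts centred at $-0.8$ to $-1.4$ with the
  magnitude growing with abundance when `effect_expr > 0`, p-values
  from the t distribution and Benjamini–Hochberg FDR. These choices
  give a few hundred TT per 2000 transcripts, comparable to real
  perturbation experiments, and were fixed once when the generator was
  designed;
* UTRs are uniform random sequence with the miRNA's 7mer-m8 seed match
  planted in truly repressed transcripts, tying the QC gate to ground
  truth.

With `effect_expr = 0` expression carries no information (neither in
the repression probability nor in the repression magnitude), which is
the negative control: the model should then match, not beat, the raw
score.

What the generator does **not** emulate: probe-level microarray
artefacts, batch effects, correlated gene-gene expression structure,
secondary (indirect) transcriptional effects of the perturbation, or
real UTR base composition. Passing tests therefore demonstrate that the
pipeline recovers the planted signal under its own assumptions, not
that it attains any particular AUC on real perturbation data.

## Numerical choices and degenerate inputs

* UTR windowing emits 50-nt windows every 25 nt until a window reaches
  the sequence end; a final fragment shorter than the step merges into
  the preceding window (possible only when window < 2·step), and
  sequences shorter than one window yield a single full-length window.
* MIRZA site aggregation uses the natural logarithm; the base is
  exposed because rank scaling erases it downstream.
* All label/size boundaries are strict, matching their definitions;
  eligibility's ">= 20 TT" is inclusive.
* Determinism: SVM fitting on fixed data is deterministic, the
  generator is fully seeded, and score files are written with six
  significant digits, so a fixed-seed simulate → train → predict run is
  byte-identical across repetitions (this is tested).
* Duplicate expression ids collapse by max (the probe-to-transcript
  convention) unless told otherwise; transcript ids are opaque strings
  and never translated.

## Problem sizes used by the test suite

The end-to-end recovery checks run leave-one-out cross-validation on 5
simulated experiments of 2000 transcripts each, over 20 generator
seeds, for both the informative-expression and flat-expression
conditions; calibration checks use 2000 null simulations. These sizes
give stable medians (seed-to-seed spread of the AUC gain is ~0.01)
while keeping the whole suite around a few minutes.

## Known limitations

* The QC gate is a simplification of full seed-landscape analysis and
  its default level is a package choice, not a reproduction of the
  original visual inclusion calls.
* Feature orientation for Total Context+ is an explicit assumption
  (exposed as configuration).
* Consensus scores are raw decision-value sums: they are comparable
  within one ensemble and context but are not calibrated probabilities.
* Real-data benchmarks (GEO/ArrayExpress perturbation series) are out
  of scope; the package consumes, and is validated on, the file formats
  those pipelines produce.
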