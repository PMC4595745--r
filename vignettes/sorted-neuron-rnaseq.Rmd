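---
title: "Differential expression for pooled sorted-neuron RNA-seq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential expression for pooled sorted-neuron RNA-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sortseq)
```

## The experimental setting

`sortseq` analyzes bulk RNA-seq of small pools of manually sorted cells —
tens to a few hundred neurons per tube, one tube per animal — as used to
profile hypothalamic AGRP and POMC neurons from fed and 24-hour food-deprived
(FD) mice. The design is two cell types crossed with two conditions, with 5–6
biological replicates per group. Three comparisons are of interest: FD versus
fed within each cell type, and AGRP versus POMC at the fed baseline.

Working from gene-level read counts (alignment and counting are upstream of
this package), the pipeline covers quantification, filtering, normalization,
precision-weighted moderated differential expression with threshold-based DEG
calls, a label-permutation estimate of the empirical false discovery rate,
ERCC spike-in calibration of sensitivity and absolute scale, hypergeometric
gene-set over-representation, and sample/gene structure analysis (MDS,
clustering, purity QC, and a spliced-isoform fraction test).

## Quantification and filtering

For gene $g$ with summed exon length $\ell_g$ (kb) in sample $j$ with library
size $N_j$ (column sum over all rows, spike-ins included):

$$\mathrm{CPM}_{gj} = \frac{c_{gj}}{N_j}\times 10^6, \qquad
  \mathrm{FPKM}_{gj} = \frac{c_{gj}}{\ell_g\, (N_j/10^6)}, \qquad
  \mathrm{TPM}_{gj} = \frac{\mathrm{FPKM}_{gj}}{\sum_g \mathrm{FPKM}_{gj}}\times 10^6.$$

Genes enter the model when CPM exceeds 1 in at least three samples; both
thresholds are strict inequalities, read literally from their definitions,
and are exposed as parameters. The TPM denominator includes the spike-in rows
by default, because the calibration below needs spike TPM on the same scale
as gene TPM; `compute_tpm(..., exclude_spikes = TRUE)` restricts the
denominator to genes when spikes should not dilute the gene scale. Group-mean
CPM, used by the DEG abundance criterion and the MDS gene filter, is computed
from raw (not TMM-rescaled) library sizes: the filter describes observed
abundance, not model-adjusted abundance.

## Normalization and the DE model

**TMM.** Composition bias is corrected by trimmed-mean-of-M-values factors:
against the reference sample (the one whose upper-quartile CPM is closest to
the mean upper-quartile), gene-wise log2 ratios $M$ of depth-normalized
proportions are doubly trimmed — 30% from each tail of $M$, 5% from each tail
of the average abundance $A$ — and averaged with inverse asymptotic-variance
weights. Factors are rescaled to product 1.

**Precision weights.** Counts are transformed to
$y_{gj} = \log_2\!\big((c_{gj}+0.5)\,/\,(\hat N_j+1)\times 10^6\big)$ with
$\hat N_j$ the TMM-scaled library size. After a per-gene linear fit on the
group-means design (one indicator per cell type × condition, no intercept),
the square-root residual standard deviation is smoothed against the mean
log2 count by lowess (span 0.5) and each observation receives weight
$s^{-4}$, with the trend clamped at its range ends. These constants are the
canonical published defaults for this transform and are all arguments.

**Moderated t.** Each gene is refit by weighted least squares; residual
variances $s_g^2$ on $d_g$ degrees of freedom are shrunk toward a prior,
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0+d_g)$, with $(d_0, s_0^2)$
estimated by moment matching on $\log s_g^2$ via trigamma inversion (prior
made infinite when the moment equation has no positive root). Contrast
coefficients are the reported log2 fold-changes; $t$ statistics use
$d_0+d_g$ degrees of freedom; q-values are Benjamini–Hochberg step-up
adjusted within each contrast. Forcing `d0 = 0` recovers the ordinary
weighted-LS t exactly, and `d0 = Inf` replaces every variance by $s_0^2$;
both limits are tested.

A gene is called DEG when q < 0.05, |log2 fc| > 1, and group-mean CPM > 20
in at least one group. All three thresholds are arguments of `call_deg()`
and `run_de()`.

Genes that are all-zero across the filtered samples are excluded before
fitting (their residual variance is undefined); the CPM filter already
guarantees this under default thresholds.

## Permutation-based empirical FDR

`run_permutation_study()` rearranges the multiset of (cell type, condition)
labels uniformly at random across samples — group sizes are preserved
exactly, sorted-cell counts stay with their tubes, and the identity labeling
is not excluded (its probability is negligible at 21 samples) — and re-runs
the full pipeline, by default including TMM and the variance trend
(`refit = TRUE`; the cheaper weight-reusing variant is a switch). The
empirical FDR per contrast is $100 \times$ mean permuted DEG count divided
by the observed count, undefined (flagged `NA`) when nothing was observed.
Re-running everything inside each permutation is the conservative reading of
label permutation and is the default.

## ERCC spike-in calibration

**Sensitivity.** Detection is presence/absence at a count threshold
(default 1 read). Under Poisson capture with rate proportional to
copies × kb — the model the generator implements, and a standard abstraction
for dilution-ladder data — the detection probability is exactly
$1-\exp(-\lambda x)$, i.e. complementary log-log in $\log x$. The package
therefore fits the pooled binomial regression with a cloglog link by default
and reports the abundance $x_{50}$ at which the fitted curve crosses 0.5,
with a profile-likelihood interval. We verified numerically that fitting a
symmetric logistic to data of this form biases $x_{50}$ downward by roughly
20% (the logistic cannot match the cloglog's asymmetric approach to 1), so
the logit link is available as an option but is not the default. Perfectly
separated data (all levels detected, none detected, or a clean split) yield
a censored result bounded by the separating interval rather than an error.

**Absolute scale.** Per sample, ordinary least squares of log10 copies on
log10 TPM over detected spikes gives the copies corresponding to 1 TPM
($10^{\text{intercept}}$), divided by the number of sorted cells in the
tube; the package reports the mean ± sd across samples. By default the fit
uses only spikes detected in *every* sample: spikes near the detection limit
enter the data conditionally on being seen, which inflates their TPM and
drags the intercept down by ~25% in simulation, while the restriction keeps
several decades of ladder and removes the conditioning bias. Samples with
fewer than 6 detected spikes or less than 2 decades of ladder span are
excluded with a warning.

## Enrichment and structure analysis

Gene-set over-representation uses the upper-tail hypergeometric probability
$P(X \ge k)$ computed in log space (stable for universes of tens of
thousands of genes), one-sided as is conventional for over-representation;
sets are intersected with the universe — by default the expression-filtered
genes that entered the fit — before counting. Venn region counts for two or
three DEG lists come from direct membership tabulation.

Sample similarity uses the pseudo-distance $1-r$ (Pearson) computed on
$\log_2(\mathrm{TPM}+1)$ over robustly expressed genes (group-mean CPM > 20
in at least one group), followed by classical (Torgerson) multidimensional
scaling. The expression scale for the correlation is not dictated by the
definition of the distance; the log scale is chosen because the distance is
otherwise dominated by the handful of most abundant transcripts, and it is
an argument. Classical rather than non-metric MDS keeps the embedding
deterministic and testable. Gene clustering standardizes each gene across
samples, correlates genes, and applies average-linkage agglomeration on
$1-r$; linkage is an argument. Marker-based purity is summarized as
pseudocount-protected fold-depletion,
$(\text{reference}+1)/(\text{sample mean}+1)$, per marker and per marker
set. The spliced-isoform fraction test compares per-sample
spliced/(spliced+unspliced) fractions between conditions with an unpaired
one-tailed t-test, pooled variance by default (the plain reading of the
classical unpaired test; Welch by flag), and also accepts rounded summary
statistics (means, SEMs, n) so printed group summaries can be checked
directly.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure the analysis
assumes, with recorded ground truth:

* **Design**: AGRP/POMC × fed/FD with n = 5, 6, 5, 5 — the study's group
  sizes. Library sizes are log-normal with mean 1e6 reads and CV 0.3; 1e6 is
  a desk-scale depth chosen so that a full dataset simulates in well under a
  second, and depth is a parameter.
* **Counts**: gene $g$ in sample $j$ is negative binomial with mean
  $L_j\,p_{gj}$ and gene-wise dispersion $\varphi_g$; baseline relative
  abundances are log-normal (sdlog 2, giving the heavy-tailed abundance
  distribution typical of transcriptomes), and dispersions are log-normal
  around 0.05 (sdlog 0.5). The dispersion scale was set so that the
  pipeline's significance power for a twofold change at n = 5 vs 6 is
  approximately 80% for well-expressed genes — the power regime reported for
  this design — and we verified the realized power is ~0.80.
* **Programmed DEG**: per-contrast fractions default to 5% (AGRP FD/fed),
  0.3% (POMC FD/fed) and 4.2% (AGRP/POMC at fed) — the asymmetry observed
  between the cell types — with true |log2 fc| uniform on [1, 3] and random
  sign. Cell-type effects are applied to both conditions of the cell type,
  so they cancel in the within-cell-type contrasts.
* **Spike-ins**: a 92-spike, 23-level twofold dilution ladder (4 spikes per
  level, lengths uniform on 0.25–2 kb) captured as Poisson with rate
  `capture_rate` per copy × kb scaled by the sample's depth factor. The
  default rate ln(2)/22 places the true 50% detection point at 22 copies ×
  kb. The true copies-per-cell at 1 TPM follows in closed form from the
  expected-count composition and is stored in the truth object.
* **Isoforms**: one robustly expressed parent gene is split binomially into
  spliced/unspliced rows with condition-dependent spliced fractions (7.4%
  fed, 15.6% FD) — the children always sum exactly to the parent.
* **Contamination**: 16 non-neuronal marker genes (astrocyte,
  oligodendrocyte, microglia, endothelial panels) are present at 0.1% of
  their reference cell-type abundance, supporting the purity report.

What the generator does **not** model: sample–sample correlation, batch or
lane effects beyond library size, length-dependent capture bias within
genes, isoform families beyond one pair, UMI structure, or read-level error.
Passing tests therefore demonstrate that the implementation recovers the
parameters of this generative model at study scale — not that the model
captures every feature of real sorted-neuron data.

`generate_null_dataset()` zeroes every programmed effect (DEG fractions and
the splicing difference) while keeping depth variation, supporting type-I
error and permutation-FDR checks. One master seed drives per-stage
substreams, so datasets are bit-reproducible and stages are isolated.

## Numerical and testing choices

Test and acceptance runs use 1,000–2,000 genes, 200 permutations and 20–50
replicates/seeds — sizes chosen so the complete suite runs in a few minutes
on a laptop while keeping Monte-Carlo error well inside the asserted bands.
The moderated-t engine, TMM factors and precision weights are each verified
against independent brute-force implementations and against the established
Bioconductor implementations of the same algorithms; the hypergeometric
tail is verified against exhaustive enumeration for all small universes.

Two calibration checks deserve a note on expected behavior. First, under a
complete null the Benjamini–Hochberg step-up makes at least one rejection
per contrast with probability close to the nominal 5% (a Simes-type
property); across three contrasts, a small fraction of null datasets will
therefore always carry one or two DEG even for a perfectly calibrated
engine — we confirmed count-for-count agreement with the reference
implementation on exactly those datasets. Second, the per-gene log2
fold-change estimate at n = 5 vs 6 has a sampling standard error of ~0.2 at
these dispersions, so its mean *absolute* error is ~0.16 for any unbiased
estimator; the meaningful recovery statement, which the tests assert, is
that the systematic bias is near zero (measured |bias| < 0.01).

## Limitations

* The engine assumes a full-rank fixed-effects design; random effects and
  duplicate-correlation structure are out of scope.
* The copies-per-cell calibration inherits the spike-in protocol's
  assumptions (known input copies, capture proportional to molar amount);
  its absolute accuracy on real data is limited by those, not by the fit.
* Quasi-likelihood F-tests and transcript-level quantification are not
  provided.
* The permutation study re-runs the full pipeline per permutation; at 1,000
  permutations on a full-size matrix this is minutes of compute, and the
  weight-reusing `refit = FALSE` switch trades conservatism for speed.
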