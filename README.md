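# sortseq

Differential expression analysis for bulk RNA-seq of **small pools of
manually sorted cells** — the design used to profile hypothalamic AGRP and
POMC neurons (appetite-promoting and appetite-suppressing populations) from
fed and 24-hour food-deprived mice, with one pool of ~40–250 sorted neurons
per animal and 5–6 animals per group.

The package is for analysts working from gene-level count matrices of such
experiments (alignment and read counting are upstream). It implements the
full downstream pipeline as tested, reusable functions:

* **Quantification** — CPM, FPKM and TPM exactly as defined
  (`compute_cpm`, `compute_fpkm`, `compute_tpm`), the expression filter
  (CPM > 1 in ≥ 3 samples; `filter_expressed`) and group-mean CPM.
* **Differential expression** — an in-package implementation of the
  TMM / precision-weight / moderated-t chain:
  trimmed-mean-of-M-values normalization (`tmm_factors`), log-CPM with
  lowess mean–variance precision weights (`voom_transform`), gene-wise
  weighted least squares with empirical-Bayes variance shrinkage
  s̃²ᵍ = (d₀s₀² + dᵍs²ᵍ)/(d₀ + dᵍ) and t statistics on d₀ + dᵍ degrees of
  freedom (`fit_moderated`), Benjamini–Hochberg step-up q-values
  (`adjust_bh`), and the DEG criteria q < 0.05, |log₂ fc| > 1, group-mean
  CPM > 20 in ≥ 1 group (`call_deg`). `run_de` chains everything.
* **Empirical FDR** — label-permutation evaluation of the whole pipeline
  (`run_permutation_study`), reporting 100 × mean(permuted DEG)/observed DEG
  per contrast (`empirical_fdr`).
* **ERCC spike-in calibration** — the 50% detection point on the
  copies × kb axis from a pooled binomial fit (`fit_detection_curve`), and
  transcript copies per cell at 1 TPM from per-sample log–log regressions
  (`fit_copies_per_tpm`).
* **Enrichment** — upper-tail hypergeometric over-representation of gene
  sets among DEG (`hypergeom_upper`, `test_set_overrepresentation`) and
  Venn region counts (`deg_overlap`).
* **Structure & QC** — 1 − correlation pseudo-distance and classical MDS
  (`correlation_distance`, `classical_mds`), DEG clustering (`cluster_deg`),
  marker-based purity reports (`purity_report`) and the spliced-isoform
  fraction test (`splicing_fraction_test`).
* **Synthetic data** — a negative-binomial generator with recorded ground
  truth (`generate_dataset`, `generate_null_dataset`) emulating the study
  design, spike-in ladder, isoform splitting and trace contamination, so
  every stage is testable without the original sequencing data.

## Worked example

```r
library(sortseq)

sim <- generate_dataset(sim_params(n_genes = 2000), seed = 11)
de  <- run_de(sim$counts, sim$design)
de
#> de_result: 1994 genes, 3 contrast(s); d0 = 15
#>  AGRP.FD-AGRP.fed AGRP.fed-POMC.fed  POMC.FD-POMC.fed
#>                79                69                 6
```

1,994 of 2,000 simulated genes pass the expression filter; the pipeline
calls 79 DEG for food deprivation in AGRP neurons but only 6 in POMC
neurons (the generator programs exactly this asymmetry), plus 69 between
the cell types at baseline. `d0 = 15` is the estimated prior degrees of
freedom of the variance shrinkage.

```r
fit_detection_curve(sim$counts, sim$ercc)
#> detection_curve: x50 = 26.9 copies x kb ( 95 % CI 24 - 30.2 )

tpm <- compute_tpm(sim$counts)
fit_copies_per_tpm(tpm[sim$counts$is_spike, ], sim$ercc, sim$design)
#> copies_per_tpm: 1 TPM = 0.317 +/- 0.121 copies/cell (21 samples)
```

The assay detects half of all transcripts at ~27 copies × kb in this draw
(the generator's true value is 22), and 1 TPM corresponds to ~0.32 copies
per cell (truth for this dataset: 0.31; the absolute scale depends on
sequencing depth, here the desk-scale default of ~1e6 reads).

```r
run_permutation_study(sim$counts, sim$design, n_perm = 50, seed = 11)
#> perm_result (50 permutations):
#>                   observed perm_mean perm_sd empirical_fdr_pct
#> AGRP.FD-AGRP.fed        79         0   0.000              0.00
#> POMC.FD-POMC.fed         6         1   7.071             16.67
#> AGRP.fed-POMC.fed       69         0   0.000              0.00
```

Most permutations yield zero DEG; a rare "biased" permutation (one that
partially reconstitutes the true groups) produces a burst, which is why the
contrast with only 6 observed DEG shows a noisy empirical FDR while the
strong contrasts sit at 0%.

The printed worked examples from the motivating study check out directly:

```r
signif(hypergeom_upper(16513, 113, 1346, 20), 2)   # E-box over-representation
#> [1] 0.00075

splicing_fraction_test(summary = list(mean = c(fed = 7.4, FD = 15.6),
                                      sem  = c(fed = 1.0, FD = 3.8),
                                      n    = c(fed = 5, FD = 6)))
#> splicing_fraction: t = 1.908 df = 9 one-tailed p = 0.0443
```

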