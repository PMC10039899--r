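# stagewave

Stage-resolved proteogenomic analysis of tumor progression cohorts.

`stagewave` is for researchers who profile many lesions per patient
across an ordered series of histopathological (sub)stages — normal
tissue, preneoplastic stages, invasive carcinoma — with somatic mutation
calling, label-free proteomics and phosphoproteomics, and who want the
stage axis itself to drive the analysis. It implements:

* **Neo-mutation waves** — a mutation key is *neo* at the earliest stage
  where any sample carries it; strict interior local maxima of the neo
  series partition the stages into contiguous phases (e.g. NT / IEN /
  advanced).
* **Mutational signatures** — 96-channel pyrimidine-centered spectra;
  KL-divergence NMF (multiplicative updates) with restart-consensus
  cophenetic rank selection; cosine matching to a reference catalog;
  per-sample APOBEC (TCW-motif) enrichment
  `(mut_tCw / mut_C) / (bg_TCW / bg_C)` with one-sided Fisher tests.
* **SCNA cis-effects** — Spearman correlation of GISTIC-thresholded copy
  states (−2..2) with protein abundance, BH-adjusted.
* **Label-free proteome** — FOT normalization (iBAQ / per-sample total,
  floored at 1e-5), E1/E2 filtering, Kruskal–Wallis stage-wise
  differential expression with one-vs-rest ratio thresholds,
  contiguity-constrained co-expression **wave panels**, SAM
  (`d = (m2 − m1)/(s + s0)` with permutation FDR), consensus clustering
  (subsampled k-means, CDF delta-area model selection), and
  match-between-runs retention-time imputation (linear/quadratic RT
  regression selected by R²).
* **Phosphoproteome** — counterpart adjustment (site / parent protein),
  prevalence filtering, and KSEA:
  `z = (mean_substrates − mean_all) · √m / sd_all`.
* **Gene-set statistics** — hypergeometric ORA and preranked GSEA with
  gene-label permutation NES/FDR.
* **Synthetic cohorts** — a first-class generator that plants known
  ground truth (mutation bursts, signature mixtures, wave panels, kinase
  shifts, cis-couplings, RT warps) so the full pipeline is testable
  without access-restricted patient data.

## Worked example

Simulate a 20-patient cohort with neo-mutation bursts planted at the
Tis and T2 stages, then detect the waves:

```r
library(stagewave)

cfg     <- sim_config(n_patients = 20, seed = 1)
catalog <- gen_mutation_catalog(cfg)
neo_mutation_gain(catalog, cfg$stages)
#> <neo_wave_result> key = variant
#>  stage total  neo is_peak  phase
#>     NT   588  588   FALSE phase1
#>    HYP  1172  584   FALSE phase1
#>    Tis  4207 3035    TRUE phase2
#>    LPC  4838  631   FALSE phase2
#>    MMC  5439  601   FALSE phase2
#>    SM1  6040  601   FALSE phase2
#>    SM2  6615  575   FALSE phase2
#>     T2  9564 2949    TRUE phase3
#>     T3 10142  578   FALSE phase3
```

Each stage's `total` counts distinct variants observed there, `neo`
those never seen at an earlier stage; the two planted burst stages are
recovered as peaks and induce the three-phase partition. Signature
extraction on the same machinery:

```r
sim   <- gen_signature_spectrum(toy_signature_profiles(3), 120,
                                load = 300, seed = 1)
model <- extract_signatures(sim$spectrum, k_range = 2:4,
                            n_restarts = 20, seed = 1)
model
#> <signature_model> k = 3 signatures, 120 samples
#> cophenetic: k2 0.984  k3 0.998  k4 0.99
cosine_match(model, toy_signature_profiles(3))
#>   signature best_match    cosine   tie
#> 1      Sig1      True2 0.9990268 FALSE
#> 2      Sig2      True3 0.9996039 FALSE
#> 3      Sig3      True1 0.9995176 FALSE
```

The cophenetic criterion selects the planted rank (k = 3) and every
recovered profile matches a distinct planted signature at cosine > 0.99.

A full simulate-then-analyze run (writes TSVs with provenance headers;
byte-reproducible for a fixed seed):

```r
simulate_cohort(sim_config(seed = 1), "sim")
run_pipeline(list(in_dir = "sim", out_dir = "out", seed = 1))
```

See `vignettes/stagewave-methods.Rmd` for the models, parameter
conventions and numerical choices, and `inst/cli/stagewave.R` for a thin
command-line driver.

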