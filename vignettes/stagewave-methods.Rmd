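---
title: "Methods: stage-resolved proteogenomic analysis with stagewave"
author: "stagewave authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-resolved proteogenomic analysis with stagewave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagewave)
```

# Scope and data model

`stagewave` analyses cohorts profiled across an ordered series of
histopathological (sub)stages — the setting of early-carcinogenesis
studies in which many lesions per patient, from normal tissue through
preneoplastic stages to invasive tumor, are dissected and profiled by
whole-exome sequencing, label-free proteomics and phosphoproteomics.
Because such patient-level data are access-restricted, every method in
the package is paired with a synthetic cohort generator that plants a
known ground truth with the same statistical structure; all claims made
by the test suite are claims about recovery of that planted truth.

Three containers run through the package: a long-form **mutation
catalog** (patient, sample, stage, gene, genomic key, trinucleotide
context), an **abundance matrix** (features x samples, `NA` for missing,
nonnegative linear scale) with a sample-annotation table, and a
**kinase-substrate map**. All files are TSV; genomic positions are
1-based and fully closed.

# Neo-mutation waves and phase partitioning

A mutation key (by default the genomic variant `(chrom, pos, ref, alt)`;
optionally the gene symbol) is *neo* at the earliest ordered stage at
which any sample in the cohort carries it. For each stage we report the
total number of keys observed and the number of neo keys; peaks of the
neo series are strict local maxima over interior stages, with a maximal
plateau counting as a single peak at its leftmost stage. The first stage
is never a peak: its neo count equals its total by construction, so a
boundary maximum there carries no information about bursts. Each peak
opens a new phase; the stages before the first peak form the initial
phase. This yields the familiar three-phase reading (normal /
intraepithelial neoplasia / advanced) when two interior bursts are
present.

Whether per-stage totals should count events or distinct sample-variant
pairs is ambiguous in practice; both are available (`per_patient`),
and the cohort-wide reading is the default.

# Mutational signatures

Spectra are 96-channel counts (six pyrimidine-centered substitutions by
sixteen flanking contexts); purine-reference records are
reverse-complemented on ingestion, and records with ambiguous bases are
skipped and counted. Signature extraction is nonnegative matrix
factorization under the Kullback–Leibler divergence — the natural choice
for count spectra — using multiplicative updates, which guarantee a
non-increasing divergence. Numerical choices: entries of the
initialization are uniform random scaled to the data mean; updates are
guarded by `eps = 1e-12`; iteration stops when the relative divergence
decrease over a 10-iteration window falls below `tol = 1e-4` or at
`max_iter = 300` (on well-separated planted profiles the fits converge
in well under 100 iterations; raising the budget did not change the
recovered profiles in our experiments). Each restart's seed is derived
deterministically from the master seed.

The rank is selected by the cophenetic correlation of the
restart-consensus matrix: each restart assigns every sample to its
dominant signature, co-assignment frequencies over all restarts define a
consensus, and the rank whose consensus is most tree-like (highest
cophenetic correlation of the average-linkage dendrogram with the
consensus distances) wins; ties go to the smaller rank, and a perfectly
crisp consensus is scored 1. This criterion is informative precisely
when samples have dominant signatures; the spectrum generator therefore
draws exposures from a sparse symmetric Dirichlet (`alpha = 0.3`), the
regime typical of real tumors. With near-uniform exposures no stable
sample partition exists and the criterion will favour small ranks — a
known limitation of stability-based rank selection, not of this
implementation.

Cosine matching to a reference catalog aligns channels by label, reports
the best match per signature, and logs exact ties (broken by reference
order). The reference is a user-supplied file rather than an embedded
database, to avoid version coupling.

## APOBEC enrichment

For each sample, the enrichment score is
`(mut_tCw / mut_C) / (bg_TCW / bg_C)`, where `mut_C` counts C>T and C>G
events, `mut_tCw` those at T[C]A or T[C]T, and the background counts
describe the sequenced territory. Significance is a one-sided Fisher
test against the background, BH-adjusted over testable samples (at least
`min_mut = 5` C-class events); the enriched flag additionally requires
score above 2. When no territory counts are supplied the uniform-context
fallback (2 of 16 contexts) is used, which is adequate for synthetic
data only.

# Proteome

**FOT normalization** divides each sample's observed iBAQ values by
their sum, so observed values sum to one per sample; values below
`1e-5` are floored to `1e-5`. Two filters are provided: E1 keeps
proteins with at least two unique peptides and cohort-maximum FOT at or
above the floor (minus a user-supplied exclusion list, e.g. keratins);
E2 keeps proteins identified in strictly more than 20% of the samples
of at least one substage, then floors with missing entries imputed at
the floor. We read "each substage" as "at least one substage": a protein
specific to one substage would otherwise be discarded by the very filter
meant to retain substage-specific biology; the literal reading is
available via `all_substages = TRUE`.

**Differential expression** per feature is the Kruskal–Wallis rank test
(tie-corrected; for two groups this is the rank-sum test) with BH
adjustment, plus a one-vs-rest ratio of group means on the linear floored
scale. The ratio uses means rather than medians — a choice we make
explicit because either is defensible — and a feature is flagged at
FDR < 0.05 with ratio at least 2 (up) or at most 0.5 (down).

**Wave panels**: each substage's flagged-high proteins define a mean
expression fingerprint over substages; substages are clustered on
1 − Pearson correlation of fingerprints under a hard contiguity
constraint (only adjacent blocks may merge, average linkage), so panels
are always contiguous stage blocks, as a "wave" must be. The cut is
chosen by mean silhouette over the contiguous cuts, with an explicit
`n_panels = 8` switch for reproducing an eight-wave analysis. A substage
with an empty high set inherits the global mean profile and is reported.

**SAM (two-class unpaired)**: `d = (mean2 − mean1) / (s + s0)` with `s`
the unequal-variance standard error, so `s0 = 0` reduces `d` exactly to
the Welch t statistic. The fudge factor `s0`, when `"auto"`, is the
percentile of the `s` distribution (grid 0, 5, …, 100) minimizing the
coefficient of variation of window-wise MADs of `d` across 100
`s`-quantile windows. Permutation expected order statistics come from
label permutations (exhaustive enumeration replaces sampling when fewer
distinct permutations exist than requested); features are called where
the sorted `d` departs from its expectation by more than `delta`, and
FDR is the median count of permuted values beyond the call cutoffs over
the number of calls. Given a target FDR instead of a delta, the smallest
delta on a 201-point quantile grid meeting the target is used.

**Consensus clustering** subsamples `ceiling(0.8 n)` samples per
repetition, runs k-means on Euclidean distance, and normalizes
co-clustering counts by co-sampling counts. The cluster number is the
largest relative increase in area under the consensus CDF (k = 2 scored
by its absolute area), and final labels are average-linkage cuts of
1 − consensus. Rare k-means failures are retried with a derived seed and
counted. Repetitions default to 1000 and scale down cleanly; the test
suite uses 100, which is sufficient for the planted two-cluster
benchmark at 4-sigma separation.

**Match-between-runs** regresses acceptor retention time on donor
retention time over shared identified peptides; if the linear fit's R^2
falls below 0.995 a quadratic fit is tried and the better model kept.
The high threshold is deliberate: with zero noise a truly linear map
fits exactly, while even mild curvature should switch the model, since
an under-fit RT map silently transfers wrong features. Donor-only
peptides are matched to unidentified acceptor features within an m/z
tolerance in ppm and an RT tolerance around the predicted time; each
acceptor feature is transferred at most once, flagged `"mbr"`.

# Phosphoproteome

Phosphosite abundances are divided by the parent protein's abundance in
the same sample (sites without a quantified counterpart pass through,
flagged; zero counterparts yield `NA`), and sites observed in fewer than
30% of samples are dropped. KSEA scores each kinase by
`z = (mean_substrates − mean_all) · sqrt(m) / sd_all` on per-site log2
fold changes, with two-sided normal p-values and BH adjustment; kinases
with fewer than `min_m = 3` quantified substrates are not reported by
default (`min_m = 1` is supported). The contrast defining the fold
changes (which groups, adjusted or raw ratios) is a parameter, since
different cohorts warrant different contrasts; both adjusted and raw
inputs are accepted.

# Gene-set statistics

ORA is the upper-tail hypergeometric test of hit/set overlap within a
universe, BH-adjusted across sets, with the signed −log10 FDR as a
differential score. Preranked GSEA uses the weighted running-sum
statistic (hit increments proportional to |score|^weight, miss
decrements 1/(N − m)); significance comes from gene-label permutations —
the appropriate null for preranked input — with NES normalized by the
mean same-sign permutation |ES| and FDR by the pooled positive/negative
null. Reported permutation p-values use the (r + 1)/(n + 1) convention,
so a p-value of exactly zero is never reported; ranking ties are broken
by stable feature order and logged.

# The synthetic cohort generator

Defaults are the study conditions the package is designed around: nine
ordered stages (NT, HYP, Tis, LPC, MMC, SM1, SM2, T2, T3) with
neo-mutation bursts at Tis and T2 — hence three phases — eight wave
panels of log2 effect 2 over contiguous substage blocks, and an FOT
floor of 1e-5. Where the setting prescribes no value we fixed one
realistic choice up front: per-stage Poisson mutation loads of 30 with
burst loads of four times the mean load; lognormal protein abundances
(log2 mean 17, between-protein SD 2, within-protein noise SD 0.5 —
0.3 in the SAM benchmark, where the planted two-fold effect is
specified); dropout logistic-decreasing in log2 abundance with overall
rate 0.2 at the median, reproducing the empirical pattern that
identifications concentrate at high abundance; mutation persistence
across a patient's stages with loss rate 0 (the cumulative model), with
a loss-rate knob because persistence in real serial lesions is not
guaranteed. Every simulated variant receives a unique genomic key, so
cohort-wide neo counts equal the planted per-stage loads exactly, and
half the records are stored purine-strand to exercise pyrimidine
collapsing. All generators draw from a single master seed through
deterministic per-module derived seeds; fixing the seed reproduces every
table bit-identically.

What the generator does *not* emulate: correlated mutation co-occurrence
structure, batch effects, peptide-to-protein inference noise, shared
variants between patients, and realistic signature catalogs (the
planted profiles are deliberately well-separated). Passing the recovery
tests therefore demonstrates correctness of the algorithms under their
stated assumptions, not performance on real cohorts.

# Problem sizes used by the test suite

The suite runs the recovery experiments at deliberately moderate sizes
chosen to exercise the asymptotics without waste: signature recovery at
200 samples x 50 restarts x 20 replicates; wave recovery at 2000
proteins x 240 samples; SAM at 1000 features, 20 samples per group, 200
permutations; consensus clustering at 300 x 50 with 100 repetitions;
KSEA calibration on 2000 null draws. `scripts/acceptance.R` re-runs the
same experiments once from a command-line seed.

# Known limitations

* Stability-based NMF rank selection is uninformative for near-uniform
  exposures (above).
* The SAM FDR is the unadjusted median-false-call estimate; no pi0
  correction is applied.
* The contiguity-constrained panel clustering is greedy; it does not
  revisit merges, which is standard for ordered agglomeration but can be
  suboptimal for pathological profiles.
* `scna_cis_effects` uses the asymptotic Spearman test; with the five
  discrete copy states ties are pervasive and exact p-values are not
  attempted.
* The uniform-context APOBEC background is a fallback for synthetic
  data; real analyses must supply territory counts.
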