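---
title: "Identifying and validating RT-qPCR reference genes with refstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and validating RT-qPCR reference genes with refstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Relative RT-qPCR quantification stands or falls with its internal controls.
A reference (housekeeping) gene is assumed to be expressed at a constant
level across every sample of the experiment, so that dividing a gene of
interest's signal by the reference signal cancels variation in input
amount, RNA quality and reverse-transcription yield. That assumption is
routinely violated — classical references such as *ACTB* or *GAPDH* drift
with culture conditions, passage number and oxygen tension — so candidate
references must be screened, ranked by dedicated stability statistics, and
validated before use. `refstab` implements that complete workflow:

1. **Screening** a genes × samples expression matrix (e.g. RNA-seq TPM from
   a tumour cohort matching the cell line under study) for candidates that
   are well expressed, low-variance and free of exceptional values.
2. **Stability ranking** of the candidates' Cq values with five algorithms
   (CV%, geNorm, NormFinder, BestKeeper, comparative ΔCt), a
   RefFinder-style consensus, and exclusion rules.
3. **Normalization** of genes of interest against multi-gene normalization
   factors with per-gene amplification efficiencies, plus acceptability
   checks on the normalization factors themselves.
4. A **synthetic-data generator** that emulates the serial-passage,
   normoxia/hypoxia culture design, so every stage is testable end to end
   without any external download.

## Screening (criteria I–III and CV%)

Screening operates on `log2(TPM)` values; RSEM `scaled_estimate`
frequencies are converted by `to_tpm()` (× 10^6) and `log2_transform()`.
Per gene, with default thresholds:

* **Criterion I, expression**: mean log2(TPM) ≥ 5 (well above assay noise).
* **Criterion II, variance**: SD of log2(TPM) ≤ 1.
* **Criterion III, no exceptional expression**: no sample deviates from the
  gene's mean log2(TPM) by a factor of two or more.

Passing genes are ranked by CV% = 100·SD/mean on the log2(TPM) scale,
lower being more stable.

Two readings of criterion III are defensible. The default reads the
factor-of-two bound literally on the log2(TPM) values themselves
(`mean/2 ≤ x ≤ 2·mean`); the alternative reads it as a 2-fold change in
TPM, i.e. `|x − mean| < 1` on the log2 scale, and is available as
`screen_criteria(outlier_rule = "log_offset")`. We default to the literal
multiplicative reading and surface the ambiguity here rather than hide it.
Zeros in TPM get no pseudocount: `log2(0)` becomes an undefined sentinel
that fails all criteria, because a usable reference must be robustly
expressed in every sample anyway. SDs are sample SDs (n − 1 denominator);
`sd_type = "population"` switches. Rank ties break lexicographically by
gene id so ranks are a strict permutation.

```{r screen-example, eval = FALSE}
x <- read_rsem_genes(list.files("rsem/", full.names = TRUE))
screened <- x |> to_tpm() |> log2_transform() |> screen_reference_candidates()
glance(screened)
```

## The five stability algorithms

All methods run on replicate-collapsed data (`collapse_replicates()`
averages the technical triplicates; the replicate SD is kept as quality
metadata). Cq values are converted to relative quantities
`RQ = E^(min Cq − Cq)` per gene, so RQ ∈ (0, 1]; the reference point is
presentation-only since any fixed per-gene constant cancels in every
log-ratio the algorithms take. Genes absent from the efficiency table
default to perfect doubling (E = 2) with a warning.

* **geNorm** — gene *j*'s M-value is the mean over partners *k* of
  SD_samples(log2(RQ_j/RQ_k)). Ranking is by stepwise exclusion of the
  argmax-M gene until two remain; those two share ranks 1–2 (reported as
  1.5 each, following the average-rank tie rule). The pairwise variation
  V(n/n+1) = SD(log2(NF_n/NF_{n+1})), with NF_n the geometric mean of the
  top-n genes' RQs, guides how many references suffice.
* **NormFinder** — model-based. Each sample's mean over genes (the common
  loading/amount effect) is removed first. Ungrouped, the stability value
  is simply the SD of the sample-centered log2 quantities. With groups
  (the hypoxia arms), each gene's intragroup variance is estimated from
  the residual mean square with the bias correction that removes the
  contamination introduced by sample-centering (factor k/(k−2) and the
  cross-gene term Σs²/(k(k−1)) for k genes), the intergroup deviation of
  the gene's group mean is shrunk by an empirical-Bayes factor
  γ²/(γ² + var), and the stability value is the average over groups of
  |shrunk deviation| + √(intragroup variance / group size). Grouping
  defaults to `condition` whenever more than one condition is present.
* **BestKeeper** — works on the Cq scale. Dispersion is the mean absolute
  deviation from the mean Cq (the original tool's "SD(±Cq)"; a plain-SD
  dialect exists), CV% = 100·dispersion/mean. The BestKeeper index is the
  per-sample geometric mean of all candidates' Cq; each gene's Pearson r
  against the index is reported and feeds the exclusion rules, while the
  ranking statistic is the dispersion.
* **Comparative ΔCt** — gene *j*'s statistic is the mean over partners of
  SD_samples(Cq_j − Cq_k): genes that track each other keep constant
  differences.
* **CV%** — 100·SD/mean, by default on the linear RQ scale. On the Cq
  scale a 50% CV would require an SD of ~12 cycles at Cq 25, which no
  real assay shows; fold-level variation is where a ">50%" exclusion
  threshold is meaningful. `scale = "cq"` switches.

A deliberate contrast worth knowing: a constant shift of *all* genes in
one sample (a loading offset) is invisible to geNorm, ΔCt and NormFinder —
it cancels in ratios and in sample-centering — but inflates BestKeeper's
dispersion, which works on raw Cq. The tests assert this contrast
explicitly.

## Consensus ranking and exclusions

`reffinder_consensus()` aggregates exactly four method rankings (ΔCt,
BestKeeper, geNorm, NormFinder) by the geometric mean of each gene's
ranks, as the RefFinder web tool does; CV% stays out of the aggregation
and participates only in exclusion. Exclusion thresholds
(`exclusion_thresholds()`): mean Cq > 28 (too weak), mean Cq < 15
(rRNA-like, too abundant), CV% > 50, BestKeeper r < 0.8. The r threshold
is configurable because published cut-offs vary; 0.8 is deliberately below
0.856, a value at which a gene can survive screening yet still normalize
poorly, so the flag errs toward keeping the user informed rather than
silently dropping candidates. Flags are advisory: `mode = "two_pass"`
removes flagged genes and re-ranks the survivors (the
exclude-then-re-analyze workflow); `"single_pass"` keeps them visible with
reasons. `combine_cultures()` merges replicate cultures by the geometric
mean of final ranks.

Note that with the default synthetic data the index-correlation rule is
strict: when the shared per-sample variation (loading SD 0.3 cycles) is
modest relative to independent gene noise, genuine correlations with the
BestKeeper index are low and many genes draw the `low_index_correlation`
flag. That is the rule working as designed — r measures how much a gene
tracks the common signal — not a defect of the generator.

## Normalization

`normalize_goi()` implements efficiency-corrected relative quantification
against multi-gene normalization factors. Per gene, `RQ =
E^(Cq_cal − Cq_sample)` with the calibrator sample (e.g. the first
passage) as the reference point, so the calibrator's log2 fold change is
identically zero without post-hoc rescaling. The normalization factor of a
reference subset is the geometric mean of its RQs in that sample;
NRQ = RQ_goi/NF; log2fc = log2(NRQ). By default all `choose(5, 3) = 10`
triplets of the selected five references are evaluated (subset size `k`
is free). With all efficiencies 2 and a single reference the computation
reduces exactly to the classical 2^−ΔΔCt, which the tests verify.

Two properties justify the design:

* **Calibrator invariance** — changing the calibrator rescales every NRQ
  by a constant, so all inter-sample fold ratios are unchanged; results
  are fully equivalent, only rescaled. This is the module's headline
  property test (tolerance 1e−9).
* **NF acceptability** — a sample's NF should lie within 2-fold (the
  conservative end of the conventional 2-to-3-fold band) of the average
  NF. "Average" is the geometric mean, since NFs are multiplicative; an
  arithmetic-mean dialect exists. Outliers point to input-quantity or
  reference-gene problems.

`efficiency_from_curve()` provides the standard-curve helper:
least-squares slope of Cq against log10 template quantity, E = 10^(−1/slope)
(slope −3.32 ⇒ E = 2). One efficiency per gene is carried in the
`efficiency_table()`.

## The synthetic-data generator

`simulate_cq()` draws Cq values under

Cq_{g,s,r} = μ_g − φ_s − β_{g,cond(s)} + ε_{g,s} + η_{g,s,r}

with a per-sample loading offset φ_s ~ N(0, τ²) shared by all genes,
gene-specific biological noise ε ~ N(0, σ_g²), technical-replicate noise
η ~ N(0, σ_tech²), and condition effects β in cycles (positive β =
induction, i.e. fewer cycles to threshold; a −β cycle shift surfaces as a
+β log2 fold change at E = 2). Noise is Gaussian on the Cq scale — the
log scale of abundance, the standard qPCR error model; heavy-tailed
options are deliberately deferred. Values outside the instrument range
are clipped into (0, 40] and counted rather than rejected, keeping
datasets complete. Standard normal draws are scaled by the SDs afterwards,
so two runs at the same seed differing only in one noise component are
comparable draw by draw.

Defaults emulate the study design the package targets: 25 candidate
genes with baselines spread over 15–30 cycles (abundant rRNA-like down to
weakly expressed), two replicate cultures S1/S2 over five consecutive
passages p7–p11 in normoxia, optional acute-24 h/acute-72 h/chronic
hypoxia arms, and 3 technical replicates — 750 reactions collapsing to
250 mean Cq values, with a 3-gene-of-interest companion collapsing to 30.
Where the design leaves a noise magnitude open we fixed realistic qPCR
values once: technical SD 0.1 cycles (typical of triplicates), loading SD
0.3 cycles, stable-gene biological SD 0.2 cycles.

`simulate_expression()` plants screening ground truth: genes passing all
three criteria and, per criterion, genes violating exactly that one.
Violating *only* the outlier criterion is only feasible with enough
samples (the exceptional value must exceed the gene mean while its SD
contribution, ≈ excess/√n, stays under the SD bound), so the generator
requires ≥ 40 samples for such genes; the emulated screening matrix has 82.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: amplification-curve artefacts and Cq-calling
error, inter-plate batch effects, correlated regulation between genes
(each gene's biological noise is independent), RNA-quality gradients, and
the compositional structure of real RNA-seq counts behind the screening
matrix. Recovery rates measured here are upper bounds for the much
messier wet-lab situation.

## Numerical and testing choices

* Geometric means are computed on the log scale; ranks use average ties,
  with residual ordering ties broken lexicographically by gene id for
  determinism.
* Stability methods require complete gene × sample matrices after
  collapse; missing cells are a named error rather than silent dropping.
* geNorm's reported per-gene statistic is the full-panel M value (the
  quantity the brute-force oracle recomputes); the stepwise-exclusion
  order determines the ranking and is exposed in `extras`.
* Oracle tests compare geNorm and ΔCt against independent brute-force
  enumerations on 200 random instances up to 6 genes × 10 samples at
  1e−12; the stochastic suites use 100 seeds (consensus recovery of 3
  planted stable genes among 12) and 50 seeds (screening recovery at 82
  samples), sizes at which the whole suite runs in a few minutes on one
  core.
* `with_seed()` restores the caller's RNG state, so package functions
  never clobber a session's random stream.

## Limitations

The NormFinder grouped model follows the published variance-decomposition
with the bias corrections stated above; other implementations differ in
small details (shrinkage constants, group weighting), so grouped
stability values should be compared between tools only by rank. The
RefFinder consensus uses unweighted geometric means of ranks; weighted
aggregation and significance testing of rank differences are out of
scope, as is any error propagation onto NRQs.
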