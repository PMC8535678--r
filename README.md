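# refstab

Identification and validation of RT-qPCR reference (housekeeping) genes,
end to end: expression-matrix screening of candidates, five stability
algorithms with a consensus ranking and exclusion rules, and
efficiency-corrected multi-reference normalization of genes of interest —
plus a synthetic-data generator emulating a serial-passage,
normoxia/hypoxia cell-culture design so the whole workflow is testable
without external downloads.

## Who it is for

Anyone normalizing RT-qPCR data who does not want to take *ACTB* or
*GAPDH* on faith: cell-line studies across passages and stress
conditions, candidate-reference discovery from a matching RNA-seq cohort,
and method development on simulated Cq data with known ground truth.

## The methods at the core

**Screening.** Candidates come from a genes × samples matrix of
log2(TPM) (RSEM `scaled_estimate` × 10⁶ → TPM → log2). A gene passes if
mean log2(TPM) ≥ 5, SD(log2 TPM) ≤ 1, and no sample deviates from the
gene mean by a factor of two or more; passing genes are ranked by
CV% = 100·SD/mean, lower = more stable.

**Stability.** On replicate-collapsed Cq data, with relative quantities
RQ = E^(minCq − Cq) per gene:

- *geNorm*: M_j = mean_k SD_s(log2(RQ_j/RQ_k)); stepwise exclusion of the
  worst gene; pairwise variation V(n/n+1) = SD(log2(NF_n/NF_{n+1})).
- *NormFinder*: variance decomposition of sample-centered log2
  quantities; with groups, |shrunk intergroup deviation| +
  √(intragroup variance/n) averaged over groups.
- *BestKeeper*: dispersion (mean absolute deviation) of Cq, CV%, and
  Pearson r against the BestKeeper index (per-sample geometric mean Cq).
- *Comparative ΔCt*: mean over partners of SD_s(Cq_j − Cq_k).
- *CV%* on the linear RQ scale.

**Consensus.** RefFinder-style: the geometric mean of the four method
ranks (ΔCt, BestKeeper, geNorm, NormFinder), with exclusion flags for
mean Cq > 28, mean Cq < 15, CV% > 50, BestKeeper r < 0.8 and a
two-pass exclude-then-re-rank mode.

**Normalization.** For each gene of interest, reference subset (all
`choose(n, k)` subsets, triplets by default) and sample:
RQ = E^(Cq_cal − Cq), NF = geometric mean of the subset's reference RQs,
NRQ = RQ/NF, log2fc = log2(NRQ), with the calibrator at exactly 0 and NF
outliers flagged beyond 2-fold of the geometric-mean NF. With E = 2 and a
single reference this is exactly the classical 2^−ΔΔCt. Standard-curve
efficiencies come from E = 10^(−1/slope).

## Worked example

Simulate the default study design (25 candidate genes, 2 cultures ×
5 passages, 3 technical replicates), rank the candidates, and normalize a
simulated gene of interest against the top-5 consensus references:

```r
library(refstab)

sim <- simulate_cq(seed = 2024)            # 750 reactions
cq  <- collapse_replicates(sim)            # 250 mean Cq values
stab <- stability_all(cq)                  # cv, genorm, normfinder, bestkeeper, delta_ct
cons <- reffinder_consensus(stab)
refs <- head(cons$gene_id[order(cons$final_rank)], 5)

goi <- collapse_replicates(
  simulate_cq(cq_sim_spec(c(AURKA = 20), gene_noise_sd = 0.4), seed = 2025)
)
res <- normalize_goi(dplyr::bind_rows(cq, goi), "AURKA", refs,
                     calibrator = "S1_p7_normoxia")
head(tidy(res)[, c("goi", "subset_id", "subset", "sample_id", "nrq", "log2fc", "nf_outlier")], 4)
#> # A tibble: 4 × 7
#>   goi   subset_id subset      sample_id         nrq  log2fc nf_outlier
#>   <chr> <chr>     <chr>       <chr>           <dbl>   <dbl> <lgl>
#> 1 AURKA T1        G03+G06+G17 S1_p10_normoxia 1.02   0.0251 FALSE
#> 2 AURKA T1        G03+G06+G17 S1_p11_normoxia 0.578 -0.790  FALSE
#> 3 AURKA T1        G03+G06+G17 S1_p7_normoxia  1      0      FALSE
#> 4 AURKA T1        G03+G06+G17 S1_p8_normoxia  1.40   0.483  FALSE
glance(res)
#> # A tibble: 1 × 5
#>   n_goi n_subsets n_samples n_nf_outliers calibrator
#>   <int>     <int>     <int>         <int> <chr>
#> 1     1        10        10             0 S1_p7_normoxia
```

Each row is one (gene of interest, reference triplet, sample): `nrq` is
the efficiency-corrected relative quantity divided by the triplet's
normalization factor, `log2fc` the fold change versus the p7 calibrator
(0 there by construction), and `nf_outlier` flags samples whose
normalization factor departs more than 2-fold from the average — here
none, i.e. the references normalize this dataset cleanly. The ten
`subset_id` blocks are the `choose(5, 3) = 10` reference triplets.

`autoplot()` methods exist for screen results, stability results,
consensus rankings and normalization results; `tidy()`/`glance()` return
tibbles throughout. A thin command-line front end with `simulate`,
`screen`, `stability`, `normalize` and `run-all` subcommands ships in
`inst/scripts/refstab`.

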