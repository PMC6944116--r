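# uvg2pipe

Analysis toolkit for the **UV-G2 checkpoint** — the G2-phase arrest coupled
to postreplication repair of UV-induced DNA lesions — covering the three
computational stages used to characterize it:

1. **Differential polysome loading.** Cells arrested at the UV-G2
   checkpoint reprogram translation: transcripts change their loading onto
   polysomes without matching changes in total mRNA. The package computes
   empirical-Bayes moderated statistics per contrast (moderated *t* and the
   B statistic, the log posterior odds of differential expression), selects
   candidates by fold change ≥ 2 and B > 0, removes generic G2-phase
   responders whose fold changes are similar in both conditions, and
   confirms candidates across microarray and RNA-seq platforms.
2. **High-content screen scoring.** Per-cell DNA-stain intensities and RPA
   focus counts are summarized per well (constrained 2n/4n mixture fit for
   cell-cycle fractions; Tukey-HSD-adjusted focus comparisons against the
   non-targeting control) and combined into integer phenotype scores with
   two-cell-line confidence tiers (siRNA: total ≥ 10 in both lines = high
   confidence; overexpression: > 2 in both / > 3 in one).
3. **Pathway deregulation score (PDS).** For a tumor cohort, a principal
   curve is fitted to pathway-restricted expression in PCA space
   (Hastie–Stuetzle projection–expectation iteration, written from
   scratch); each sample's normalized arc-length position along the curve —
   0 = reference-like, 1 = maximally deregulated — is related to the UV
   signature mutation (USM) load via Spearman correlation, load-subgroup
   comparisons (boundaries 3.6 and 54.6 mutations/Mb), and per-gene
   contribution ranking.

Raw microarray, imaging and cohort data are not redistributed; instead,
`gen_polysome()`, `gen_screen()` and `gen_cohort()` generate synthetic
inputs of the same shape with planted, recoverable structure (effect
classes, phenotype archetypes, a latent deregulation axis coupled to
mutation load), so the whole chain is testable end to end.

## Worked example

The `analysis/` directory holds the numbered workflow
(`01_simulate.R` … `04_pds_cohort.R`). A condensed version:

```r
library(uvg2pipe)

# planted polysome-profiling experiment -> candidate selection
sim <- gen_polysome(polysome_sim_spec(seed = 1))
res <- candidate_pipeline(sim$microarray, sim$rnaseq)
length(res$uvg2_minus_g2)            # 130 candidates after G2 subtraction
length(res$high_confidence)          # 109 confirmed on both platforms
res$regulation$uvg2$summary$frac_polysome_only  # 0.81

# cohort: PDS vs UV signature mutation load
co <- gen_cohort(cohort_sim_spec(seed = 1))
assoc <- cohort_association(co$expr, co$loads$usm_per_mb)
assoc$correlation                    # rho = 0.163, n = 352, p = 2.1e-03
round(assoc$group_comparison$medians, 2)
#  zero  low  mid high
#  0.03 0.50 0.58 0.76
```

Running `Rscript analysis/04_pds_cohort.R` after `01_simulate.R` prints the
corresponding quantities with the subgroup sizes (14 / 53 / 257 / 28 at
seed 1), the
BH-adjusted rank-sum comparisons (zero-load baseline significantly below the
mid- and high-load groups), the top individual contributing genes, and the
recovery of the planted deregulation axis (Spearman(PDS, t) = 0.98).
Interpretation: tumors with higher UV-mutation burden sit farther along the
pathway deregulation curve, and the planted association (calibrated to a
weak rho ≈ 0.25) is recovered within sampling error.

## Layout

```
R/                  package code (generators, moderated stats, candidate
                    selection, screen scoring, principal-curve PDS,
                    cohort association)
analysis/           numbered workflow drivers writing under results/
inst/extdata/       synthetic 43-gene pathway panel (GMT)
tests/testthat/     unit, property and acceptance tests
scripts/            acceptance.R
vignettes/          methods vignette
```
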