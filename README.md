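# oligomiR

Statistical toolkit for asking whether genomically clustered microRNAs —
prototypically the 14q32 (DLK1–DIO3) cluster — mark an *oligometastatic*
phenotype: clinically limited metastatic disease that may be curable with
local therapy, as opposed to widespread polymetastasis.

The package is aimed at computational biologists analysing miRNA
profiling of metastasis cohorts. It re-implements, as tested and reusable
functions, the complete statistical chain connecting a differential miRNA
list to a phenotype:

1. **Genomic-locus enrichment.** Given the array panel (the sampling
   frame) and a differential miRNA set of size *n* containing *k* members
   of a prespecified locus, the null resamples size-*n* sets uniformly
   without replacement and counts locus members. The empirical p-value is
   the add-one estimator (r + 1)/(B + 1) over B replicates (default
   10⁶); the exact marginal is the hypergeometric upper tail
   P(X ≥ k), X ~ Hypergeom(N, K, n), computed alongside as an oracle.
2. **Pathway co-targeting.** Predicted targets (interaction scores ≥ 0.6)
   are tested per (miRNA, pathway) by hypergeometric over-representation
   against the gene universe, combined across miRNAs per pathway with
   Fisher's method (−2 Σ ln pᵢ ~ χ²₂ₖ), arranged as a clustered
   −log₁₀(p) heat-map matrix, grouped into AIM
   (adhesion/invasion/motility), ICS and CSS functional classes, ranked
   per miRNA by AIM burden, and exported as a pathway–miRNA co-targeting
   network (pathways hit by ≥ 2 miRNAs).
3. **Differential suppression.** Transfection arrays are quantile
   normalized; each miRNA-vs-control contrast is scored by the SAM
   statistic d = (x̄₁ − x̄₂)/(s + s₀) with an exhaustive
   balanced-relabeling permutation FDR (all 6 relabelings for duplicate
   arrays); suppressed probes are gated at FDR ≤ 5% and fold change
   ≥ 1.4 (≥ 2.0 for the set handed back to pathway analysis).
4. **Co-repression overlap.** Venn membership-pattern counts over 2–4
   suppressed sets, plus pairwise 2×2 chi-squared tests (no continuity
   correction) over an explicit probe population, with an exact
   hypergeometric fallback.
5. **Survival stratification.** Patients are split at the median of mean
   expression of a 4-miRNA panel; recurrence-free survival is compared by
   Kaplan–Meier curves and the log-rank test.

A first-class synthetic-data module generates every input with planted,
recoverable ground truth (locus enrichment, pathway-concentrated
targeting, shared suppression, a survival hazard ratio), so the whole
chain can be validated end to end without any external download.

## Worked example

```r
library(oligomiR)

cfg    <- synthConfig(seed = 42)     # study-scale synthetic conditions
bundle <- simulateBundle(cfg)        # panel, sets, scores, arrays, cohort

## is the differential set enriched for the 14q32 locus?
permutationLocusTest(bundle$surgical, bundle$panel, "14q32",
                     nPerm = 1e5, seed = 42)
#> Locus-enrichment permutation test (14q32)
#>   observed 17 of 39 in locus (panel: 20 of 377)
#>   empirical p = < 0.0001 (100000 replicates), exact p = 3.97e-16

## rank locus miRNAs by adhesion/invasion/motility pathway burden
targets <- thresholdTargets(bundle$scores, tau = 0.6)
cells   <- enrichmentTable(targets, bundle$pathways,
                           geneUniverse(bundle$scores))
head(rankByAim(cells, bundle$pathways), 3)
#>           mir n_significant_aim aim_score rank
#> 1 syn-miR-327                 7  141.7732    1
#> 2 syn-miR-024                 4  237.4961    2
#> 3 syn-miR-228                 3  236.1592    3
bundle$groundTruth$top_mir            # the planted top miRNA
#> [1] "syn-miR-327"

## recurrence-free survival, high vs low mean 4-miR expression
st <- survivalStratified(bundle$survival, bundle$groundTruth$planted_mirs)
st$logrank
#> Log-rank test: chisq = 4.32 on 1 df, p = 0.03766
sapply(st$curves, survivalAt, t = 60)
#> high  low
#> 0.60 0.27
```

The observed 17/39 locus members are far beyond the ~2 expected under
uniform sampling from a 20-of-377 panel, the planted miRNA is recovered
as the top AIM-ranked candidate, and the high-expression half of the
cohort shows 60% vs 27% recurrence-free survival at five years
(log-rank p = 0.038).

The full chain (simulate → locus test → enrichment → differential
expression → overlap → survival) runs as one seeded, provenance-logged
call:

```r
report <- runPipeline(defaultRunConfig(seed = 1, n_perm = 1e5),
                      outDir = "run1")
```

or from a shell via `inst/scripts/run-pipeline.R`.

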