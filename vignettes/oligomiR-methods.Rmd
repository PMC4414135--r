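---
title: "Methods: locus enrichment, pathway co-targeting, co-repression and survival for clustered microRNAs"
author: "oligomiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locus enrichment, pathway co-targeting, co-repression and survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligomiR)
```

oligomiR implements the statistical chain used to connect a differential
microRNA list — typically miRNAs over-expressed in oligometastatic
versus polymetastatic lesions — to a phenotype, through four linked
analyses: genomic-locus enrichment, pathway co-targeting, co-repression
of transfection targets, and survival stratification. This vignette is
the package's account of the models, their assumptions, the defaults and
why they were chosen, and what the synthetic validation does and does
not demonstrate.

## Genomic-locus enrichment

The question is whether a differential set of $n$ miRNAs contains more
members of a prespecified locus (e.g. the 14q32/DLK1–DIO3 cluster, $K$
members on an $N$-miRNA array) than chance allows. The null model
resamples whole sets of size $n$ uniformly without replacement from the
panel and counts locus members; the test is one-sided for enrichment,
with replicates tying the observed count $k$ counted as exceedances
(the standard conservative convention).

Two readings of "randomly choosing a miRNA and comparing the incidence"
are possible — single Bernoulli draws versus whole-set resampling. The
package implements whole-set resampling: its marginal is exactly the
hypergeometric law of single draws aggregated over the set, and it keeps
the replicate statistic ("incidence in the set") identical in form to
the observed one. The exact marginal
$P(X \ge k),\; X \sim \mathrm{Hypergeom}(N, K, n)$ is computed alongside
every permutation run (`exactLocusTest()`) and acts as the test's
analytic oracle; the suite checks agreement within Monte-Carlo error on
dozens of random instances and against brute-force subset enumeration
for all configurations with $N \le 12$.

The empirical p-value uses the add-one estimator
$(r + 1)/(B + 1)$ so that zero exceedances at $B = 10^6$ replicates
reports $\approx 10^{-6}$ rather than an impossible zero; the display
layer prints "< 0.0001" when $r = 0$ at $B \ge 10^4$. The default
$B = 10^6$ matches the scale at which such tests are conventionally
run; pipeline configurations used for routine validation set
$B = 10^5$, and both values are recorded in the run's provenance block.
The panel is taken to contain miRNA records only (control probes are
assumed to have been stripped at load time).

## Pathway co-targeting

Predicted miRNA–gene interaction scores in $[0, 1]$ are thresholded at
$\tau = 0.6$ (the conventional microT cut-off; boundary included). For
each miRNA target set $T$ and pathway $P$ inside a gene universe $U$,
over-representation is the hypergeometric upper tail
$P(X \ge |T \cap P|)$ with $X \sim \mathrm{Hypergeom}(|U|, |P|, |T|)$.
The gene universe defaults to the union of all scored genes — the set
the predictor actually scored — and can be overridden with an explicit
list; no universe choice is neutral, and making it explicit keeps the
denominator auditable.

Per-pathway evidence is combined **across miRNAs** with Fisher's method,
$X^2 = -2\sum_i \ln p_i \sim \chi^2_{2k}$: a pathway column in the
heat map summarises how consistently the miRNA panel targets it. (The
alternative reading — combining across pathways within a miRNA — would
summarise rows, which is not what the heat-map column semantics need.)
With a single input the combination is the identity on $p$, which the
suite checks to $10^{-12}$. P-values are floored at $10^{-300}$ before
the log so underflowed values cannot produce infinities.

Significance is applied at $\alpha = 0.05$ to the combined statistic
when selecting heat-map columns; per-cell p-values are deliberately not
multiplicity-corrected, mirroring common practice for these screens —
the per-cell calls feed ranking and network summaries, not confirmatory
claims. Rows are ordered by agglomerative clustering with Euclidean
distance and average linkage: no linkage is canonical for such heat
maps, and average linkage on a deterministic tie rule gives a fully
reproducible order. miRNAs are ranked by AIM
(adhesion/invasion/motility) burden — primarily the count of AIM
pathways significant at $\alpha$, then the summed $-\log_{10} p$ over
them, with lexicographic identifier order breaking ties. The
co-targeting network keeps pathways significantly associated with at
least `minMirs = 2` miRNAs.

## Differential suppression (SAM)

Transfection arrays are quantile normalized (every column receives the
across-column rank means; tied entries get the mean of their tied
ranks' reference values), an idempotent transform verified against
hand-worked examples. Each miRNA-vs-control contrast is scored by the
SAM relative difference
$d = (\bar{x}_T - \bar{x}_C)/(s + s_0)$, where $s$ is the pooled
standard error and $s_0$ an exchangeability constant. The default
$s_0$ is the median of the per-probe pooled standard errors: the
original percentile-search tuning is stochastic in implementation
detail, while the median is robust, deterministic, and close to it in
practice; $s_0$ is configurable, and must be positive when probes can
be constant (e.g. noise-free synthetic data).

With duplicate arrays the permutation null enumerates **all six
balanced relabelings** of the four columns rather than sampling —
randomness adds nothing when the group is this small. At each observed
$|d|$ threshold the estimated FDR is the median false-call count across
relabelings divided by the observed call count, capped at 1; q-values
take the running minimum over thresholds at least as liberal, making
them monotone non-increasing in $|d|$. Two consequences are worth
stating plainly: q-value granularity is set by six relabelings (of
which identity and its complement always count the observed calls), so
q-values are coarse; and the estimator is conservative, so at realistic
noise the recovered suppressed sets are reliable but incomplete subsets
of the planted truth. Null calibration (median zero calls at FDR 5%
over a hundred simulated null experiments) holds by test.

Suppressed probes satisfy fold change treated/control $\le 1/1.4$
("suppressed 1.4-fold or greater") at FDR $\le$ 5%; the stricter
$\ge 2.0$-fold gate produces the set handed back to pathway
over-representation. Fold-change comparisons are made on the log2 scale
with a $10^{-9}$ tolerance so planted shifts of exactly $\log_2 1.4$
survive floating-point round trips, and boundary cases ("exactly
2-fold") are included. Analysis stays at probe level; collapsing probes
to genes is left to the caller because no collapse rule is canonical.

## Co-repression overlap

`vennCounts()` classifies each member of the union of 2–4 suppressed
sets into its exact membership pattern ($2^k - 1$ regions; counts are
checked against brute-force element classification and always sum to
the union size). Pairwise association is a Pearson chi-squared on the
2×2 table over an explicit probe population $N$, without continuity
correction, as is standard for these contingency comparisons. $N$ — the
number of probes detected across all arrays — is a **required
argument**: whether "detected" means any array or all arrays is a data
processing decision the package cannot make, so it is never defaulted.
When an expected cell is zero the function refuses and points to the
exact option (`exact = TRUE`, the one-sided hypergeometric test), which
is also the recommended fallback for small expected counts. The
chi-squared and exact tails agree within 0.3 in $\log_{10} p$ on
enriched overlaps of balanced sets; for depleted overlaps the two are
not comparable (two-sided statistic versus one-sided enrichment tail),
which is why the comparison in the test suite is made on the
enrichment side where the test is actually used.

## Survival stratification

Patients are scored by the arithmetic mean of expression over a miRNA
panel (classically four 14q32 members) and split at the **joint cohort
median**; "greater than the group median" is read literally, so ties at
the median go to the low group. Kaplan–Meier curves use the product-limit
estimator with censoring ordered after events at equal times, and the
two groups are compared by the standard log-rank test (1 df). Five
years is interpreted as 60 months. Greenwood variances are available
from the underlying fit but are not used for testing. These are
textbook estimators, so they are delegated to the `survival` package
behind the package's own interfaces; the suite still verifies the hand
product-limit example, the equality of the KM curve with one minus the
empirical CDF under no censoring, and the log-rank statistic against an
independent observed-minus-expected tabulation.

## The synthetic-data generator

`synthConfig()` fixes the study conditions the pipeline is validated
under; `simulateBundle()` generates every input plus a
`ground_truth.json` sidecar so each stage can be scored for recovery.
All stages derive their RNG stream from the seed plus a fixed per-stage
offset: identical seed and configuration give bit-identical fixtures.

* **Panel and differential sets.** 377 miRNAs with 20 in one contiguous
  locus window; the total and locus counts are stand-ins (the real
  array's composition is not published) and stay configurable.
  Differential sets of 39 miRNAs are drawn by sequential weighted
  sampling without replacement (renormalized weights — the scheme base
  R's weighted `sample()` implements; stated explicitly because several
  unequal-probability schemes exist). The default locus odds of 17 was
  solved so the expected locus count is ~14 of 39, the configuration
  reported for surgical cohorts; the bundled SBRT-like set uses odds
  4.1 for an expected ~5 of 29. `plantDifferentialSet()` fixes the
  composition exactly when the printed fraction itself is wanted.
* **Pathways and target scores.** 20 pathways of 100–200 genes in a
  4000-gene universe, group labels cycling AIM/ICS/CSS. Background
  scores are uniform with a configurable above-threshold rate (0.3):
  the simplest background under which the hypergeometric null is exact.
  These dimensions were chosen so that null pathway overlaps are large
  (~30–60) and pathway sizes vary, making the discrete hypergeometric
  p-value effectively continuous — a requirement for the
  Kolmogorov–Smirnov uniformity check the suite runs at concentration
  zero. They are proportionally richer than genome-scale reality
  (thousands of targets in a ~20k universe against 50–300-gene
  pathways), trading literal scale for exact calibration at desk scale.
  Planted miRNAs draw a `targetingConcentration` fraction (0.5) of
  their above-threshold targets from designated pathways.
* **Transfection arrays.** 2000 probes, duplicate arrays per condition,
  probe baselines N(8, 1.5), homoscedastic Gaussian log2 noise
  (SD 0.25) — matching SAM's exchangeability assumption and keeping
  recovery tests analytic. Planted suppressed sets of ~150 probes per
  miRNA (the reported thousands of probesets scaled to the 2000-probe
  array) share 31% of their union between two or more miRNAs, the
  reported sharing level; the planted shift is 1 log2 unit.
* **Survival.** 24 patients per group. Group separation is built into
  the expression draws and the realized median split defines the
  event-generating groups, so split and hazard are consistent by
  construction. Event times are exponential with the high-expression
  group at $-\ln(0.6)/60$ per month (~60% recurrence-free at five
  years) and a low-vs-high hazard ratio of 3. A `censorRate` fraction
  (0.2) of patients drops out — censored with no event — at a uniform
  time before the 72-month horizon, plus administrative censoring at
  the horizon; rate 1 therefore yields an all-censored cohort. Random
  dropout slightly dilutes the observed event rate relative to the
  nominal hazards, which is irrelevant to null calibration (dropout is
  group-independent) and immaterial for the power checks run here.

What passing on these fixtures shows — and does not. The synthetic data
are Gaussian, homoscedastic, probe-independent, and free of batch
structure, array artefacts, missingness, and correlated genes inside
pathways. Green tests therefore demonstrate that the statistics are
implemented correctly and are calibrated and powered under their own
assumptions; they do not demonstrate robustness to the violations real
profiling data exhibit.

## Problem sizes used by the validation suite

Routine validation runs at the defaults above with: $10^5$ permutation
replicates for locus tests (50 random oracle-comparison instances and
20 end-to-end runs), 500 seeds for the pathway-null uniformity check,
200 seeds for the log-rank null, 100 seeds for SAM null calibration at
500 probes, and exhaustive enumeration up to $N = 12$ for the
hypergeometric oracle. These sizes give every stochastic check a
comfortable margin at conventional error rates while keeping the whole
suite in the low minutes on one core.

## Known limitations

* Target scores are consumed, not computed: no sequence-level binding
  model is included.
* The SAM permutation FDR with duplicate arrays is coarse (six
  relabelings) and conservative; with more replicates the same code
  enumerates all balanced relabelings of the larger design.
* Per-cell enrichment p-values are not multiplicity-corrected (a
  Benjamini–Hochberg pass can be applied downstream via
  `stats::p.adjust` on the cell table).
* Single prespecified locus per test: no multi-locus scan correction,
  no coordinate liftover, no miRBase version reconciliation.
* Probe-level differential expression only; gene collapse is the
  caller's responsibility.
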