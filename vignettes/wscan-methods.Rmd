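---
title: "The W-test: model, calibration and design choices"
author: "wscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The W-test: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wscan)
```

## The statistic

`wscan` tests the association between a binary phenotype and a *set* of
categorical genetic markers. A set of SNPs (each coded 0/1/2 by minor-allele
count), or a SNP together with a binarized CpG, partitions the cohort into
the k non-empty joint genotype categories actually observed. Against the
case/control split this gives a k-by-2 contingency table with cell counts
n~1i~ (cases) and n~0i~ (controls), class totals N~1~ and N~0~, and
conditional cell probabilities p&#770;~1i~ = n~1i~/N~1~,
p&#770;~0i~ = n~0i~/N~0~. The W statistic is

$$
W \;=\; h \sum_{i=1}^{k}
\left[\,\log\frac{\hat p_{1i}/(1-\hat p_{1i})}{\hat p_{0i}/(1-\hat p_{0i})}
\Big/ SE_i\right]^2 \;\sim\; \chi^2_f ,
$$

where SE~i~ is the Woolf large-sample standard error of the i-th log odds
ratio, $SE_i = \sqrt{1/n_{1i} + 1/(N_1-n_{1i}) + 1/n_{0i} + 1/(N_0-n_{0i})}$.
The per-category terms are squared Wald z-statistics of "category i versus
the rest"; they are correlated, so their sum is not chi-squared with k
degrees of freedom. The scale h and the degrees of freedom f absorb that
correlation: they are either category-count defaults or estimated from the
data's own permutation null (below). Because f adapts to the data set, the
test remains calibrated under genetic architectures — rare categories, many
near-empty cells — where a naive chi-squared reference drifts.

### Defaults for h and f

Without calibration the package uses f = k − 1 and h = (k − 1)/k. The choice
of h is forced by a boundary condition: at k = 2 the two per-category terms
are identical (the two log odds ratios are negatives of each other with the
same SE), so S = 2z² and only h = 1/2 makes W equal the squared Wald log-OR
z-statistic of the 2-by-2 table — the stated special case of the test. The
reciprocal convention h = k/(k − 1), which appears in some descriptions of
the statistic, would quadruple the statistic at k = 2; it is kept available
behind `compat = "printed"` for comparison, and nowhere else.

### Zero cells

Non-empty categories define k, so a fully empty cell never enters. A
category on the table margin (n~1i~ or n~0i~ equal to 0 or to its class
total) would make the log odds ratio infinite; such a category gets the
Haldane–Anscombe correction — 0.5 added to all four counts entering *that*
category's odds ratio — leaving k and all other cells untouched. Missing
genotypes are removed listwise per marker set, not per scan, so every test
uses the maximal complete data for its own set.

## Calibrating h and f from the permutation null

`w_calibrate()` runs B bootstrap replicates. Each replicate permutes the
phenotype labels (sampling without replacement — this preserves both the
genotype structure the adaptive f is meant to absorb and the case/control
totals, which subject resampling would not), draws `n_sample` marker sets of
the target order uniformly without replacement, and records the unscaled sum
S = Σz² with its k. Stratifying the draws by k and writing m = mean(S),
v = var(S), the moment-matched parameters are

$$ h = 2m/v, \qquad f = 2m^2/v, $$

the unique pair under which hS has the mean (f) and variance (2f) of a
χ²~f~ — a Satterthwaite-style two-moment fit. By construction h·m = f and
h²·v = 2f hold exactly; f is generally fractional and may exceed k − 1, and
the chi-squared survival function is evaluated at non-integer f throughout.
Strata with fewer than `min_per_k` draws (default 100) or zero variance fall
back to the defaults with a warning.

Defaults are B = 400 and `n_sample` = 1000: on a null cohort of 1,000
subjects and 200 SNPs the run-to-run coefficient of variation of the
calibrated h falls roughly as 1/√B and is in the sub-percent range by
B = 400, where the estimate is effectively converged. Phenotypes are
re-permuted per replicate (not per set); sets are drawn without replacement
within a replicate and independently across replicates. The SNP–CpG variant
`w_calibrate_snp_cpg()` draws (SNP, recoded CpG) pairs instead, so the null
category structure (k ≤ 6) matches the test that will consume the table.

## Scans, screening and multiple testing

`w_scan_main()` tests every polymorphic marker; constant markers are skipped
but still count toward the design size. `w_scan_interactions()` enumerates
all size-`order` combinations of the candidate markers; with `input_pval`
set, candidates are the markers whose *main-effect* p-value passes the
threshold. Main-effect screening is used for every order (including ≥ 3):
it matches the pairwise workflow, is the cheapest filter, and keeps the
screened set identical across orders. `output_pval` filters the report only
— it never changes which tests are performed or how thresholds are computed.

The Bonferroni annotation divides alpha by the *full* design count
C(n_markers, order), because that is how genome-wide thresholds are quoted
for two-stage scans (the screening is data-dependent, so the honest
family-wise denominator is the design, not the survivors); the
per-performed-test threshold is also reported. Ties in p are broken
lexicographically by marker id so reports are reproducible byte for byte.

`sample_size_feasibility()` gives the standard pre-scan check for high
orders: under HWE and marker independence the expected count of each of the
3^order joint cells is n times a product of genotype probabilities, and an
order is flagged feasible when at most 25% of cells expect fewer than 2
subjects.

## SNP–CpG interactions

Methylation beta values are binarized per CpG by two-means clustering
(`recode_methylation()`): Lloyd's algorithm with centers initialized at the
column minimum and maximum. This initialization makes the recode
deterministic and seed-free, and for one-dimensional data min/max
initialization cannot land in a worse local optimum than a random start.
Assignment updates stop when stable (at most 100 iterations); a point
equidistant from both centers joins the low cluster; the cluster with the
larger center is coded high (1). Each CpG is clustered independently —
pooling CpGs would let a plate-level shift in one site move another site's
threshold.

Candidate pairs are cis only: same (normalized) chromosome and base-pair
distance ≤ `window_size`, inclusive, strand-agnostic, with 10,000 bp as the
default window — the conventional cis-regulation radius for SNP–CpG
analyses. Each pair is then a 2-marker set whose joint categories (genotype
× methylation level, k ≤ 6) feed the same W machinery.

## Diagnostics

`w_diagnosis()` returns, per k, the observed W histogram
(Freedman–Diaconis bin widths with a floor of 10 bins), the χ²~f~ density at
that k's fitted f on a grid covering [0, 1.1·max W], and a
Kolmogorov–Smirnov distance as the numeric goodness-of-fit summary — the
quantitative version of "the fitted curve follows the histogram".
`qq_data()` returns expected-vs-observed −log~10~ p with expected quantiles
(i − 0.5)/n — chosen over i/(n + 1) because it is the standard GWAS QQ
convention and symmetric in the tails — plus the genomic-inflation-style
lambda (median observed χ²₁ quantile over its null median). Computation is
separated from rendering: both objects carry data, and `autoplot()` draws
them; tests assert on the data, never on pixels.

## The synthetic cohort generator

`sim_genotypes()` draws independent SNPs under HWE (genotype ~
Binomial(2, MAF)); `sim_phenotype()` implements a penetrance model on the
odds scale — baseline odds prevalence/(1 − prevalence), multiplied by `or`
for every effect whose target joint category the subject carries — so a
planted effect translates directly into the log odds-ratio terms the
statistic measures; `sim_methylation()` draws each CpG from a two-component
truncated-normal mixture on [0, 1] (defaults: means 0.2/0.8, sd 0.07,
mixing 0.5 — the bimodal shape of array beta values); `sim_positions()`
scatters markers uniformly over chromosomes and can plant SNP–CpG pairs at
exact distances. All generators are reproducible given a seed.

What the generator deliberately omits: linkage disequilibrium (SNPs are
independent), population stratification, quantitative phenotypes, covariates
and cell-type mixture in methylation. Tests passing on these cohorts
therefore demonstrate correctness of the statistic, its calibration and its
ranking behavior under clean nulls and planted effects — not robustness to
LD-induced correlation or confounding in real cohorts.

## Problem sizes used in the checks

The shipped checks run at desk scale, chosen so each property is measured
with useful precision: null calibration on 2,000 single-marker tests at
n = 800 (binomial 99% band of ±1.3 points around the 5% level);
moment-matching recovery at 50,000 draws per (scale, df) setting (relative
error well inside 5%); calibration convergence over B ∈ {50, 200, 400} with
20 repeats on a 1,000 × 200 null cohort; power ordering with 100 replicates
of a planted pair among 50 null pairs at n = 2,000.

For the power study the baseline case probability is 0.3 — case-control
cohorts for psychiatric and metabolic disease typically enrol one case per
two-to-three controls, and an unbalanced design is the harder, more
realistic setting for an odds-ratio-based statistic. With the planted effect
at odds multiplier 4 on the rare (2,2) double-homozygote cell at MAF 0.4
(cell frequency ≈ 2.6%, about 51 carriers at n = 2,000), the planted pair's
noncentrality sits near the upper tail of 50 null χ²₈ draws, so its top-1
rate is high but not overwhelming — around 0.8 in our runs. Raising the cell
frequency (MAF 0.5) or the multiplier pushes it to 1; we report the rate the
stated conditions actually produce rather than tuning the conditions.

## Known limitations

* P-values are asymptotic; no exact small-sample (Fisher-type) option.
* The Haldane–Anscombe policy is one defensible zero-cell treatment;
  alternatives (e.g. per-table rather than per-cell correction) would shift
  borderline statistics slightly.
* High-order scans are combinatorial; the package guards with `max_sets`
  and the feasibility check rather than attempting genome-wide order-3
  enumeration.
* Delimited text is the only input format (no PLINK/VCF ingestion); the
  readers validate entries and report cell coordinates on failure.
* The package's functions are the interface; there is no shell entry point,
  matching how this family of tools is used from R scripts.
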