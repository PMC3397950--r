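---
title: "Methods: methylation-biomarker discovery and evaluation with cervmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation-biomarker discovery and evaluation with cervmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervmeth)
```

# Overview

cervmeth implements a two-phase methylation-biomarker workflow. In the
discovery phase, MeDIP tiling-array probe intensities are scanned for
promoter regions enriched for methylated DNA in carcinoma but not in normal
epithelium, and the resulting gene list is narrowed by external evidence,
re-expression after demethylating treatment, and pooled MSP. In the
pre-validation phase, the surviving markers are quantified by QMSP in a
graded cohort and judged as diagnostic classifiers. This vignette explains
the statistical model behind each stage, the tunable parameters and their
defaults, what the synthetic-data generators do and do not emulate, and the
numerical choices made where the procedure was genuinely open.

# Enrichment calling on tiling arrays

## Centering

Array-to-array intensity offsets are removed by subtracting the Tukey
biweight mean of all probe log2 ratios. The estimator (`biweight_mean()`)
starts at the sample median with its scale fixed at the raw median absolute
deviation, reweights each value by $w_i = (1-u_i^2)^2$ for $|u_i|<1$ with
$u_i = (x_i - m)/(c\,\mathrm{MAD})$, and iterates the weighted mean to a
tolerance of $10^{-6}$. The tuning constant defaults to $c = 5$, a mild
setting that fully rejects only far outliers; when the MAD degenerates to
zero the median is returned. Because the median and MAD are
shift-equivariant, centering — and therefore every downstream call — is
invariant under a global shift of the log2 ratios, which the test suite
checks numerically. The estimator is verified against an independent oracle
that minimizes the corresponding bounded $\rho$ objective directly. Note
that with a fixed bulk and one gross outlier the estimate tracks the
*bulk's* center, which can lie on the far side of the median from the
arithmetic mean; robustness, not betweenness, is the estimator's contract.

## Windowed one-sided KS scoring

For each probe, the window is the set of probes on the same chromosome
whose interval midpoint lies within half the window width (default 500 bp,
so ±250 bp) of the probe's midpoint; the background is every other probe on
the array. The probe's score is $-\log_{10}$ of the one-sided two-sample
Kolmogorov–Smirnov p-value for the hypothesis that the window's centered
ratios are shifted positive relative to the background, using

$$D^+ = \sup_x\,[F_{\mathrm{bg}}(x) - F_{\mathrm{win}}(x)].$$

Three design points were open and are resolved as follows:

* **Window membership** is by probe midpoint around the anchor probe's
  midpoint — symmetric and independent of probe order.
* **Background** is the rest of the whole array, not the rest of the
  chromosome. The statistic compares a local window with the array-wide
  intensity distribution.
* **P-value regime.** For windows of at most `small_sample_exact_limit`
  probes (default 10, which covers the default geometry of ~5 probes per
  500 bp window at 100 bp spacing), the p-value is the *exact* permutation
  tail probability $P(D^+ \ge d)$ under random reassignment of the pooled
  values. For tie-free data this is computed by first-passage path counting
  over the lattice of pooled-order prefixes ($O(m^2)$ binomial terms, so it
  is exact even against backgrounds of tens of thousands of probes); with
  ties, a dynamic program over tie groups is used. Larger windows fall back
  to the one-sided asymptotic bound $\exp(-2 d^2 mn/(m+n))$, which is
  conservative. The regime boundary is configurable and recorded.

The exact regime gives a clean calibration guarantee: for any threshold
$s$, the per-probe chance of a null score reaching $s$ is at most
$10^{-s}$. The acceptance suite confirms both the exactness (equality with
full enumeration over all $\binom{m+n}{m}$ assignments for small problems)
and the null calibration at the default cutoff of 2.0 on 10,000-probe
arrays.

## Region calling and annotation

Probes scoring at or above `score_cutoff` (default 2.0) are merged into
regions when the genomic gap from the end of one qualifying probe to the
start of the next is at most `merge_gap` (default: the window width).
Regions keep their maximum member score as `peak_score` and are dropped if
supported by fewer than `min_probes_per_window` (default 2) qualifying
probes. Region construction is not fully pinned down by the array vendor's
published parameters; these defaults mirror the window geometry and are
configurable. The published cutoff is applied to per-probe scores (region
peak scores are retained, so a caller can re-threshold on maxima). A gene
is called enriched when any region overlaps its promoter interval by at
least one base, in 0-based half-open coordinates on both sides; genes hit
by several regions are reported once with their best peak score and the
region multiplicity as an attribute.

# Candidate triage

The funnel is pure set logic plus two thresholded filters, and every input
gene leaves it with a verdict and a reason, so retained and excluded sets
partition the input at each stage:

1. cancer-specific = (enriched in SCC ∩ enriched in AC) \\ enriched in
   Normal;
2. external evidence: keep genes present in the expression-down list or the
   T-DMR list (which list matched is recorded);
3. re-expression: keep genes whose fold change after demethylating
   treatment reaches `min_fold` (default 2.0) in at least `min_lines`
   (default 1) cell line. The published record shows bar charts without a
   numeric threshold, so both knobs are explicit and echoed in the run log;
4. an explicit, user-supplied assay-failure drop list (assay failure is not
   computable from data);
5. pooled-MSP exclusion: any methylation (`positive_level`, default 1 on
   the 0–4 ordinal scale) in a normal pool, a blood pool, or a blood flag
   excludes the gene;
6. prioritization: genes methylated in at least `min_cancer_pools`
   (default 5, "more than four") of the SCC/AC pools are prioritized,
   sorted by pool count then gene id.

Counts in the published funnel mix region- and gene-level units; this
module operates strictly at gene level and carries region multiplicity only
as an annotation.

# M-index quantification

$$\text{M-index} = 10{,}000 \times 2^{\,Cp_{\mathrm{COL2A}} - Cp_{\mathrm{gene}}}$$

The scale anchor is exact: equal crossing points give 10,000, and each
extra target cycle halves the index. A reference Cp above 36 cycles means
too little amplifiable input DNA, so the reaction is a *detection failure*:
the M-index is missing, never zero, and failed samples are excluded
listwise from all downstream statistics with a per-grade failure summary
always reported. The cutoff applies to the reference gene only — a high
target Cp is a legitimate low-methylation measurement. No floor or clipping
is applied to small indices.

# Diagnostic evaluation

`evaluate_marker()` reproduces the standard pre-validation battery:

* **Trend across grades**: Kruskal–Wallis on midranks with tie correction
  (via `stats::kruskal.test`), and Mann–Whitney against Normal per grade.
  For samples of at most 8 per arm the Mann–Whitney p-value is exact — the
  full permutation distribution of $U$ over the pooled midranks is computed
  by a shift-algorithm dynamic program (ties included) and the two-sided
  tail is $P(|U - mn/2| \ge |u - mn/2|)$; larger samples use the normal
  approximation with tie and continuity corrections.
* **Medians** per grade with percentile-bootstrap intervals (default 2000
  resamples, seeded; fewer than three observations yield a flagged point
  estimate).
* **Dichotomization**: cases are always an upper segment of the grade
  order. The three standard schemes are CIN2+/CIN1−, CIN3+/CIN2−, and
  SCC/SCC−.
* **AUC** by the Mann–Whitney identity with ties counted one-half, its
  interval by the DeLong placement variance truncated to [0, 1]. The test
  suite proves the identity against a brute-force pairwise oracle on every
  random input and cross-checks interval endpoints against pROC.
* **Cutoff**: the published operating points come without a stated
  criterion, so the default is Youden's $J$ maximized over observed values
  (ties broken toward higher specificity, then the larger value, making the
  choice deterministic), with a `fixed` mode to reproduce any given
  operating point. A sample exactly at the cutoff counts positive under the
  default `ge` rule (configurable).
* **Proportions** (sensitivity, specificity) carry Wilson score intervals;
  accuracy is reported as $(TP+TN)/n$ at the cutoff, *separately* from the
  AUC, because "accuracy" is used for both in the field.
* **Power** at the cutoff is that of the two-sided two-proportion z-test
  (pooled null standard error, unpooled alternative) at the observed arm
  sizes and $\alpha = 0.05$; it is validated against Monte-Carlo rejection
  frequencies of the same test. Degenerate 0/0 positivity is reported as
  undefined, flagged.

Interval methods (DeLong, Wilson, percentile bootstrap) are stated choices:
the originals do not say how their intervals were computed, and these are
the standard defensible options; each report records them.

# Synthetic data: what it emulates and what it does not

## Tiling arrays

`simulate_tiling_groups()` emulates a promoter tiling design: promoters of
1 kb are laid out to cover most of the simulated coordinate space (CpG
promoter arrays tile promoters, not intergenic space), probes every 100 bp,
and each group (SCC, AC, Normal) hypermethylates its own random promoter
subset. Defaults plant 30% of promoters in each carcinoma group and 5% in
normals — carcinomas methylate promoters widely on such arrays, normals
rarely. Planted probes get a mean log2-ratio shift of 1.5 over a baseline
of 0 with Gaussian noise of SD 0.5. Noise can be given a spatial
correlation length of 400 bp (a moving average matched to the 300–500 bp
sonication fragment size, with the marginal variance restored); setting
`fragment_smoothing_bp = 0` gives i.i.d. probes, which is the regime in
which the exact-p calibration guarantee applies and which the calibration
and recovery tests use. The generator returns the planted truth separately
from the data files — fixtures never embed their own answers.

Not emulated: two-channel image processing, dye bias, probe GC effects,
copy-number artifacts, or HPV covariates. Passing recovery tests therefore
show the scoring and calling machinery is correct and calibrated under the
stated noise model — not that real arrays are free of those artifacts.

## QMSP cohorts

`simulate_qmsp_cohort()` draws each sample's M-index log-normally around
its grade median ($\mathrm{meanlog} = \log$ median, `sdlog` defaulting to
1.5 — medians on a positive scale with wide intervals are the shape a
log-normal reproduces most simply), draws the reference Cp from
$N(30, 1)$, and sets the target Cp so the M-index formula inverts the draw
exactly — the round-trip through `cohort_m_indexes()` is exact to floating
point and is asserted at $10^{-9}$ relative error. A configurable fraction
of samples (default 1%, matching the small attrition between enrolled and
analyzed sample counts in the emulated cohort) receives a reference Cp
above 36 to exercise the failure rule. Default grade medians and sizes are
the published ZNF582 values (0.01/0.06/0.19/1.71/31.95 at
156/55/31/46/39). Pooled samples are treated as single samples; whether
pooled DNA averages methylation linearly is not modeled.

Because the arms are mixtures of log-normals, the generator's true AUC has
a closed form (`cohort_true_auc()`):
$\sum_{c,k} w_c w_k\,\Phi\!\big((\mu_c - \mu_k)/\sqrt{\sigma_c^2+\sigma_k^2}\big)$,
which the acceptance suite uses as the recovery target at cohort sizes
$n$ and $10n$. Under the default dispersion the synthetic CIN3+ AUC
(≈0.98) is higher than real cervical-scraping cohorts achieve; the
generator is a correctness instrument, not a forecast of clinical
performance.

# Numerical and engineering choices

* Coordinates are 0-based half-open internally and BED on disk; interval
  overlap is delegated to GenomicRanges/IRanges.
* All tabular interchange is TSV with a header; every writer's output is
  re-readable by the matching reader (round-trip tested). Missing Cp values
  are empty fields, never 0.
* One top-level seed drives everything: stage seeds are the first draws of
  `sample.int` under that seed, so each stage is independently
  reproducible, and re-running a pipeline configuration reproduces its
  output directory byte for byte.
* Exact-p path counting accumulates binomial terms in double precision;
  the largest intermediate is $\binom{m+n}{m} \lesssim 10^{40}$ at the
  default exact limit, far inside double range, and the acceptance suite
  pins equality with enumeration to $10^{-11}$.
* Test and acceptance problem sizes (10,000-probe arrays, 10–20 seeds,
  10,000-replicate calibrations, cohorts up to 3,270) were chosen so the
  whole battery completes in a few minutes while keeping Monte-Carlo
  tolerances meaningful; the vignette-level claims above are exactly the
  properties the suite computes, no more.

# Known limitations

* The exact KS p-value assumes exchangeability; spatially correlated noise
  (`fragment_smoothing_bp > 0`) inflates local dependence, and the score
  threshold is then conservative in rate terms only on average — the null
  calibration guarantee is proven for the i.i.d. regime.
* Whether the original array software scored windows against the whole
  array or per chromosome is not documented; the whole-array reading is
  implemented. Both readings coincide on single-chromosome simulations.
* The asymptotic one-sided KS bound overstates p slightly for moderate
  windows, so scores just below the cutoff in that regime are conservative.
* Region-level multiple-testing control beyond the score cutoff is
  deliberately absent, matching the emulated analysis.
* The triage funnel reproduces mechanism, not the original gene identities,
  which would require reprocessing the original deposits.
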