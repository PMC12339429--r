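---
title: "Methods: disproportionality signals and two-sample Mendelian randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signals and two-sample Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvmr)
```

`pvmr` pairs two study designs that answer different questions about a
drug–adverse-event association. Disproportionality analysis of a
spontaneous reporting system (SRS) asks whether the event is co-reported
with the drug more often than independence would predict — an association
signal, confounded by everything that shapes reporting. Two-sample
Mendelian randomization (MR) asks whether genetically proxied exposure
shifts the outcome — a causal contrast, valid under its own, different
assumptions. This vignette records the models, the parameter choices, the
numerical conventions, and what the simulation-based tests do and do not
establish.

## 1. The spontaneous-report store

Reports are held in a long layout (one row per report, per drug mention,
per MedDRA preferred term). Ingest normalizes drug names (lower-case,
collapsed whitespace, optional user-supplied synonym map — no standard
dictionary is bundled because none is freely redistributable), codes sex
as female/male/unknown, maps outcomes onto a fixed token set, and treats
unparseable or out-of-range ages as missing without dropping the row.
Rows lacking a report id or any parseable PT code are uncodable and are
skipped with a count.

**Deduplication.** SRS extracts contain versioned resubmissions and
cross-listed duplicates. Among records sharing the composite key
(report id, sex, country) exactly one survives: highest case version,
then latest receipt date, then last position in file order. The key
matches how duplicate submissions are recognized in practice; the
tie-break order is a determinism convention of this package (sources
rarely document theirs), chosen so that re-running ingest can never
reorder survivors.

**Age bands.** Two schemes are provided: a descriptive scheme
(0–11, 12–17, 18–34, 35–64, 65–79, ≥80) for demographic tables, and a
regression scheme of four half-open bands [0,18), [18,45), [45,66),
[66,∞) used as model covariates. Half-open bands guarantee that every age
maps to exactly one band; the printed rendering of the labels is
configurable because reporting conventions vary (e.g. "18–44" vs
"18–45").

## 2. Disproportionality statistics

All three statistics compare the observed count *a* of reports carrying
both the target drug and the target event against its expectation under
independence within the database, from the 2×2 table (a, b, c, d),
N = a+b+c+d:

* **ROR** = ad/bc with the log-normal interval
  exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d)); criterion a ≥ 3 and lower limit
  > 1.
* **PRR** = [a/(a+b)]/[c/(c+d)] with the Pearson χ² of the table;
  criterion a ≥ 3, PRR ≥ 2, χ² ≥ 4.
* **IC** = log2((a+0.5)/(E+0.5)), E = (a+b)(a+c)/N, with the standard
  approximate lower credibility bound
  IC025 = IC − 3.3(a+0.5)^−1/2 − 2(a+0.5)^−3/2; criterion IC025 > 0.
  This is the shrinkage observed-to-expected form in the Bayesian
  confidence propagation tradition; the +0.5 shrinkage keeps every cell
  configuration finite and pulls small-count estimates toward zero.

A pair is a **signal** when at least two of three criteria fire. The
two-of-three rule guards against any single method's small-sample
pathologies.

Numerical conventions, each exposed as an argument:

* **Zero cells.** The Haldane–Anscombe 0.5 is added to all four cells for
  the ROR and PRR point estimates when any cell is zero (the result is
  marked `corrected`); the χ² is always computed on the uncorrected
  counts; a zero drug or comparator margin is a domain error. The a ≥ 3
  criterion always refers to the uncorrected count.
* **χ² continuity correction.** Pearson without Yates correction by
  default — the more common choice in the pharmacovigilance literature —
  with `yates = TRUE` available for auditability.
* **Volcano statistics.** For each PT co-reported with the drug, the
  two-sided Fisher exact p (hypergeometric enumeration with the customary
  (1+1e−7) tie tolerance) is Bonferroni-adjusted by the number of
  distinct PTs tested *for that drug* — the per-drug framing matches the
  plot the numbers feed, and avoids penalizing by the tens of thousands
  of MedDRA terms never observed with the drug. The x-axis value is
  log10 ROR.

## 3. Clinical-priority triage

Signals are graded 0–2 on four criteria and summed (0–8): clinical
relevance (designated medical event 2, important medical event 1,
neither 0), reporting rate among the drug's reports (≥10% → 2,
[1%, 10%) → 1, below 1% → 0), case fatality among the event's reports
(>50% → 2, [25%, 50%] → 1, below 25% → 0), and stability (3 of 3 methods
positive → 2, 2 of 3 → 1, else 0). Totals 0–2/3–5/6–8 map to
low/moderate/high priority. Published tables print the middle bands with
overlapping edge labels; the edges implemented here are fixed by the
worked cells those tables also print (a rate of exactly 1% scores 1, a
fatality of exactly 25% or 50% scores 1). DME/IME membership is an input
flag: the EMA lists are licensing-encumbered, so no lookup is bundled.
Scoring eligibility defaults to "at least one method positive"
(`priority_gate = "any"`), the broader of the two gates in circulation,
with the stricter majority gate available.

## 4. Report-level logistic regression

The binary target-event indicator among the drug's reports is modelled on
age band and sex by maximum likelihood (IRLS via `stats::glm`,
convergence tolerance 1e−10, 50-iteration cap), reported as odds ratios
with Wald 95% intervals (exp(β̂ ± 1.96·SE)) and Wald p-values — the
presentation used in the field's result tables, hence Wald rather than
profile intervals. Records with unknown age or sex are excluded listwise;
a coefficient diverging beyond 15 on the log-odds scale is reported as
(quasi-)separated with infinite-interval markers instead of a spurious
number. Covariates are screened univariably at α = 0.05 and only
screen-passers enter the multivariable model — the screen-then-adjust
flow standard in this literature.

## 5. Two-sample Mendelian randomization

**Instrument selection.** Exposure SNPs are screened at p < 5e−6 (the
threshold appropriate for a small protein GWAS, where genome-wide 5e−8
would leave too few instruments; both are plain arguments), greedily
LD-clumped (retain the smallest-p SNP, discard same-chromosome SNPs
within 10,000 kb with r² > 0.001 against it, repeat), and filtered to
F = (β/se)² > 10, the conventional weak-instrument bar. Absent LD
entries are treated as unlinked; every exclusion is logged with a reason
so panel attrition is auditable.

**Harmonization.** Panels are intersected on SNP id and the outcome
effect aligned to the exposure's effect allele, flipping the sign and
complementing the allele frequency when the alleles are swapped (directly
or after strand complement). Palindromic A/T and C/G SNPs with exposure
allele frequency in [0.42, 0.58] are dropped as strand-unresolvable; the
window is an argument.

**Estimators.** With aligned effects (β̂ₓⱼ, β̂ᵧⱼ) and first-order weights
wⱼ = se(β̂ᵧⱼ)⁻²:

* **IVW** (primary): weighted regression through the origin,
  β̂ = Σwβ̂ₓβ̂ᵧ / Σwβ̂ₓ²; multiplicative random-effects SE, inflating the
  fixed-effect SE by max(1, √(Q/(k−1))) so heterogeneity can widen but
  never narrow the interval; normal reference. Consistent when all
  instruments are valid.
* **MR-Egger**: weighted regression with a free intercept after orienting
  every instrument to its exposure-increasing allele (the slope is
  orientation-invariant; the intercept is only interpretable as
  directional pleiotropy under a common orientation). The slope is
  consistent under the InSIDE assumption even when all instruments are
  pleiotropic. Inference uses the t reference with k−2 df. The slope SE
  carries the same truncated inflation as IVW; the intercept test uses
  the exact weighted-least-squares t-test (untruncated residual
  variance). The asymmetry is deliberate: a causal-effect interval should
  never be narrower than its fixed-effect counterpart, but a diagnostic
  test must hold its nominal size — with truncated inflation the
  intercept test's empirical size collapses to well under 1%, making it
  nearly blind as a pleiotropy alarm.
* **Weighted median**: interpolation of the ordered per-SNP Wald ratios
  at cumulative weight one half, weights se(ratio)⁻² (first order);
  consistent when ≥50% of the weight is valid. SE by seeded parametric
  bootstrap (per-SNP effects redrawn from their normal sampling
  distributions; default 1000 draws).
* **Simple/weighted mode**: argmax of a normal-kernel density of the
  ratios on a 512-point grid spanning the ratios ± 3 bandwidths;
  bandwidth is the modified Silverman rule 0.9·min(sd, mad)·k^−1/5
  (falling back to the sd when the MAD degenerates to zero under
  majority ties) times a `bandwidth_factor` (default 1); consistent under
  plurality validity. SE by the same bootstrap.

**Diagnostics.** Cochran's Q (residual weighted SS about the IVW or Egger
fit, χ² on k−1 or k−2 df); the Egger intercept test; MR-PRESSO (observed
leave-one-out residual sum of squares ranked against ≥1000 seeded
parametric simulations under the fitted no-outlier model, with per-SNP
outlier p-values Bonferroni-adjusted by k); leave-one-out IVW re-fits
with an influence flag when any re-fit leaves the full-set interval. A
single pipeline seed drives every bootstrap and simulation.

## 6. What the generators emulate — and what they do not

`simulate_srs()` plants one drug–event association in an otherwise
independent report stream: drug ~ Bernoulli(p), event probability
multiplied by a relative risk on drug reports (optionally shifted on the
logit scale by age band), decoy PTs independent, demographics drawn from
fixed category frequencies. Defaults (200,000 reports, drug prevalence
0.5%, background event rate 3×10⁻⁴, relative risk 12, demographic
frequencies mirroring published brain-neoplasm report characteristics
including 45% unknown age) reproduce the rare-event regime in which the
disproportionality statistics are actually used, where expected ROR ≈
planted RR. Not emulated: drug co-prescription correlation, reporting
trends over time, stimulated-reporting waves, or MedDRA term hierarchy —
so passing tests show the statistics are correct under independence and
planted association, not that real SRS confounding is handled.

`simulate_gwas_pair()` draws true exposure effects uniformly in
magnitude 0.10–0.45 (random allele orientation applied afterwards, as
allele coding in real summary data is arbitrary), observes them with
SE 0.03 — the instrument-strength regime of a ~3,300-sample protein
GWAS, F roughly 11–225 — and generates outcome effects as
β_causal·βₓ + pleiotropy + heterogeneity + noise at SE 0.15, the scale of
a ~179,000-sample binary-trait GWAS. Directional pleiotropy is planted in
the exposure-increasing orientation, which is the frame in which
"directional" is identifiable at all. Defaults: k = 9 instruments and
true log-OR 0.347 (OR ≈ 1.41), the scale of the motivating analysis.
Two-sample independence and absence of sample overlap are assumed, as in
the design itself. Because observed p-values fluctuate around the
selection threshold, a simulated panel run through the full pipeline may
lose instruments at selection — deliberate, and mirrored in the exclusion
log.

## 7. Numerical and testing conventions

All 95% intervals use the conventional 1.96. Degenerate inputs fail
loudly with the stage name (`[mr_egger] ...`), never silently: empty
report sets, zero margins, constant exposure effects (Egger
unidentifiable), empty instrument sets after selection. The
single-instrument Wald ratio is available only behind an explicit
`allow_single` flag. Pipeline run logs carry the package version and an
md5 fingerprint of the analysis-relevant configuration (output paths
excluded), and contain no timestamps, so reruns are byte-identical.

The test suite's problem sizes are chosen to estimate each calibration
quantity to useful Monte-Carlo precision at interactive cost: 200
replicates for bias/coverage/size checks (MC-SE of a coverage estimate
≈ 1.5 points), 500 for type-I error, 100 paired runs for MR-PRESSO
specificity/sensitivity, 1000 random tables for oracle-equivalence
checks, and SRS calibration at 50,000–200,000 reports where the
rare-event asymptotics the statistics rely on actually hold. Mean-bias
assertions use the two-sided 2·MC-SE bound that an unbiased estimator
passes with 95% probability.

## 8. Known limitations

* The IC's credibility bound is the standard closed-form approximation,
  not the exact posterior quantile; differences are visible only at very
  small a.
* The weighted median and mode standard errors are bootstrap-based and
  therefore seed-dependent at the third decimal for the default 1000
  draws.
* MR-Egger's slope is attenuated under weak instruments (measurably so at
  F near the inclusion bar), so its point estimate should be read as a
  consistency check on IVW, not a replacement — the usual reading.
* Listwise deletion of unknown age/sex assumes missingness unrelated to
  the event given the drug, which in real SRS data is optimistic.
* The clumping implementation is greedy and quadratic in candidate count;
  it is intended for instrument panels (tens to hundreds of SNPs), not
  genome-wide clumping.
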