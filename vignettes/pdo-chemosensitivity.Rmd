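---
title: "Scoring organoid chemosensitivity and linking it to outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring organoid chemosensitivity and linking it to outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciws)
```

## The problem

Neoadjuvant chemotherapy (NAT) is standard of care in osteosarcoma, but
response varies widely and radiology reports it late. Patient-derived
organoids (PDOs) grown from biopsy or resection tissue can be exposed to
the actual drugs of the treatment regimen ex vivo, producing a functional
readout weeks before imaging can. This package implements the analysis
chain for such screens: converting live/dead readouts into scores,
grading residual proliferative capacity, labelling clinical ground truth,
and quantifying how well the ex vivo scores anticipate it.

## The scores

**SCIR.** Each drug's raw readout is a cell inhibition rate (CIR), the
percentage of dead cells after 96 h of exposure. Untreated organoids die
spontaneously at some background rate, so the standardized rate is
`SCIR = CIR_drug - CIR_control`, clamped to [0, 100]. The clamp at zero
is deliberate: the quantity models the kill fraction *attributable to the
drug*, which cannot be negative; an excess of control death is assay
noise, not drug protection.

**Tiers.** SCIR is discretized into four ordinal efficacy tiers:
`-` (< 30%), `+` (30 to < 60%), `++` (60 to < 80%), `+++` (>= 80%).
Lower bounds are inclusive throughout, so the boundary values 30/60/80
fall in the upper tier and 100 maps to `+++`.

**CIWS.** The cell inhibition weighted score sums the tier values
(0--3) of the four MAPI drugs — methotrexate, doxorubicin, cisplatin,
ifosfamide — giving an integer in 0--12. Carboplatin is screened and
reported but never enters the sum; the `regimen` argument makes that
explicit and overridable. A sample is called sensitive when CIWS >= 5.
Note the score is a sum of ordinal *tier values*, not of raw SCIRs: the
tier-sum definition is the one that reproduces the worked example below
(a 5+/3+ paired course), and summing raw percentages would put the score
on a 0--400 scale where the 5+ cutoff is meaningless.

```{r}
ex <- pdo_example_tiers()
compute_ciws(ex$pre)
compute_ciws(ex$post)
delta_ciws(compute_ciws(ex$pre), compute_ciws(ex$post))
```

## OFP grading

Organoid formation potential grades the culture's proliferative capacity:
I (robust), II (intermediate), III (minimal/non-forming). The published
definitions are partly qualitative ("abundant" vs "few" EdU-positive
nuclei), so the decision tree in `grade_ofp()` is one consistent
operationalization, with thresholds exposed in `ofp_thresholds()`:
EdU-positive fraction >= 0.40 for grade I, < 0.05 forcing grade III,
minimum cluster diameter 30 µm, robust diameter > 100 µm, and a 3-week
(day-21, inclusive) formation window inside a 28-day observation period.
Two choices deserve note. First, when features conflict — a large
cluster with near-zero EdU — proliferation dominates and the culture is
grade III, because OFP is defined as a proliferation metric. Second,
grade I additionally requires sustained growth; robust-looking cultures
whose expansion declines fall to grade II. For outcome stratification
grade I forms the high-growth-potential group and II/III the low group:
after chemotherapy, *low* residual formation potential is the favourable
state.

## Clinical ground truth

`classify_recist()` applies the RECIST 1.1 target-lesion rules to
sum-of-longest-diameter (SLD) measurements with a fixed evaluation order
CR → PD → PR → SD. PD takes precedence over PR when growth from a deep
nadir coexists with a large drop from baseline (standard RECIST
ordering), ratios are compared exactly without rounding, and a baseline
SLD of zero without vanished target lesions is an error rather than a
silent division. Responder/nonresponder binarization keeps only PD as
nonresponse, and all concordance tables use the *adverse* outcome as the
positive class. Five-year disease-free survival is labelled with an
inclusive 60-month benchmark; patients censored earlier are
`INDETERMINATE` and are excluded from accuracy denominators (and counted
in the report) rather than imputed.

For paired pre/post analyses RECIST categories are coded CR = 3, PR = 2,
SD = 1, PD = 0, so a falling ordinal means worsening — the same sign
convention as a falling CIWS. Directional concordance compares the signs
of the two paired deltas, and the rank correlations are computed between
ΔCIWS and ΔRECIST-ordinal directly (concordant courses give positive
coefficients under this coding; reports that code RECIST with higher =
worse negate their delta to achieve the same thing).

## Cutpoint selection

`maxstat_cutpoint()` dichotomizes an ordinal score against survival by
maximally selected rank statistics, deliberately restricted: candidates
are the ordinal midpoints {3.5, 4.5, 5.5}, each side of an admissible
split must retain at least `ceiling(minprop * n)` subjects
(minprop = 0.25), and the admissible candidate maximizing the two-group
log-rank statistic wins. Restricting to three interpretable midpoints
instead of scanning all observed values trades a little power for
stability and interpretability at small n. Ties are broken to the
*lowest* candidate: deterministic, and it favours the larger sensitive
group. Per-candidate p-values are ordinary log-rank tail probabilities
and are labelled unadjusted for selection — with three candidates and
n ≈ 23 a maximal-selection correction would be far more conservative
than the published analysis, and the selected midpoint, not its p-value,
is the deliverable. Stability is assessed by resampling subjects with
replacement (B = 1000 by default, seeded); resamples where a candidate
loses admissibility skip it, and resamples with no admissible candidate
are tallied in a `none` bucket so the frequencies always sum to 1.

## Survival machinery

Kaplan--Meier estimation, the log-rank test and the binary-covariate Cox
model are delegated to the `survival` package (product-limit estimator;
hypergeometric-variance log-rank with simultaneous risk-set evaluation
at ties; Breslow tie handling and Newton iteration to gradient tolerance
1e-9 for the partial likelihood), wrapped behind this package's
interfaces so that the cutpoint search and the reporting layer share one
implementation. The wrappers add the guard rails the small-cohort
setting needs: a group with zero events makes the partial likelihood
monotone, so the fit is flagged non-estimable and the coefficient capped
instead of reported as a plausible number, and Wald intervals are
flagged whenever a group has fewer than five events. Group mean survival
is reported under *both* the arithmetic mean of follow-up times and the
restricted mean survival time (area under the KM curve to a 60-month
horizon), tagged by method, because published figure captions rarely say
which estimator they used; with complete follow-up to the horizon the
two coincide.

## Exact small-sample statistics

At n = 13--18 asymptotic intervals are untrustworthy, so everything is
exact: Clopper--Pearson beta-quantile intervals for every proportion;
an exact binomial test of accuracy against 0.5 whose default sidedness
is the one-sided upper tail (the form consistent with the worked
example's printed p-values of 0.004 at 15/18 and 0.011 at 11/13;
two-sided doubling is available via an argument); and an exact McNemar
test that doubles the smaller binomial tail of the discordant counts and
caps at 1. Cohen's kappa is unweighted, for 2x2 and for the 3x3
directional table alike. Rank correlations use average ranks (Spearman)
and the tie-corrected tau-b (Kendall); for n <= 10 pairs their p-values
come from exhaustive enumeration of all permutations (a small compiled
routine — 10! arrangements — cross-checked in the tests against a naive
R enumeration at n = 6), switching to the usual asymptotics above that.

## The synthetic cohort

`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes, so every stage is testable with known ground truth and
no external data. The defaults describe the study design the package
targets: 23 patients, 31 samples (18 pre-NAT, 13 post-NAT, 8 paired),
five drugs, latent sensitivity prevalence 0.6.

Choices worth explaining:

* **Bounded noise.** Per-drug SCIRs are drawn as
  `100 * Beta(k*m, k*(1-m))` around a per-sample potency `m`, itself
  beta-distributed per latent class (means 0.68 sensitive / 0.36
  resistant, concentration k = 35). A bounded-scale model respects
  [0, 100] without the distortions post-hoc clamping of Gaussian noise
  would introduce.
* **Potency persists within a patient.** Paired pre/post samples share
  their potency unless the latent class flips (probability 0.25 of
  acquired resistance per sensitive patient), so a biologically stable
  patient shows a stable CIWS up to assay noise, and an acquiring
  patient shows the characteristic 5+ → 3+ style drop.
* **Survival attaches to the realized CIWS class.** Hazards are
  exponential per class — resistant median DFS 7 months, sensitive
  hazard multiplied by the true hazard ratio (default 0.2) — keyed to
  the *realized* CIWS >= 5 classification of the patient's latest
  sample. That makes 4.5 the exact ground-truth midpoint by
  construction, which is what the recovery tests need; overall survival
  adds an exponential post-progression time (mean 18 months), and both
  endpoints are administratively censored at 60 months (the default
  cohort is fully followed, as validation cohorts of this kind are).
* **Labels are generated inside their defining regions.** Lesion
  trajectories are drawn so the intended RECIST category is recovered
  exactly by the classifier, and culture features inside the intended
  OFP grade's region of the decision tree — the generator tests assert
  this self-consistency at 100%.

What the generator does *not* emulate: pharmacokinetics, dose--response
shape (screens use single fixed concentrations), correlation between
specific drugs, inter-rater variability in RECIST reads, or non-random
censoring. Passing recovery tests therefore show that the pipeline's
statistics are computed correctly under the assumed structure — not that
the structure captures every feature of real cohorts.

## Problem sizes and numerical choices

The recovery suites use cohorts of n = 200 (100 seeds) for cutpoint
recovery and two arms of 200 (100 seeds) for Cox hazard-ratio recovery —
large enough that recovery failures indicate defects rather than
sampling noise, small enough to run routinely. Interval coverage is
checked with 10^4 binomial draws per (p, n) combination. Log-rank and
exact tests are verified against first-principles oracles (explicit
risk-set tables; term-by-term pmf summation; recursive permutation
enumeration) on cohorts up to n = 25, where the oracles are fast and
unarguable. Ties in the cutpoint statistic are resolved with a 1e-8
tolerance; survival gradient tolerance is 1e-9; no p-value or proportion
is rounded before comparison, only for display (one decimal in percent).

## Interfaces

The package is function-first: `simulate_cohort()` → `score_samples()` /
`grade_ofp()` / `classify_recist()` → `maxstat_cutpoint()` /
`concordance_report()` → `run_reproduction()`, with `read_cohort()` /
`write_cohort()` / `write_report()` owning the CSV contracts (UTF-8,
header row, flags as 0/1, months as decimals, `"5+"` notation parsed on
read). These functions, plus `scripts/acceptance.R` at the repository
root, are the command surface; a separate shell CLI would only wrap
them.

## Known limitations

The OFP decision tree is one consistent operationalization of partly
qualitative published definitions, with thresholds exposed rather than
claimed authoritative. The cutpoint's per-candidate p-values are
unadjusted for selection by design. Directional kappa for the 3-level
paired comparison is unweighted; a weighted variant would need a
justification the small tables cannot provide. And every cohort-level
survival quantity in this package's reports is computed from synthetic
or user-supplied cohorts — the package validates its statistics against
worked-example confusion counts and against generator ground truth, not
against any deposited patient-level dataset (none exists for this study
design).
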