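---
title: "Comparing peak V̇O2 prediction equations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing peak V̇O2 prediction equations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vo2compare)
```

## The problem

Cardiopulmonary exercise testing expresses a patient's measured peak oxygen
uptake relative to a predicted value,
$$\mathrm{pp} = \frac{\dot{V}O_{2\,peak}^{measured}}{\dot{V}O_{2\,peak}^{predicted}} \times 100,$$
and interpretation schemes classify exercise capacity as *normal* when
$\mathrm{pp} \ge 80\%$ (the comparison is always on the continuous value;
the threshold is inclusive). Different laboratories' software defaults to
different prediction equations, which were derived in different
populations, exercise modalities and eras. This package quantifies how much
that choice matters — for an individual (the dashboard and sweep curves)
and for a cohort (agreement statistics and difference regressions).

## The six equations and the registry

The registry (`inst/extdata/equations.yaml`) holds one block per equation:
its functional form, coefficients (per sex, and per mode where the equation
is modality-specific), native units, and validity domain. All predictions
are returned in absolute mL/min.

* **FRIEND** — a single registry-wide equation in native imperial units:
  relative V̇O2peak (mL/kg/min) $= 45.2 - 0.35\,\mathrm{age} - 10.9\,\mathrm{sex}
  - 0.15\,\mathrm{wt}_{lb} + 0.68\,\mathrm{ht}_{in} - 0.46\,\mathrm{mode}$,
  with sex coded male = 1 / female = 2 and mode treadmill = 1 / cycle = 2,
  multiplied by body mass in kg for the absolute value. The mode term makes
  it modality-specific, so it never receives the external correction.
* **Wasserman** — the weight-based cycle form without ideal-weight
  branching: men $\mathrm{wt}\,(50.72 - 0.372\,\mathrm{age})$, women
  $(\mathrm{wt}+43)\,(22.78 - 0.17\,\mathrm{age})$ mL/min.
* **Hansen** — the later ideal-weight-branched edition of the same scheme.
  With ideal weight $W_i$ (men $0.79\,\mathrm{ht} - 60.7$, women
  $0.65\,\mathrm{ht} - 42.8$ kg): at or above $W_i$ the prediction is the
  Wasserman form evaluated at $W_i$ plus 6 mL/min per kg of excess mass;
  below $W_i$ it is the Wasserman form at the midpoint $(W + W_i)/2$. The
  branches meet at $W = W_i$, where Hansen equals Wasserman exactly (a unit
  test asserts both the collapse and continuity). For treadmill tests the
  cycle result is scaled by 1.11 *inside* the equation — it is
  modality-specific, so its `correction_applied` is always 1.
* **Bruce** — treadmill, per-kg, age-only, sedentary-adult forms (men
  $57.8 - 0.445\,\mathrm{age}$, women $42.3 - 0.356\,\mathrm{age}$
  mL/kg/min). The original publication also reports active-adult
  coefficients; the sedentary set was chosen once because the package's
  target users evaluate clinical referral populations. Both live in the
  registry and are swappable without code changes.
* **Jones** — cycle, absolute form
  $0.046\,\mathrm{ht} - 0.021\,\mathrm{age} - 0.62\,[\mathrm{female}] - 4.31$
  L/min.
* **Neder** — cycle, sex-specific age + weight forms in mL/min. Of the six
  coefficient sets this is the one we could least firmly pin to its
  original publication; it is deliberately registry-isolated so a corrected
  set can be dropped in by editing one YAML block. The female block was
  scaled from the male one by a typical female/male aerobic-capacity ratio.
  No headline result in this package depends on it.

**Modality correction.** For the four equations with a single native mode,
comparing against a test in the other modality applies a fixed factor:
cycle-native prediction vs treadmill test ×1.11, treadmill-native vs cycle
test ×0.89. The −11% direction is implemented literally as ×0.89 rather
than ÷1.11; the two differ by about 1%, and the factors are named constants
(`mode_correction_factors()`) so either convention can be audited. Unit
conversions are fixed at 1 lb = 0.453592 kg, 1 in = 2.54 cm.

**Domains.** Equation domains default to the subject-record bounds (age
15–90, height 120–220 cm, weight 30–250 kg). A subject outside an
equation's *source-study* age range is predicted anyway but with a warning,
because in clinical practice every equation is routinely applied beyond its
derivation sample; refusing would make the comparison impossible for most
real referrals.

## Display conventions

Two integer display rules coexist deliberately. The equation-comparison
calculator truncates (floor): 68.33% displays as 68, 114.64% as 114.
Metabolic-cart derived-variable panels round half up: 81.52% displays
as 82. Both are exposed through named arguments (`display_percent()`,
`percent_of_predicted()`), and classification never uses a display value.

## Agreement statistics

For a cohort, percent predicted is computed per subject per equation
(an $n \times 6$ matrix) and summarized three ways:

* **Cohen's κ** between each pair's normal/reduced classifications,
  $\kappa = (p_o - p_e)/(1 - p_e)$ with marginal-product chance agreement;
  perfect observed agreement returns exactly 1, which also resolves the
  two-identical-constant-raters case where $p_e = 1$. Interpretation bands
  are half-open (`[0.21, 0.41)` fair, `[0.41, 0.61)` moderate, ...) so the
  touching endpoints of the conventional verbal scale label
  deterministically.
* **Reclassification**, counted in both directions (reduced→normal and
  normal→reduced) with the symmetry `n_to_normal(a,b) = n_to_reduced(b,a)`
  checked as a property test.
* **Absolute differences** $|pp_a - pp_b|$, summarized by median and
  quartiles under the linear-interpolation convention (R quantile type 7);
  the convention is echoed in the output because these quartiles are
  reported values.

The global test is **Friedman's rank test** with effect size **Kendall's
W**. The statistic is computed from the classical rank-sum formula on
within-subject ranks, with mean ranks on ties and *no* tie-correction
denominator, so that $W = \chi^2 / (n(k-1))$ holds as an exact identity.
The test suite checks the statistic against an independent brute-force
oracle (ranks rebuilt from pairwise comparisons) on 200 random matrices and
against the tie-corrected reference implementation on tie-free matrices,
where the two coincide. Post hoc, all $k(k-1)/2$ pairs are compared with
paired Wilcoxon signed-rank tests and Bonferroni adjustment
($p_{adj} = \min(1, 15\,p_{raw})$ for six equations); an all-zero
difference vector gets $p = 1$ by convention. "Exact all-pairs" procedures
vary between implementations, so the method name is recorded in the report
and can be swapped without changing the report schema.

## Difference regressions

For each pair, the *signed* difference in continuous percent predicted
(corrected values) is regressed by OLS, with intercept, on scaled
covariates: age per decade, BMI per 5 kg/m², female (ref male), treadmill
(ref bike), and race indicators with white as reference
({white, black, asian, other}; unknown maps to other). Ethnicity is not a
regressor. Estimates are reported on the scaled-covariate scale, so a BMI
coefficient reads as "change in the pairwise pp-difference per 5 BMI
units". Scaling equivariance (per-decade estimate = 10 × per-year
estimate) and residual orthogonality are property-tested, and parameter
recovery is verified by simulation: with a known coefficient vector and
Gaussian noise, estimates land within sampling error and 95% confidence
intervals cover each true coefficient at their nominal rate over 200
replicates (empirical coverage required in [0.90, 0.99]).

Two degenerate-design policies differ on purpose: `fit_difference_model()`
*errors* on rank deficiency, naming the collinear columns, because a user
supplying a broken design should hear about it; the cohort pipeline, which
builds its own design, silently drops indicators that are *constant* in the
cohort at hand (no subjects of some race level, a single-mode cohort) and
reports those terms as NA, because an absent level is an estimability fact
about the data, not an error. A `correction = FALSE` switch re-runs the
whole pipeline on native predictions as a sensitivity analysis.

## The synthetic cohort generator

Clinical CPET referral data generally cannot be shared, so the generator
produces cohorts with the marginal structure of the population the package
targets: 89% male, 60% treadmill; age normal with median 44 and IQR 37–51
(sd from IQR/1.349), clipped to the observed 24–67 range; BMI log-normal
with median 31.0 and IQR 28.2–34.9; heights sex-shifted normal (male mean
176.3 sd 6.5, female mean 162.5 sd 6.3, chosen so the 89/11 mixture median
is 175.3 cm); weight derived as BMI·(ht/100)²; race and ethnicity from the
target frequencies. Measured V̇O2peak is generated *through* the Hansen
mode-matched prediction times a truncated-normal fitness ratio,
$\max(0.2,\ N(0.83, 0.15))$ — a modeling choice, not an empirical claim,
made so that percent-predicted values correlate realistically with
anthropometrics and straddle the 80% threshold (about 42% of subjects fall
below 80% of the Hansen prediction under these defaults).

What the generator does *not* emulate: between-site metabolic-cart and
time-averaging differences, repeat tests, missingness, and any real joint
dependence of fitness on age, sex or BMI beyond what flows through the
Hansen equation. Passing pipeline tests on synthetic cohorts therefore
demonstrates correctness of the computations and invariants, not agreement
with any clinical cohort's published summary numbers.

## Problem sizes and determinism

Test and demonstration sizes were chosen to be statistically meaningful at
interactive speed: property loops use 20×6 matrices (200 of them for the
Friedman oracle), regression recovery uses n = 500 with 200
confidence-interval replicates, generator calibration is checked at
n = 20,000 (medians within 2% of target), and cohort-pipeline structure
tests use n ≈ 60–305. All stochastic tests fix seeds; the pipeline itself
is deterministic, and serialized reports are byte-identical across reruns.
Percent values are kept at full precision in memory and rounded only at
serialization (default 1 decimal).

## Known limitations

* Four of the six coefficient sets come from decades-old publications with
  ambiguous variants (activity status for Bruce, covariate set for Neder);
  the registry isolates, but cannot eliminate, that uncertainty.
* Cohen's κ is unweighted and the capacity grading is binary; no
  multi-level grading or weighted agreement is offered.
* The difference regressions are plain OLS — no mixed effects or robust
  errors for multi-site structure.
* The ±11% modality factor is a population-level constant; true
  treadmill–cycle differences vary between individuals.
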