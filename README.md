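# vo2compare

Reference equations turn a measured peak oxygen uptake (V̇O2peak) from a
cardiopulmonary exercise test (CPET) into a *percent predicted* value,

```
V̇O2peak-pp = measured V̇O2peak / predicted V̇O2peak × 100,
```

and clinical interpretation algorithms branch on a fixed threshold
(capacity is "normal" when V̇O2peak-pp ≥ 80%). The catch is that commonly
used prediction equations disagree — often by enough to move the same
patient across that threshold. `vo2compare` is an R toolkit for clinicians
and exercise-physiology researchers to quantify that disagreement:

* **Six prediction equations** (FRIEND, Wasserman, Hansen, Bruce, Jones,
  Neder) behind an editable YAML coefficient registry, with sex branches,
  native-unit handling (lb/in vs kg/cm), the Hansen ideal-body-weight
  branching (men `0.79·ht − 60.7` kg, women `0.65·ht − 42.8` kg), and the
  ±11% cycle↔treadmill modality correction for equations without
  modality-specific forms.
* **Classification agreement**: Cohen's κ with interpretation bands,
  bidirectional reclassification counts, absolute-difference quartiles,
  Friedman's rank test with Kendall's W effect size (`W = χ²/(n(k−1))`),
  and all-pairs post hoc comparisons with Bonferroni adjustment.
* **Difference regression**: OLS of pairwise percent-predicted differences
  on scaled covariates (age per decade, BMI per 5 kg/m², sex, test mode,
  race).
* **Sweep curves**: percent predicted versus body mass (50–150 kg) and age
  (±15 years) with ideal-weight and actual-weight markers.
* **CPET derived variables** (METs, ventilatory equivalents, O2 pulse,
  percent of predicted) and illustrative disability cut-off flags.
* **A synthetic cohort generator** calibrated to a Veteran referral
  population (89% male, median age 44, BMI 31, 60% treadmill) so the whole
  pipeline is testable without restricted clinical data.

## Worked example

A 37-year-old man (67 in, 280 lb) tested on a treadmill reached a V̇O2peak
of 3560 mL/min. From R:

```r
library(vo2compare)
s <- cpet_subject("case", age = 37, sex = "male", height = 67 * 2.54,
                  weight = 280 * 0.453592, mode = "treadmill",
                  measured_vo2 = 3560)
vo2_dashboard(s)
```

or from the shell (`system.file("cli", "vo2compare", package = "vo2compare")`):

```sh
vo2compare calc --age 37 --sex M --height 67 --weight 280 \
  --height-units in --weight-units lb --mode treadmill --vo2 3560
```

```
  equation predicted    pp pp_display   class
    friend      3105 114.6        114  normal
 wasserman      5210  68.3         68 reduced
    hansen      3380 105.3        105  normal
     bruce      5250  67.8         67 reduced
     jones      3043 117.0        116  normal
     neder      3736  95.3         95  normal
```

`predicted` is each equation's V̇O2peak in mL/min after modality handling
(Wasserman is cycle-native, so its 4694 mL/min prediction is raised 11% for
this treadmill test). `pp` is the continuous percent predicted and
`pp_display` its integer calculator display (floor rule). The same subject
is 68% predicted — "reduced", a finding that would prompt a disease
work-up — under Wasserman, but 114% — comfortably normal — under FRIEND:
the interpretation hinges entirely on the software's default equation.
Four of the six equations call this patient normal.

Cohort-scale analysis takes a CSV
(`id,age_years,sex,height_cm,weight_kg,mode,vo2peak_ml_min[,race,ethnicity]`):

```r
co  <- simulate_cohort(305, seed = 42)        # or read_cohort("cohort.csv")
rep <- run_cohort_comparison(co, cohort_config(threshold = 80))
rep                       # per-equation summaries, 15 pairwise analyses,
                          # Friedman test, difference regressions
write_cohort_report(rep, "out/")   # table4/5/6 analogues + report.yaml
```

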