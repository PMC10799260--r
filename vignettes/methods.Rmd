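---
title: "Methods: creatinine-based AKI detection, alerting and trial analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: creatinine-based AKI detection, alerting and trial analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akialert)
```

`akialert` implements the computational machinery of a pragmatic electronic
acute-kidney-injury (AKI) alert trial: creatinine-criteria detection and
staging, eligibility screening, stratified seeded randomization with
throttled alerts, the trial's outcome definitions, its statistical analyses,
and a synthetic electronic-health-record generator that lets the whole
pipeline run — and be tested — without patient data. This vignette explains
the models and conventions, the choices made where the clinical definitions
leave room, and what the synthetic experiments do and do not demonstrate.

## Detection and staging

Serum creatinine (SCr) is handled in mg/dL throughout (× 88.4 for µmol/L;
tables declaring µmol/L are converted on input). A series is a set of
timestamped measurements per admission, expressed in hours since admission;
negative times represent pre-admission history, which remains a legitimate
baseline comparator.

An episode begins at the earliest measurement time $t$ at which

$$\mathrm{SCr}(t) - \min_{(t-48,\,t]} \mathrm{SCr} \ge 0.3\ \text{mg/dL}
\quad\text{or}\quad
\mathrm{SCr}(t) \ge 1.5 \times \min_{(t-168,\,t]} \mathrm{SCr}.$$

**Window convention.** Rolling minima use the half-open trailing window
$(t-w,\ t]$: a measurement exactly $w$ hours earlier is excluded, the
measurement at $t$ is included. Inclusion of the index measurement is
harmless — a value cannot rise 0.3 mg/dL or 1.5-fold over itself — and makes
the single-measurement window well defined. All threshold comparisons carry
a $10^{-9}$ numeric slack so values lying exactly on a printed threshold
(a 0.3 rise, a 1.5 ratio) behave as the criteria read despite binary
floating point.

**Baseline.** The episode baseline is the 7-day rolling minimum at onset,
frozen for the episode; every staging ratio is taken against it. Stage 3
holds once kidney replacement therapy has started, the ratio reaches 3.0,
or the high-creatinine rule fires; stage 2 covers ratios in $[2.0, 3.0)$;
stage 1 otherwise (the episode already satisfies a stage-1 criterion).

**The 4.0 mg/dL rule.** The stage-3 creatinine clause is ambiguous between
"SCr value ≥ 4.0 mg/dL" and "rise ≥ 4.0 mg/dL". The default (`scr4_rule =
"value"`) implements the value reading — standard KDIGO semantics for a
patient already meeting AKI criteria — with the literal increase reading
available as `"increase"`.

**eGFR.** The 2009 CKD-EPI creatinine equation without the race
coefficient is the default: the cohort the defaults emulate is ethnically
homogeneous, and the publication names the equation family but not the
variant. The race-coefficient 2009 form and the 2021 refit sit behind the
`variant` argument. The implementation is checked against hand evaluations
of the published constants and for strict monotonicity in creatinine and
age.

Detection is evaluated at measurement times only — the alert system reacts
to arriving laboratory results, not to retrospective sweeps. A brute-force
oracle that checks every ordered measurement pair against both criteria
agrees with the rolling-window implementation on a thousand random short
series in the test suite.

## Screening, randomization, alerts

The seven exclusions (baseline eGFR < 15 mL/min/1.73 m², ESKD admission,
kidney-transplant history, community-acquired AKI, stay < 24 h, baseline
SCr < 0.5 mg/dL, repeat admission) are evaluated in that order; the decision
is order-independent, the reported reason is the first that applies.
"Community-acquired" has no operational definition in the source material;
the package's documented approximation is: the baseline window at onset
contains no in-admission measurement earlier than onset (the baseline rests
entirely on history), or the criteria are already met at the first
in-admission measurement.

Randomization uses one reproducible stream per stratum: stratum $k$ (0-based
over medical-ICU, medical-ward, surgical-ICU, surgical-ward) is seeded with
$20180101 + k$. The generator algorithm is unstated in the source; the
package fixes R's Mersenne-Twister and treats the seed scheme plus draw
index as the reproducibility contract, so assignment depends only on
`(stratum, draw_index)`, bit-identically across runs and platforms.
Allocation is simple 1:1 Bernoulli by default ("randomized 1:1" does not
specify blocking); permuted blocks of configurable size are available.
Every alert is randomized at trigger time; exclusions are recorded and
applied afterwards, so analyses run on the modified intention-to-treat
population, mirroring the trial's flow in which over-inclusive automated
alerts were pruned during analysis.

Alert messages fill a fixed template (bed, ward, admission date, creatinine
with two decimals, test date, consultation number) and are capped at 3 per
admission — a patient-level cap over any trigger sequence — to limit alert
fatigue.

## Outcomes

All windows are half-open intervals $(r,\ r + h]$ from the randomization
timestamp with $h$ = 48, 72, 168, 672 or 2160 hours. Hour-based windows
were chosen over calendar days because the data model carries timestamps
and calendar days would import a local-midnight convention the definitions
do not state.

The primary outcome is the maximum eGFR change within 7 days: eGFR at AKI
minus the lowest eGFR at follow-up measurement times, with the lowest eGFR
set to 0 if the patient dies in the window; the relative form divides by
eGFR at randomization. eGFR at AKI and at randomization are treated as the
same quantity — randomization is triggered by the alert. With no follow-up
measurement and no death the outcome is missing; no imputation is performed
anywhere, and denominators shrink accordingly.

Recovery at discharge has no printed definition; the package's explicit,
configurable default is: alive at discharge, free of in-hospital dialysis,
and last creatinine below 1.5 × the episode baseline. Anemia correction
requires hemoglobin strictly over 9.0 g/dL. Progression compares the stage
at randomization with the highest strictly-later in-hospital stage and only
ever records a strictly higher stage.

## Statistics

Risk differences are reported in percentage points,
$100(\hat p_a - \hat p_b)$, with the Wald interval
$\pm z_{1-\alpha/2}\sqrt{\hat p_a \hat q_a/n_a + \hat p_b \hat q_b/n_b}$ and
a Pearson χ² p-value without continuity correction. Wald is the default
because it reproduces the recomputable printed intervals to the printed
decimal (e.g. 17.1–24.4 for the IV-fluids row); one printed row (kidney
ultrasonography) is not exactly Wald, and a Newcombe hybrid-score interval
is available behind `method = "newcombe"` for boundary-respecting intervals
at extreme proportions.

The Mann-Whitney comparison defaults to an exact enumeration of the
rank-sum distribution (midranks, so ties are handled) whenever the number
of group splits is small, and otherwise to the normal approximation with
the tie-corrected variance. A pure normal approximation cannot track the
exact small-sample distribution at corner splits (1 vs 7 observations:
exact two-sided p = 0.25 against a normal 0.13), which is why the exact
path exists and is the automatic choice at small $n$. The tests pin the
exact path to the null Wilcoxon distribution and the normal path to an
independent implementation.

The Hodges-Lehmann shift estimate is literally the median of all pairwise
between-group differences; its confidence interval inverts the rank-sum
test. Subgroup analyses fit univariate binary logistic regressions per
subgroup level (odds ratio with Wald CI) plus a product-term model for the
interaction p-value; complete separation is flagged and the interval
reported as unbounded. The sample-size rule is the two-group
normal-approximation formula with the enrolment total inflated by
$1/(1-\text{attrition})$ and rounded up to a planning granularity of 100;
with σ = 13.4, means 19.0 vs 17.1, two-sided α = 0.05 and 90% power it
gives 1046 per group — consistent with the published plan of 1050 — and an
inflated total of 3000 at 30% attrition. The stated "2-tailed .025-level
test for an overall α = .05" is internally ambiguous; the default uses
$z_{0.975}$, which is the reading that reproduces the published plan.
No multiplicity correction is applied, matching the source analyses.

## The synthetic generator

The generator emulates the study conditions, not kidney physiology. Its
defaults are the trial's marginal rates: 1.4 injected episodes per 100
admissions, stage mix 50/25/25%, baseline creatinine log-normal with median
0.87 mg/dL (IQR ≈ 0.70–1.18), onset a log-normal around 6.5 days after
admission, 60.6% ICU, 70.7% male, age ≈ 65 (54–72), 11/35/38% cumulative
mortality at 7/28/90 days among AKI patients (the 7-day component scaled
×0.6/1.0/1.8 by stage), 12% 7-day dialysis concentrated in stage-3 episodes
(≈48% conditional, consistent with the published marginals), and per-arm
care-process probabilities equal to the two arms' observed rates. Setting
the two members of every care-effect pair equal yields a null
configuration. Lab cadence is one draw per ~24 h on wards and 6–12 h in
ICU — a plausible practice pattern chosen to exercise the window logic, as
draw frequency is not described in the source.

Trajectories are piecewise log-linear in creatinine with multiplicative
noise (CV 5%), clamped per patient so that a non-AKI series can never meet
either criterion — the swing stays below both 0.3 mg/dL and 1.5-fold for
the patient's baseline. Injection rewrites the post-onset segment as a rise
to `ratio ×` the measured 7-day nadir, a plateau, and a partial exponential
recovery. Two construction guarantees make ground truth exact rather than
probabilistic: the pre-onset nadir is placed where it is still inside the
rolling window at the peak (otherwise a slow riser's baseline can drift out
of the window and a genuine stage-1 injection would go undetected), and the
peak itself is always observed. Peak ratios for stage-1/2 injections are
drawn from the feasible part of their bands so the creatinine value never
crosses the 4.0 mg/dL stage-3 rule; `inject_aki()` refuses impossible
requests instead of silently mis-staging. Each admission derives its RNG
substream from the global seed by counter, so cohorts are reproducible and
independent of iteration order, and the generator randomizes detected
episodes with the same seed scheme the pipeline uses — the two agree
assignment-for-assignment.

What passing tests on synthetic cohorts demonstrate: the detection,
staging, windowing, randomization and outcome arithmetic are correct, and
the analysis stack is calibrated (null-effect cohorts reject at ≈5%). What
they do not demonstrate: realism of creatinine dynamics, comorbidity
structure, informative lab-draw timing, or clinician behavior beyond the
configured event probabilities — conclusions about real cohorts require
real data.

## Numerical and scale choices

Problem sizes in the tests and the acceptance script are desk-scale by
design: cohorts of 60–400 admissions for property checks (with elevated
incidence so enough episodes exist), 25 000 admissions at the trial's 1.4%
incidence for the incidence-recovery check, 500 replicate cohorts for the
null calibration, 1000 random series against the brute-force detection
oracle, and all splits with $n_1+n_2 \le 10$ for the exact Mann-Whitney
comparison. Logistic fits rely on `stats::glm` (IRLS); separation is
flagged at |coefficient| > 15 or SE > 100. Degenerate inputs are first-class:
empty windows return a no-value signal, zero denominators and empty samples
are errors, an all-tied Mann-Whitney returns p = 1, and an empty cohort
aborts the pipeline with a stage-named error.

## Known limitations

Urine-output KDIGO criteria are out of scope (the alert design is
creatinine-only); community-acquired AKI and recovery-at-discharge rules
are documented approximations of undescribed operational definitions; the
generator's trajectory model is tuned to marginal medians only; costs and
consultation workflows are not modelled; and the primary-outcome medians of
a real cohort are not reproducible from printed summaries — the package
instead verifies the arithmetic identities and distributional properties
that are checkable without patient-level data.
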