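---
title: "Methods: audit-log workflow measurement, black-hole imputation and matched evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: audit-log workflow measurement, black-hole imputation and matched evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its own methods: the measurement
model, the statistical procedures, the simulator that stands in for
protected EHR data, and the numerical and design choices a maintainer would
want spelled out.

## 1. The workflow model

An outpatient encounter is modelled as an ordered sequence of workflow
points:

```
CHECKIN_START <= CHECKIN_END <= ROOM_START <= MA_LOGIN <= MA_LOGOFF
  <= MA_EXIT <= PHYS_ENTER <= PHYS_LOGIN <= PHYS_LOGOFF <= PHYS_EXIT
  <= PATIENT_EXIT (<= CHECKOUT)
```

Six of these leave an audit footprint (check-in start/end, MA login/logoff,
physician login/logoff). The remaining boundaries are **black holes**:
steps with no EHR interaction, spanned by five named intervals
(`blackhole_intervals()`), e.g. `PHYS_ENTER_TO_LOGIN` — a physician enters
the room and converses before touching the keyboard. `MA_EXIT` (the
MA/nurse leaving the room) is carried as an explicit point because the
MA-logoff-to-exit interval needs an observable endpoint to be calibrated
at all.

All timestamps are stored as UTC instants; input files may carry zone
offsets. Durations are reported in fractional minutes. One audit record is
one click.

### Extraction rules

- `CHECKIN_START`/`CHECKIN_END`: first/last front-desk-role record at a
  front-desk workstation. These are process times (when the front desk
  worked the check-in), which is why their observed-vs-derived differences
  are the largest in validation data.
- `MA_LOGIN`/`MA_LOGOFF`: first LOGIN / last LOGOFF by a medical assistant
  or nurse in the examination room.
- `PHYS_LOGIN`/`PHYS_LOGOFF`: first LOGIN / last LOGOFF by the encounter's
  *primary* physician in the examination room. If several physician-role
  users appear, the one with the most exam-room records is the physician;
  the encounter is flagged.
- Missing supporting events leave the point missing — nothing is ever
  fabricated at extraction time.
- EHR exam-room time sessionizes the primary physician's exam-room records
  into LOGIN→LOGOFF sessions and sums their lengths. An orphan session
  (LOGIN without LOGOFF) closes at its last record plus `session_gap_min`
  (default 1 minute) if feature records followed the LOGIN, at the LOGIN
  itself otherwise, and is always capped at the next LOGIN. The default gap
  reflects that an abandoned session's tail activity is bounded by the
  device's idle timeout, not by the next day's logoff record.
- Clicks count *all* primary-physician records for the encounter —
  pre-visit chart review, exam-room sessions, post-visit wrap-up — so the
  click outcome is deliberately not bounded by any time outcome.

Total encounter time is defined check-in to patient exit (not check-out):
the patient-exit definition is the one the imputation chain can support at
every encounter, and `CHECKOUT` is retained as an optional extra point.

## 2. Calibration, variance decomposition, imputation

**Calibration** pairs, per encounter, the directly observed boundary with
the adjacent audit-derived point (e.g. observed `PHYS_ENTER` with audit
`PHYS_LOGIN`) and keeps the sample of differences as the interval's
empirical distribution. Negative differences are transcription slips;
they are clipped to zero and counted rather than discarded, mirroring how a
validation study reviews rather than deletes discrepant records. An
interval with zero usable pairs is simply absent, and imputation fails
loudly if it is needed.

**Variance decomposition** fits, per interval, a sequential (type I) ANOVA
with the physician entered first as a categorical factor and then four
patient demographics (age, sex, race, ethnicity). Shares are the
sequential sums-of-squares proportions; physician-first ordering matches
the substantive question ("how much is clinician habit?") and is the
documented tie-break since sequential shares depend on order. With a
single physician the share is undefined and flagged.

**Imputation** draws, per encounter and interval, one uniform resample
from the calibrated empirical sample — not from a parametric fit, and
pooled across physicians even though the ANOVA typically shows large
physician shares. Physician-conditional draws are a documented possible
extension; the pooled draw keeps the imputation's distribution identical
to the calibration sample and therefore auditable. Order violations after
imputation are clipped to the nearest feasible time, never redrawn, so the
set of drawn values remains exactly a resample of the calibration sample.
Audit-observed points are never moved. The resampling RNG is seeded
explicitly (`impute_points(..., seed = )`), and the pipeline derives
per-stage sub-seeds from one global seed so stages can be rerun
independently.

## 3. Validation outputs

`discrepancy_table()` mirrors the standard audit-validation summary: per
workflow point, n (% of observed encounters), mean (SD), median (IQR) of
observed − derived in minutes, with linear-interpolation quartiles
(`quantile` type 7 — stated because IQR values depend on the convention).
Points that cannot be derived from audit data appear as sentinel rows with
`NA` statistics. `flag_outliers()` queues encounters whose difference
deviates from the label mean by ≥ k SDs (default 2) for manual review;
"≥ 2 SD" is read as absolute deviation from the mean difference, the usual
screening rule.

## 4. Matching and effect estimation

Exposure to a voluntary point-of-care tool is confounded twice: physicians
choose whether to adopt, and physicians choose the patients for whom they
launch it. The package therefore matches at two levels with greedy
propensity matching (cases in descending score order, nearest eligible
control within a caliper, without replacement, ties broken by id):

- **Physician level** on panel composition (annual volume, appointments
  per day, panel age/sex/ethnicity mix, condition prevalences, practice
  type, Charlson bands). The pipeline uses a permissive caliper (1.0
  logit-SD) here: physician samples are tiny and an over-tight caliper
  discards most of the cohort, which costs far more information than the
  residual panel imbalance it prevents.
- **Patient level**, one-to-one, on demographics plus encounter-mix
  percentages (15-/30-minute appointments, LOS 3/4, cardiometabolic
  primary-diagnosis rates), caliper 0.2 SD of the logit of the score — the
  standard convention, since no caliper is forced by the design.

Propensity scores are maximum-likelihood logistic fits; under separation a
ridge-penalized fit supplies the scores with a warning. Balance is reported
as standardized mean differences, pre match (all cases vs the full pool)
and post match, with |SMD| < 0.1 as the adequacy threshold.

Outcomes are collapsed to one value per patient (mean over the patient's
eligible encounters) before testing: control patients contribute several
encounters where case patients often contribute one, and encounter-level
two-sample tests would pseudo-replicate. The primary estimate is the
matched-cluster linear mixed model `outcome ~ exposure + (1 | cluster)`
fit by REML, effect = the exposure coefficient, 95% CI by normal
approximation on its standard error; when clusters are exact pairs this
estimator equals the mean of within-pair differences. The Welch
(unequal-variance) two-tailed t-test is computed alongside; Welch rather
than pooled because arm variances have no reason to be equal. If the mixed
fit fails or is degenerate, a cluster-robust OLS estimate is substituted
and flagged. Stratified tables split by scheduled appointment band (≤ 20
vs ≥ 30 minutes; other lengths are excluded with a count) or by
cardiometabolic primary diagnosis; strata with fewer than two complete
clusters emit a reason code instead of an estimate. No outcome-model
covariates and no multiplicity correction are applied — inference leans on
the matching, and the stratified rows are descriptive.

## 5. The clinic simulator

`simulate_clinic()` is a seeded discrete-event generator producing, per
encounter: ground-truth times for every workflow point, audit events that
are *structurally* blind to the black-hole boundaries, time-motion records
with per-point observer jitter and missingness, and full encounter /
patient / physician metadata. All times are whole seconds (audit logs carry
second granularity), which also makes truth-vs-derived comparisons exact in
floating point.

Defaults describe a time-motion-calibrated primary-care clinic:
appointments 15/20/30/40 min (35/25/30/10%), sequential slots from 08:00
per physician-day; check-in ≈ 1.5 min; waiting ≈ 8 min; MA rooming session
≈ 4 min; physician exam-room EHR total ≈ 9 min in one or two sessions;
~6 clicks/min in session plus pre-/post-visit activity totalling ≈ 150
clicks per encounter. The five black-hole defaults (mean (SD) minutes):
MA-room-to-login 0.73 (1.01), MA-logoff-to-exit 0.51 (1.39),
physician-enter-to-login 2.62 (1.61), physician-logoff-to-exit 0.82
(1.29), physician-exit-to-patient-exit 2.72 (4.11), with duration-scale
physician/patient variance shares of 11.6/35.1, 6.9/46.7, 62.2/14.8,
11.1/23.0 and 39.1/17.5 percent respectively. Observer jitter is zero-mean
Gaussian with per-point SDs defaulting to the observed-vs-derived SDs of
the validation analysis (so the discrepancy table is a meaningful
analogue); missingness rates default to the coverage observed there
(70–100% per point).

**Black-hole construction.** Durations are built as
`d = m · f_phys · f_pat · f_res`, a product of three positive lognormal
factors. Given marginal mean `m`, SD `s` (so `T = s²/m²`) and target
duration-scale shares `p_phys`, `p_pat`, the factor variances are solved
as `A = p_phys·T`, `B = p_pat·T`, `(1+A)(1+B)(1+C) = 1+T`, which makes the
marginal mean/SD *and* the sequential-ANOVA shares match the configured
values simultaneously (the cross-terms land in the residual, as they do in
a real ANOVA). The realized physician factor (one draw per physician) and
the patient factor (a fixed linear combination of age, sex, race,
ethnicity) are standardized to their target sample moments: with a
clinic's worth of physicians, raw draws would let the realized share
wander by tens of points, defeating recovery tests. The patient factor is
a function of observed demographics only — exactly what the decomposition
regresses on. Gamma and empirical families are available for the marginal;
a `mean = 0` or `sd = 0` specification degenerates to constants, the
configuration used by the exactness tests.

**Exposure and effects.** Tool launches follow a logistic model on patient
covariates (age, sex, conditions, appointment length) plus a physician
random intercept, restricted to post-period encounters of pilot
physicians. The default coefficients make exposure genuinely confounded:
older, diabetic, hypertensive patients both receive the tool more often
and accrue more EHR time (`outcome_confounding`). `inject_effect()`
applies the treatment truth before events are realized: exposed
encounters' true EHR time drops by `delta_ehr` exactly (clipped at zero,
sessions rescaled proportionally, later points shifted), and click counts
are scaled and rounded. Band-specific `delta_ehr` overrides support
stratum-specific recovery tests.

**What the simulator does not emulate**, and hence what passing tests do
not show about real data: shared workstations and badge-switching,
physicians covering each other mid-encounter, systematic (non-zero-mean)
observer offsets, clock skew between front-desk and exam-room machines,
EHR idle auto-logoffs, overlapping concurrent encounters for one
physician, and any drift of outcomes between pre and post periods. The
validation and quality-report machinery exists precisely because real
extracts contain these; the simulator only proves the algorithms correct
under the stated model.

## 6. Validation protocol and problem sizes

The test suite fixes these scales as the package's validation protocol:
brute-force oracle equivalence on 200 sparse encounters; exactness under a
degenerate (zero-black-hole, zero-jitter) configuration on 1,000
encounters; calibration recovery of the 2.62-minute interval within
±0.15 min on 2,000 encounters; per-label mean observed-vs-derived
difference under 1 minute on a 101-encounter observed cohort; recovery of
a 62.2% physician variance share within ±5 points at n = 5,000 (20
physicians); matching balance (all post-match |SMD| < 0.1, with pre-match
imbalance > 0.3) on 500 cases vs 2,000 controls; mixed-model recovery of a
−2.0-minute effect within ±0.3 at 1,000 matched pairs with ≥ 90% CI
coverage over 200 replicates of 150 pairs; and type-I error in
[0.03, 0.07] over 1,000 null replicates at 50 units per arm, each method
under its own sampling model (independent arms for the t-test, shared
cluster effects for the mixed model).

## 7. Known limitations

- The end-to-end pipeline estimate is mildly attenuated relative to the
  injected truth (≈ −1.5 recovered for a −2.0 truth in the README demo):
  residual post-caliper imbalance and physician-level clustering are real
  features of a matched quasi-experimental design, and the reported CI
  reflects patient-level uncertainty only. With few physicians the
  between-physician contribution dominates and single-cohort estimates
  scatter accordingly.
- Single imputation: black-hole draws are not multiply imputed, so
  downstream CIs do not propagate imputation uncertainty. The imputed
  intervals enter two of the four outcomes (total encounter time and
  exam-room time); EHR time and clicks are imputation-free.
- Audit-derived EHR time counts logged-in wall-clock time; staring at the
  patient while logged in is indistinguishable from active use.
- Calibration clipping biases short-interval means upward when observer
  jitter is comparable to the interval (visible in the MA intervals);
  the clip count in the model object is the diagnostic.
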