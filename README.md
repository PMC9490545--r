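# auditflow

Measuring clinical workflow from EHR audit logs.

Every action a clinician takes in an electronic health record leaves an
audit-log entry: who (user and role), when (timestamp), where (workstation)
and what (the feature accessed). `auditflow` turns those event streams into
encounter-level workflow measurements for outpatient primary care — when the
patient checked in, when the medical assistant (MA) roomed them, when the
physician entered the examination room, how long the physician spent in the
EHR while there, and how many clicks the encounter cost — and provides the
statistical machinery to evaluate whether a point-of-care tool changes those
measurements. It is aimed at health-services and clinical-informatics
researchers who have audit-log extracts and want scalable, validated
workflow outcomes without running a time-motion observer behind every
encounter.

## The measurement problem

Some workflow steps never touch the EHR. A physician typically enters the
examination room, greets the patient, and only then logs in; they log off
before they leave; the patient lingers after the physician exits. These
intervals are **black holes**: invisible in audit data, observable only in
person. `auditflow` handles them the way a time-motion validation study
does:

1. **Extraction.** Audit-observable workflow points are derived per
   encounter: check-in start/end from front-desk records, MA login/logoff
   and physician login/logoff from examination-room sessions. Physician EHR
   time is the sum of login→logoff session lengths; clicks are the count of
   the physician's log entries (pre-visit, in-room and post-visit).
2. **Calibration.** For encounters with paired direct observation, each
   black hole's empirical duration distribution is the sample of
   differences between the observed boundary and the adjacent audit point
   (negative differences clipped to zero and counted). A sequential ANOVA
   decomposes each interval's variance into physician, patient-demographic
   and residual shares.
3. **Imputation.** For every encounter, the unobservable boundaries are
   filled by uniform resampling from the calibrated empirical samples:
   `PHYS_ENTER = PHYS_LOGIN − draw`, `PHYS_EXIT = PHYS_LOGOFF + draw`,
   `PATIENT_EXIT = PHYS_EXIT + draw`, with order violations clipped, never
   redrawn.
4. **Validation.** Observed-vs-derived discrepancy tables (n (%), mean
   (SD), median (IQR)) and a ≥ k·SD review queue reproduce the standard
   audit-validation workflow.
5. **Evaluation.** Two-level propensity-score greedy matching (physicians
   on panel composition, then patients nested within matched physicians),
   standardized-mean-difference balance checks, and effect estimation per
   efficiency measure by Welch t-tests on patient-level outcomes and by a
   linear mixed model `outcome ~ exposure + (1 | matched cluster)` fit by
   REML, stratified by scheduled appointment length (≤20 vs ≥30 min) or by
   cardiometabolic primary diagnosis.

Because real audit extracts are protected data, the package ships a seeded
discrete-event clinic simulator (`simulate_clinic()`) that generates ground
truth timelines, the corresponding audit events (with the black holes
properly invisible), jittered time-motion observations, and a confounded,
injectable tool-exposure process — so every algorithm above is testable
end to end against known truth.

## Worked example

Simulate a clinic with a two-minute true reduction in physician exam-room
EHR time (and 15% fewer clicks) for tool-exposed encounters, then recover
it:

```r
library(auditflow)

cfg <- sim_config(n_encounters = 500, seed = 42,
                  effect = list(delta_ehr = 2, click_mult = 0.9))
sim <- simulate_clinic(cfg)

points  <- derive_workflow_points(sim$events, sim$location_map)
model   <- calibrate_blackholes(sim$time_motion, points,
                                sim$encounters, sim$patients)
print(model)
#> Black-hole duration model (5 intervals)
#>   MA_ROOM_TO_LOGIN           n= 456  mean= 0.79  sd= 0.96  clipped=46
#>                              physician 16.6% / patient 28.2% / residual 55.2%
#>   MA_LOGOFF_TO_EXIT          n= 365  mean= 0.49  sd= 0.81  clipped=83
#>                              physician 6.7% / patient 29.8% / residual 63.5%
#>   PHYS_ENTER_TO_LOGIN        n= 458  mean= 2.59  sd= 1.66  clipped=0
#>                              physician 66.4% / patient 10.0% / residual 23.5%
#>   PHYS_LOGOFF_TO_EXIT        n= 437  mean= 0.84  sd= 1.18  clipped=51
#>                              physician 11.2% / patient 24.7% / residual 64.2%
#>   PHYS_EXIT_TO_PATIENT_EXIT  n= 404  mean= 3.19  sd= 5.12  clipped=32
#>                              physician 35.6% / patient 15.2% / residual 49.2%
```

The calibrated physician-enter-to-login interval (mean 2.59 min, SD 1.66,
66% of variance between physicians) matches the generator's configured
distribution; the samples feed `impute_points()`, after which
`compute_measures()` yields the four per-encounter outcomes:

```r
imputed  <- impute_points(points, model, seed = 7)
measures <- compute_measures(imputed, sim$events, sim$location_map)
head(measures, 3)
#>   encounter_id total_encounter_min phys_exam_room_min phys_ehr_exam_min total_clicks
#> 1      E000001            93.85000           42.86667         35.716667          328
#> 2      E000002            38.71667           15.96667          8.933333          145
#> 3      E000003            29.13333           13.06667         11.766667          150
```

The full pipeline — simulate, extract, calibrate, impute, validate, match,
evaluate — runs as one call (or as `inst/cli/auditflow run`):

```r
cfg <- sim_config(n_encounters = 3500, n_patients = 2200, n_physicians = 30,
                  seed = 6, exposure = list(intercept = -1.2, pilot_frac = 0.3),
                  effect = list(delta_ehr = 2, click_mult = 0.85))
run_pipeline(cfg, seed = 6, out_dir = "demo-out")
read.csv("demo-out/effects.csv") |>
  subset(method == "mixed" & stratum == "overall")
#>               measure n_case n_control mean_diff ci_low  ci_high        p
#> 1 total_encounter_min    186       186     -1.77  -3.44  -0.0882 3.91e-02
#> 3  phys_exam_room_min    186       186     -1.59  -2.62  -0.5513 2.67e-03
#> 5   phys_ehr_exam_min    186       186     -1.46  -2.38  -0.5369 1.92e-03
#> 7        total_clicks    186       186    -20.87 -26.13 -15.6103 7.28e-15
```

The matched-cluster mixed model attributes a ~1.5-minute EHR-time saving
(95% CI −2.4 to −0.5) and ~21 fewer clicks to the tool; the injected truth
was −2 minutes and ×0.85 clicks, and post-match covariate imbalance is
below |SMD| = 0.1 (`demo-out/balance.csv`). The residual gap between −1.5
and −2 is the honest cost of a matched quasi-experimental design at this
sample size; the methods vignette discusses it.

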