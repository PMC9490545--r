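test_that("patient-level outcomes are per-patient means over encounters", {
  meas <- data.frame(encounter_id = c("E1", "E2", "E3"),
                     total_encounter_min = c(10, 20, 30),
                     phys_exam_room_min = c(5, 15, 9),
                     phys_ehr_exam_min = c(4, 10, 7),
                     total_clicks = c(100L, 200L, 50L),
                     stringsAsFactors = FALSE)
  enc <- data.frame(encounter_id = c("E1", "E2", "E3"),
                    patient_id = c("A", "A", "B"), stringsAsFactors = FALSE)
  po <- patient_level_outcomes(meas, enc)
  expect_equal(po$total_encounter_min[po$patient_id == "A"], 15)
  expect_equal(po$total_encounter_min[po$patient_id == "B"], 30)
  expect_equal(po$n_encounters, c(2L, 1L))
  # missing encounter values are dropped from the mean, not zeroed
  meas$phys_ehr_exam_min[2] <- NA
  po2 <- patient_level_outcomes(meas, enc)
  expect_equal(po2$phys_ehr_exam_min[po2$patient_id == "A"], 4)
})

test_that("identical arms give a zero difference with p = 1", {
  r <- mean_diff_ttest(c(3, 3, 3), c(3, 3, 3))
  expect_equal(r$mean_diff, 0)
  expect_equal(r$p, 1)
})

test_that("the Welch statistic matches the textbook formula", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  r <- mean_diff_ttest(x, y)
  expect_equal(r$mean_diff, -3)
  # independent hand computation of Welch t, df, p
  se <- sqrt(var(x) / 3 + var(y) / 3)
  tstat <- -3 / se
  df <- se^4 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(r$df, df)          # = 4 for equal variances
  expect_equal(r$p, 2 * pt(-abs(tstat), df))
})

test_that("swapping the arms negates the difference, p unchanged", {
  set.seed(11)
  x <- rnorm(30, 10, 2); y <- rnorm(40, 11, 3)
  a <- mean_diff_ttest(x, y); b <- mean_diff_ttest(y, x)
  expect_equal(a$mean_diff, -b$mean_diff)
  expect_equal(a$p, b$p)
})

test_that("noise-free paired clusters return the within-pair difference", {
  df <- data.frame(outcome = c(10, 8, 12, 10), exposed = c(0, 1, 0, 1),
                   cluster = c("c1", "c1", "c2", "c2"))
  r <- mixed_model_effect(df$outcome, df$exposed, df$cluster)
  expect_equal(r$mean_diff, -2, tolerance = 1e-6)
})

test_that("a constant outcome gives a zero effect with a degenerate CI", {
  df <- data.frame(outcome = rep(5, 6), exposed = rep(c(0, 1), 3),
                   cluster = rep(c("a", "b", "c"), each = 2))
  r <- mixed_model_effect(df$outcome, df$exposed, df$cluster)
  expect_equal(r$mean_diff, 0, tolerance = 1e-9)
  expect_equal(r$ci_low, r$ci_high, tolerance = 1e-8)
})

test_that("clusters missing an arm are rejected", {
  expect_error(mixed_model_effect(c(1, 2, 3, 4), c(1, 1, 0, 1),
                                  c("a", "a", "b", "b")),
               "lack a case or a control")
})

test_that("with exact pairs the mixed effect equals the paired-difference mean", {
  set.seed(12)
  d <- simulate_matched_outcomes(80, effect = -1.7, cluster_sd = 3, resid_sd = 2)
  r <- mixed_model_effect(d$outcome, d$exposed, d$cluster)
  paired <- mean(d$outcome[d$exposed == 1] - d$outcome[d$exposed == 0])
  expect_equal(r$mean_diff, paired, tolerance = 1e-6)
  expect_equal(r$method, "mixed")
})

test_that("stratified effects find a stratum-specific injected signal", {
  set.seed(13)
  n_pairs <- 120
  pid_case <- sprintf("case%03d", seq_len(n_pairs))
  pid_ctl <- sprintf("ctl%03d", seq_len(n_pairs))
  m <- list(pairs = data.frame(case_id = pid_case, control_id = pid_ctl,
                               cluster_id = sprintf("cl%03d", seq_len(n_pairs)),
                               stringsAsFactors = FALSE))
  # two encounters per patient: one short (<=20), one long (>=30) appointment;
  # the effect exists only in the short stratum
  mk <- function(ids, short_shift) {
    do.call(rbind, lapply(ids, function(id) {
      data.frame(encounter_id = paste0(id, c("_s", "_l")), patient_id = id,
                 scheduled_length_min = c(15, 30),
                 primary_dx = "diabetes", stringsAsFactors = FALSE)
    }))
  }
  enc <- rbind(mk(pid_case), mk(pid_ctl))
  base <- rnorm(nrow(enc), 20, 3)
  is_case_short <- grepl("case", enc$patient_id) & enc$scheduled_length_min == 15
  val <- base - 4 * is_case_short
  meas <- data.frame(encounter_id = enc$encounter_id,
                     total_encounter_min = val, phys_exam_room_min = val / 2,
                     phys_ehr_exam_min = val / 3, total_clicks = 100L,
                     stringsAsFactors = FALSE)
  eff <- stratified_effects(meas, enc, m, strata = "appt", methods = "mixed")
  short <- eff[eff$stratum == "<=20" & eff$measure == "total_encounter_min", ]
  long <- eff[eff$stratum == ">=30" & eff$measure == "total_encounter_min", ]
  expect_lt(short$p, 0.001)
  expect_lt(abs(short$mean_diff + 4), 1)
  expect_gt(long$p, 0.05)
  expect_lt(abs(long$mean_diff), 1)
})

test_that("off-band appointment lengths are excluded and counted", {
  m <- list(pairs = data.frame(case_id = "A", control_id = "B",
                               cluster_id = "cl1", stringsAsFactors = FALSE))
  enc <- data.frame(encounter_id = c("E1", "E2", "E3"),
                    patient_id = c("A", "B", "B"),
                    scheduled_length_min = c(15, 15, 25),
                    primary_dx = "other", stringsAsFactors = FALSE)
  meas <- data.frame(encounter_id = enc$encounter_id,
                     total_encounter_min = c(10, 12, 14),
                     phys_exam_room_min = 5, phys_ehr_exam_min = 3,
                     total_clicks = 10L, stringsAsFactors = FALSE)
  eff <- stratified_effects(meas, enc, m, strata = "appt", methods = "ttest")
  expect_equal(attr(eff, "n_excluded_encounters"), 1)
  expect_false("25" %in% eff$stratum)
})

test_that("a single-stratum spec reduces to the unstratified estimate", {
  set.seed(14)
  d <- simulate_matched_outcomes(60, effect = -2)
  ids <- c(sprintf("case%02d", 1:60), sprintf("ctl%02d", 1:60))
  pid <- ifelse(d$exposed == 1, sprintf("case%02d", d$cluster),
                sprintf("ctl%02d", d$cluster))
  m <- list(pairs = data.frame(case_id = sprintf("case%02d", 1:60),
                               control_id = sprintf("ctl%02d", 1:60),
                               cluster_id = sprintf("cl%02d", 1:60),
                               stringsAsFactors = FALSE))
  enc <- data.frame(encounter_id = sprintf("E%03d", seq_len(nrow(d))),
                    patient_id = pid, scheduled_length_min = 20,
                    primary_dx = "other", stringsAsFactors = FALSE)
  meas <- data.frame(encounter_id = enc$encounter_id,
                     total_encounter_min = d$outcome,
                     phys_exam_room_min = d$outcome, phys_ehr_exam_min = d$outcome,
                     total_clicks = 1L, stringsAsFactors = FALSE)
  overall <- stratified_effects(meas, enc, m, strata = "none", methods = "mixed")
  banded <- stratified_effects(meas, enc, m, strata = "appt", methods = "mixed")
  o <- overall[overall$measure == "total_encounter_min", ]
  b <- banded[banded$measure == "total_encounter_min", ]
  expect_equal(nrow(b), 1)
  expect_equal(b$mean_diff, o$mean_diff, tolerance = 1e-9)
})

test_that("strata with too few complete clusters emit a reason, not an estimate", {
  m <- list(pairs = data.frame(case_id = "A", control_id = "B",
                               cluster_id = "cl1", stringsAsFactors = FALSE))
  enc <- data.frame(encounter_id = c("E1", "E2"), patient_id = c("A", "B"),
                    scheduled_length_min = 15, primary_dx = "diabetes",
                    stringsAsFactors = FALSE)
  meas <- data.frame(encounter_id = c("E1", "E2"),
                     total_encounter_min = c(10, 11), phys_exam_room_min = 5,
                     phys_ehr_exam_min = 3, total_clicks = 5L,
                     stringsAsFactors = FALSE)
  eff <- stratified_effects(meas, enc, m, strata = "dx", methods = "mixed")
  r <- eff[eff$measure == "total_encounter_min", ]
  expect_true(is.na(r$mean_diff))
  expect_match(r$note, "cluster")
})
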