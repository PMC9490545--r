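#' Simulator configuration
#'
#' Builds the configuration object for [simulate_clinic()]. Defaults emulate
#' an outpatient primary-care clinic: scheduled appointments of 15/20/30/40
#' minutes, front-desk check-in, medical-assistant (MA) rooming, physician
#' examination-room EHR sessions, and the five unobservable "black hole"
#' intervals (MA rooming to MA login, MA logoff to exit, physician entering
#' the room to EHR login, physician logoff to exit, physician exit to
#' patient exit). Black-hole means/SDs and variance shares default to the
#' values observed in the underlying time-motion study.
#'
#' @param ... Named overrides, merged recursively into the defaults (e.g.
#'   `n_encounters = 500`, `blackholes = list(PHYS_ENTER_TO_LOGIN =
#'   list(mean = 0, sd = 0))`).
#' @return A list of class `sim_config`.
#' @details Black-hole distributions are specified per interval as
#'   `list(family, mean, sd, phys_share, patient_share)` with
#'   `family` one of `"lognormal"` (default), `"gamma"`, `"empirical"`
#'   (requires a `sample` element). Shares are duration-scale variance
#'   proportions attributable to the physician and to patient demographics
#'   (age, sex, race, ethnicity); the remainder is residual.
#' @export
sim_config <- function(...) {
  defaults <- list(
    n_encounters = 200L,
    n_physicians = 10L,
    n_patients = NULL,          # default: ~ 70% of encounter count
    seed = 1L,
    appt_mix = c("15" = 0.35, "20" = 0.25, "30" = 0.30, "40" = 0.10),
    period_mix = c(pre = 0.5, post = 0.5),
    pre_window = c("2015-04-01", "2016-03-31"),
    post_window = c("2016-06-01", "2017-06-30"),
    los_probs = c("2" = 0.08, "3" = 0.42, "4" = 0.40, "5" = 0.10),
    primary_dx_probs = c(diabetes = 0.045, hypertension = 0.045,
                         hyperlipidemia = 0.012, other = 0.898),
    blackholes = list(
      MA_ROOM_TO_LOGIN = list(family = "lognormal", mean = 0.73, sd = 1.01,
                              phys_share = 0.116, patient_share = 0.351),
      MA_LOGOFF_TO_EXIT = list(family = "lognormal", mean = 0.51, sd = 1.39,
                               phys_share = 0.069, patient_share = 0.467),
      PHYS_ENTER_TO_LOGIN = list(family = "lognormal", mean = 2.62, sd = 1.61,
                                 phys_share = 0.622, patient_share = 0.148),
      PHYS_LOGOFF_TO_EXIT = list(family = "lognormal", mean = 0.82, sd = 1.29,
                                 phys_share = 0.111, patient_share = 0.230),
      PHYS_EXIT_TO_PATIENT_EXIT = list(family = "lognormal", mean = 2.72,
                                       sd = 4.11, phys_share = 0.391,
                                       patient_share = 0.175)
    ),
    visit = list(
      checkin_mean = 1.5, checkin_sd = 1.0,   # front-desk check-in duration
      wait_mean = 8, wait_sd = 5,             # waiting room
      ma_mean = 4, ma_sd = 1.5,               # MA exam-room session
      phys_gap_mean = 3, phys_gap_sd = 2,     # MA exit -> physician enters
      ehr_mean = 9, ehr_sd = 3.5,             # physician exam-room EHR total
      p_two_sessions = 0.4,
      break_mean = 2, break_sd = 1,           # off-EHR gap between sessions
      click_rate = 6,                         # physician clicks / min in session
      ma_click_rate = 3,
      previsit_clicks = 60, postvisit_clicks = 30
    ),
    # per-label observer jitter SD (min) for time-motion records; labels
    # that are also audit-derivable default to the observed-vs-audit SDs
    # of the validation study, the rest to 15 s of observer precision
    tm_jitter_sd = c(CHECKIN_START = 1.5, CHECKIN_END = 2.9, ROOM_START = 0.25,
                     MA_LOGIN = 1.7, MA_LOGOFF = 0.5, MA_EXIT = 0.25,
                     PHYS_ENTER = 0.25, PHYS_LOGIN = 1.5, PHYS_LOGOFF = 1.9,
                     PHYS_EXIT = 0.25, PATIENT_EXIT = 0.25),
    # per-label probability a time-motion observation is missing
    tm_miss = c(CHECKIN_START = 0, CHECKIN_END = 0, ROOM_START = 0.08,
                MA_LOGIN = 0.25, MA_LOGOFF = 0.22, MA_EXIT = 0.25,
                PHYS_ENTER = 0.09, PHYS_LOGIN = 0.25, PHYS_LOGOFF = 0.29,
                PHYS_EXIT = 0.12, PATIENT_EXIT = 0.09),
    phys_re_sd = 0.15,   # physician random effect, log EHR-time scale
    pat_re_sd = 0.10,    # patient random effect, log EHR-time scale
    # confounding: covariates that raise both exposure odds and EHR time
    outcome_confounding = c(age_z = 0.08, dm = 0.25, htn = 0.10),
    exposure = list(enabled = TRUE, post_only = TRUE, pilot_frac = 0.5,
                    intercept = -1.5,
                    coef = c(age_z = 0.4, female = 0.2, dm = 0.8, htn = 0.4,
                             dyslip = 0.3, appt15 = 0.3),
                    phys_sd = 0.5),
    effect = list(delta_ehr = 0, click_mult = 1, by_appt_band = NULL),
    feasibility_factor = 3
  )
  cfg <- utils::modifyList(defaults, list(...))
  if (is.null(cfg$n_patients)) cfg$n_patients <- max(2L, round(cfg$n_encounters * 0.7))
  validate_sim_config(cfg)
  class(cfg) <- c("sim_config", "list")
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_encounters >= 1, cfg$n_physicians >= 1, cfg$n_patients >= 1)
  if (abs(sum(cfg$appt_mix) - 1) > 1e-6) stop("appt_mix must sum to 1")
  if (!all(names(cfg$appt_mix) %in% c("15", "20", "30", "40")))
    stop("appt_mix names must be among 15/20/30/40")
  for (nm in names(cfg$blackholes)) {
    bh <- cfg$blackholes[[nm]]
    if (bh$mean < 0 || bh$sd < 0) stop("black hole ", nm, ": mean/sd must be >= 0")
    sh <- c(bh$phys_share %||% 0, bh$patient_share %||% 0)
    if (any(sh < 0) || sum(sh) > 1) stop("black hole ", nm, ": invalid shares")
    if (identical(bh$family, "empirical") && !length(bh$sample))
      stop("black hole ", nm, ": empirical family needs a sample")
  }
  jit <- cfg$tm_jitter_sd
  if (any(jit < 0)) stop("tm_jitter_sd must be >= 0")
  if (any(cfg$tm_miss < 0 | cfg$tm_miss > 1)) stop("tm_miss must be in [0,1]")
  v <- cfg$visit
  in_room <- v$ma_mean + v$phys_gap_mean + v$ehr_mean + v$break_mean +
    sum(vapply(cfg$blackholes, function(b) b$mean, numeric(1)))
  mean_appt <- sum(as.numeric(names(cfg$appt_mix)) * cfg$appt_mix)
  if (in_room > cfg$feasibility_factor * mean_appt) {
    stop("infeasible config: expected in-room time ", round(in_room, 1),
         " min exceeds ", cfg$feasibility_factor, "x the mean scheduled length")
  }
  invisible(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# lognormal draw parameterized by natural-scale mean/sd
rlnorm_ms <- function(n, m, s) {
  if (m <= 0) return(rep(0, n))
  if (s <= 0) return(rep(m, n))
  sig2 <- log(1 + (s / m)^2)
  stats::rlnorm(n, log(m) - sig2 / 2, sqrt(sig2))
}

# Rescale a positive factor vector to sample mean 1 and sample variance v.
standardize_factor <- function(f, v) {
  if (v <= 0 || length(f) < 2L || stats::sd(f) == 0) return(rep(1, length(f)))
  out <- 1 + (f - mean(f)) / stats::sd(f) * sqrt(v)
  pmax(out, 0.01)
}

# One black-hole duration vector. phys_z: one standard-normal draw per
# physician for this interval; pat_z: standardized patient-covariate score
# per encounter. The lognormal family multiplies three positive factors
# (physician, patient, residual) whose variances A, B, C are solved so that
# the duration-scale marginal matches (mean, sd) and the duration-scale
# ANOVA shares match (phys_share, patient_share):
#   A = p_phys * cv^2, B = p_pat * cv^2, (1+A)(1+B)(1+C) = 1 + cv^2.
# Realized physician and patient factors are standardized to their target
# sample moments so realized shares do not drift with few physicians.
draw_blackhole <- function(spec, phys_idx, phys_z, pat_z) {
  n <- length(phys_idx)
  m <- spec$mean; s <- spec$sd
  fam <- spec$family %||% "lognormal"
  if (fam == "empirical")
    return(spec$sample[sample.int(length(spec$sample), n, replace = TRUE)])
  if (m <= 0) return(rep(0, n))
  if (s <= 0) return(rep(m, n))
  cv2 <- (s / m)^2
  p_p <- spec$phys_share %||% 0
  p_b <- spec$patient_share %||% 0
  A <- p_p * cv2
  B <- p_b * cv2
  C <- max(0, (1 + cv2) / ((1 + A) * (1 + B)) - 1)
  f_phys <- standardize_factor(exp(phys_z * sqrt(log(1 + A)))[phys_idx], A)
  f_pat <- standardize_factor(exp(pat_z * sqrt(log(1 + B))), B)
  resid <- if (fam == "gamma") {
    mg <- 1; sg2 <- C
    if (C > 0) stats::rgamma(n, shape = mg^2 / sg2, scale = sg2 / mg) else rep(1, n)
  } else {
    if (C > 0) stats::rlnorm(n, -log(1 + C) / 2, sqrt(log(1 + C))) else rep(1, n)
  }
  pmax(m * f_phys * f_pat * resid, 0)
}

#' Simulate a clinic's encounters, audit log and time-motion records
#'
#' Discrete-event simulation of outpatient encounters. For each encounter
#' the full ground-truth timeline is generated (check-in through patient
#' exit), role-stamped audit events are emitted at the front desk and in the
#' examination room, and jittered, partially missing time-motion
#' observations are recorded. The black-hole boundary times (rooming start,
#' MA exit, physician enter/exit, patient exit) generate **no** audit
#' events: they are observable only in the time-motion output, exactly the
#' censoring structure the calibration and imputation machinery exists to
#' handle.
#'
#' @param config A [sim_config()] object (or a plain list passed to it).
#' @return A list of class `clinic_sim` with elements `encounters`, `truth`
#'   (per-encounter true times as UTC `POSIXct` plus the four true
#'   efficiency measures), `events`, `time_motion`, `location_map`,
#'   `physicians`, `patients`, and the `config` used.
#' @export
simulate_clinic <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_encounters
  J <- cfg$n_physicians
  v <- cfg$visit

  ## physicians, patients --------------------------------------------------
  phys_id <- sprintf("P%03d", seq_len(J))
  pilot <- stats::runif(J) < (cfg$exposure$pilot_frac %||% 1)
  if (isTRUE(cfg$exposure$enabled) && !any(pilot)) pilot[1] <- TRUE
  physicians <- data.frame(
    physician_id = phys_id,
    practice_type = sample(c("family", "internal"), J, replace = TRUE),
    pilot = pilot,
    stringsAsFactors = FALSE
  )
  phys_bh_z <- matrix(stats::rnorm(J * 5), nrow = J,
                      dimnames = list(phys_id, names(cfg$blackholes)))
  phys_out_re <- stats::rnorm(J, 0, cfg$phys_re_sd)
  phys_exp_u <- stats::rnorm(J, 0, cfg$exposure$phys_sd)

  np <- cfg$n_patients
  pat_id <- sprintf("PT%05d", seq_len(np))
  age <- round(pmin(pmax(stats::rnorm(np, 58, 14), 18), 95))
  sex <- sample(c("F", "M"), np, replace = TRUE, prob = c(0.55, 0.45))
  race <- sample(c("White", "Black", "Asian", "Other"), np, replace = TRUE,
                 prob = c(0.55, 0.12, 0.22, 0.11))
  ethnicity <- sample(c("Hispanic", "NonHispanic"), np, replace = TRUE,
                      prob = c(0.15, 0.85))
  dm <- stats::rbinom(np, 1, 0.35)
  htn <- stats::rbinom(np, 1, 0.60)
  dyslip <- stats::rbinom(np, 1, 0.50)
  none <- dm + htn + dyslip == 0   # cardiometabolic panel: force >= 1
  htn[none] <- 1L
  patients <- data.frame(
    patient_id = pat_id, age = age, sex = sex, race = race,
    ethnicity = ethnicity, dm = dm, htn = htn, dyslip = dyslip,
    charlson = stats::rpois(np, 1.2),
    physician_id = phys_id[sample.int(J, np, replace = TRUE)],
    stringsAsFactors = FALSE
  )
  pat_out_re <- stats::rnorm(np, 0, cfg$pat_re_sd)

  ## encounters ------------------------------------------------------------
  p_i <- sample.int(np, n, replace = TRUE)
  enc <- data.frame(
    encounter_id = sprintf("E%06d", seq_len(n)),
    patient_id = pat_id[p_i],
    physician_id = patients$physician_id[p_i],
    stringsAsFactors = FALSE
  )
  j_i <- match(enc$physician_id, phys_id)
  enc$period <- sample(names(cfg$period_mix), n, replace = TRUE,
                       prob = cfg$period_mix)
  win <- list(pre = as.Date(cfg$pre_window), post = as.Date(cfg$post_window))
  enc$date <- as.Date(NA)
  for (p in names(win)) {
    k <- enc$period == p
    days <- seq(win[[p]][1], win[[p]][2], by = "day")
    enc$date[k] <- days[sample.int(length(days), sum(k), replace = TRUE)]
  }
  enc$scheduled_length_min <- as.integer(sample(names(cfg$appt_mix), n,
                                                replace = TRUE, prob = cfg$appt_mix))
  enc$los_level <- as.integer(sample(names(cfg$los_probs), n, replace = TRUE,
                                     prob = cfg$los_probs))
  enc$primary_dx <- sample(names(cfg$primary_dx_probs), n, replace = TRUE,
                           prob = cfg$primary_dx_probs)
  code_of <- c(diabetes = "E11", hypertension = "I10", hyperlipidemia = "E78")
  other_pool <- c("Z00", "J06", "M54", "K21", "F41")
  chronic <- mapply(function(d, h, l) {
    paste(c("E11"[d == 1], "I10"[h == 1], "E78"[l == 1]), collapse = ";")
  }, patients$dm[p_i], patients$htn[p_i], patients$dyslip[p_i])
  extra <- other_pool[sample.int(length(other_pool), n, replace = TRUE)]
  prim_code <- ifelse(enc$primary_dx == "other",
                      other_pool[sample.int(length(other_pool), n, replace = TRUE)],
                      code_of[enc$primary_dx])
  enc$dx_codes <- vapply(seq_len(n), function(i) {
    paste(unique(c(prim_code[i], strsplit(chronic[i], ";")[[1]], extra[i])),
          collapse = ";")
  }, character(1))

  # sequential slots per physician-day from 08:00 UTC, 5-min turnover
  ord <- order(enc$physician_id, enc$date)
  grp <- paste(enc$physician_id, enc$date)[ord]
  slotlen <- enc$scheduled_length_min[ord] + 5
  off <- stats::ave(slotlen, grp, FUN = function(x) c(0, utils::head(cumsum(x), -1L)))
  t0 <- numeric(n)
  t0[ord] <- as.numeric(as.POSIXct(paste(enc$date[ord], "08:00:00"), tz = "UTC")) +
    off * 60

  ## covariate scores ------------------------------------------------------
  age_z <- (patients$age[p_i] - 58) / 14
  female <- as.numeric(patients$sex[p_i] == "F")
  race_coef <- c(White = 0, Black = 0.3, Asian = 0.2, Other = 0.25)
  hisp <- as.numeric(patients$ethnicity[p_i] == "Hispanic")
  pat_raw <- 0.6 * age_z + 0.5 * female + race_coef[patients$race[p_i]] +
    0.4 * hisp
  pat_z <- if (stats::sd(pat_raw) > 0) as.numeric(scale(pat_raw)) else rep(0, n)

  ## black holes (minutes) -------------------------------------------------
  bh <- sapply(names(cfg$blackholes), function(nm) {
    draw_blackhole(cfg$blackholes[[nm]], j_i, phys_bh_z[, nm], pat_z)
  })
  bh <- matrix(bh, nrow = n, dimnames = list(NULL, names(cfg$blackholes)))

  ## timeline (whole seconds since epoch; audit logs carry second
  ## granularity, and integer seconds keep truth-vs-derived arithmetic exact)
  checkin_start <- round(t0 - stats::runif(n, 3, 12) * 60)
  checkin_end <- round(checkin_start + rlnorm_ms(n, v$checkin_mean, v$checkin_sd) * 60)
  room_start <- round(checkin_end + rlnorm_ms(n, v$wait_mean, v$wait_sd) * 60)
  ma_login <- round(room_start + bh[, "MA_ROOM_TO_LOGIN"] * 60)
  ma_logoff <- round(ma_login + rlnorm_ms(n, v$ma_mean, v$ma_sd) * 60)
  ma_exit <- round(ma_logoff + bh[, "MA_LOGOFF_TO_EXIT"] * 60)
  phys_enter <- round(ma_exit + rlnorm_ms(n, v$phys_gap_mean, v$phys_gap_sd) * 60)
  phys_login <- round(phys_enter + bh[, "PHYS_ENTER_TO_LOGIN"] * 60)

  conf <- cfg$outcome_confounding
  lp_out <- conf["age_z"] * age_z + conf["dm"] * patients$dm[p_i] +
    conf["htn"] * patients$htn[p_i]
  ehr_total <- rlnorm_ms(n, v$ehr_mean, v$ehr_sd) *
    exp(phys_out_re[j_i] + pat_out_re[p_i] + lp_out)
  two <- stats::rbinom(n, 1, v$p_two_sessions) == 1
  w1 <- ifelse(two, stats::runif(n, 0.3, 0.7), 1)
  brk <- ifelse(two, pmax(rlnorm_ms(n, v$break_mean, v$break_sd), 0.05), 0)

  ## exposure --------------------------------------------------------------
  exposure <- rep(FALSE, n)
  if (isTRUE(cfg$exposure$enabled)) {
    ce <- cfg$exposure$coef
    lp_exp <- cfg$exposure$intercept + phys_exp_u[j_i] +
      ce["age_z"] * age_z + ce["female"] * female +
      ce["dm"] * patients$dm[p_i] + ce["htn"] * patients$htn[p_i] +
      ce["dyslip"] * patients$dyslip[p_i] +
      ce["appt15"] * (enc$scheduled_length_min == 15)
    pr <- stats::plogis(lp_exp)
    eligible <- if (isTRUE(cfg$exposure$post_only)) enc$period == "post" else rep(TRUE, n)
    eligible <- eligible & pilot[j_i]   # only pilot physicians launch the tool
    exposure <- eligible & stats::runif(n) < pr
    mean_pr <- mean(pr[eligible])
  } else mean_pr <- 0
  enc$exposure <- as.logical(exposure)
  attr(enc, "exposure_mean_pr") <- mean_pr

  ## base click counts -----------------------------------------------------
  clicks_in <- stats::rpois(n, v$click_rate * ehr_total)
  clicks_pre <- stats::rpois(n, v$previsit_clicks)
  clicks_post <- stats::rpois(n, v$postvisit_clicks)

  ## truth table (pre-effect), then inject the treatment effect ------------
  truth <- data.frame(
    encounter_id = enc$encounter_id,
    patient_id = enc$patient_id, physician_id = enc$physician_id,
    exposure = enc$exposure, stringsAsFactors = FALSE
  )
  truth$CHECKIN_START <- checkin_start; truth$CHECKIN_END <- checkin_end
  truth$ROOM_START <- room_start
  truth$MA_LOGIN <- ma_login; truth$MA_LOGOFF <- ma_logoff
  truth$MA_EXIT <- ma_exit
  truth$PHYS_ENTER <- phys_enter; truth$PHYS_LOGIN <- phys_login
  truth$n_sessions <- 1L + as.integer(two)
  truth$w1 <- w1; truth$brk_min <- brk
  truth$ehr_min <- ehr_total
  truth$clicks_in <- clicks_in; truth$clicks_pre <- clicks_pre
  truth$clicks_post <- clicks_post
  truth$delta_applied <- 0; truth$click_mult_applied <- 1

  truth <- inject_effect(truth, cfg$effect,
                         appt_band = appt_band(enc$scheduled_length_min))

  ## finish the timeline with post-effect EHR time -------------------------
  s1_start <- phys_login
  s1_end <- round(s1_start + truth$ehr_min * truth$w1 * 60)
  s2_start <- ifelse(two, round(s1_end + truth$brk_min * 60), NA_real_)
  s2_end <- ifelse(two, round(s2_start + truth$ehr_min * (1 - truth$w1) * 60),
                   NA_real_)
  phys_logoff <- ifelse(two, s2_end, s1_end)
  phys_exit <- round(phys_logoff + bh[, "PHYS_LOGOFF_TO_EXIT"] * 60)
  patient_exit <- round(phys_exit + bh[, "PHYS_EXIT_TO_PATIENT_EXIT"] * 60)
  checkout <- round(patient_exit + (16 + rlnorm_ms(n, 2, 1)) * 60)

  truth$PHYS_LOGOFF <- phys_logoff; truth$PHYS_EXIT <- phys_exit
  truth$PATIENT_EXIT <- patient_exit; truth$CHECKOUT <- checkout
  truth$s1_start <- s1_start; truth$s1_end <- s1_end
  truth$s2_start <- s2_start; truth$s2_end <- s2_end

  # true efficiency measures, via the same minute arithmetic the
  # extraction engine uses
  truth$total_encounter_min <- (patient_exit - checkin_start) / 60
  truth$phys_exam_room_min <- (phys_exit - phys_enter) / 60
  truth$phys_ehr_exam_min <- ((s1_end - s1_start) +
                                ifelse(two, s2_end - s2_start, 0)) / 60
  truth$total_clicks <- 2L * truth$n_sessions + truth$clicks_in +
    truth$clicks_pre + truth$clicks_post

  ## audit events ----------------------------------------------------------
  ws_fd <- "WS-FD-01"
  ws_ex <- sprintf("WS-EX-%03d", seq_len(J))
  ws_off <- sprintf("WS-OFF-%03d", seq_len(J))
  location_map <- data.frame(
    workstation_id = c(ws_fd, ws_ex, ws_off),
    location_class = c("front_desk", rep("exam_room", J), rep("other", J)),
    stringsAsFactors = FALSE
  )
  ma_role <- sample(c("medical_assistant", "nurse"), J, replace = TRUE,
                    prob = c(0.8, 0.2))
  ma_user <- sprintf("MA%03d", seq_len(J))
  fd_user <- "FD001"
  feature_codes <- c("CHART_REVIEW", "MED_LIST", "NOTE_EDIT", "ORDER_ENTRY",
                     "RESULT_VIEW", "MSG_VIEW")

  ev <- list()
  add <- function(eid, uid, role, ws, ts, code) {
    data.frame(encounter_id = eid, user_id = uid, user_role = role,
               workstation_id = ws, timestamp = ts, action_code = code,
               stringsAsFactors = FALSE)
  }
  # front desk: open at CHECKIN_START, complete at CHECKIN_END, extras between
  n_fd_mid <- stats::rpois(n, 1)
  mid_i <- rep(seq_len(n), n_fd_mid)
  mid_ts <- checkin_start[mid_i] +
    stats::runif(length(mid_i)) * (checkin_end - checkin_start)[mid_i]
  ev$fd <- add(c(enc$encounter_id, enc$encounter_id, enc$encounter_id[mid_i]),
               fd_user, "front_desk", ws_fd,
               c(checkin_start, checkin_end, mid_ts),
               c(rep("CHECKIN_OPEN", n), rep("CHECKIN_COMPLETE", n),
                 rep("DEMOGRAPHICS_VIEW", length(mid_i))))
  # MA exam-room session
  n_ma_mid <- stats::rpois(n, v$ma_click_rate * (ma_logoff - ma_login) / 60)
  mam_i <- rep(seq_len(n), n_ma_mid)
  mam_ts <- ma_login[mam_i] + stats::runif(length(mam_i)) *
    (ma_logoff - ma_login)[mam_i]
  ev$ma <- add(c(enc$encounter_id, enc$encounter_id, enc$encounter_id[mam_i]),
               ma_user[c(j_i, j_i, j_i[mam_i])],
               ma_role[c(j_i, j_i, j_i[mam_i])],
               ws_ex[c(j_i, j_i, j_i[mam_i])],
               c(ma_login, ma_logoff, mam_ts),
               c(rep("LOGIN", n), rep("LOGOFF", n),
                 rep("VITALS_ENTRY", length(mam_i))))
  # physician sessions (LOGIN/LOGOFF pairs) and in-session clicks
  s_eid <- c(enc$encounter_id, enc$encounter_id[two])
  s_ji <- c(j_i, j_i[two])
  s_lo <- c(s1_start, s2_start[two])
  s_hi <- c(s1_end, s2_end[two])
  ev$sess <- add(c(s_eid, s_eid), sprintf("%s", phys_id[c(s_ji, s_ji)]),
                 "physician", ws_ex[c(s_ji, s_ji)], c(s_lo, s_hi),
                 c(rep("LOGIN", length(s_lo)), rep("LOGOFF", length(s_hi))))
  ck_in <- truth$clicks_in
  n2 <- ifelse(two, stats::rbinom(n, ck_in, pmin(pmax(1 - truth$w1, 0), 1)), 0L)
  n1 <- ck_in - n2
  in1_i <- rep(seq_len(n), n1)
  in2_i <- rep(seq_len(n), n2)
  in_ts <- c(s1_start[in1_i] + stats::runif(length(in1_i)) * (s1_end - s1_start)[in1_i],
             s2_start[in2_i] + stats::runif(length(in2_i)) * (s2_end - s2_start)[in2_i])
  in_i <- c(in1_i, in2_i)
  ev$clicks <- add(enc$encounter_id[in_i], phys_id[j_i[in_i]], "physician",
                   ws_ex[j_i[in_i]], in_ts,
                   feature_codes[sample.int(6, length(in_i), replace = TRUE)])
  # pre-visit chart review (while the patient checks in / waits) and
  # post-visit wrap-up (before checkout closes the encounter), office workstation
  pre_i <- rep(seq_len(n), truth$clicks_pre)
  pre_ts <- checkin_start[pre_i] + stats::runif(length(pre_i)) *
    pmax(room_start - checkin_start - 30, 1)[pre_i]
  post_i <- rep(seq_len(n), truth$clicks_post)
  post_ts <- patient_exit[post_i] + 30 +
    stats::runif(length(post_i)) * (checkout - patient_exit - 60)[post_i]
  ev$prepost <- add(enc$encounter_id[c(pre_i, post_i)],
                    phys_id[j_i[c(pre_i, post_i)]], "physician",
                    ws_off[j_i[c(pre_i, post_i)]], c(pre_ts, post_ts),
                    feature_codes[sample.int(6, length(pre_i) + length(post_i),
                                             replace = TRUE)])
  events <- do.call(rbind, ev)
  events$timestamp <- round(events$timestamp)
  events <- events[order(events$encounter_id, events$timestamp), , drop = FALSE]
  events$timestamp <- as.POSIXct(events$timestamp, origin = "1970-01-01", tz = "UTC")
  rownames(events) <- NULL

  ## time-motion records ---------------------------------------------------
  labs <- setdiff(workflow_point_labels(), "CHECKOUT")
  tm <- do.call(rbind, lapply(labs, function(lb) {
    tt <- truth[[lb]]
    keep <- !is.na(tt) & stats::runif(n) >= cfg$tm_miss[[lb]]
    jit <- if (cfg$tm_jitter_sd[[lb]] > 0)
      stats::rnorm(sum(keep), 0, cfg$tm_jitter_sd[[lb]]) else 0
    data.frame(encounter_id = enc$encounter_id[keep], point_label = lb,
               observed_time = round(tt[keep] + jit * 60),
               stringsAsFactors = FALSE)
  }))
  tm <- tm[order(tm$encounter_id, match(tm$point_label, workflow_point_labels())), ]
  tm$observed_time <- as.POSIXct(tm$observed_time, origin = "1970-01-01", tz = "UTC")
  rownames(tm) <- NULL

  for (cl in c("CHECKIN_START", "CHECKIN_END", "ROOM_START", "MA_LOGIN",
               "MA_LOGOFF", "MA_EXIT", "PHYS_ENTER", "PHYS_LOGIN",
               "PHYS_LOGOFF", "PHYS_EXIT", "PATIENT_EXIT", "CHECKOUT",
               "s1_start", "s1_end", "s2_start", "s2_end")) {
    truth[[cl]] <- as.POSIXct(truth[[cl]], origin = "1970-01-01", tz = "UTC")
  }

  structure(list(encounters = enc, truth = truth, events = events,
                 time_motion = tm, location_map = location_map,
                 physicians = physicians, patients = patients,
                 config = cfg),
            class = "clinic_sim")
}

appt_band <- function(scheduled_length_min) {
  ifelse(scheduled_length_min <= 20, "<=20",
         ifelse(scheduled_length_min >= 30, ">=30", NA_character_))
}

#' Inject a treatment effect into ground-truth timelines
#'
#' Applies the configured effect to every exposed row of a truth table:
#' true physician exam-room EHR time is reduced by `delta_ehr` minutes
#' (clipped at zero) and true click counts are scaled by `click_mult`
#' (rounded to the nearest integer). Unexposed rows are untouched.
#'
#' @param truth Truth table (as built inside [simulate_clinic()]) with at
#'   least columns `exposure`, `ehr_min`, `clicks_in`, `clicks_pre`,
#'   `clicks_post`.
#' @param effect List with `delta_ehr` (minutes), `click_mult`
#'   (multiplier), and optional `by_appt_band` (named vector of
#'   `delta_ehr` overrides for bands `"<=20"`/`">=30"`).
#' @param appt_band Optional per-row appointment band used with
#'   `by_appt_band`.
#' @return The modified truth table; columns `delta_applied` and
#'   `click_mult_applied` record what was done.
#' @export
inject_effect <- function(truth, effect, appt_band = NULL) {
  delta <- rep(effect$delta_ehr %||% 0, nrow(truth))
  if (!is.null(effect$by_appt_band) && !is.null(appt_band)) {
    for (b in names(effect$by_appt_band)) {
      delta[!is.na(appt_band) & appt_band == b] <- effect$by_appt_band[[b]]
    }
  }
  mult <- effect$click_mult %||% 1
  stopifnot(all(is.finite(delta)), is.finite(mult))
  k <- which(truth$exposure)
  if (!length(k)) return(truth)
  new_ehr <- pmax(truth$ehr_min[k] - delta[k], 0)
  truth$delta_applied[k] <- truth$ehr_min[k] - new_ehr
  truth$ehr_min[k] <- new_ehr
  if (mult != 1) {
    for (col in c("clicks_in", "clicks_pre", "clicks_post")) {
      truth[[col]][k] <- as.integer(round(truth[[col]][k] * mult))
    }
    truth$click_mult_applied[k] <- mult
  }
  if (all(c("s1_start", "PATIENT_EXIT") %in% names(truth))) {
    # timeline already realized: shrink the sessions, shift every later
    # point earlier by the saved time, keep the black-hole gaps intact
    red <- truth$delta_applied[k] * 60
    two <- !is.na(truth$s2_start[k])
    w1 <- truth$w1[k]
    truth$s1_end[k] <- truth$s1_end[k] - round(red * w1)
    truth$s2_start[k[two]] <- truth$s2_start[k[two]] - round(red * w1)[two]
    truth$s2_end[k[two]] <- truth$s2_end[k[two]] - round(red)[two]
    for (col in c("PHYS_LOGOFF", "PHYS_EXIT", "PATIENT_EXIT", "CHECKOUT")) {
      truth[[col]][k] <- truth[[col]][k] - round(red)
    }
    truth$phys_ehr_exam_min[k] <- pmax(truth$phys_ehr_exam_min[k] -
                                         truth$delta_applied[k], 0)
    truth$phys_exam_room_min[k] <- truth$phys_exam_room_min[k] -
      truth$delta_applied[k]
    truth$total_encounter_min[k] <- truth$total_encounter_min[k] -
      truth$delta_applied[k]
    truth$total_clicks[k] <- 2L * truth$n_sessions[k] + truth$clicks_in[k] +
      truth$clicks_pre[k] + truth$clicks_post[k]
  }
  truth
}

#' Simulate outcomes for an already-matched cohort
#'
#' Generates one case and one control outcome per matched cluster:
#' `outcome = mean + cluster effect + exposed * effect + residual`, the
#' data-generating model under which the matched-cluster mixed model is the
#' natural estimator. Used to validate effect recovery and confidence
#' interval calibration at scale.
#'
#' @param n_pairs Number of matched case-control pairs (clusters).
#' @param effect True exposure effect (e.g. minutes of EHR time).
#' @param cluster_sd SD of the shared cluster (pair) random intercept.
#' @param resid_sd Residual SD.
#' @param mean Baseline outcome mean.
#' @return `data.frame` with columns `outcome`, `exposed` (0/1), `cluster`.
#' @export
simulate_matched_outcomes <- function(n_pairs, effect = 0, cluster_sd = 3,
                                      resid_sd = 2, mean = 10) {
  b <- stats::rnorm(n_pairs, 0, cluster_sd)
  data.frame(
    outcome = mean + rep(b, each = 2) + rep(c(0, 1), n_pairs) * effect +
      stats::rnorm(2 * n_pairs, 0, resid_sd),
    exposed = rep(c(0L, 1L), n_pairs),
    cluster = rep(seq_len(n_pairs), each = 2)
  )
}

#' Write / read a ground-truth timeline file (JSON Lines)
#'
#' The truth file exists for testing and validation only; real audit-log
#' analyses have no such file.
#'
#' @param truth Truth table from [simulate_clinic()].
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  for (cl in names(out)) {
    if (inherits(out[[cl]], "POSIXct")) out[[cl]] <- format_timestamp(out[[cl]])
  }
  con <- file(path, "w"); on.exit(close(con))
  jsonlite::stream_out(out, con, verbose = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  out <- jsonlite::stream_in(file(path), verbose = FALSE)
  for (cl in names(out)) {
    if (is.character(out[[cl]]) && all(grepl("^\\d{4}-\\d{2}-\\d{2}T", out[[cl]]) |
                                       is.na(out[[cl]]))) {
      out[[cl]] <- parse_timestamp(out[[cl]])
    }
  }
  out
}
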