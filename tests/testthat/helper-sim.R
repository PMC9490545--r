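# Shared fixtures and an independent brute-force reference implementation.

bh_names <- c("MA_ROOM_TO_LOGIN", "MA_LOGOFF_TO_EXIT", "PHYS_ENTER_TO_LOGIN",
              "PHYS_LOGOFF_TO_EXIT", "PHYS_EXIT_TO_PATIENT_EXIT")

all_labels_no_checkout <- c("CHECKIN_START", "CHECKIN_END", "ROOM_START",
                            "MA_LOGIN", "MA_LOGOFF", "MA_EXIT", "PHYS_ENTER",
                            "PHYS_LOGIN", "PHYS_LOGOFF", "PHYS_EXIT",
                            "PATIENT_EXIT")

zero_blackholes <- function() {
  lapply(setNames(nm = bh_names), function(x) {
    list(family = "lognormal", mean = 0, sd = 0, phys_share = 0,
         patient_share = 0)
  })
}

zero_jitter <- function() setNames(rep(0, 11), all_labels_no_checkout)

no_miss <- function() setNames(rep(0, 11), all_labels_no_checkout)

# all black holes and observer jitter switched off: audit-derivable times
# coincide with truth, so everything downstream must be exact
degenerate_config <- function(n, seed) {
  sim_config(n_encounters = n, seed = seed, blackholes = zero_blackholes(),
             tm_jitter_sd = zero_jitter())
}

# a clinic whose tool uptake is strongly confounded by patient mix: older,
# diabetic, hypertensive patients (who also accrue more EHR time) are far
# more likely to have the tool launched
confounded_config <- function(seed, n_encounters = 5600, n_patients = 4000) {
  sim_config(n_encounters = n_encounters, n_patients = n_patients, seed = seed,
             exposure = list(post_only = FALSE, pilot_frac = 1,
                             intercept = -3.3,
                             coef = c(age_z = 0.9, female = 0.3, dm = 1.2,
                                      htn = 0.5, dyslip = 0.4, appt15 = 0.5)))
}

patient_features <- function(su) {
  su[, c("age", "female", "hispanic", "pct_appt15", "pct_appt30", "pct_los3",
         "pct_los4", "pct_dx_dm", "pct_dx_htn", "pct_dx_dyslip"), drop = FALSE]
}

# low click rates so encounters stay small (<= 60 events each)
sparse_config <- function(n, seed) {
  sim_config(n_encounters = n, seed = seed,
             visit = list(click_rate = 1, ma_click_rate = 0.5,
                          previsit_clicks = 5, postvisit_clicks = 3,
                          ehr_mean = 8, ehr_sd = 2))
}

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

# long point table -> wide, for assertions
points_wide_test <- function(points) {
  ids <- unique(points$encounter_id)
  out <- data.frame(encounter_id = ids, stringsAsFactors = FALSE)
  for (lb in unique(points$label)) {
    p <- points[points$label == lb, ]
    out[[lb]] <- p$time[match(ids, p$encounter_id)]
  }
  out
}

# a minimal hand-built encounter log: front-desk pair, MA pair, physician pair
hand_log <- function(eid = "E1") {
  data.frame(
    encounter_id = eid,
    user_id = c("FD1", "FD1", "MA1", "MA1", "DR1", "DR1", "DR1", "DR1"),
    user_role = c("front_desk", "front_desk", "medical_assistant",
                  "medical_assistant", "physician", "physician", "physician",
                  "physician"),
    workstation_id = c("W_FD", "W_FD", "W_EX", "W_EX", "W_EX", "W_EX", "W_EX",
                       "W_EX"),
    timestamp = ts_utc(c("2016-06-01 08:55:00", "2016-06-01 08:57:30",
                         "2016-06-01 09:05:00", "2016-06-01 09:09:00",
                         "2016-06-01 09:14:00", "2016-06-01 09:18:00",
                         "2016-06-01 09:20:00", "2016-06-01 09:26:00")),
    action_code = c("CHECKIN_OPEN", "CHECKIN_COMPLETE", "LOGIN", "LOGOFF",
                    "LOGIN", "CHART_REVIEW", "NOTE_EDIT", "LOGOFF"),
    stringsAsFactors = FALSE
  )
}

hand_map <- function() {
  data.frame(workstation_id = c("W_FD", "W_EX", "W_OFF"),
             location_class = c("front_desk", "exam_room", "other"),
             stringsAsFactors = FALSE)
}

## ---- independent brute-force reference (plain loops, no shared code) ----

brute_derive_points <- function(events, map) {
  loc <- map$location_class[match(events$workstation_id, map$workstation_id)]
  out <- list()
  for (eid in unique(events$encounter_id)) {
    sel <- events$encounter_id == eid
    ev <- events[sel, ]
    lc <- loc[sel]
    o <- order(ev$timestamp)
    ev <- ev[o, ]; lc <- lc[o]
    t <- as.numeric(ev$timestamp)
    res <- c()
    fd <- ev$user_role == "front_desk" & lc == "front_desk"
    if (any(fd)) {
      res["CHECKIN_START"] <- min(t[fd])
      res["CHECKIN_END"] <- max(t[fd])
    }
    ma <- ev$user_role %in% c("medical_assistant", "nurse") & lc == "exam_room"
    if (any(ma)) {
      ml <- ma & ev$action_code == "LOGIN"
      res["MA_LOGIN"] <- if (any(ml)) min(t[ml]) else min(t[ma])
      mo <- ma & ev$action_code == "LOGOFF"
      res["MA_LOGOFF"] <- if (any(mo)) max(t[mo]) else max(t[ma])
    }
    ph <- ev$user_role == "physician"
    if (any(ph)) {
      users <- unique(ev$user_id[ph])
      best <- NULL; best_n <- -1
      for (u in sort(users)) {
        nu <- sum(ph & ev$user_id == u & lc == "exam_room")
        if (nu > best_n) { best <- u; best_n <- nu }
      }
      px <- ph & ev$user_id == best & lc == "exam_room"
      if (any(px)) {
        pl <- px & ev$action_code == "LOGIN"
        res["PHYS_LOGIN"] <- if (any(pl)) min(t[pl]) else min(t[px])
        po <- px & ev$action_code == "LOGOFF"
        res["PHYS_LOGOFF"] <- if (any(po)) max(t[po]) else max(t[px])
      }
    }
    if (length(res)) {
      out[[eid]] <- data.frame(encounter_id = eid, label = names(res),
                               time = unname(res), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  lab_order <- c("CHECKIN_START", "CHECKIN_END", "ROOM_START", "MA_LOGIN",
                 "MA_LOGOFF", "MA_EXIT", "PHYS_ENTER", "PHYS_LOGIN",
                 "PHYS_LOGOFF", "PHYS_EXIT", "PATIENT_EXIT", "CHECKOUT")
  df <- df[order(df$encounter_id, match(df$label, lab_order)), ]
  rownames(df) <- NULL
  df
}

brute_measures <- function(points, events, map, gap_min = 1) {
  ec <- brute_ehr_clicks(events, map, gap_min)
  ids <- sort(unique(c(points$encounter_id, ec$encounter_id)))
  out <- NULL
  for (eid in ids) {
    p <- points[points$encounter_id == eid, ]
    tget <- function(lb) {
      t <- p$time[p$label == lb]
      if (length(t)) as.numeric(t) else NA_real_
    }
    total <- (tget("PATIENT_EXIT") - tget("CHECKIN_START")) / 60
    exam <- (tget("PHYS_EXIT") - tget("PHYS_ENTER")) / 60
    j <- which(ec$encounter_id == eid)
    ehr <- if (length(j)) ec$ehr_min[j] else if (!is.na(exam)) 0 else NA_real_
    clicks <- if (length(j)) ec$clicks[j] else 0L
    out <- rbind(out, data.frame(
      encounter_id = eid, total_encounter_min = total,
      phys_exam_room_min = exam, phys_ehr_exam_min = min(ehr, exam),
      total_clicks = as.integer(clicks), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

brute_ehr_clicks <- function(events, map, gap_min = 1) {
  loc <- map$location_class[match(events$workstation_id, map$workstation_id)]
  out <- list()
  for (eid in unique(events$encounter_id)) {
    sel <- events$encounter_id == eid
    ev <- events[sel, ]; lc <- loc[sel]
    o <- order(ev$timestamp)
    ev <- ev[o, ]; lc <- lc[o]
    t <- as.numeric(ev$timestamp)
    ph <- ev$user_role == "physician"
    clicks <- 0L; total <- 0
    if (any(ph)) {
      users <- unique(ev$user_id[ph])
      best <- NULL; best_n <- -1
      for (u in sort(users)) {
        nu <- sum(ph & ev$user_id == u & lc == "exam_room")
        if (nu > best_n) { best <- u; best_n <- nu }
      }
      clicks <- sum(ph & ev$user_id == best)
      px <- which(ph & ev$user_id == best & lc == "exam_room")
      open <- NA; last_feat <- NA
      for (i in px) {
        if (ev$action_code[i] == "LOGIN") {
          if (!is.na(open)) {
            end <- if (is.na(last_feat)) open else min(last_feat + gap_min * 60, t[i])
            total <- total + end - open
          }
          open <- t[i]; last_feat <- NA
        } else if (ev$action_code[i] == "LOGOFF") {
          if (!is.na(open)) { total <- total + t[i] - open; open <- NA; last_feat <- NA }
        } else if (!is.na(open)) last_feat <- t[i]
      }
      if (!is.na(open)) {
        end <- if (is.na(last_feat)) open else last_feat + gap_min * 60
        total <- total + end - open
      }
    }
    out[[eid]] <- data.frame(encounter_id = eid, ehr_min = total / 60,
                             clicks = clicks, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
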