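#' Calibrate black-hole interval distributions
#'
#' A "black hole" is a workflow step with no EHR footprint: it can only be
#' observed in person. Calibration pairs, per encounter, the time-motion
#' observation of the unobservable endpoint with the audit-derived (or,
#' when no audit endpoint exists, observed) adjacent point, and keeps the
#' empirical sample of paired differences as that interval's duration
#' distribution. Negative differences -- observer transcription slips --
#' are clipped to zero and counted.
#'
#' @param time_motion Time-motion records ([read_time_motion()] schema).
#' @param audit_points Audit-derived workflow points
#'   ([derive_workflow_points()]).
#' @param encounters,patients Optional encounter and patient metadata; when
#'   both are given, a physician/patient variance decomposition
#'   ([decompose_variance()]) is stored per interval.
#' @return An object of class `blackhole_model`: per interval, the clipped
#'   empirical `sample` (minutes), `n`, `mean`, `sd`, `n_clipped`, and
#'   optionally `shares`. Intervals with zero usable pairs are absent.
#' @export
calibrate_blackholes <- function(time_motion, audit_points,
                                 encounters = NULL, patients = NULL) {
  obs <- tm_wide(time_motion)
  aud <- points_wide(audit_points)
  ids <- union(obs$encounter_id, aud$encounter_id)
  o <- obs[match(ids, obs$encounter_id), , drop = FALSE]
  a <- aud[match(ids, aud$encounter_id), , drop = FALSE]
  defs <- blackhole_intervals()
  intervals <- list()
  for (i in seq_len(nrow(defs))) {
    nm <- defs$interval[i]
    from_lb <- defs$from[i]; to_lb <- defs$to[i]
    side <- defs$audit_side[i]
    from_t <- if (side == "from") a[[from_lb]] else o[[from_lb]]
    to_t <- if (side == "to") a[[to_lb]] else o[[to_lb]]
    if (is.null(from_t) || is.null(to_t)) next
    ok <- !is.na(from_t) & !is.na(to_t)
    if (!any(ok)) next
    d <- mins_between(from_t[ok], to_t[ok])
    ncl <- sum(d < 0)
    d <- pmax(d, 0)
    intervals[[nm]] <- list(
      sample = d, encounter_id = ids[ok], n = length(d),
      mean = mean(d), sd = stats::sd(d), n_clipped = ncl
    )
    if (!is.null(encounters) && !is.null(patients)) {
      eid <- ids[ok]
      phys <- encounters$physician_id[match(eid, encounters$encounter_id)]
      pat <- patients[match(encounters$patient_id[match(eid, encounters$encounter_id)],
                            patients$patient_id), , drop = FALSE]
      keep <- !is.na(phys)
      if (sum(keep) >= 3 && length(unique(phys[keep])) >= 2) {
        intervals[[nm]]$shares <- decompose_variance(
          d[keep], phys[keep], pat$age[keep], pat$sex[keep],
          pat$race[keep], pat$ethnicity[keep])
      }
    }
  }
  structure(list(intervals = intervals), class = "blackhole_model")
}

# time-motion long table -> wide, one POSIXct column per label
tm_wide <- function(tm) {
  p <- tm
  names(p)[names(p) == "point_label"] <- "label"
  names(p)[names(p) == "observed_time"] <- "time"
  points_wide(p)
}

#' @export
print.blackhole_model <- function(x, ...) {
  cat("Black-hole duration model (", length(x$intervals), " intervals)\n", sep = "")
  for (nm in names(x$intervals)) {
    e <- x$intervals[[nm]]
    cat(sprintf("  %-26s n=%4d  mean=%5.2f  sd=%5.2f  clipped=%d\n",
                nm, e$n, e$mean, e$sd, e$n_clipped))
    if (!is.null(e$shares)) {
      cat(sprintf("  %26s physician %.1f%% / patient %.1f%% / residual %.1f%%\n",
                  "", e$shares["physician"], e$shares["patient"],
                  e$shares["residual"]))
    }
  }
  invisible(x)
}

#' Decompose black-hole duration variance
#'
#' Sequential (type I) analysis of variance of interval durations on the
#' physician (entered first, as a categorical factor) and then four patient
#' demographics: age, sex, race, ethnicity. Returns the percentage of total
#' variance attributed to each block; the three shares sum to 100.
#'
#' @param durations Numeric vector of interval durations (minutes).
#' @param physician Physician id per duration (>= 2 distinct values).
#' @param age,sex,race,ethnicity Patient covariates per duration.
#' @return Named numeric vector `c(physician=, patient=, residual=)` in
#'   percent. With a single physician the physician share is undefined
#'   (`NA`) and a warning is raised.
#' @export
decompose_variance <- function(durations, physician, age, sex, race, ethnicity) {
  stopifnot(is.numeric(durations), all(is.finite(durations)))
  if (length(unique(physician)) < 2) {
    warning("variance decomposition needs >= 2 physicians; physician share undefined")
    return(c(physician = NA_real_, patient = NA_real_, residual = NA_real_))
  }
  df <- data.frame(d = durations, phys = factor(physician), age = age,
                   sex = sex, race = race, ethnicity = ethnicity,
                   stringsAsFactors = FALSE)
  # drop patient covariates that are constant (or absent) in this sample
  pat_terms <- c("age", "sex", "race", "ethnicity")
  pat_terms <- pat_terms[vapply(pat_terms, function(v) {
    length(unique(df[[v]][!is.na(df[[v]])])) >= 2
  }, logical(1))]
  fml <- stats::reformulate(c("phys", pat_terms), response = "d")
  fit <- stats::lm(fml, data = df)
  av <- suppressWarnings(stats::anova(fit))  # only the SS are used
  ss <- av[["Sum Sq"]]
  terms <- rownames(av)
  total <- sum(ss)
  if (total <= 0) return(c(physician = 0, patient = 0, residual = 100))
  phys_pct <- 100 * ss[terms == "phys"] / total
  pat_pct <- 100 * sum(ss[terms %in% pat_terms]) / total
  c(physician = phys_pct, patient = pat_pct,
    residual = 100 - phys_pct - pat_pct)
}

#' Impute black-hole boundary points into audit-derived point sets
#'
#' For every encounter whose physician login and logoff are present, draws
#' interval durations by uniform resampling from the calibrated empirical
#' samples (one independent draw per encounter per interval, pooled across
#' physicians) and fills the points the audit log cannot see:
#' `PHYS_ENTER = PHYS_LOGIN - draw`, `PHYS_EXIT = PHYS_LOGOFF + draw`,
#' `PATIENT_EXIT = PHYS_EXIT + draw`, and (when MA points are available)
#' `ROOM_START = MA_LOGIN - draw` and `MA_EXIT = MA_LOGOFF + draw`.
#' Draws that would violate the canonical order are clipped to the nearest
#' feasible time (never redrawn); clips are counted in the `"n_clipped"`
#' attribute. Audit-observed points are never moved.
#'
#' @param points Audit-derived workflow points.
#' @param model A `blackhole_model` from [calibrate_blackholes()].
#' @param seed Optional integer seed for the resampling draws.
#' @param ma_points Impute `ROOM_START`/`MA_EXIT` too (default `TRUE`,
#'   skipped silently when the MA intervals are uncalibrated).
#' @return The input points plus the imputed rows (`provenance =
#'   "imputed"`), sorted by encounter and canonical order. Attributes:
#'   `"n_clipped"`, `"skipped"` (encounter ids lacking physician
#'   login/logoff).
#' @export
impute_points <- function(points, model, seed = NULL, ma_points = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  need <- c("PHYS_ENTER_TO_LOGIN", "PHYS_LOGOFF_TO_EXIT",
            "PHYS_EXIT_TO_PATIENT_EXIT")
  absent <- setdiff(need, names(model$intervals))
  if (length(absent)) {
    stop("black-hole model has no calibrated interval(s): ",
         paste(absent, collapse = ", "))
  }
  w <- points_wide(points)
  ok <- !is.na(w$PHYS_LOGIN) & !is.na(w$PHYS_LOGOFF)
  skipped <- w$encounter_id[!ok]
  w <- w[ok, , drop = FALSE]
  n <- nrow(w)
  n_clipped <- 0L
  resample <- function(s, k) s[sample.int(length(s), k, replace = TRUE)]
  draw <- function(nm) resample(model$intervals[[nm]]$sample, n)
  num <- function(x) as.numeric(x)

  phys_enter <- num(w$PHYS_LOGIN) - draw("PHYS_ENTER_TO_LOGIN") * 60
  floor_t <- pmax(num(w$MA_LOGOFF), num(w$MA_EXIT), num(w$MA_LOGIN),
                  num(w$CHECKIN_END), na.rm = TRUE)
  floor_t[!is.finite(floor_t)] <- -Inf
  clip <- phys_enter < floor_t
  n_clipped <- n_clipped + sum(clip)
  phys_enter <- pmax(phys_enter, floor_t)

  phys_exit <- num(w$PHYS_LOGOFF) + draw("PHYS_LOGOFF_TO_EXIT") * 60
  patient_exit <- phys_exit + draw("PHYS_EXIT_TO_PATIENT_EXIT") * 60

  keep_new <- function(lb, times) {
    miss <- is.na(w[[lb]])   # an already-present point is never overwritten
    data.frame(encounter_id = w$encounter_id[miss], label = lb,
               time = times[miss], stringsAsFactors = FALSE)
  }
  new <- list(
    keep_new("PHYS_ENTER", phys_enter),
    keep_new("PHYS_EXIT", phys_exit),
    keep_new("PATIENT_EXIT", patient_exit)
  )
  if (ma_points && "MA_ROOM_TO_LOGIN" %in% names(model$intervals)) {
    has <- !is.na(w$MA_LOGIN) & is.na(w$ROOM_START)
    if (any(has)) {
      rs <- num(w$MA_LOGIN)[has] -
        resample(model$intervals[["MA_ROOM_TO_LOGIN"]]$sample, sum(has)) * 60
      lo <- num(w$CHECKIN_END)[has]
      cl <- !is.na(lo) & rs < lo
      n_clipped <- n_clipped + sum(cl)
      rs[cl] <- lo[cl]
      new <- c(new, list(data.frame(encounter_id = w$encounter_id[has],
                                    label = "ROOM_START", time = rs,
                                    stringsAsFactors = FALSE)))
    }
  }
  if (ma_points && "MA_LOGOFF_TO_EXIT" %in% names(model$intervals)) {
    has <- !is.na(w$MA_LOGOFF) & is.na(w$MA_EXIT)
    if (any(has)) {
      mx <- num(w$MA_LOGOFF)[has] +
        resample(model$intervals[["MA_LOGOFF_TO_EXIT"]]$sample, sum(has)) * 60
      hi <- phys_enter[has]
      cl <- mx > hi
      n_clipped <- n_clipped + sum(cl)
      mx[cl] <- hi[cl]
      new <- c(new, list(data.frame(encounter_id = w$encounter_id[has],
                                    label = "MA_EXIT", time = mx,
                                    stringsAsFactors = FALSE)))
    }
  }
  add <- do.call(rbind, new)
  add$time <- as.POSIXct(add$time, origin = "1970-01-01", tz = "UTC")
  add$provenance <- "imputed"
  out <- rbind(points[, c("encounter_id", "label", "time", "provenance")], add)
  out <- out[order(out$encounter_id, match(out$label, workflow_point_labels())), ]
  rownames(out) <- NULL
  attr(out, "n_clipped") <- n_clipped
  attr(out, "skipped") <- skipped
  out
}

#' Serialize / restore a black-hole model as JSON
#' @param model A `blackhole_model`.
#' @param path File path.
#' @export
write_blackhole_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_blackhole_model
#' @export
read_blackhole_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m, class = "blackhole_model")
}
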