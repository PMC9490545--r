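#' Cardiometabolic diagnosis codes
#'
#' The eligibility code set: diabetes mellitus, hypertension and
#' dyslipidemia. Kept deliberately small and overridable -- real analyses
#' supply their full grouper.
#' @return Named character vector of codes.
#' @export
cardiometabolic_codes <- function() {
  c(diabetes = "E11", hypertension = "I10", hyperlipidemia = "E78")
}

#' Physician panel summaries
#'
#' Aggregates each physician's encounters into the panel covariates used
#' by the physician-level propensity model: annual encounter volume, mean
#' appointments per day, panel age-band mix, proportion female, proportion
#' Hispanic, proportions with each cardiometabolic condition, practice
#' type, and Charlson-band mix.
#'
#' @param encounters Encounter table.
#' @param patients Patient table (with `age`, `sex`, `ethnicity`, `dm`,
#'   `htn`, `dyslip`, `charlson`).
#' @param physicians Optional physician table carrying `practice_type`.
#' @return One row per physician.
#' @export
summarize_physicians <- function(encounters, patients, physicians = NULL) {
  pi <- match(encounters$patient_id, patients$patient_id)
  e <- cbind(encounters, patients[pi, setdiff(names(patients), "patient_id"),
                                  drop = FALSE])
  res <- lapply(split(e, e$physician_id), function(g) {
    span_yr <- max(as.numeric(max(g$date) - min(g$date) + 1) / 365.25, 1 / 365.25)
    ab <- cut(g$age, c(-Inf, 29, 49, 64, Inf),
              labels = c("lt30", "30_49", "50_64", "ge65"))
    ch <- cut(g$charlson, c(-Inf, 0, 2, Inf), labels = c("0", "1_2", "ge3"))
    data.frame(
      physician_id = g$physician_id[1],
      annual_volume = nrow(g) / span_yr,
      mean_appts_per_day = nrow(g) / length(unique(g$date)),
      p_age_lt30 = mean(ab == "lt30"), p_age_30_49 = mean(ab == "30_49"),
      p_age_50_64 = mean(ab == "50_64"), p_age_ge65 = mean(ab == "ge65"),
      p_female = mean(g$sex == "F"),
      p_hispanic = mean(g$ethnicity == "Hispanic"),
      p_dm = mean(g$dm == 1), p_dyslip = mean(g$dyslip == 1),
      p_htn = mean(g$htn == 1),
      p_charlson_0 = mean(ch == "0"), p_charlson_1_2 = mean(ch == "1_2"),
      p_charlson_ge3 = mean(ch == "ge3"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  if (!is.null(physicians)) {
    out$practice_type <- physicians$practice_type[
      match(out$physician_id, physicians$physician_id)]
  }
  rownames(out) <- NULL
  out
}

#' Patient-level summaries
#'
#' Aggregates each patient's encounters into the covariates of the
#' patient-level propensity model: demographics plus the percentage of
#' 15- and 30-minute appointments, of level-of-service 3 and 4 visits, and
#' of encounters with each cardiometabolic condition as primary diagnosis.
#'
#' @inheritParams summarize_physicians
#' @return One row per patient; percentages on the 0-100 scale.
#' @export
summarize_patients <- function(encounters, patients) {
  res <- lapply(split(encounters, encounters$patient_id), function(g) {
    data.frame(
      patient_id = g$patient_id[1],
      n_encounters = nrow(g),
      pct_appt15 = 100 * mean(g$scheduled_length_min == 15),
      pct_appt30 = 100 * mean(g$scheduled_length_min == 30),
      pct_los3 = 100 * mean(g$los_level == 3),
      pct_los4 = 100 * mean(g$los_level == 4),
      pct_dx_dm = 100 * mean(g$primary_dx == "diabetes"),
      pct_dx_htn = 100 * mean(g$primary_dx == "hypertension"),
      pct_dx_dyslip = 100 * mean(g$primary_dx == "hyperlipidemia"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  pi <- match(out$patient_id, patients$patient_id)
  out$age <- patients$age[pi]
  out$female <- as.numeric(patients$sex[pi] == "F")
  out$race <- patients$race[pi]
  out$hispanic <- as.numeric(patients$ethnicity[pi] == "Hispanic")
  rownames(out) <- NULL
  out
}

#' Fit a propensity score model
#'
#' Maximum-likelihood logistic regression of case status on the supplied
#' features. Units with any missing feature are excluded with a warning.
#' Under (near-)separation the MLE is unstable; a ridge-penalized logistic
#' fit is then used for the scores, with a warning.
#'
#' @param features `data.frame` of covariates (numeric, or character/factor
#'   which are expanded to indicators).
#' @param labels Logical or 0/1 case indicator, one per row of `features`.
#' @return Numeric vector of propensity scores in (0, 1), `NA` for
#'   excluded rows; attributes `"coefficients"` and `"method"`
#'   (`"mle"` or `"ridge"`).
#' @export
fit_propensity <- function(features, labels) {
  y <- as.numeric(labels)
  stopifnot(length(y) == nrow(features), all(y %in% c(0, 1)))
  if (sum(y) == 0 || sum(y) == length(y))
    stop("propensity model needs at least one case and one control")
  cc <- stats::complete.cases(features)
  if (!all(cc)) warning(sum(!cc), " unit(s) with missing features excluded")
  # drop constant columns: no information, and they break the ridge fallback
  keep <- vapply(features, function(v) length(unique(v[cc])) >= 2, logical(1))
  x <- features[, keep, drop = FALSE]
  scores <- rep(NA_real_, length(y))
  if (ncol(x) == 0) {
    scores[cc] <- mean(y[cc])
    attr(scores, "method") <- "intercept"
    return(scores)
  }
  df <- cbind(.y = y, x)[cc, , drop = FALSE]
  fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
  p <- stats::fitted(fit)
  sep <- !fit$converged || any(p < 1e-8) || any(p > 1 - 1e-8)
  if (sep) {
    warning("possible separation in propensity model; using ridge-penalized fit")
    mm <- stats::model.matrix(~ . - .y, data = df)[, -1, drop = FALSE]
    if (ncol(mm) < 2) mm <- cbind(mm, `..pad` = 0)  # glmnet needs >= 2 columns
    rf <- glmnet::glmnet(mm, df$.y, family = "binomial", alpha = 0,
                         lambda = 1e-3)
    p <- as.numeric(stats::predict(rf, mm, type = "response"))
    attr(scores, "method") <- "ridge"
  } else {
    attr(scores, "method") <- "mle"
    attr(scores, "coefficients") <- stats::coef(fit)
  }
  scores[cc] <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  scores
}

#' Greedy propensity-score matching
#'
#' Cases are processed in descending propensity-score order; each takes its
#' nearest eligible control(s) within the caliper, without replacement.
#' Deterministic: ties in score order and in control distance break on the
#' lexicographically smallest unit id.
#'
#' @param case_scores,control_scores Named numeric vectors of scores in
#'   (0, 1); names are unit ids.
#' @param ratio Controls per case (1 for one-to-one).
#' @param caliper Caliper width: multiples of the SD of the logit of the
#'   pooled scores (`caliper_scale = "logit_sd"`, the 0.2-SD convention) or
#'   an absolute difference on the score scale (`"absolute"`).
#' @param caliper_scale See `caliper`.
#' @return Object of class `matched_cohort`: `pairs`
#'   (`case_id`, `control_id`, `cluster_id`), `unmatched` case ids,
#'   `caliper_width` (on the distance scale used), `ratio`.
#' @export
greedy_match <- function(case_scores, control_scores, ratio = 1,
                         caliper = 0.2, caliper_scale = c("logit_sd", "absolute")) {
  caliper_scale <- match.arg(caliper_scale)
  stopifnot(all(case_scores > 0 & case_scores < 1),
            all(control_scores >= 0 | !length(control_scores)))
  lg <- function(p) log(p / (1 - p))
  if (caliper_scale == "logit_sd") {
    s <- stats::sd(lg(c(case_scores, control_scores)))
    if (!is.finite(s) || s == 0) s <- 1
    width <- caliper * s
    dcase <- lg(case_scores); dctl <- lg(control_scores)
  } else {
    width <- caliper
    dcase <- case_scores; dctl <- control_scores
  }
  ord <- order(-case_scores, names(case_scores))
  avail <- rep(TRUE, length(control_scores))
  ctl_ids <- names(control_scores)
  pairs <- vector("list", length(ord))
  unmatched <- character(0)
  for (k in seq_along(ord)) {
    i <- ord[k]
    got <- character(0)
    for (r in seq_len(ratio)) {
      d <- abs(dctl - dcase[i])
      d[!avail] <- Inf
      j <- which(d <= width + 1e-12)
      if (!length(j)) break
      j <- j[order(d[j], ctl_ids[j])][1]
      got <- c(got, ctl_ids[j])
      avail[j] <- FALSE
    }
    if (!length(got)) {
      unmatched <- c(unmatched, names(case_scores)[i])
    } else {
      pairs[[k]] <- data.frame(case_id = names(case_scores)[i],
                               control_id = got,
                               cluster_id = names(case_scores)[i],
                               stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(pairs)) {
    pairs <- data.frame(case_id = character(), control_id = character(),
                        cluster_id = character(), stringsAsFactors = FALSE)
  }
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, unmatched = unmatched, caliper_width = width,
                 caliper_scale = caliper_scale, ratio = ratio),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat("Matched cohort:", length(unique(x$pairs$case_id)), "matched case(s),",
      nrow(x$pairs), "control(s),", length(x$unmatched), "unmatched case(s)\n")
  cat("Caliper:", signif(x$caliper_width, 3), "on the", x$caliper_scale,
      "scale; ratio 1:", x$ratio, "\n")
  invisible(x)
}

#' Assign patients to the pre or post study period
#'
#' Drops encounters falling in the washout (tool stabilization) window or
#' outside both study windows, and labels each remaining patient by the
#' window of their first qualifying visit.
#'
#' @param encounters Encounter table with a `date` column.
#' @param pre_window,post_window Length-2 `Date` (or coercible) vectors,
#'   inclusive; must not overlap.
#' @param washout Optional length-2 window excluded from both periods.
#' @return List: `encounters` (filtered, with `period` recomputed from the
#'   date), `patients` (`patient_id`, `period`), `n_dropped`.
#' @export
assign_period <- function(encounters, pre_window, post_window, washout = NULL) {
  pre_window <- as.Date(pre_window); post_window <- as.Date(post_window)
  if (pre_window[2] >= post_window[1])
    stop("pre and post windows overlap (or are out of order)")
  d <- encounters$date
  in_pre <- d >= pre_window[1] & d <= pre_window[2]
  in_post <- d >= post_window[1] & d <= post_window[2]
  drop <- !(in_pre | in_post)
  if (!is.null(washout)) {
    washout <- as.Date(washout)
    drop <- drop | (d >= washout[1] & d <= washout[2])
  }
  e <- encounters[!drop, , drop = FALSE]
  e$period <- ifelse(e$date <= pre_window[2], "pre", "post")
  first <- e[order(e$patient_id, e$date), ]
  first <- first[!duplicated(first$patient_id), ]
  list(encounters = e,
       patients = data.frame(patient_id = first$patient_id,
                             period = first$period, stringsAsFactors = FALSE),
       n_dropped = sum(drop))
}

#' Filter encounters to the eligible cardiometabolic set
#'
#' Keeps encounters whose diagnosis codes intersect the cardiometabolic
#' code set and (optionally) whose patient belongs to a matched pair.
#'
#' @param encounters Encounter table (`dx_codes` `;`-separated).
#' @param code_set Character vector of qualifying codes.
#' @param matched Optional [greedy_match()] result at the patient level;
#'   when given, only patients appearing in its pairs are kept.
#' @return The filtered encounter table.
#' @export
eligible_encounters <- function(encounters, code_set = cardiometabolic_codes(),
                                matched = NULL) {
  stopifnot(length(code_set) >= 1)
  hit <- vapply(strsplit(encounters$dx_codes, ";", fixed = TRUE),
                function(cs) any(cs %in% code_set), logical(1))
  e <- encounters[hit, , drop = FALSE]
  if (!is.null(matched)) {
    ids <- unique(c(matched$pairs$case_id, matched$pairs$control_id))
    e <- e[e$patient_id %in% ids, , drop = FALSE]
  }
  rownames(e) <- NULL
  e
}

#' Percentage of encounters with a cardiometabolic primary diagnosis
#'
#' @param encounters Encounter table with a `primary_dx` column.
#' @return Percentage on the 0-100 scale.
#' @export
pct_primary_cardiometabolic <- function(encounters) {
  100 * mean(encounters$primary_dx %in%
               c("diabetes", "hypertension", "hyperlipidemia"))
}

#' Covariate balance before and after matching
#'
#' Standardized mean difference (SMD) per covariate:
#' `(mean_case - mean_control) / sqrt((var_case + var_control) / 2)`,
#' with 0/0 reported as 0. Pre-match uses all cases against the full
#' control pool; post-match uses the matched units only.
#'
#' @param data `data.frame` with an id column and numeric covariates.
#' @param case_ids,control_ids Unit ids of all cases and the full control
#'   pool.
#' @param matched A [greedy_match()] result.
#' @param covariates Character vector of covariate columns (numeric).
#' @param id_col Name of the id column.
#' @return `data.frame` with columns `covariate`, `smd_pre`, `smd_post`.
#' @export
balance_table <- function(data, case_ids, control_ids, matched,
                          covariates, id_col = "id") {
  smd <- function(ids_a, ids_b, v) {
    a <- data[[v]][match(ids_a, data[[id_col]])]
    b <- data[[v]][match(ids_b, data[[id_col]])]
    num <- mean(a, na.rm = TRUE) - mean(b, na.rm = TRUE)
    den <- sqrt((stats::var(a, na.rm = TRUE) + stats::var(b, na.rm = TRUE)) / 2)
    if (!is.finite(den) || den == 0) {
      if (abs(num) < 1e-12) return(0) else return(Inf * sign(num))
    }
    num / den
  }
  out <- data.frame(covariate = covariates, stringsAsFactors = FALSE)
  out$smd_pre <- vapply(covariates, function(v) smd(case_ids, control_ids, v),
                        numeric(1))
  out$smd_post <- vapply(covariates, function(v) {
    smd(matched$pairs$case_id, matched$pairs$control_id, v)
  }, numeric(1))
  out
}
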