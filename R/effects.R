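measure_names <- function() {
  c("total_encounter_min", "phys_exam_room_min", "phys_ehr_exam_min",
    "total_clicks")
}

#' Patient-level outcome values
#'
#' Collapses encounter-level efficiency measures to one value per patient
#' per measure (the mean over the patient's eligible encounters). Control
#' patients contribute several encounters where case patients often
#' contribute one; collapsing first avoids pseudo-replication in the
#' two-sample tests.
#'
#' @param measures Encounter-level measures ([compute_measures()] schema).
#' @param encounters Encounter table (maps encounters to patients).
#' @return `data.frame`: `patient_id`, `n_encounters`, one column per
#'   measure (mean of the non-missing encounter values; `NA` if none).
#' @export
patient_level_outcomes <- function(measures, encounters) {
  pid <- encounters$patient_id[match(measures$encounter_id,
                                     encounters$encounter_id)]
  res <- lapply(split(seq_len(nrow(measures)), pid), function(idx) {
    row <- data.frame(patient_id = pid[idx][1], n_encounters = length(idx),
                      stringsAsFactors = FALSE)
    for (m in measure_names()) {
      v <- measures[[m]][idx]
      row[[m]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    row
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Welch two-sample t-test on a mean difference
#'
#' Two-tailed unequal-variance t-test; the difference reported is
#' `mean(case) - mean(control)`. When both arms are constant the test
#' statistic is undefined: equal means give p = 1 by convention, unequal
#' means p = 0.
#'
#' @param case_values,control_values Numeric vectors (>= 2 values each).
#' @return List with `mean_diff`, `p`, `df`, `se`.
#' @export
mean_diff_ttest <- function(case_values, control_values) {
  x <- case_values[!is.na(case_values)]
  y <- control_values[!is.na(control_values)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  d <- mean(x) - mean(y)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(list(mean_diff = d, p = if (d == 0) 1 else 0, df = NA_real_,
                se = 0))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(mean_diff = d, p = unname(tt$p.value), df = unname(tt$parameter),
       se = unname(tt$stderr))
}

#' Matched-cluster mixed-model effect estimate
#'
#' Fits `outcome ~ exposure + (1 | cluster)` by REML, where a cluster is a
#' matched case-control set. The effect is the exposure coefficient; the
#' 95% CI uses the normal approximation on its standard error. If the
#' mixed fit fails, an ordinary least squares fit with cluster-robust
#' (CR0) standard errors is used and flagged.
#'
#' @param outcome Numeric outcome per unit.
#' @param exposed 0/1 (or logical) exposure indicator per unit.
#' @param cluster Matched-set id per unit; every cluster must contain at
#'   least one exposed and one unexposed member.
#' @return List: `mean_diff`, `ci_low`, `ci_high`, `p`, `se`, `method`
#'   (`"mixed"` or `"ols_robust"`).
#' @export
mixed_model_effect <- function(outcome, exposed, cluster) {
  ok <- !is.na(outcome)
  outcome <- outcome[ok]; exposed <- as.numeric(exposed)[ok]
  cluster <- as.character(cluster)[ok]
  if (length(unique(cluster)) < 2) stop("mixed model needs >= 2 clusters")
  both <- tapply(exposed, cluster, function(e) any(e == 1) && any(e == 0))
  if (!all(both)) {
    stop(sum(!both), " cluster(s) lack a case or a control member")
  }
  df <- data.frame(y = outcome, x = exposed, cl = cluster)
  est <- tryCatch(suppressMessages(suppressWarnings({
    fit <- lme4::lmer(y ~ x + (1 | cl), data = df, REML = TRUE)
    b <- lme4::fixef(fit)[["x"]]
    se <- sqrt(Matrix::diag(stats::vcov(fit))[2])
    if (!is.finite(se)) se <- stats::coef(summary(fit))["x", "Std. Error"]
    if (!is.finite(se)) stop("no standard error from mixed fit")
    list(b = b, se = se, method = "mixed")
  })), error = function(e) NULL)
  if (is.null(est)) {
    # degenerate or non-converged mixed fit: cluster-robust OLS, flagged
    fit <- stats::lm(y ~ x, data = df)
    vc <- suppressWarnings(sandwich::vcovCL(fit, cluster = df$cl))
    est <- list(b = stats::coef(fit)[["x"]], se = sqrt(vc["x", "x"]),
                method = "ols_robust")
  }
  b <- unname(est$b); se <- unname(est$se)
  p <- if (se == 0) {
    if (abs(b) < 1e-12) 1 else 0
  } else 2 * stats::pnorm(-abs(b) / se)
  list(mean_diff = b, ci_low = b - 1.959963984540054 * se,
       ci_high = b + 1.959963984540054 * se, p = p, se = se,
       method = est$method)
}

#' Stratified case-control effect estimates
#'
#' Builds the full effect table for the four efficiency measures, overall
#' or stratified by scheduled appointment length (bands <=20 and >=30
#' minutes; other lengths are excluded and counted) or by cardiometabolic
#' primary diagnosis. Outcomes are collapsed to the patient level within
#' each stratum; the primary estimate is the matched-cluster mixed model,
#' with the Welch t-test available alongside.
#'
#' @param measures Encounter-level measures.
#' @param encounters Encounter table.
#' @param matched Patient-level [greedy_match()] result; clusters are its
#'   matched sets.
#' @param strata `"none"`, `"appt"` or `"dx"`.
#' @param methods Any of `"mixed"`, `"ttest"`.
#' @return `data.frame` with columns `measure`, `stratum`, `n_case`,
#'   `n_control`, `pct`, `mean_diff`, `ci_low`, `ci_high`, `p`, `method`,
#'   `note` (reason code for rows without an estimate).
#' @export
stratified_effects <- function(measures, encounters, matched,
                               strata = c("none", "appt", "dx"),
                               methods = c("mixed", "ttest")) {
  strata <- match.arg(strata)
  methods <- match.arg(methods, several.ok = TRUE)
  pairs <- matched$pairs
  role <- c(stats::setNames(rep("case", nrow(pairs)), pairs$case_id),
            stats::setNames(rep("control", nrow(pairs)), pairs$control_id))
  clus <- c(stats::setNames(pairs$cluster_id, pairs$case_id),
            stats::setNames(pairs$cluster_id, pairs$control_id))
  enc <- encounters[encounters$patient_id %in% names(role), , drop = FALSE]
  enc$stratum <- switch(
    strata,
    none = "overall",
    appt = appt_band(enc$scheduled_length_min),
    dx = ifelse(enc$primary_dx %in% c("diabetes", "hypertension",
                                      "hyperlipidemia"),
                enc$primary_dx, NA_character_)
  )
  n_excluded <- sum(is.na(enc$stratum))
  enc <- enc[!is.na(enc$stratum), , drop = FALSE]
  n_total <- nrow(enc)
  rows <- list()
  for (st in sort(unique(enc$stratum))) {
    e_st <- enc[enc$stratum == st, , drop = FALSE]
    m_st <- measures[measures$encounter_id %in% e_st$encounter_id, , drop = FALSE]
    po <- patient_level_outcomes(m_st, e_st)
    po$role <- role[po$patient_id]
    po$cluster <- clus[po$patient_id]
    pct <- 100 * nrow(e_st) / n_total
    for (m in measure_names()) {
      v_case <- po[[m]][po$role == "case"]
      v_ctl <- po[[m]][po$role == "control"]
      base <- data.frame(measure = m, stratum = st,
                         n_case = sum(!is.na(v_case)),
                         n_control = sum(!is.na(v_ctl)), pct = pct,
                         stringsAsFactors = FALSE)
      for (meth in methods) {
        r <- cbind(base, mean_diff = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, p = NA_real_, method = meth,
                   note = "", stringsAsFactors = FALSE)
        est <- tryCatch({
          if (meth == "mixed") {
            keep <- !is.na(po[[m]])
            cl_ok <- tapply(po$role[keep], po$cluster[keep], function(r2) {
              any(r2 == "case") && any(r2 == "control")
            })
            use <- keep & po$cluster %in% names(cl_ok)[cl_ok]
            if (length(unique(po$cluster[use])) < 2)
              stop("fewer than 2 complete clusters")
            mixed_model_effect(po[[m]][use],
                               po$role[use] == "case", po$cluster[use])
          } else {
            tt <- mean_diff_ttest(v_case, v_ctl)
            c(tt, list(ci_low = tt$mean_diff - 1.959963984540054 * tt$se,
                       ci_high = tt$mean_diff + 1.959963984540054 * tt$se))
          }
        }, error = function(e) conditionMessage(e))
        if (is.character(est)) {
          r$note <- est
        } else {
          r$mean_diff <- est$mean_diff; r$ci_low <- est$ci_low
          r$ci_high <- est$ci_high; r$p <- est$p
        }
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_excluded_encounters") <- n_excluded
  out
}
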