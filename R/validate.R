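#' Per-encounter observed-vs-derived time differences
#'
#' Joins time-motion observations with derived workflow points and returns
#' one row per (encounter, label) present in both, with the difference
#' `observed - derived` in minutes.
#'
#' @param observed Time-motion records ([read_time_motion()] schema).
#' @param derived Derived workflow points ([derive_workflow_points()] /
#'   [impute_points()] output).
#' @return `data.frame` with columns `encounter_id`, `label`, `diff_min`.
#' @export
discrepancy_differences <- function(observed, derived) {
  key_o <- paste(observed$encounter_id, observed$point_label, sep = "\r")
  key_d <- paste(derived$encounter_id, derived$label, sep = "\r")
  i <- match(key_o, key_d)
  ok <- !is.na(i)
  data.frame(
    encounter_id = observed$encounter_id[ok],
    label = observed$point_label[ok],
    diff_min = mins_between(derived$time[i[ok]], observed$observed_time[ok]),
    stringsAsFactors = FALSE
  )
}

#' Observed-vs-derived discrepancy summary table
#'
#' Summarizes, per workflow point, the difference between the
#' time-motion-observed time and the audit-derived time: n (% of observed
#' encounters), mean (SD), median (IQR), all in minutes. Labels that are
#' observed but have no derived counterpart (black-hole boundaries when
#' comparing against pure audit points) appear with `NA` statistics,
#' mirroring a "not available in audit log data" sentinel. Quartiles use
#' linear interpolation (`stats::quantile` type 7).
#'
#' @inheritParams discrepancy_differences
#' @return `data.frame` with columns `label`, `n`, `pct`, `mean`, `sd`,
#'   `median`, `q1`, `q3`; attribute `"differences"` carries the
#'   per-encounter rows used.
#' @export
discrepancy_table <- function(observed, derived) {
  d <- discrepancy_differences(observed, derived)
  n_enc <- length(unique(observed$encounter_id))
  if (!nrow(d)) warning("no overlapping (encounter, label) pairs between sources")
  labs <- intersect(workflow_point_labels(), unique(observed$point_label))
  rows <- lapply(labs, function(lb) {
    x <- d$diff_min[d$label == lb]
    if (!length(x)) {
      return(data.frame(label = lb, n = 0L, pct = 0, mean = NA_real_,
                        sd = NA_real_, median = NA_real_, q1 = NA_real_,
                        q3 = NA_real_, stringsAsFactors = FALSE))
    }
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(label = lb, n = length(x),
               pct = 100 * length(x) / n_enc,
               mean = mean(x), sd = stats::sd(x),
               median = q[2], q1 = q[1], q3 = q[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "differences") <- d
  out
}

#' Flag encounters with large observed-vs-derived discrepancies
#'
#' Screens each workflow point's differences for review: an encounter is
#' flagged when its difference deviates from the label's mean difference
#' by at least `k` standard deviations. Labels whose SD is zero (all
#' differences identical) flag nothing.
#'
#' @param differences Per-encounter differences from
#'   [discrepancy_differences()] (or the `"differences"` attribute of
#'   [discrepancy_table()]).
#' @param k SD multiplier (default 2).
#' @return `data.frame` with columns `encounter_id`, `label`, `diff_min` --
#'   the review queue.
#' @export
flag_outliers <- function(differences, k = 2) {
  stopifnot(k >= 0)
  out <- lapply(split(differences, differences$label), function(d) {
    if (nrow(d) < 2) return(NULL)
    s <- stats::sd(d$diff_min)
    if (s == 0) return(NULL)
    d[abs(d$diff_min - mean(d$diff_min)) >= k * s, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(encounter_id = character(), label = character(),
                      diff_min = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out[order(out$label, out$encounter_id), , drop = FALSE]
}
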