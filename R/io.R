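#' Read an EHR audit log
#'
#' Reads a delimited (CSV) or JSON Lines audit log into a validated event
#' table. One record is one EHR log entry -- i.e. one "click" -- carrying
#' who (user and role), when (timestamp), where (workstation) and what
#' (action code).
#'
#' @param path Path to the file.
#' @param schema Optional named character vector mapping the canonical
#'   column names (`encounter_id`, `user_id`, `user_role`, `workstation_id`,
#'   `timestamp`, `action_code`) to the column names used in the file.
#' @param format `"auto"` (by extension), `"csv"` or `"jsonl"`.
#' @param strict If `TRUE` (default) any malformed row aborts the read with
#'   an error naming the offending line(s); if `FALSE` malformed rows are
#'   dropped with a warning.
#' @return A `data.frame` of events sorted by (`encounter_id`, `timestamp`)
#'   with columns `encounter_id`, `user_id`, `user_role`, `workstation_id`,
#'   `timestamp` (UTC `POSIXct`), `action_code`.
#' @export
read_audit_log <- function(path, schema = NULL, format = c("auto", "csv", "jsonl"),
                           strict = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("audit log not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$|\\.ndjson$", path)) "jsonl" else "csv"
  }
  raw <- if (format == "jsonl") {
    jsonlite::stream_in(file(path), verbose = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  }
  need <- c("encounter_id", "user_id", "user_role", "workstation_id",
            "timestamp", "action_code")
  if (!is.null(schema)) {
    missing_map <- setdiff(need, names(schema))
    schema <- c(schema, stats::setNames(missing_map, missing_map))
    absent <- setdiff(unname(schema[need]), names(raw))
    if (length(absent)) stop("audit log missing column(s): ",
                             paste(absent, collapse = ", "))
    raw <- raw[, unname(schema[need])]
    names(raw) <- need
  } else {
    absent <- setdiff(need, names(raw))
    if (length(absent)) stop("audit log missing column(s): ",
                             paste(absent, collapse = ", "))
    raw <- raw[, need]
  }
  raw$timestamp <- parse_timestamp(raw$timestamp)
  bad_ts <- which(is.na(raw$timestamp))
  bad_role <- which(!(raw$user_role %in% user_roles()))
  bad_code <- which(is.na(raw$action_code) | raw$action_code == "")
  bad <- sort(unique(c(bad_ts, bad_role, bad_code)))
  if (length(bad)) {
    # +1: header line
    msg <- sprintf("%d malformed audit row(s) at line(s) %s", length(bad),
                   paste(utils::head(bad + 1L, 10L), collapse = ", "))
    if (strict) stop(msg) else {
      warning(msg, "; rows dropped")
      raw <- raw[-bad, , drop = FALSE]
    }
  }
  raw <- raw[order(raw$encounter_id, raw$timestamp), , drop = FALSE]
  rownames(raw) <- NULL
  raw
}

#' Write an audit log
#' @param events Event table as returned by [read_audit_log()] or
#'   [simulate_clinic()].
#' @param path Output path.
#' @param format `"csv"` or `"jsonl"`.
#' @export
write_audit_log <- function(events, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  out <- events
  out$timestamp <- format_timestamp(out$timestamp)
  if (format == "jsonl") {
    con <- file(path, "w"); on.exit(close(con))
    jsonlite::stream_out(out, con, verbose = FALSE)
  } else {
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read time-motion observation records
#'
#' Each row is one workflow point directly observed for one encounter.
#' At most one record per (encounter, label) is allowed; rows whose times
#' violate the canonical workflow order within an encounter are kept (the
#' validation module surfaces them) but reported via the
#' `"order_violations"` attribute.
#'
#' @param path CSV with columns `encounter_id`, `point_label`,
#'   `observed_time`.
#' @param strict As in [read_audit_log()].
#' @return `data.frame` with `observed_time` parsed to UTC `POSIXct`.
#' @export
read_time_motion <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("time-motion file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("encounter_id", "point_label", "observed_time")
  absent <- setdiff(need, names(raw))
  if (length(absent)) stop("time-motion file missing column(s): ",
                           paste(absent, collapse = ", "))
  raw <- raw[, need]
  raw$observed_time <- parse_timestamp(raw$observed_time)
  bad <- which(is.na(raw$observed_time) |
                 !(raw$point_label %in% workflow_point_labels()))
  if (length(bad)) {
    msg <- sprintf("%d malformed time-motion row(s) at line(s) %s",
                   length(bad), paste(utils::head(bad + 1L, 10L), collapse = ", "))
    if (strict) stop(msg) else {
      warning(msg, "; rows dropped")
      raw <- raw[-bad, , drop = FALSE]
    }
  }
  dup <- duplicated(raw[, c("encounter_id", "point_label")])
  if (any(dup)) {
    stop("duplicate (encounter_id, point_label) in time-motion file at line(s) ",
         paste(which(dup) + 1L, collapse = ", "))
  }
  viol <- order_violations(raw, "point_label", "observed_time")
  if (nrow(viol)) {
    warning(nrow(viol), " time-motion row(s) violate the canonical workflow order; kept")
  }
  raw <- raw[order(raw$encounter_id, raw$observed_time), , drop = FALSE]
  rownames(raw) <- NULL
  attr(raw, "order_violations") <- viol
  raw
}

#' @rdname read_time_motion
#' @param records Time-motion table.
#' @export
write_time_motion <- function(records, path) {
  out <- records
  out$observed_time <- format_timestamp(out$observed_time)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# Rows whose time precedes an earlier canonical label's time within the
# same encounter.
order_violations <- function(df, label_col, time_col) {
  ord <- match(df[[label_col]], workflow_point_labels())
  res <- lapply(split(seq_len(nrow(df)), df$encounter_id), function(idx) {
    o <- idx[order(ord[idx])]
    t <- as.numeric(df[[time_col]][o])
    prev_max <- cummax(c(-Inf, utils::head(t, -1L)))
    bad <- which(t < prev_max - 1e-9)
    if (!length(bad)) return(NULL)
    data.frame(encounter_id = df$encounter_id[o[bad]],
               label = df[[label_col]][o[bad]], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(encounter_id = character(), label = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Read a workstation location map
#'
#' @param path CSV with columns `workstation_id`, `location_class`.
#' @return `data.frame` mapping each workstation to a location class in
#'   `location_classes()`.
#' @export
read_location_map <- function(path) {
  if (!file.exists(path)) stop("location map not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("workstation_id", "location_class")
  absent <- setdiff(need, names(raw))
  if (length(absent)) stop("location map missing column(s): ",
                           paste(absent, collapse = ", "))
  raw <- raw[, need]
  bad <- which(!(raw$location_class %in% location_classes()))
  if (length(bad)) stop("unknown location class at line(s) ",
                        paste(bad + 1L, collapse = ", "))
  if (anyDuplicated(raw$workstation_id))
    stop("duplicate workstation_id in location map")
  raw
}

#' @rdname read_location_map
#' @param map Location-map table.
#' @export
write_location_map <- function(map, path) {
  utils::write.csv(map[, c("workstation_id", "location_class")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Resolve workstation ids to location classes
#'
#' Every workstation id appearing in a log must be mapped; an unmapped id
#' is an error (the analysis cannot proceed with unknown locations).
#'
#' @param map Location map from [read_location_map()].
#' @param workstation_id Character vector of ids to resolve.
#' @return Character vector of location classes.
#' @export
lookup_location <- function(map, workstation_id) {
  i <- match(workstation_id, map$workstation_id)
  if (anyNA(i)) {
    stop("unmapped workstation id(s): ",
         paste(utils::head(unique(workstation_id[is.na(i)]), 5L),
               collapse = ", "))
  }
  map$location_class[i]
}

#' Read / write encounter metadata
#'
#' Encounter tables carry scheduling and clinical context: scheduled
#' appointment length (15/20/30/40 min), level of service, primary
#' diagnosis, full diagnosis-code list (`;`-separated in the file),
#' pre/post study period and whether the point-of-care tool was launched.
#'
#' @param path CSV path.
#' @return `data.frame` with `date` parsed to `Date`, `dx_codes` as a
#'   `;`-separated string and `exposure` logical.
#' @export
read_encounters <- function(path) {
  if (!file.exists(path)) stop("encounter file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("encounter_id", "patient_id", "physician_id", "date",
            "scheduled_length_min", "los_level", "primary_dx", "dx_codes",
            "period", "exposure")
  absent <- setdiff(need, names(raw))
  if (length(absent)) stop("encounter file missing column(s): ",
                           paste(absent, collapse = ", "))
  raw$date <- as.Date(raw$date)
  raw$exposure <- as.logical(raw$exposure)
  stopifnot(all(raw$scheduled_length_min > 0))
  raw
}

#' @rdname read_encounters
#' @param encounters Encounter table.
#' @export
write_encounters <- function(encounters, path) {
  utils::write.csv(encounters, path, row.names = FALSE)
  invisible(path)
}

#' Read / write derived workflow point sets
#'
#' @param path CSV with columns `encounter_id`, `label`, `time`,
#'   `provenance` (one of `observed`, `audit`, `imputed`).
#' @return `data.frame` with `time` parsed to UTC `POSIXct`.
#' @export
read_points <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("encounter_id", "label", "time", "provenance")
  absent <- setdiff(need, names(raw))
  if (length(absent)) stop("points file missing column(s): ",
                           paste(absent, collapse = ", "))
  raw <- raw[, need]
  raw$time <- parse_timestamp(raw$time)
  raw
}

#' @rdname read_points
#' @param points Workflow-point table.
#' @export
write_points <- function(points, path) {
  out <- points
  out$time <- format_timestamp(out$time)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
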