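#' Controlled vocabularies for audit-log workflow analysis
#'
#' Canonical workflow-point labels, EHR user roles, workstation location
#' classes and black-hole interval names used throughout the package.
#' Workflow points are ordered: later labels never precede earlier ones
#' within an encounter (ties allowed).
#'
#' @format Character vectors of allowed values.
#' @name vocab
NULL

#' @rdname vocab
#' @export
workflow_point_labels <- function() {
  c("CHECKIN_START", "CHECKIN_END", "ROOM_START",
    "MA_LOGIN", "MA_LOGOFF", "MA_EXIT",
    "PHYS_ENTER", "PHYS_LOGIN", "PHYS_LOGOFF", "PHYS_EXIT",
    "PATIENT_EXIT", "CHECKOUT")
}

#' @rdname vocab
#' @export
user_roles <- function() {
  c("front_desk", "medical_assistant", "nurse", "physician")
}

#' @rdname vocab
#' @export
location_classes <- function() {
  c("front_desk", "exam_room", "other")
}

#' Black-hole interval definitions
#'
#' The five workflow intervals that leave no footprint in the audit log
#' ("black holes"): each is bounded by a start and end workflow point, at
#' least one of which is observable only by direct (time-motion)
#' observation. Durations run from `from` to `to`.
#'
#' @return A data frame with columns `interval`, `from`, `to`, and
#'   `audit_side` ("from", "to" or "none"): which endpoint, if either, is
#'   derivable from the audit log.
#' @export
blackhole_intervals <- function() {
  data.frame(
    interval = c("MA_ROOM_TO_LOGIN", "MA_LOGOFF_TO_EXIT",
                 "PHYS_ENTER_TO_LOGIN", "PHYS_LOGOFF_TO_EXIT",
                 "PHYS_EXIT_TO_PATIENT_EXIT"),
    from = c("ROOM_START", "MA_LOGOFF", "PHYS_ENTER", "PHYS_LOGOFF",
             "PHYS_EXIT"),
    to = c("MA_LOGIN", "MA_EXIT", "PHYS_LOGIN", "PHYS_EXIT",
           "PATIENT_EXIT"),
    audit_side = c("to", "from", "to", "from", "none"),
    stringsAsFactors = FALSE
  )
}

# Labels that can be derived from audit events alone.
audit_derivable_labels <- function() {
  c("CHECKIN_START", "CHECKIN_END", "MA_LOGIN", "MA_LOGOFF",
    "PHYS_LOGIN", "PHYS_LOGOFF")
}

#' Parse ISO 8601 timestamps to UTC instants
#'
#' Accepts `YYYY-MM-DDTHH:MM:SS` with an optional fractional second and an
#' optional zone designator (`Z`, `+HH:MM` or `+HHMM`). Zone-less stamps are
#' taken as UTC. All results are stored as UTC `POSIXct` so that duration
#' arithmetic is unaffected by daylight-saving transitions.
#'
#' @param x Character vector of timestamps.
#' @return `POSIXct` vector in UTC; unparseable entries are `NA`.
#' @export
parse_timestamp <- function(x) {
  x <- as.character(x)
  y <- sub("Z$", "+0000", x)
  y <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", y)
  has_tz <- grepl("[+-][0-9]{4}$", y)
  y[!has_tz] <- paste0(y[!has_tz], "+0000")
  out <- as.POSIXct(strptime(y, format = "%Y-%m-%dT%H:%M:%OS%z", tz = "UTC"))
  # fall back to space-separated datetimes
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    out[bad] <- as.POSIXct(strptime(x[bad], format = "%Y-%m-%d %H:%M:%OS",
                                    tz = "UTC"))
  }
  out
}

#' Format UTC instants as ISO 8601
#' @param x `POSIXct` vector.
#' @return Character vector `YYYY-MM-DDTHH:MM:SSZ` (fractional seconds kept
#'   to millisecond precision when present).
#' @export
format_timestamp <- function(x) {
  ifelse(is.na(x), NA_character_,
         paste0(format(x, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC"), "Z"))
}

# Minutes between two POSIXct vectors (b - a). Single shared formula so
# generator truth and audit-derived durations agree bit-for-bit.
mins_between <- function(a, b) {
  (as.numeric(b) - as.numeric(a)) / 60
}
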