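#' Identify the primary physician of each encounter
#'
#' When several physician-role users touch an encounter, the one with the
#' most examination-room records is taken as "the physician" (outpatient
#' primary-care encounters have one attending PCP); the others are ignored
#' and the encounter is flagged. Ties break on the lexicographically
#' smallest user id.
#'
#' @param events Audit events (any number of encounters), with a
#'   `location` column or resolvable via `location_map`.
#' @param location_map Location map (see [read_location_map()]).
#' @return `data.frame` with columns `encounter_id`, `physician_user`,
#'   `n_physician_users`.
#' @export
primary_physicians <- function(events, location_map = NULL) {
  ev <- with_location(events, location_map)
  ph <- ev[ev$user_role == "physician", , drop = FALSE]
  if (!nrow(ph)) {
    return(data.frame(encounter_id = character(), physician_user = character(),
                      n_physician_users = integer(), stringsAsFactors = FALSE))
  }
  # exam-room record count per (encounter, user); users with no exam-room
  # records still score 0 so single-physician encounters always resolve
  key <- paste(ph$encounter_id, ph$user_id, sep = "\r")
  n_exam <- tapply(ph$location == "exam_room", key, sum)
  parts <- do.call(rbind, strsplit(names(n_exam), "\r", fixed = TRUE))
  cand <- data.frame(encounter_id = parts[, 1], user_id = parts[, 2],
                     n_exam = as.integer(n_exam), stringsAsFactors = FALSE)
  cand <- cand[order(cand$encounter_id, -cand$n_exam, cand$user_id), ]
  nu <- tapply(cand$user_id, cand$encounter_id, length)
  first <- !duplicated(cand$encounter_id)
  out <- data.frame(encounter_id = cand$encounter_id[first],
                    physician_user = cand$user_id[first],
                    stringsAsFactors = FALSE)
  out$n_physician_users <- as.integer(nu[out$encounter_id])
  out
}

# attach a location column resolved from the workstation map
with_location <- function(events, location_map) {
  if (!is.null(events$location)) return(events)
  if (is.null(location_map)) stop("location_map required to resolve workstations")
  events$location <- lookup_location(location_map, events$workstation_id)
  events
}

#' Derive audit-observable workflow points
#'
#' Reconstructs, for every encounter in the event stream, the workflow
#' points that leave an audit footprint: check-in start/end (first/last
#' front-desk-role record at the front desk), MA login/logoff (first LOGIN
#' / last LOGOFF by a medical assistant or nurse in the examination room)
#' and physician login/logoff (first LOGIN / last LOGOFF by the primary
#' physician in the examination room). Black-hole boundary points
#' (rooming start, MA exit, physician enter/exit, patient exit) are never
#' fabricated here; they are absent until [impute_points()] fills them.
#' A LOGOFF (or LOGIN) that has no matching record is derived from the
#' last (or first) event of that role in the examination room and flagged
#' in the quality report.
#'
#' @inheritParams primary_physicians
#' @return `data.frame` with columns `encounter_id`, `label`, `time`,
#'   `provenance` (always `"audit"`), sorted by encounter and canonical
#'   label order. Attribute `"quality"` holds a `data.frame` of flagged
#'   `(encounter_id, issue)` rows.
#' @export
derive_workflow_points <- function(events, location_map = NULL) {
  ev <- with_location(events, location_map)
  ev <- ev[order(ev$encounter_id, ev$timestamp), , drop = FALSE]
  ts <- as.numeric(ev$timestamp)
  enc <- ev$encounter_id
  quality <- list()

  first_by <- function(sel) {
    if (!any(sel)) return(numeric(0))
    tapply(ts[sel], enc[sel], min)
  }
  last_by <- function(sel) {
    if (!any(sel)) return(numeric(0))
    tapply(ts[sel], enc[sel], max)
  }
  coalesce_pts <- function(primary, fallback, issue) {
    extra <- setdiff(names(fallback), names(primary))
    if (length(extra)) {
      quality[[issue]] <<- data.frame(encounter_id = extra, issue = issue,
                                      stringsAsFactors = FALSE)
      primary <- c(primary, fallback[extra])
    }
    primary
  }

  fd <- ev$user_role == "front_desk" & ev$location == "front_desk"
  ma <- ev$user_role %in% c("medical_assistant", "nurse") &
    ev$location == "exam_room"
  pp <- primary_physicians(ev)
  multi <- pp$encounter_id[pp$n_physician_users > 1]
  if (length(multi)) {
    quality$multiple_physicians <- data.frame(
      encounter_id = multi, issue = "multiple_physicians",
      stringsAsFactors = FALSE)
  }
  is_primary <- ev$user_role == "physician" &
    ev$user_id == pp$physician_user[match(enc, pp$encounter_id)]
  is_primary[is.na(is_primary)] <- FALSE
  px <- is_primary & ev$location == "exam_room"

  pts <- list(
    CHECKIN_START = first_by(fd),
    CHECKIN_END = last_by(fd),
    MA_LOGIN = coalesce_pts(first_by(ma & ev$action_code == "LOGIN"),
                            first_by(ma), "ma_login_fallback"),
    MA_LOGOFF = coalesce_pts(last_by(ma & ev$action_code == "LOGOFF"),
                             last_by(ma), "ma_logoff_fallback"),
    PHYS_LOGIN = coalesce_pts(first_by(px & ev$action_code == "LOGIN"),
                              first_by(px), "phys_login_fallback"),
    PHYS_LOGOFF = coalesce_pts(last_by(px & ev$action_code == "LOGOFF"),
                               last_by(px), "phys_logoff_fallback")
  )
  out <- do.call(rbind, lapply(names(pts), function(lb) {
    p <- pts[[lb]]
    if (!length(p)) return(NULL)
    data.frame(encounter_id = names(p), label = lb, time = unname(p),
               provenance = "audit", stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(encounter_id = character(), label = character(),
                      time = numeric(), provenance = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$encounter_id, match(out$label, workflow_point_labels())), ]
  out$time <- as.POSIXct(out$time, origin = "1970-01-01", tz = "UTC")
  rownames(out) <- NULL
  q <- do.call(rbind, quality)
  if (is.null(q)) q <- data.frame(encounter_id = character(),
                                  issue = character(), stringsAsFactors = FALSE)
  rownames(q) <- NULL
  attr(out, "quality") <- q
  out
}

#' Cumulative physician EHR time in the examination room
#'
#' Sessionizes the primary physician's examination-room records into
#' LOGIN -> LOGOFF sessions and sums their lengths. A session whose LOGIN
#' never receives a LOGOFF is closed at its last record plus
#' `session_gap_min` when feature records followed the LOGIN, or at the
#' LOGIN itself (zero length) when nothing followed; an implicit close is
#' capped at the next LOGIN.
#'
#' @inheritParams primary_physicians
#' @param session_gap_min Minutes added when closing an orphan session
#'   (default 1).
#' @return `data.frame` with columns `encounter_id`, `ehr_min`,
#'   `n_sessions`, `n_orphan` (sessions closed without an explicit LOGOFF).
#' @export
ehr_exam_time <- function(events, location_map = NULL, session_gap_min = 1) {
  stopifnot(session_gap_min > 0)
  ev <- with_location(events, location_map)
  ev <- ev[order(ev$encounter_id, ev$timestamp), , drop = FALSE]
  pp <- primary_physicians(ev)
  px <- ev$user_role == "physician" & ev$location == "exam_room" &
    ev$user_id == pp$physician_user[match(ev$encounter_id, pp$encounter_id)]
  px[is.na(px)] <- FALSE
  sub <- ev[px, , drop = FALSE]
  if (!nrow(sub)) {
    return(data.frame(encounter_id = character(), ehr_min = numeric(),
                      n_sessions = integer(), n_orphan = integer(),
                      stringsAsFactors = FALSE))
  }
  gap_s <- session_gap_min * 60
  res <- lapply(split(seq_len(nrow(sub)), sub$encounter_id), function(idx) {
    t <- as.numeric(sub$timestamp[idx])
    code <- sub$action_code[idx]
    total <- 0; nsess <- 0L; orphan <- 0L
    open <- NA_real_; last_in <- NA_real_
    close_open <- function(cap) {
      # orphan close: last event + gap if anything followed the LOGIN
      end <- if (is.na(last_in)) open else min(last_in + gap_s, cap)
      total <<- total + (end - open)
      orphan <<- orphan + 1L
      open <<- NA_real_; last_in <<- NA_real_
    }
    for (i in seq_along(t)) {
      if (code[i] == "LOGIN") {
        if (!is.na(open)) close_open(cap = t[i])
        open <- t[i]; last_in <- NA_real_; nsess <- nsess + 1L
      } else if (code[i] == "LOGOFF") {
        if (!is.na(open)) {
          total <- total + (t[i] - open)
          open <- NA_real_; last_in <- NA_real_
        }
      } else if (!is.na(open)) {
        last_in <- t[i]
      }
    }
    if (!is.na(open)) close_open(cap = Inf)
    c(total / 60, nsess, orphan)
  })
  out <- data.frame(encounter_id = names(res),
                    ehr_min = vapply(res, `[`, numeric(1), 1L),
                    n_sessions = as.integer(vapply(res, `[`, numeric(1), 2L)),
                    n_orphan = as.integer(vapply(res, `[`, numeric(1), 3L)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Total physician clicks per encounter
#'
#' One audit record is one EHR log entry, i.e. one click. Counts every
#' record of the encounter's primary physician at any location -- the
#' pre-visit chart review, the examination-room sessions and the
#' post-visit wrap-up all count.
#'
#' @inheritParams primary_physicians
#' @return `data.frame` with columns `encounter_id`, `total_clicks`.
#' @export
count_clicks <- function(events, location_map = NULL) {
  if (!nrow(events)) {
    return(data.frame(encounter_id = character(), total_clicks = integer(),
                      stringsAsFactors = FALSE))
  }
  ev <- events
  pp <- primary_physicians(ev, location_map)
  sel <- ev$user_role == "physician" &
    ev$user_id == pp$physician_user[match(ev$encounter_id, pp$encounter_id)]
  sel[is.na(sel)] <- FALSE
  cnt <- table(factor(ev$encounter_id[sel], levels = unique(ev$encounter_id)))
  data.frame(encounter_id = names(cnt), total_clicks = as.integer(cnt),
             stringsAsFactors = FALSE)
}

#' Compute per-encounter efficiency measures
#'
#' The four efficiency outcomes: total encounter time (check-in to patient
#' exit), physician time in the examination room (enter to exit),
#' physician EHR time in the examination room (session sum, clipped to the
#' room time) and total physician clicks. The first three need the imputed
#' black-hole boundary points; a measure whose required points are missing
#' is `NA`, never zero.
#'
#' @param points Workflow points after imputation (see [impute_points()]).
#' @inheritParams ehr_exam_time
#' @return `data.frame` with columns `encounter_id`, `total_encounter_min`,
#'   `phys_exam_room_min`, `phys_ehr_exam_min`, `total_clicks`.
#' @export
compute_measures <- function(points, events, location_map = NULL,
                             session_gap_min = 1) {
  wide <- points_wide(points)
  ehr <- ehr_exam_time(events, location_map, session_gap_min)
  clk <- count_clicks(events, location_map)
  ids <- sort(unique(c(wide$encounter_id, ehr$encounter_id)))
  out <- data.frame(encounter_id = ids, stringsAsFactors = FALSE)
  w <- wide[match(ids, wide$encounter_id), , drop = FALSE]
  gmin <- function(a, b) mins_between(a, b)
  out$total_encounter_min <- gmin(w$CHECKIN_START, w$PATIENT_EXIT)
  out$phys_exam_room_min <- gmin(w$PHYS_ENTER, w$PHYS_EXIT)
  e <- ehr$ehr_min[match(ids, ehr$encounter_id)]
  e[is.na(e) & !is.na(out$phys_exam_room_min)] <- 0
  out$phys_ehr_exam_min <- pmin(e, out$phys_exam_room_min)
  out$total_clicks <- clk$total_clicks[match(ids, clk$encounter_id)]
  out$total_clicks[is.na(out$total_clicks)] <- 0L
  neg <- which(out$total_encounter_min < 0 | out$phys_exam_room_min < 0)
  if (length(neg)) {
    stop("negative duration after imputation for encounter(s): ",
         paste(utils::head(out$encounter_id[neg], 5L), collapse = ", "))
  }
  out
}

# long points table -> one row per encounter, one POSIXct column per label
points_wide <- function(points) {
  ids <- unique(points$encounter_id)
  out <- data.frame(encounter_id = ids, stringsAsFactors = FALSE)
  for (lb in workflow_point_labels()) {
    p <- points[points$label == lb, , drop = FALSE]
    out[[lb]] <- as.POSIXct(p$time[match(ids, p$encounter_id)],
                            origin = "1970-01-01", tz = "UTC")
  }
  out
}
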