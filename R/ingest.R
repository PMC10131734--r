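EVENT_COLS <- c("user_id", "account_created", "start", "session_type",
                "completed", "duration_min")

# Row-wise ISO-8601 parsing: unparseable entries become NA (to be rejected
# with their row numbers) instead of aborting the whole read.
parse_timestamp <- function(x) {
  fmts <- c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
            "%Y-%m-%d %H:%M", "%Y-%m-%dT%H:%M")
  out <- as.POSIXct(rep(NA_character_, length(x)), tz = "UTC")
  for (fmt in fmts) {
    idx <- which(is.na(out))
    if (!length(idx)) break
    out[idx] <- as.POSIXct(strptime(x[idx], fmt, tz = "UTC"))
  }
  out
}

#' Read a meditation-app event log from CSV
#'
#' The dialect is comma-separated UTF-8 with a header and one row per app
#' session: `user_id` (opaque id), `account_created` (ISO date), `start`
#' (ISO timestamp, minute precision or better, single local clock),
#' `session_type` (one of the app's nine feature types), `completed`
#' (logical), `duration_min` (minutes). Malformed rows — unparseable
#' timestamps, negative durations, sessions starting before the account
#' existed — are rejected with a warning listing their row numbers; a
#' missing column is a format error.
#'
#' @param path path to the CSV file.
#' @return a validated event-log data frame with typed columns.
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stopf("event log not found: %s", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(EVENT_COLS, names(raw))
  if (length(missing))
    stopf("format error: missing required column(s): %s",
          paste(missing, collapse = ", "))
  validate_event_log(raw)
}

#' Validate and type an in-memory event log
#'
#' Applies the same row-level checks as [read_event_log()] to a data frame
#' already in memory (for example, one produced by [simulate_events()]).
#'
#' @param events data frame with the event-log columns.
#' @return the typed event log with invalid rows dropped (and a warning
#'   naming them).
#' @export
validate_event_log <- function(events) {
  missing <- setdiff(EVENT_COLS, names(events))
  if (length(missing))
    stopf("format error: missing required column(s): %s",
          paste(missing, collapse = ", "))
  out <- events[EVENT_COLS]
  if (!inherits(out$start, "POSIXct"))
    out$start <- parse_timestamp(as.character(out$start))
  if (!inherits(out$account_created, "Date"))
    out$account_created <- as.Date(strptime(as.character(out$account_created),
                                            "%Y-%m-%d", tz = "UTC"))
  if (is.character(out$completed))
    out$completed <- as.logical(out$completed)
  if (is.numeric(events$completed)) out$completed <- events$completed != 0
  out$duration_min <- suppressWarnings(as.numeric(out$duration_min))
  out$user_id <- as.character(out$user_id)

  bad <- is.na(out$start) | is.na(out$account_created) |
    is.na(out$completed) | is.na(out$duration_min) | out$duration_min < 0 |
    is.na(out$user_id) | out$user_id == "" |
    as.Date(out$start, tz = "UTC") < out$account_created
  if (any(bad)) {
    idx <- which(bad)
    show <- paste(head(idx, 10), collapse = ", ")
    warnf("rejected %d malformed row(s) (rows %s%s)", length(idx), show,
          if (length(idx) > 10) ", ..." else "")
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Enrollment-day index of a session
#'
#' Day 1 is the account-creation day; a session on the `n`-th calendar day
#' after creation has index `n + 1`. Clock time is ignored: a 23:59 session
#' on the creation day is day 1, one at 00:00 the next day is day 2.
#'
#' @param start session start timestamp(s) (`POSIXct`).
#' @param account_created account creation date(s) (`Date`).
#' @return integer vector of enrollment-day indices (>= 1).
#' @export
day_index <- function(start, account_created) {
  d <- as.integer(as.Date(start, tz = "UTC") - as.Date(account_created)) + 1L
  if (any(is.na(d)) || any(d < 1L))
    stopf("session start precedes account creation")
  d
}

#' Users meeting the early-engagement eligibility criterion
#'
#' A user is eligible when they used the app — any session type, completed
#' or not — at least `min_uses` times within their first `window_days`
#' enrollment days (both bounds inclusive).
#'
#' @param events an event log.
#' @param min_uses minimum number of app uses (default 8).
#' @param window_days length of the early window in days (default 60, i.e.
#'   the first two months).
#' @return sorted character vector of eligible user ids (possibly empty).
#' @export
eligible_users <- function(events, min_uses = 8L, window_days = 60L) {
  if (nrow(events) == 0L) return(character(0))
  d <- day_index(events$start, events$account_created)
  early <- events$user_id[d <= window_days]
  counts <- table(early)
  sort(names(counts)[counts >= min_uses])
}

#' Qualifying meditation sessions
#'
#' Filters an event log to the sessions the analysis counts as meditation:
#' type `Meditation`, tagged completed, and 3 to 60 minutes long (both ends
#' inclusive), and attaches the enrollment-day index `d`. When `max_day` is
#' given, sessions beyond that enrollment day are dropped as well — the
#' 180-day cap used for features and daily-probability modelling; outcome
#' construction passes `max_day = NULL` to keep the full history.
#'
#' @param events an event log (or an already-filtered session table —
#'   the operation is idempotent).
#' @param max_day optional inclusive cap on the enrollment day.
#' @return a session table: the qualifying rows plus an integer column `d`.
#' @export
meditation_sessions <- function(events, max_day = NULL) {
  keep <- events$session_type == "Meditation" &
    events$completed &
    events$duration_min >= 3 & events$duration_min <= 60
  out <- events[keep, , drop = FALSE]
  out$d <- if (nrow(out)) day_index(out$start, out$account_created) else integer(0)
  if (!is.null(max_day)) out <- out[out$d <= max_day, , drop = FALSE]
  rownames(out) <- NULL
  out
}
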