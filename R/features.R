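#' Time-of-day window of a session start
#'
#' The 24-hour clock is partitioned into four half-open windows: morning
#' \[04:00, 10:00), midday \[10:00, 16:00), evening \[16:00, 22:00) and
#' late night \[22:00, 04:00), the last wrapping midnight. Assignment
#' depends only on the local clock time of the start.
#'
#' @param start `POSIXct` timestamp(s).
#' @return factor with levels `morning`, `midday`, `evening`, `late_night`.
#' @export
tod_window <- function(start) {
  m <- clock_minutes(start)
  w <- ifelse(m >= 240 & m < 600, "morning",
       ifelse(m >= 600 & m < 960, "midday",
       ifelse(m >= 960 & m < 1320, "evening", "late_night")))
  factor(w, levels = TOD_LEVELS)
}

#' Time-of-day preference of one user
#'
#' Proportion of a user's meditation sessions starting in each of the four
#' time-of-day windows.
#'
#' @param starts the user's session start timestamps (at least one).
#' @return named numeric 4-vector summing to 1.
#' @export
tod_proportions <- function(starts) {
  if (length(starts) == 0L)
    stopf("time-of-day preference is undefined for a user with no sessions")
  tab <- table(tod_window(starts))
  p <- as.numeric(tab) / length(starts)
  names(p) <- TOD_LEVELS
  p
}

#' Timing entropy (temporal consistency)
#'
#' Shannon entropy, in nats, of a distribution over the four time-of-day
#' windows: `H = -sum(p * log(p))` with the `0 * log(0) = 0` convention.
#' `H = 0` means all sessions fall in a single window (perfect temporal
#' consistency); the maximum `log(4) = 1.386` (printed 1.38 at two
#' decimals) means equal use of all four windows.
#'
#' @param p nonnegative probability vector summing to 1 (tolerance 1e-9).
#' @return entropy in nats.
#' @examples
#' timing_entropy(c(1, 0, 0, 0))          # 0
#' timing_entropy(rep(0.25, 4))           # log(4) = 1.386...
#' @export
timing_entropy <- function(p) {
  if (any(!is.finite(p)) || any(p < 0))
    stopf("domain error: probabilities must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9)
    stopf("domain error: probabilities must sum to 1 (got %.12f)", sum(p))
  q <- p[p > 0]
  -sum(q * log(q)) + 0   # + 0 avoids IEEE negative zero when H = 0
}

#' Short-term maintenance outcome (sessions in months six and seven)
#'
#' Counts qualifying meditation sessions in the sixth and seventh 30-day
#' month of the account, i.e. enrollment days 151 to 210 inclusive. With
#' `convention = "calendar"`, months are calendar months after the
#' account-creation date instead.
#'
#' @param d enrollment-day indices of one user's all-time sessions.
#' @param convention `"fixed30"` (default) or `"calendar"`.
#' @param account_created account-creation date, required for the calendar
#'   convention.
#' @param dates session dates, required for the calendar convention.
#' @return integer count (0 allowed).
#' @export
outcome_m67 <- function(d, convention = c("fixed30", "calendar"),
                        account_created = NULL, dates = NULL) {
  convention <- match.arg(convention)
  if (convention == "fixed30") return(sum(d >= 151L & d <= 210L))
  if (is.null(account_created) || is.null(dates))
    stopf("calendar convention needs account_created and session dates")
  bounds <- seq(as.Date(account_created), by = "month", length.out = 8L)
  sum(as.Date(dates) >= bounds[6L] & as.Date(dates) < bounds[8L])
}

#' Long-term maintenance outcome (day of last session)
#'
#' The enrollment-day index of the user's last observed qualifying
#' meditation session, uncensored.
#'
#' @param d enrollment-day indices of one user's all-time sessions (at
#'   least one).
#' @return integer day index (>= 1).
#' @export
outcome_ls <- function(d) {
  if (length(d) == 0L)
    stopf("day of last session is undefined for a user with no sessions")
  max(d)
}

#' Account creation date as day of year
#'
#' @param account_created `Date` vector within the study year.
#' @param year the study year (default 2017).
#' @return integer day-of-year, 1 for January 1 through 365 for December 31.
#' @export
acd <- function(account_created, year = 2017L) {
  date <- as.Date(account_created)
  if (any(format(date, "%Y") != as.character(year)))
    stopf("account creation date outside the study year %d", year)
  as.integer(date - as.Date(sprintf("%d-01-01", year))) + 1L
}

#' Per-user features and outcomes
#'
#' Combines the timing features (time-of-day proportions, entropy, session
#' count), computed on the capped feature-window session table, with the
#' maintenance outcomes M67 and LS, computed on the all-time session table,
#' and the account-creation day of year. Users present in the all-time
#' table but with no session inside the feature window get `NA` features
#' (they are excluded listwise from feature-based models); the number of
#' such users is attached as attribute `n_dropped`.
#'
#' @param sessions_feat session table capped at the feature window (see
#'   [meditation_sessions()] with `max_day`).
#' @param sessions_all all-time session table for the same log.
#' @param year study year for [acd()].
#' @param m67_convention month convention passed to [outcome_m67()].
#' @return data frame with one row per user: `user_id`, `p_morning`,
#'   `p_midday`, `p_evening`, `p_late_night`, `entropy`, `n_sessions`,
#'   `m67`, `ls`, `acd`.
#' @export
user_features <- function(sessions_feat, sessions_all, year = 2017L,
                          m67_convention = "fixed30") {
  ids <- sort(unique(sessions_all$user_id))
  if (length(ids) == 0L) stopf("no users with qualifying sessions")
  acct <- sessions_all$account_created[match(ids, sessions_all$user_id)]
  feat_split <- split(sessions_feat, factor(sessions_feat$user_id, levels = ids))
  all_split <- split(sessions_all, factor(sessions_all$user_id, levels = ids))

  res <- lapply(ids, function(u) {
    sf <- feat_split[[u]]
    sa <- all_split[[u]]
    if (nrow(sf) > 0L) {
      p <- tod_proportions(sf$start)
      h <- timing_entropy(p)
      n <- nrow(sf)
    } else {
      p <- rep(NA_real_, 4L)
      h <- NA_real_
      n <- 0L
    }
    c(p, entropy = h, n_sessions = n,
      m67 = outcome_m67(sa$d, convention = m67_convention,
                        account_created = sa$account_created[1L],
                        dates = as.Date(sa$start, tz = "UTC")),
      ls = outcome_ls(sa$d))
  })
  out <- as.data.frame(do.call(rbind, res))
  names(out) <- c("p_morning", "p_midday", "p_evening", "p_late_night",
                  "entropy", "n_sessions", "m67", "ls")
  out <- cbind(user_id = ids, out, acd = acd(acct, year = year),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  n_dropped <- sum(out$n_sessions == 0L)
  if (n_dropped > 0L)
    message(sprintf("%d user(s) have no session in the feature window; features set to NA",
                    n_dropped))
  attr(out, "n_dropped") <- n_dropped
  out
}
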