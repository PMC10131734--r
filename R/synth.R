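#' Simulation configuration for synthetic event logs
#'
#' Bundles and validates the parameters of the synthetic event-log
#' generator. The defaults describe a cohort that looks like a commercial
#' meditation-app user base: accounts opened uniformly over a calendar year,
#' a daily meditation probability starting at `p_day1` on day 1 and decaying
#' to `p_day1 * (1 - decay_target)` by day 180, archetype-driven time-of-day
#' preferences, and a background stream of non-meditation app uses.
#'
#' @param n_users number of simulated users.
#' @param seed master integer seed; per-user substreams are derived from it
#'   deterministically, so growing `n_users` does not reshuffle earlier users.
#' @param year_start first day of the account-creation year (a `Date`).
#' @param archetype_mix probabilities of the four time-of-day archetypes
#'   (`high_sustained`, `high_decaying`, `moderate`, `low`), either a length-4
#'   vector shared by all windows or a 4 x 4 matrix with one row per window
#'   (morning, midday, evening, late_night). Each row must sum to 1.
#' @param p_day1 pooled probability of meditating on day 1, in (0, 1).
#' @param decay_target fractional reduction of the pooled daily probability
#'   by day 180, in \[0, 1).
#' @param other_session_rate expected non-meditation app uses per user-day.
#' @param duration_log_mean,duration_log_sd lognormal parameters for session
#'   duration in minutes (truncated to (0, 120]).
#' @param completion_prob probability that a meditation session is tagged
#'   completed.
#' @param churn_rate daily probability of permanent abandonment once
#'   `churn_start` is reached; the abandonment day is geometric, giving the
#'   day-of-last-session outcome a realistic spread. 0 disables churn.
#' @param churn_start first day at which abandonment can occur (default 181,
#'   so churn does not distort the modelled 180-day decay window).
#' @param horizon_days days of activity simulated per user; at least 730 is
#'   recommended so last-session days have realistic spread.
#' @param max_sessions_per_day cap on meditation sessions per user-day.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_events()]
#' @export
sim_config <- function(n_users = 500L,
                       seed = 1L,
                       year_start = as.Date("2017-01-01"),
                       archetype_mix = c(high_sustained = 0.10,
                                         high_decaying = 0.20,
                                         moderate = 0.35,
                                         low = 0.35),
                       p_day1 = 0.55,
                       decay_target = 0.66,
                       other_session_rate = 0.25,
                       duration_log_mean = log(11),
                       duration_log_sd = 0.45,
                       completion_prob = 0.85,
                       churn_rate = 0.004,
                       churn_start = 181L,
                       horizon_days = 730L,
                       max_sessions_per_day = 3L) {
  if (!is.numeric(n_users) || n_users < 1 || n_users > 20000)
    stopf("configuration error: n_users must be a positive integer (at most 20000)")
  if (!(is.numeric(p_day1) && p_day1 > 0 && p_day1 < 1))
    stopf("configuration error: p_day1 must lie in (0, 1)")
  if (!(is.numeric(decay_target) && decay_target >= 0 && decay_target < 1))
    stopf("configuration error: decay_target must lie in [0, 1)")
  if (!(is.numeric(completion_prob) && completion_prob >= 0 && completion_prob <= 1))
    stopf("configuration error: completion_prob must lie in [0, 1]")
  if (other_session_rate < 0)
    stopf("configuration error: other_session_rate must be nonnegative")
  if (!(is.numeric(churn_rate) && churn_rate >= 0 && churn_rate < 1))
    stopf("configuration error: churn_rate must lie in [0, 1)")
  if (churn_start < 1)
    stopf("configuration error: churn_start must be positive")
  if (horizon_days < 1)
    stopf("configuration error: horizon_days must be positive")
  mix <- archetype_mix
  if (is.null(dim(mix))) mix <- matrix(mix, nrow = 4, ncol = 4, byrow = TRUE)
  mix <- as.matrix(mix)
  if (!all(dim(mix) == c(4L, 4L)))
    stopf("configuration error: archetype_mix must be length 4 or 4 x 4")
  if (any(mix < 0) || any(abs(rowSums(mix) - 1) > 1e-8))
    stopf("configuration error: archetype_mix rows must be probabilities summing to 1")
  rownames(mix) <- TOD_LEVELS
  colnames(mix) <- ARCHETYPES
  structure(list(n_users = as.integer(n_users), seed = as.integer(seed),
                 year_start = as.Date(year_start), archetype_mix = mix,
                 p_day1 = p_day1, decay_target = decay_target,
                 other_session_rate = other_session_rate,
                 duration_log_mean = duration_log_mean,
                 duration_log_sd = duration_log_sd,
                 completion_prob = completion_prob,
                 churn_rate = churn_rate,
                 churn_start = as.integer(churn_start),
                 horizon_days = as.integer(horizon_days),
                 max_sessions_per_day = as.integer(max_sessions_per_day)),
            class = "sim_config")
}

ARCHETYPES <- c("high_sustained", "high_decaying", "moderate", "low")

#' Prototype weekly engagement curve of a time-of-day archetype
#'
#' Each archetype is a stylised cluster prototype: `high_sustained` keeps a
#' high weekly engagement probability throughout; `high_decaying` starts
#' high and decays towards zero; `moderate` holds a middling level; `low`
#' stays near zero.
#'
#' @param archetype one of `"high_sustained"`, `"high_decaying"`,
#'   `"moderate"`, `"low"`.
#' @param weeks number of weekly values to return.
#' @return numeric vector of length `weeks` with values in \[0, 1\].
#' @export
archetype_curve <- function(archetype, weeks = 25L) {
  archetype <- match.arg(archetype, ARCHETYPES)
  weeks <- as.integer(weeks)
  if (weeks < 1) stopf("weeks must be a positive integer")
  switch(archetype,
         high_sustained = rep(0.80, weeks),
         high_decaying  = 0.80 * exp(-0.18 * (seq_len(weeks) - 1)),
         moderate       = rep(0.45, weeks),
         low            = rep(0.05, weeks))
}

# Pooled daily meditation probability before per-user modulation: a logistic
# ramp in time from p_day1 (d = 1) to p_day1 * (1 - decay_target) (d = 180),
# continued past day 180 by exponential churn with a 300-day time constant.
base_daily_prob <- function(days, p_day1, decay_target) {
  g <- plogis((days - 90) / 30)
  g1 <- plogis((1 - 90) / 30)
  g180 <- plogis((180 - 90) / 30)
  u <- pmin((g - g1) / (g180 - g1), 1)
  p <- p_day1 * (1 - decay_target * u)
  p180 <- p_day1 * (1 - decay_target)
  late <- days > 180
  p[late] <- p180 * exp(-(days[late] - 180) / 300)
  p
}

# Clock minute-of-day sampled uniformly within a window; late_night wraps
# midnight, so draws land in [22:00, 24:00) or [00:00, 04:00).
sample_window_minutes <- function(window, n) {
  r <- runif(n) * 360
  switch(window,
         morning = 240 + r,
         midday = 600 + r,
         evening = 960 + r,
         late_night = ifelse(r < 120, 1320 + r, r - 120))
}

rtrunc_lnorm <- function(n, meanlog, sdlog, upper = 120) {
  qlnorm(runif(n) * plnorm(upper, meanlog, sdlog), meanlog, sdlog)
}

#' Simulate a synthetic meditation-app event log
#'
#' Generates per-user session streams with the statistical structure the
#' downstream analysis assumes. Each user receives an account-creation date
#' uniform over the configured year, one time-of-day archetype per window,
#' and a static intensity multiplier; on each day a meditation session
#' occurs with the decaying pooled probability times that intensity, its
#' start window is drawn from the user's (archetype-driven, slowly evolving)
#' window mixture, its clock time is uniform within the window, durations
#' are truncated-lognormal and completion flags Bernoulli. Non-meditation
#' sessions arrive as a Poisson stream. Fully deterministic for a fixed
#' seed, with per-user substreams.
#'
#' @param config a [sim_config()].
#' @return an object of class `meditod_sim`: a list with `events` (the event
#'   log, see [read_event_log()] for the schema) and `truth` (per-user
#'   ground-truth archetypes and intensities plus the configuration).
#' @examples
#' sim <- simulate_events(sim_config(n_users = 20, horizon_days = 240))
#' head(sim$events)
#' @export
simulate_events <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n_weeks <- ceiling(config$horizon_days / 7)
  curves <- vapply(ARCHETYPES, archetype_curve, numeric(n_weeks),
                   weeks = n_weeks)
  # expected sum of week-1 window weights under the mix, for normalising the
  # per-user intensity so the pooled day-1 frequency matches p_day1
  e_week1 <- sum(config$archetype_mix %*% curves[1L, ])
  other_types <- setdiff(SESSION_TYPES, "Meditation")
  p0 <- base_daily_prob(seq_len(config$horizon_days),
                        config$p_day1, config$decay_target)
  week_of_day <- pmin(((seq_len(config$horizon_days) - 1) %/% 7) + 1, n_weeks)

  users <- vector("list", config$n_users)
  truth_rows <- vector("list", config$n_users)
  id_fmt <- paste0("u%0", max(4, nchar(config$n_users)), "d")
  for (i in seq_len(config$n_users)) {
    uid <- sprintf(id_fmt, i)
    sub_seed <- (config$seed %% 100003L) + 104729L * i
    res <- with_seed(sub_seed, {
      acct <- config$year_start + (sample.int(365L, 1L) - 1L)
      arch <- vapply(TOD_LEVELS, function(w) {
        sample(ARCHETYPES, 1L, prob = config$archetype_mix[w, ])
      }, character(1))
      wmat <- curves[, arch, drop = FALSE]   # n_weeks x 4 window weights
      colnames(wmat) <- TOD_LEVELS
      s_u <- sum(wmat[1L, ]) / e_week1
      churn_day <- if (config$churn_rate > 0) {
        config$churn_start - 1L + rgeom(1L, config$churn_rate) + 1L
      } else config$horizon_days
      churn_day <- min(churn_day, config$horizon_days)
      p_u <- pmin(p0 * s_u, 0.95)
      active <- which(runif(config$horizon_days) < p_u)
      active <- active[active <= churn_day]
      med <- NULL
      if (length(active)) {
        extra <- if (config$max_sessions_per_day > 1L)
          rbinom(length(active), config$max_sessions_per_day - 1L, 0.2)
        else integer(length(active))
        d_sess <- rep(active, extra + 1L)
        wk <- week_of_day[d_sess]
        win <- vapply(wk, function(k) {
          wts <- wmat[k, ]
          if (sum(wts) <= 0) wts <- rep(1, 4)
          sample(TOD_LEVELS, 1L, prob = wts)
        }, character(1))
        mins <- numeric(length(win))
        for (w in TOD_LEVELS) {
          j <- which(win == w)
          if (length(j)) mins[j] <- sample_window_minutes(w, length(j))
        }
        med <- data.frame(
          user_id = uid, account_created = acct,
          start = as.POSIXct(acct, tz = "UTC") +
            (d_sess - 1) * 86400 + floor(mins) * 60,
          session_type = "Meditation",
          completed = runif(length(d_sess)) < config$completion_prob,
          duration_min = round(rtrunc_lnorm(length(d_sess),
                                            config$duration_log_mean,
                                            config$duration_log_sd), 2),
          stringsAsFactors = FALSE)
      }
      oth <- NULL
      n_other <- rpois(1L, config$other_session_rate * config$horizon_days)
      if (n_other > 0) {
        d_oth <- sample.int(config$horizon_days, n_other, replace = TRUE)
        d_oth <- d_oth[d_oth <= churn_day]
        n_other <- length(d_oth)
      }
      if (n_other > 0) {
        oth <- data.frame(
          user_id = uid, account_created = acct,
          start = as.POSIXct(acct, tz = "UTC") +
            (d_oth - 1) * 86400 + floor(runif(n_other) * 1440) * 60,
          session_type = sample(other_types, n_other, replace = TRUE),
          completed = runif(n_other) < 0.8,
          duration_min = round(rtrunc_lnorm(n_other,
                                            config$duration_log_mean,
                                            config$duration_log_sd), 2),
          stringsAsFactors = FALSE)
      }
      ev <- rbind(med, oth)
      if (!is.null(ev)) ev <- ev[order(ev$start), , drop = FALSE]
      list(events = ev,
           truth = data.frame(user_id = uid, account_created = acct,
                              intensity = s_u, churn_day = churn_day,
                              arch_morning = arch[["morning"]],
                              arch_midday = arch[["midday"]],
                              arch_evening = arch[["evening"]],
                              arch_late_night = arch[["late_night"]],
                              stringsAsFactors = FALSE))
    })
    users[[i]] <- res$events
    truth_rows[[i]] <- res$truth
  }
  events <- do.call(rbind, users[!vapply(users, is.null, logical(1))])
  rownames(events) <- NULL
  truth <- list(users = do.call(rbind, truth_rows), config = config)
  structure(list(events = events, truth = truth), class = "meditod_sim")
}

#' @export
print.meditod_sim <- function(x, ...) {
  cat("Synthetic meditation-app event log\n")
  cat(sprintf("  users: %d   events: %d   horizon: %d days   seed: %d\n",
              x$truth$config$n_users, nrow(x$events),
              x$truth$config$horizon_days, x$truth$config$seed))
  invisible(x)
}

#' True pooled daily meditation probability of a simulated cohort
#'
#' Closed-form mean over users of the generator's daily occurrence
#' probability, for use as ground truth in recovery checks.
#'
#' @param sim a `meditod_sim` object.
#' @param days day indices (default the full simulated horizon).
#' @return numeric vector of pooled probabilities, one per day.
#' @export
true_mean_curve <- function(sim, days = NULL) {
  cfg <- sim$truth$config
  days <- days %||% seq_len(cfg$horizon_days)
  p0 <- base_daily_prob(days, cfg$p_day1, cfg$decay_target)
  pmat <- outer(p0, sim$truth$users$intensity, function(p, s) pmin(p * s, 0.95))
  alive <- outer(days, sim$truth$users$churn_day, `<=`)
  rowMeans(pmat * alive)
}

#' Simulate user features with known regression structure
#'
#' Regression-recovery mode of the generator: draws per-user feature vectors
#' (session count, timing entropy, a time-of-day proportion) directly and
#' builds the outcome from a known linear model plus Gaussian noise, so OLS
#' recovery of the generating coefficients can be verified.
#'
#' @param n_users number of users.
#' @param seed integer seed.
#' @param coefs named generating coefficients: `intercept`, `n_sessions`,
#'   `entropy`, `tod`.
#' @param sigma residual standard deviation.
#' @return list with `data` (data frame `y`, `n_sessions`, `entropy`, `tod`)
#'   and `coefs` (the generating coefficients).
#' @export
simulate_regression <- function(n_users = 2000L, seed = 1L,
                                coefs = c(intercept = 5, n_sessions = 0.4,
                                          entropy = -2, tod = 2.5),
                                sigma = 6) {
  stopifnot(all(c("intercept", "n_sessions", "entropy", "tod") %in% names(coefs)))
  with_seed(seed, {
    n_sessions <- round(rlnorm(n_users, log(25), 0.6))
    entropy <- runif(n_users, 0, log(4))
    tod <- rbeta(n_users, 2, 3)
    y <- coefs[["intercept"]] + coefs[["n_sessions"]] * n_sessions +
      coefs[["entropy"]] * entropy + coefs[["tod"]] * tod +
      rnorm(n_users, 0, sigma)
    list(data = data.frame(y = y, n_sessions = n_sessions,
                           entropy = entropy, tod = tod),
         coefs = coefs)
  })
}

#' Write an event log or ground-truth table to CSV
#'
#' @param events event-log data frame (see [read_event_log()] for columns).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_event_log <- function(events, path) {
  out <- events
  out$start <- format(out$start, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  out$account_created <- format(out$account_created, "%Y-%m-%d")
  out$completed <- ifelse(out$completed, "TRUE", "FALSE")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @param truth the `truth` element of a [simulate_events()] result.
#' @export
write_truth <- function(truth, path) {
  write.csv(truth$users, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
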