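ts <- function(x) as.POSIXct(paste("2017-05-01", x), tz = "UTC")

test_that("time-of-day windows partition the clock at the stated boundaries", {
  expect_equal(as.character(tod_window(ts("04:00"))), "morning")
  expect_equal(as.character(tod_window(ts("09:59"))), "morning")
  expect_equal(as.character(tod_window(ts("10:00"))), "midday")
  expect_equal(as.character(tod_window(ts("15:59"))), "midday")
  expect_equal(as.character(tod_window(ts("16:00"))), "evening")
  expect_equal(as.character(tod_window(ts("21:59"))), "evening")
  expect_equal(as.character(tod_window(ts("22:00"))), "late_night")
  expect_equal(as.character(tod_window(ts("03:59"))), "late_night")
  # every minute of the day maps to exactly one window
  mins <- seq(0, 24 * 60 - 1)
  w <- tod_window(as.POSIXct("2017-05-01", tz = "UTC") + mins * 60)
  expect_false(anyNA(w))
  expect_equal(as.numeric(table(w)), rep(360, 4))
})

test_that("time-of-day proportions are direct session counts", {
  p <- tod_proportions(ts(c("07:00", "12:00", "18:00", "23:00")))
  expect_equal(unname(p), rep(0.25, 4))
  p <- tod_proportions(rep(ts("07:00"), 10))
  expect_equal(unname(p), c(1, 0, 0, 0))
  p <- tod_proportions(ts(c("07:00", "07:30", "20:00")))
  expect_equal(unname(p), c(2 / 3, 0, 1 / 3, 0))
  expect_error(tod_proportions(as.POSIXct(character(0), tz = "UTC")),
               "no sessions")
})

test_that("timing entropy matches its defining values", {
  expect_equal(timing_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(timing_entropy(rep(0.25, 4)), log(4))
  expect_equal(timing_entropy(c(0.5, 0.5, 0, 0)), log(2))
  expect_error(timing_entropy(c(-0.1, 0.6, 0.25, 0.25)), "nonnegative")
  expect_error(timing_entropy(c(0.5, 0.2, 0.2, 0.2)), "sum to 1")
})

test_that("entropy is bounded, permutation-invariant, and coarsening-monotone", {
  with_seed <- meditod:::with_seed
  ps <- with_seed(11, lapply(1:50, function(i) {
    g <- rgamma(4, shape = runif(1, 0.2, 3))
    g / sum(g)
  }))
  for (p in ps) {
    h <- timing_entropy(p)
    expect_gte(h, 0)
    expect_lte(h, log(4) + 1e-12)
    expect_equal(timing_entropy(sample(p)), h)
    # merging any two windows never increases entropy
    for (i in 1:3) for (j in (i + 1):4) {
      q <- p[-j]
      q[i] <- p[i] + p[j]
      expect_lte(timing_entropy(q), h + 1e-12)
    }
  }
  expect_equal(timing_entropy(c(0.7, 0.3, 0, 0) / 1), timing_entropy(c(0.3, 0.7, 0, 0)))
})

test_that("M67 counts sessions on days 151-210 inclusive", {
  expect_equal(outcome_m67(c(151L, 210L)), 2L)
  expect_equal(outcome_m67(150L), 0L)
  expect_equal(outcome_m67(211L), 0L)
  # one session every day for a year gives the full 60-day block
  expect_equal(outcome_m67(1:365), 60L)
})

test_that("LS is the maximum enrollment day and requires a session", {
  expect_equal(outcome_ls(c(1L, 5L, 400L)), 400L)
  expect_equal(outcome_ls(1L), 1L)
  expect_error(outcome_ls(integer(0)), "undefined")
})

test_that("mean LS in a geometric-churn cohort matches exact enumeration", {
  cfg <- sim_config(n_users = 200, horizon_days = 250, seed = 55,
                    p_day1 = 0.8, decay_target = 0,
                    archetype_mix = c(0, 0, 1, 0),
                    other_session_rate = 0, completion_prob = 0.9,
                    churn_rate = 0.012, churn_start = 1,
                    max_sessions_per_day = 1)
  sim <- simulate_events(cfg)
  s <- meditation_sessions(sim$events)
  ls <- tapply(s$d, s$user_id, max)

  # enumeration oracle: qualifying-session probability per user-day
  r <- (plnorm(60, cfg$duration_log_mean, cfg$duration_log_sd) -
          plnorm(3, cfg$duration_log_mean, cfg$duration_log_sd)) /
    plnorm(120, cfg$duration_log_mean, cfg$duration_log_sd)
  q <- 0.8 * 0.9 * r
  H <- 250L
  kappa <- 0.012
  # churn day C = 1 + G, G ~ Geom(kappa), capped at the horizon
  pC <- kappa * (1 - kappa)^(0:(H - 2))
  pC <- c(pC, 1 - sum(pC))                       # P(C = 1..H)
  e_num <- 0
  p_any <- 0
  for (cday in 1:H) {
    m <- 1:cday
    p_ls <- q * (1 - q)^(cday - m)               # P(LS = m | C = cday)
    e_num <- e_num + pC[cday] * sum(m * p_ls)
    p_any <- p_any + pC[cday] * sum(p_ls)
  }
  oracle <- e_num / p_any                        # E[LS | >= 1 session]
  se <- sd(ls) / sqrt(length(ls))
  expect_lt(abs(mean(ls) - oracle), 3 * se)
})

test_that("account-creation day of year spans the calendar", {
  expect_equal(acd(as.Date("2017-01-01")), 1L)
  expect_equal(acd(as.Date("2017-12-31")), 365L)
  expect_equal(acd(as.Date("2017-02-01")), 32L)
  expect_error(acd(as.Date("2018-01-01")), "study year")
})

test_that("outcomes use all-time sessions while features use the capped window", {
  log <- make_log(
    evt("a", "2017-01-01", "2017-01-05 07:00:00"),
    evt("a", "2017-01-01", "2017-07-19 07:00:00"),   # d = 200, in months 6-7
    evt("a", "2017-01-01", "2017-10-27 20:00:00"))   # d = 300
  s_all <- meditation_sessions(log)
  s_cap <- meditation_sessions(log, max_day = 180)
  f <- user_features(s_cap, s_all)
  expect_equal(f$n_sessions, 1)
  expect_equal(f$m67, 1)
  expect_equal(f$ls, 300)
  expect_equal(f$acd, 1L)
  expect_equal(f$p_morning, 1)
  expect_equal(f$entropy, 0)
  # reusing the capped table for outcomes would change them
  expect_false(outcome_m67(s_cap$d) == f$m67)
  expect_false(outcome_ls(s_cap$d) == f$ls)
})

test_that("per-user proportions always sum to one and entropy stays in range", {
  sim <- fixture_sim()
  s_all <- meditation_sessions(sim$events)
  s_cap <- meditation_sessions(sim$events, max_day = 180)
  f <- suppressMessages(user_features(s_cap, s_all))
  has <- f$n_sessions > 0
  psum <- rowSums(f[has, c("p_morning", "p_midday", "p_evening", "p_late_night")])
  expect_equal(unname(psum), rep(1, sum(has)))
  expect_true(all(f$entropy[has] >= 0 & f$entropy[has] <= log(4) + 1e-12))
  expect_true(all(f$ls >= 1))
  expect_true(all(f$m67 >= 0))
  expect_true(all(f$acd >= 1 & f$acd <= 365))
})
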