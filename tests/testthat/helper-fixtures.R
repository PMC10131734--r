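# Hand-built event-log rows for filter-level tests.
evt <- function(user = "u1", acct = "2017-03-01", start = "2017-03-01 08:00:00",
                type = "Meditation", completed = TRUE, dur = 10) {
  data.frame(user_id = user,
             account_created = as.Date(acct),
             start = as.POSIXct(start, tz = "UTC"),
             session_type = type,
             completed = completed,
             duration_min = dur,
             stringsAsFactors = FALSE)
}

make_log <- function(...) do.call(rbind, list(...))

# One moderate synthetic cohort shared across tests (memoised).
.fixtures <- new.env(parent = emptyenv())
fixture_sim <- function() {
  if (is.null(.fixtures$sim))
    .fixtures$sim <- simulate_events(
      sim_config(n_users = 150, horizon_days = 400, seed = 101))
  .fixtures$sim
}

# Well-separated archetype trajectories with known labels.
archetype_bundles <- function(n_per = 40, noise = 0.05, seed = 404) {
  archetypes <- c("high_sustained", "high_decaying", "moderate", "low")
  x <- meditod:::with_seed(seed, {
    m <- do.call(rbind, lapply(archetypes, function(a)
      matrix(rep(archetype_curve(a, 25), each = n_per), n_per)))
    pmin(pmax(m + matrix(rnorm(4 * n_per * 25, 0, noise), 4 * n_per), 0), 1)
  })
  list(x = x, labels = rep(1:4, each = n_per))
}

# A homogeneous daily panel with known per-day probabilities.
make_panel <- function(n_users, p, n_days = 180L, seed = 1L) {
  users <- sprintf("s%04d", seq_len(n_users))
  p_day <- rep(p, length.out = n_days)
  y <- meditod:::with_seed(seed,
    rbinom(n_users * n_days, 1L, rep(p_day, n_users)))
  out <- data.frame(user_id = factor(rep(users, each = n_days), levels = users),
                    d = rep(seq_len(n_days), n_users),
                    y = y)
  attr(out, "window") <- "any"
  attr(out, "n_days") <- n_days
  class(out) <- c("daily_panel", "data.frame")
  out
}
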