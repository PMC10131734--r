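test_that("the daily panel marks exactly the window-active days", {
  log <- evt("a", "2017-01-01", "2017-01-05 07:00:00")
  s <- meditation_sessions(log)
  pan <- build_daily_panel(s, window = "morning", users = "a")
  expect_equal(nrow(pan), 180L)
  expect_equal(pan$y[pan$d == 5], 1L)
  expect_equal(sum(pan$y), 1L)
  pan_e <- build_daily_panel(s, window = "evening", users = "a")
  expect_equal(sum(pan_e$y), 0L)
  expect_error(build_daily_panel(s, users = character(0)), "empty user set")
})

test_that("panel row sums equal brute-force distinct-active-day counts", {
  sim <- fixture_sim()
  s <- meditation_sessions(sim$events, max_day = 180)
  users <- sort(unique(s$user_id))[1:40]
  for (w in c("any", "morning", "late_night")) {
    pan <- build_daily_panel(s, window = w, users = users)
    got <- tapply(pan$y, pan$user_id, sum)
    sel <- s$user_id %in% users
    if (w != "any") sel <- sel & tod_window(s$start) == w
    sub <- s[sel, ]
    want <- vapply(users, function(u)
      length(unique(sub$d[sub$user_id == u])), numeric(1))
    expect_equal(as.numeric(got[users]), as.numeric(want))
    expect_true(all(pan$y %in% 0:1))
    expect_equal(as.numeric(table(pan$user_id)), rep(180, length(users)))
  }
})

test_that("a constant-probability panel is recovered within 0.03 everywhere", {
  pan <- make_panel(150, 0.3, seed = 5)
  fit <- fit_gamm(pan)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$curve - 0.3)), 0.03)
  # accepted IRLS steps never increase the penalized deviance
  expect_true(all(diff(fit$trajectory) <= 1e-8))
})

test_that("a heavy penalty collapses to the intercept-only fit", {
  pan <- make_panel(80, 0.25, seed = 9)
  fit <- fit_gamm(pan, lambda = 1e8)
  p_glm <- mean(pan$y)  # intercept-only logistic fit is the pooled mean
  expect_lt(max(abs(fit$curve - p_glm)), 1e-3)
})

test_that("a smooth periodic signal is recovered within Monte-Carlo bands", {
  n_users <- 300
  b <- cyclic_cubic_basis(180, 8, cyclic = TRUE)
  period <- max(b$knots) - min(b$knots)
  truth <- plogis(-1 + 0.8 * sin(2 * pi * ((1:180) - 1) / period))
  pan <- make_panel(n_users, truth, seed = 13)
  fit <- fit_gamm(pan)
  expect_lt(max(abs(fit$curve - truth)), 0.05)
  expect_lt(mean(abs(fit$curve - truth)), 0.015)
  # cross-check against an independent penalized-spline logistic fit
  gfit <- mgcv::gam(y ~ s(d, bs = "cc", k = 8), family = stats::binomial(),
                    data = pan)
  gcurve <- as.numeric(predict(gfit, data.frame(d = 1:180), type = "response"))
  expect_lt(max(abs(fit$curve - gcurve)), 0.03)
})

test_that("duplicating every user leaves the population curve unchanged", {
  pan <- make_panel(30, 0.4, n_days = 90, seed = 17)
  users2 <- c(levels(pan$user_id), paste0("dup_", levels(pan$user_id)))
  pan2 <- rbind(pan, transform(pan, user_id = paste0("dup_", user_id)))
  pan2$user_id <- factor(pan2$user_id, levels = users2)
  attr(pan2, "n_days") <- 90L
  class(pan2) <- c("daily_panel", "data.frame")
  f1 <- fit_gamm(pan, lambda = 0.1)
  f2 <- fit_gamm(pan2, lambda = 0.1)
  expect_equal(f1$curve, f2$curve, tolerance = 1e-6)
})

test_that("the population curve is the basis expansion through the link", {
  pan <- make_panel(40, 0.35, n_days = 120, seed = 21)
  fit <- fit_gamm(pan, lambda = 1)
  X <- cbind(1, basis_matrix(fit$basis, 1:120, constrained = TRUE))
  expect_equal(fit$curve, drop(plogis(X %*% coef(fit))), tolerance = 1e-12)
  expect_equal(predict_curve(fit), fit$curve)
  expect_equal(predict(fit, type = "link"), drop(X %*% coef(fit)),
               tolerance = 1e-12)
  expect_equal(predict(fit), fit$curve, tolerance = 1e-12)
  # the logistic link preserves monotonicity
  eta <- seq(2, -2, length.out = 50)
  expect_true(all(diff(plogis(eta)) < 0))
})

test_that("percent change is the relative day-1 to day-180 difference", {
  expect_equal(percent_change(c(0.5, 0.25)), -50)
  expect_equal(percent_change(rep(0.37, 180)), 0)
  expect_error(percent_change(c(0, 0.5)), "p\\(1\\) = 0")
  expect_error(percent_change(0.5), "at least two")
})

test_that("the simulated cohort's fitted decay matches the generator", {
  sim <- simulate_events(sim_config(n_users = 500, horizon_days = 200,
                                    seed = 1))
  s <- meditation_sessions(sim$events, max_day = 180)
  pan <- build_daily_panel(s, users = sort(unique(sim$events$user_id)))
  fit <- fit_gamm(pan, cyclic = FALSE)
  pc <- percent_change(fit)
  expect_gt(pc, -72)
  expect_lt(pc, -60)
  # population curve stays a probability and p(1) is near the configured level
  expect_true(all(fit$curve > 0 & fit$curve < 1))
  expect_lt(abs(fit$curve[1] - 0.5), 0.1)
})

test_that("the any-window curve dominates each single window", {
  sim <- fixture_sim()
  s <- meditation_sessions(sim$events, max_day = 180)
  users <- sort(unique(s$user_id))
  fits <- lapply(c("any", "morning", "midday", "evening", "late_night"),
                 function(w) {
                   pan <- build_daily_panel(s, window = w, users = users)
                   fit_gamm(pan, cyclic = FALSE, lambda = 0.1)
                 })
  p_any <- fits[[1]]$curve
  for (k in 2:5)
    expect_true(all(p_any >= fits[[k]]$curve - 0.05))
})

test_that("quartile subsets use linear-interpolation quantiles with ties", {
  f <- data.frame(user_id = c("a", "b", "c", "d"), m67 = 1:4, ls = c(2, 2, 2, 2))
  expect_identical(quartile_subset(f, "m67", "bottom"), "a")
  expect_identical(quartile_subset(f, "m67", "top"), "d")
  # degenerate ties: everyone is in both subsets
  expect_identical(quartile_subset(f, "ls", "bottom"), f$user_id)
  expect_identical(quartile_subset(f, "ls", "top"), f$user_id)
  g <- data.frame(user_id = sprintf("u%02d", 1:20),
                  m67 = meditod:::with_seed(3, rpois(20, 5)))
  bot <- quartile_subset(g, "m67", "bottom")
  top <- quartile_subset(g, "m67", "top")
  expect_true(all(c(bot, top) %in% g$user_id))
  expect_length(intersect(bot, top), 0)
})
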