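#' Build a user-by-day binary meditation panel
#'
#' For every user and enrollment day `d = 1..n_days`, `y` is 1 when the
#' user has at least one qualifying session starting that day (within the
#' given time-of-day window, if one is named) and 0 otherwise. Every user
#' contributes exactly `n_days` rows, including users with no session in
#' the window.
#'
#' @param sessions a session table (see [meditation_sessions()]) already
#'   capped at `n_days`.
#' @param window `"any"` or one of the four window labels.
#' @param users character vector of user ids to include (must be
#'   non-empty); defaults to the users present in `sessions`.
#' @param n_days panel length in days (default 180).
#' @return a `daily_panel` data frame with columns `user_id` (factor),
#'   `d` and `y`.
#' @export
build_daily_panel <- function(sessions, window = "any", users = NULL,
                              n_days = 180L) {
  window <- match.arg(window, c("any", TOD_LEVELS))
  users <- users %||% sort(unique(sessions$user_id))
  if (length(users) == 0L) stopf("empty user set")
  n_days <- as.integer(n_days)
  sel <- sessions$d <= n_days & sessions$user_id %in% users
  if (window != "any") sel <- sel & tod_window(sessions$start) == window
  act <- sessions[sel, c("user_id", "d")]
  ui <- match(act$user_id, users)
  y <- integer(length(users) * n_days)
  y[unique((ui - 1L) * n_days + act$d)] <- 1L
  out <- data.frame(user_id = factor(rep(users, each = n_days), levels = users),
                    d = rep(seq_len(n_days), length(users)),
                    y = y)
  attr(out, "window") <- window
  attr(out, "n_days") <- n_days
  class(out) <- c("daily_panel", "data.frame")
  out
}

# One penalized-IRLS fit at fixed smoothing parameters.
#
# Model: logit P(y = 1 | u, d) = x(d)'c + b_u, minimising
#   deviance + n * lambda * c' S c + theta * sum(b_u^2),
# i.e. the mixed model written as a ridge penalty on per-user intercepts.
# The working normal equations are solved by block elimination: the
# user-intercept block is diagonal, so the smooth coefficients come from a
# small Schur-complement system and the intercepts back-substitute.
pirls_fixed <- function(y, dvec, ui, n_users, Xd, Sfull, lambda, theta,
                        cc_init = NULL, b_init = NULL,
                        tol = 1e-8, max_iter = 200L) {
  n <- length(y)
  p <- ncol(Xd)
  Xrows <- Xd[dvec, , drop = FALSE]
  cc <- cc_init %||% c(qlogis(min(max(mean(y), 1e-3), 1 - 1e-3)), rep(0, p - 1L))
  b <- b_init %||% rep(0, n_users)
  Pen <- n * lambda * Sfull

  pen_dev <- function(cc, b) {
    eta <- drop(Xrows %*% cc) + b[ui]
    mu <- plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
    dev + drop(crossprod(cc, Pen %*% cc)) + theta * sum(b^2)
  }

  pd_old <- pen_dev(cc, b)
  trajectory <- pd_old
  converged <- FALSE
  iter <- 0L
  Sw <- NULL
  for (iter in seq_len(max_iter)) {
    eta <- drop(Xrows %*% cc) + b[ui]
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-6)
    z <- eta + (y - mu) / w

    WX <- Xrows * w
    XtWX <- crossprod(Xrows, WX)
    M <- rowsum(WX, ui, reorder = TRUE)            # n_users x p
    Sw <- drop(rowsum(w, ui, reorder = TRUE))
    Dv <- Sw + theta
    r1 <- drop(crossprod(Xrows, w * z))
    r2 <- drop(rowsum(w * z, ui, reorder = TRUE))
    Asc <- XtWX + Pen - crossprod(M / sqrt(Dv))
    rhs <- r1 - drop(crossprod(M, r2 / Dv))
    cc_new <- drop(solve(Asc, rhs))
    b_new <- drop((r2 - M %*% cc_new) / Dv)

    # step-halve until the penalized deviance does not increase
    step <- 1
    repeat {
      cc_try <- cc + step * (cc_new - cc)
      b_try <- b + step * (b_new - b)
      pd_new <- pen_dev(cc_try, b_try)
      if (pd_new <= pd_old + 1e-10 || step < 1e-4) break
      step <- step / 2
    }
    cc <- cc_try
    b <- b_try
    trajectory <- c(trajectory, pd_new)
    if (abs(pd_old - pd_new) / (abs(pd_new) + 0.1) < tol) {
      converged <- TRUE
      pd_old <- pd_new
      break
    }
    pd_old <- pd_new
  }

  # diagnostics at the solution
  eta <- drop(Xrows %*% cc) + b[ui]
  mu <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
  w <- pmax(mu * (1 - mu), 1e-6)
  WX <- Xrows * w
  XtWX <- crossprod(Xrows, WX)
  M <- rowsum(WX, ui, reorder = TRUE)
  Sw <- drop(rowsum(w, ui, reorder = TRUE))
  Dv <- Sw + theta
  Xsc <- XtWX - crossprod(M / sqrt(Dv))
  Asc <- Xsc + Pen
  edf_fixed <- sum(diag(solve(Asc, Xsc)))
  t_u <- Sw / Dv
  edf <- edf_fixed + sum(t_u)
  dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
  gcv <- n * dev / (n - min(edf, n - 1))^2

  list(cc = cc, b = b, deviance = dev, pen_deviance = pd_old, edf = edf,
       edf_fixed = edf_fixed, t_u = t_u, gcv = gcv, converged = converged,
       iterations = iter, trajectory = trajectory)
}

#' Fit the daily meditation-probability model
#'
#' Estimates the probability of meditating on each enrollment day with a
#' penalized logistic additive model: a cubic regression spline smooth of
#' enrollment day (cyclic by default, 8 knots) plus a per-user random
#' intercept, fitted by penalized iteratively reweighted least squares.
#' The random intercepts enter as a ridge penalty whose precision is
#' updated by a fixed-point step (the standard mixed-model-as-penalty
#' identity), so the fit is deterministic and needs no external mixed-model
#' engine. The curvature penalty is scaled by the number of observations,
#' making a fixed `lambda` comparable across cohort sizes; when `lambda`
#' is `NULL` it is chosen by approximate GCV over a log-spaced grid.
#'
#' @param panel a [build_daily_panel()] result.
#' @param n_knots number of spline knots (default 8).
#' @param cyclic wrap the smooth so the last day rejoins day 1? Default
#'   `TRUE`. Note the wrap forces the fitted curve to return to its day-1
#'   level, which suits periodic signals but not a monotone decay; pass
#'   `FALSE` for decay summaries.
#' @param lambda fixed per-observation smoothing parameter, or `NULL` for
#'   GCV selection.
#' @param lambda_grid candidate grid used when `lambda` is `NULL`.
#' @param tol relative penalized-deviance convergence tolerance.
#' @param max_iter maximum IRLS iterations per fit.
#' @return an object of class `meditod_gamm` with, among others, the
#'   population curve `curve` (`p_hat(d)` at random intercept 0), smooth
#'   coefficients, per-user intercepts `b`, `lambda`, the intercept
#'   variance `sigma2_b`, effective degrees of freedom and convergence
#'   diagnostics.
#' @seealso [predict_curve()], [percent_change()]
#' @export
fit_gamm <- function(panel, n_knots = 8L, cyclic = TRUE, lambda = NULL,
                     lambda_grid = 10^seq(-6, 2, by = 1),
                     tol = 1e-8, max_iter = 200L) {
  if (!nrow(panel)) stopf("empty panel")
  n_days <- attr(panel, "n_days") %||% max(panel$d)
  basis <- cyclic_cubic_basis(n_days = n_days, n_knots = n_knots,
                              cyclic = cyclic)
  Xd <- cbind(1, basis$con$X)
  p <- ncol(Xd)
  Sfull <- matrix(0, p, p)
  Sfull[-1L, -1L] <- basis$con$S

  ui <- as.integer(panel$user_id)
  users <- levels(panel$user_id)
  y <- panel$y
  dvec <- panel$d

  run_at <- function(lam, cc0 = NULL, b0 = NULL) {
    theta <- 10
    fit <- NULL
    for (outer in seq_len(10L)) {
      fit <- pirls_fixed(y, dvec, ui, length(users), Xd, Sfull, lam, theta,
                         cc_init = cc0, b_init = b0,
                         tol = tol, max_iter = max_iter)
      cc0 <- fit$cc
      b0 <- fit$b
      sigma2 <- sum(fit$b^2) / max(sum(fit$t_u), 1e-8)
      sigma2 <- min(max(sigma2, 1e-8), 100)
      theta_new <- 1 / sigma2
      if (abs(log(theta_new) - log(theta)) < 1e-2) {
        theta <- theta_new
        break
      }
      theta <- theta_new
    }
    fit$theta <- theta
    fit$sigma2_b <- 1 / theta
    fit
  }

  gcv_table <- NULL
  if (is.null(lambda)) {
    fits <- vector("list", length(lambda_grid))
    cc0 <- NULL
    b0 <- NULL
    for (j in seq_along(lambda_grid)) {
      fits[[j]] <- run_at(lambda_grid[j], cc0, b0)
      cc0 <- fits[[j]]$cc
      b0 <- fits[[j]]$b
    }
    gcv_table <- data.frame(lambda = lambda_grid,
                            gcv = vapply(fits, `[[`, numeric(1), "gcv"),
                            edf = vapply(fits, `[[`, numeric(1), "edf"))
    best <- which.min(gcv_table$gcv)
    lambda <- lambda_grid[best]
    fit <- fits[[best]]
  } else {
    fit <- run_at(lambda)
  }

  if (!fit$converged)
    stopf("IRLS did not converge in %d iterations; last penalized deviances: %s",
          max_iter,
          paste(signif(tail_n(fit$trajectory, 5L), 8), collapse = ", "))
  if (any(abs(fit$b) > 10))
    warnf("%d user intercept(s) exceed 10 on the logit scale (near-separation; bounded by the ridge)",
          sum(abs(fit$b) > 10))

  curve <- drop(plogis(Xd %*% fit$cc))
  structure(list(coefficients = setNames(fit$cc, c("(Intercept)",
                                                   paste0("s(d).", seq_len(p - 1L)))),
                 b = setNames(fit$b, users), basis = basis, lambda = lambda,
                 theta = fit$theta, sigma2_b = fit$sigma2_b,
                 curve = curve, edf = fit$edf, edf_fixed = fit$edf_fixed,
                 deviance = fit$deviance, gcv = fit$gcv,
                 gcv_table = gcv_table, converged = fit$converged,
                 iterations = fit$iterations, trajectory = fit$trajectory,
                 n_obs = length(y),
                 n_users = length(users), n_days = n_days,
                 window = attr(panel, "window") %||% "any",
                 panel = panel),
            class = "meditod_gamm")
}

tail_n <- function(x, n) x[max(1L, length(x) - n + 1L):length(x)]

#' Population daily-probability curve of a fitted model
#'
#' The predicted probability of meditating on each day for a typical user
#' (random intercept zero): `p_hat(d) = plogis(f(d))`.
#'
#' @param fit a [fit_gamm()] result.
#' @return numeric vector of probabilities for days `1..n_days`.
#' @export
predict_curve <- function(fit) {
  stopifnot(inherits(fit, "meditod_gamm"))
  fit$curve
}

#' Day-1 to day-180 percent change of a probability curve
#'
#' `100 * (p(last) - p(1)) / p(1)`, the summary used to quantify how much
#' the daily meditation probability decays over the modelling window.
#'
#' @param x a `meditod_gamm` fit or a numeric probability curve.
#' @return percent change (negative for decay).
#' @export
percent_change <- function(x) {
  curve <- if (inherits(x, "meditod_gamm")) x$curve else as.numeric(x)
  if (length(curve) < 2L) stopf("curve must cover at least two days")
  p1 <- curve[1L]
  if (p1 <= 0) stopf("undefined percent change: p(1) = 0")
  100 * (curve[length(curve)] - p1) / p1
}

#' Bottom- or top-quartile users by an outcome
#'
#' Quartiles use the linear-interpolation quantile definition
#' (`stats::quantile`, type 7); boundary ties are included, so the bottom
#' subset is `outcome <= Q1` and the top subset `outcome >= Q3`.
#'
#' @param features a [user_features()] table.
#' @param outcome `"m67"` or `"ls"`.
#' @param which `"bottom"` or `"top"`.
#' @return character vector of user ids.
#' @export
quartile_subset <- function(features, outcome = c("m67", "ls"),
                            which = c("bottom", "top")) {
  outcome <- match.arg(outcome)
  which <- match.arg(which)
  v <- features[[outcome]]
  if (length(v) < 4L) stopf("need at least 4 users for quartile subsets")
  if (which == "bottom") {
    features$user_id[v <= quantile(v, 0.25, type = 7)]
  } else {
    features$user_id[v >= quantile(v, 0.75, type = 7)]
  }
}

#' @export
print.meditod_gamm <- function(x, ...) {
  cat(sprintf("Penalized logistic additive model (%s cubic smooth, %d knots)\n",
              if (x$basis$cyclic) "cyclic" else "natural", x$basis$n_knots))
  cat(sprintf("  window: %s   users: %d   observations: %d\n",
              x$window, x$n_users, x$n_obs))
  cat(sprintf("  lambda: %.3g   sigma^2_b: %.3g   edf: %.1f\n",
              x$lambda, x$sigma2_b, x$edf))
  cat(sprintf("  p(1) = %.3f   p(%d) = %.3f   change: %+.1f%%\n",
              x$curve[1L], x$n_days, x$curve[x$n_days], percent_change(x)))
  invisible(x)
}

#' @export
summary.meditod_gamm <- function(object, ...) {
  out <- list(window = object$window, n_users = object$n_users,
              n_obs = object$n_obs, lambda = object$lambda,
              sigma2_b = object$sigma2_b, edf = object$edf,
              deviance = object$deviance, converged = object$converged,
              iterations = object$iterations,
              p1 = object$curve[1L], p_last = object$curve[object$n_days],
              pct_change = percent_change(object))
  class(out) <- "summary.meditod_gamm"
  out
}

#' @export
print.summary.meditod_gamm <- function(x, ...) {
  cat("Daily meditation-probability model\n")
  cat(sprintf("  window %s, %d users, %d user-days\n", x$window, x$n_users, x$n_obs))
  cat(sprintf("  smoothing lambda %.3g (edf %.1f), intercept variance %.3g\n",
              x$lambda, x$edf, x$sigma2_b))
  cat(sprintf("  deviance %.1f, converged after %d IRLS iterations\n",
              x$deviance, x$iterations))
  cat(sprintf("  p(1) = %.3f, p(last) = %.3f, percent change %+.1f%%\n",
              x$p1, x$p_last, x$pct_change))
  invisible(x)
}

#' @export
coef.meditod_gamm <- function(object, ...) object$coefficients

#' Predict from a daily-probability model
#'
#' @param object a `meditod_gamm` fit.
#' @param days days at which to predict (default `1..n_days`).
#' @param type `"response"` for probabilities, `"link"` for the logit.
#' @param ... unused.
#' @return numeric vector of predictions at random intercept zero.
#' @export
predict.meditod_gamm <- function(object, days = NULL,
                                 type = c("response", "link"), ...) {
  type <- match.arg(type)
  days <- days %||% seq_len(object$n_days)
  X <- cbind(1, basis_matrix(object$basis, days, constrained = TRUE))
  eta <- drop(X %*% object$coefficients)
  if (type == "response") plogis(eta) else eta
}

#' @export
fitted.meditod_gamm <- function(object, ...) {
  X <- cbind(1, basis_matrix(object$basis, object$panel$d, constrained = TRUE))
  plogis(drop(X %*% object$coefficients) + object$b[as.integer(object$panel$user_id)])
}

#' @export
residuals.meditod_gamm <- function(object,
                                   type = c("deviance", "pearson", "response"),
                                   ...) {
  type <- match.arg(type)
  mu <- fitted(object)
  y <- object$panel$y
  switch(type,
         response = y - mu,
         pearson = (y - mu) / sqrt(mu * (1 - mu)),
         deviance = sign(y - mu) *
           sqrt(pmax(-2 * (y * log(mu) + (1 - y) * log(1 - mu)), 0)))
}

#' Plot the fitted daily-probability curve
#'
#' @param x a `meditod_gamm` fit.
#' @param add_observed overlay the pooled daily frequencies?
#' @param ... passed to [graphics::plot()].
#' @export
plot.meditod_gamm <- function(x, add_observed = TRUE, ...) {
  plot(seq_len(x$n_days), x$curve, type = "l", lwd = 2, ylim = c(0, 1),
       xlab = "Enrollment day", ylab = "P(meditation)",
       main = sprintf("Daily meditation probability (%s)", x$window), ...)
  if (add_observed) {
    obs <- tapply(x$panel$y, x$panel$d, mean)
    lines(as.integer(names(obs)), obs, col = "grey60")
    legend("topright", legend = c("model", "observed"), lwd = c(2, 1),
           col = c("black", "grey60"), bty = "n")
  }
  invisible(x)
}
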