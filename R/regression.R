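#' Ordinary least squares with standardized coefficients
#'
#' Fits `y ~ X` by OLS (via [stats::lm()]'s QR decomposition), returning
#' for every predictor the raw coefficient `B`, its standard error from the
#' unbiased residual variance, the standardized coefficient
#' `beta = B * sd(x) / sd(y)`, and a two-sided t-test p-value on
#' `n - p - 1` degrees of freedom. Rank deficiency is an error naming the
#' collinear columns rather than a silent drop.
#'
#' @param y numeric outcome vector.
#' @param X numeric predictor matrix or data frame (no intercept column;
#'   one is added).
#' @return an object of class `meditod_ols`: the coefficient table plus
#'   `n_obs`, `r_squared` and the underlying `lm` fit.
#' @export
fit_ols <- function(y, X) {
  X <- as.data.frame(X)
  if (anyNA(y) || anyNA(X)) {
    keep <- complete.cases(y, X)
    y <- y[keep]
    X <- X[keep, , drop = FALSE]
  }
  if (nrow(X) <= ncol(X) + 1L)
    stopf("need more observations (%d) than predictors plus intercept (%d)",
          nrow(X), ncol(X) + 1L)
  const <- vapply(X, function(v) sd(v) == 0, logical(1))
  if (any(const))
    stopf("constant predictor column(s): %s",
          paste(names(X)[const], collapse = ", "))
  dat <- cbind(.y = y, X)
  fit <- lm(.y ~ ., data = dat)
  cf <- coef(fit)
  if (anyNA(cf))
    stopf("rank-deficient design; collinear column(s): %s",
          paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)
  tab <- sm$coefficients
  preds <- names(X)
  sdx <- vapply(X, sd, numeric(1))
  sdy <- sd(y)
  coef_table <- data.frame(
    predictor = c("(Intercept)", preds),
    B = tab[, "Estimate"],
    SE = tab[, "Std. Error"],
    beta = c(NA_real_, tab[preds, "Estimate"] * sdx / sdy),
    p = tab[, "Pr(>|t|)"],
    row.names = NULL)
  structure(list(coefficients = coef_table, n_obs = nrow(X),
                 r_squared = sm$r.squared, sigma = sm$sigma, lm = fit),
            class = "meditod_ols")
}

#' @export
print.meditod_ols <- function(x, digits = 4, ...) {
  cat(sprintf("Linear regression: n = %d, R^2 = %.3f\n", x$n_obs, x$r_squared))
  tab <- x$coefficients
  tab$B <- signif(tab$B, digits)
  tab$SE <- signif(tab$SE, digits)
  tab$beta <- signif(tab$beta, digits)
  tab$p <- format.pval(tab$p, digits = 3, eps = 1e-3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.meditod_ols <- function(object, ...) {
  setNames(object$coefficients$B, object$coefficients$predictor)
}

#' @export
summary.meditod_ols <- function(object, ...) object

#' 95% confidence intervals for the raw coefficients
#' @param object a `meditod_ols` fit.
#' @param parm,level,... as in [stats::confint()].
#' @export
confint.meditod_ols <- function(object, parm, level = 0.95, ...) {
  stats::confint(object$lm, level = level, ...)
}

#' Per-window regression of a maintenance outcome on usage features
#'
#' One multiple linear regression per time-of-day window: the outcome (M67
#' or LS) on the session count over the feature window, the timing entropy
#' `H`, and the window's time-of-day proportion `T`. `T` enters as a raw
#' proportion in \[0, 1\], so its coefficient is the full contrast between
#' never (`T = 0`) and always (`T = 1`) meditating in that window. For the
#' LS outcome the account-creation day of year is added to correct the
#' unequal observation horizon. The four window proportions sum to 1, which
#' is why each window gets its own model: entering all four at once is
#' rank-deficient (and [fit_ols()] refuses to do it silently). Users with
#' `NA` features (no session in the feature window) are excluded listwise.
#'
#' @param features a [user_features()] table.
#' @param outcome `"m67"` or `"ls"`.
#' @param tod one of the four window labels.
#' @param include_acd include the account-creation covariate? Defaults to
#'   `TRUE` exactly when `outcome = "ls"`.
#' @return a [fit_ols()] object with attributes `outcome` and `tod`.
#' @export
tod_regression <- function(features, outcome = c("m67", "ls"),
                           tod = TOD_LEVELS,
                           include_acd = identical(outcome, "ls")) {
  outcome <- match.arg(outcome)
  tod <- match.arg(tod)
  tcol <- paste0("p_", tod)
  keep <- complete.cases(features[c("n_sessions", "entropy", tcol, outcome)])
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message(sprintf("excluding %d user(s) without features from the %s/%s regression",
                    n_dropped, outcome, tod))
  dat <- features[keep, , drop = FALSE]
  if (sd(dat[[tcol]]) == 0)
    stopf("degenerate time-of-day proportion for window %s (no variation)", tod)
  X <- data.frame(n_sessions = dat$n_sessions, entropy = dat$entropy,
                  tod_prop = dat[[tcol]])
  if (include_acd) X$acd <- dat$acd
  fit <- fit_ols(dat[[outcome]], X)
  attr(fit, "outcome") <- outcome
  attr(fit, "tod") <- tod
  attr(fit, "n_dropped") <- n_dropped
  fit
}

#' All eight per-window outcome regressions
#'
#' Runs [tod_regression()] for both outcomes and all four windows and
#' stacks the coefficient tables into one long data frame (the shape of a
#' published multiple-regression summary table).
#'
#' @param features a [user_features()] table.
#' @return data frame with columns `outcome`, `tod`, `predictor`, `B`,
#'   `SE`, `beta`, `p`, `n_obs`.
#' @export
tod_regressions <- function(features) {
  rows <- list()
  for (outcome in c("m67", "ls")) {
    for (tod in TOD_LEVELS) {
      fit <- tod_regression(features, outcome = outcome, tod = tod)
      tab <- fit$coefficients
      tab <- tab[tab$predictor != "(Intercept)", , drop = FALSE]
      tab <- cbind(outcome = outcome, tod = tod, tab, n_obs = fit$n_obs)
      rows[[paste(outcome, tod)]] <- tab
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
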