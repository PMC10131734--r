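#' Cubic regression spline basis over enrollment days
#'
#' Builds the spline basis and curvature penalty for the daily-probability
#' smooth: by default a cyclic cubic regression spline with `n_knots`
#' evenly spaced knots over `[1, n_days]`, whose value and first two
#' derivatives match at the wrapped endpoints; with `cyclic = FALSE`, an
#' ordinary cubic regression spline on the same knots. Both come with the
#' integrated-squared-second-derivative penalty matrix. The raw basis
#' contains the constant function in its span with zero penalty; the
#' constrained variant (used inside [fit_gamm()] next to an explicit
#' intercept) is centred to sum to zero over the observed days.
#'
#' @param n_days number of days in the domain (default 180).
#' @param n_knots number of knots (>= 4; default 8).
#' @param cyclic wrap the smooth so day `n_days` rejoins day 1?
#' @return an object of class `meditod_basis` holding the raw and
#'   constrained design matrices (`raw$X`, `con$X`), penalties (`raw$S`,
#'   `con$S`) and knot locations.
#' @export
cyclic_cubic_basis <- function(n_days = 180L, n_knots = 8L, cyclic = TRUE) {
  if (n_knots < 4L) stopf("n_knots must be at least 4")
  dd <- data.frame(d = as.numeric(seq_len(n_days)))
  spec <- mgcv::s(d, bs = if (cyclic) "cc" else "cr", k = n_knots)
  sm_raw <- mgcv::smoothCon(spec, data = dd, absorb.cons = FALSE)[[1L]]
  sm_con <- mgcv::smoothCon(spec, data = dd, absorb.cons = TRUE)[[1L]]
  knots <- if (cyclic) sm_raw$xp else sm_raw$xp %||% attr(sm_raw, "knots")
  structure(list(n_days = as.integer(n_days), n_knots = as.integer(n_knots),
                 cyclic = cyclic, knots = as.numeric(knots),
                 raw = list(X = sm_raw$X, S = sm_raw$S[[1L]], sm = sm_raw),
                 con = list(X = sm_con$X, S = sm_con$S[[1L]], sm = sm_con)),
            class = "meditod_basis")
}

#' Evaluate a spline basis at arbitrary days
#'
#' For a cyclic basis, days are wrapped modulo the knot range first, so
#' `basis_matrix(b, 1)` and `basis_matrix(b, n_days)` agree for a wrap at
#' `[1, n_days]`.
#'
#' @param basis a [cyclic_cubic_basis()].
#' @param days numeric vector of evaluation points.
#' @param constrained use the centred (sum-to-zero) parameterisation?
#' @return design matrix with one row per day.
#' @export
basis_matrix <- function(basis, days, constrained = FALSE) {
  days <- as.numeric(days)
  if (basis$cyclic) {
    k0 <- min(basis$knots)
    k1 <- max(basis$knots)
    days <- ((days - k0) %% (k1 - k0)) + k0
  }
  sm <- if (constrained) basis$con$sm else basis$raw$sm
  mgcv::PredictMat(sm, data.frame(d = days))
}

#' @export
print.meditod_basis <- function(x, ...) {
  cat(sprintf("%s cubic regression spline basis: %d knots over [1, %d]\n",
              if (x$cyclic) "Cyclic" else "Natural", x$n_knots, x$n_days))
  invisible(x)
}
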