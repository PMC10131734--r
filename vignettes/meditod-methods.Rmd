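---
title: "Methods: timing features, daily-probability models and trajectory profiles"
author: "meditod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: timing features, daily-probability models and trajectory profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meditod)
```

## The problem

Common habit-formation advice says to meditate at the same time every
day, preferably in the morning. With timestamped app logs this is
testable: does a user's time-of-day (TOD) preference, and the
*consistency* of their timing, predict whether they keep using the app?
`meditod` packages the three analyses that answer it — daily-probability
curves over the first 180 days, per-window outcome regressions, and
clustering of 25-week TOD trajectories — together with the filtering
rules that define the sample, and a synthetic generator that stands in
for proprietary log data.

## Data model and filters

An event log has one row per app session: `user_id`,
`account_created`, `start` (minute precision, one local clock — no
timezone or DST handling, which logs of this kind do not carry),
`session_type` (nine app features), `completed`, `duration_min`.

* **Eligibility**: a user enters the sample with at least 8 uses of any
  type and completion status in their first 60 days (`eligible_users()`).
  "First two months" is read as days 1–60 inclusive, consistent with the
  d = 1 origin (the account-creation day is enrollment day 1).
* **Qualifying meditation sessions**: type `Meditation`, tagged
  completed, duration in [3, 60] minutes, both ends inclusive
  (`meditation_sessions()`). The 180-day cap is applied only where the
  analysis calls for it: features and daily-probability panels use days
  1–180, while the outcomes M67 and LS are computed on the full history.
* Duplicate rows are kept; the analysis never deduplicates.

## Timing features

The four windows — morning [04:00, 10:00), midday [10:00, 16:00),
evening [16:00, 22:00), late night [22:00, 04:00) — partition the clock;
half-open intervals make the partition exact at any sub-minute
precision. TOD preference is the per-window proportion of a user's
qualifying sessions; temporal consistency is its Shannon entropy in
nats, `H = -sum(p * log(p))` with `0 log 0 = 0`. The natural logarithm
is fixed by the statistic's stated maximum ln 4 = 1.386 at the uniform
distribution (a base-2 version would peak at 2). Useful properties,
all tested: H is permutation-invariant, bounded in [0, ln 4], zero
exactly when one window carries all mass, and never increased by
merging windows.

M67 counts qualifying sessions on days 151–210: "months six and seven"
under 30-day months, chosen because 6 × 30 matches the analysis's
"first 180 days"; a calendar-month alternative is available via
`outcome_m67(convention = "calendar")`. LS is the enrollment day of the
last observed session, uncensored — users still active at the end of
the log simply get the last day observed. The feature window defaults
to 180 days, with 60 supported through
`run_config(feature_window_days = 60)`: descriptions of this covariate
vary between "first 60" and "first 180" days in the source analyses,
so both are provided and the default is declared, not inferred.

## The daily-probability model

For the panel of binary indicators y(u, d) — user u had at least one
qualifying session on day d, overall or within one window — the model is
a logistic additive model with a per-user random intercept:

logit P(y = 1 | u, d) = f(d) + b_u.

* **Smooth**: f is a cubic regression spline on 8 evenly spaced knots
  over [1, 180] with an integrated-squared-curvature penalty, built by
  `mgcv::smoothCon` and centred to sum to zero over the observed days,
  next to an explicit intercept. The cyclic variant (`cyclic = TRUE`,
  the default of `fit_gamm()`) wraps value and first two derivatives at
  the domain ends.
* **Random intercepts as ridge**: the b_u enter as a quadratic penalty
  `theta * sum(b_u^2)`, the classical mixed-model-as-penalty identity.
  The precision `theta = 1/sigma^2_b` is updated by a fixed-point step
  `sigma^2_b = sum(b_u^2) / sum(t_u)` with t_u the intercepts'
  effective degrees of freedom, iterated to convergence. This keeps the
  fit deterministic, dependency-free and fast at desk scale.
* **Fitting**: penalized IRLS. Each working least-squares problem is
  solved by block elimination — the intercept block is diagonal, so the
  smooth coefficients come from a small Schur-complement system and the
  b_u back-substitute; cost is linear in the panel size. Step-halving
  guarantees the penalized deviance never increases; convergence is a
  relative change below 1e-8, at most 200 iterations (non-convergence
  is an error carrying the deviance trajectory). Complete separation is
  bounded by the ridge and flagged with a warning.
* **Smoothing selection**: the curvature penalty is scaled by the
  number of observations (objective = deviance + n λ c'Sc), so a fixed
  λ means the same smoothness per observation at any cohort size — and
  duplicating every user provably leaves the curve unchanged. When λ is
  not fixed, it is chosen by approximate GCV,
  n·deviance/(n − edf)², over a log-spaced grid 10⁻⁶…10², with warm
  starts across the grid.

The population curve is p̂(d) = plogis(f(d)) at b = 0 — a
typical-user (conditional) probability, not the marginal pooled
frequency; with real heterogeneity the two differ by Jensen's
inequality, which is why the intercept-only-limit test uses a
homogeneous panel.

**Cyclic versus natural smooth.** A cyclic basis whose wrap spans
[1, 180] forces f(1) = f(180): the fitted curve must return to its
day-1 level, and the day-1 → day-180 percent change,
100·(p̂(180) − p̂(1))/p̂(1), is pinned to ~0. That is appropriate for
genuinely periodic signals but contradicts a monotone engagement decay,
where the percent change is the quantity of interest. `fit_gamm()`
keeps the cyclic basis as its default; the pipeline's decay summaries
(`run_config()`) default to the natural cubic spline for exactly this
reason, and either can be selected everywhere.

Decay summaries are produced for the full cohort and for the bottom and
top quartiles of each outcome; quartiles use the linear-interpolation
quantile (type 7) with boundary ties included.

## Outcome regressions

Per window, OLS of the outcome on (n_sessions, H, T_window), plus ACD
for LS. T enters as a raw proportion in [0, 1], so its coefficient is
the full never-to-always contrast; a 0.1 increase in T moves the
prediction by 0.1·B. Standardized coefficients are β = B·sd(x)/sd(y);
p-values are two-sided t-tests on n − p − 1 degrees of freedom, with no
multiplicity correction (none is part of the analysis). The four window
proportions are linearly dependent (they sum to 1), so entering them
jointly is rank-deficient; `fit_ols()` detects this and errors naming
the collinear columns rather than silently dropping one. Users with no
session in the feature window have undefined features and are excluded
listwise, with a logged count. Heteroscedasticity-robust errors are
deliberately not the default (nothing in the analysis calls for them).

## Trajectory profiles

Weeks w = 1…25 cover days 7(w−1)+1…7w (d ≤ 175). The weekly value for
a window is the number of distinct days that week with a qualifying
session starting in the window, divided by 7 — a probability by
construction, defined even for empty weeks. (The alternative,
sessions-in-window over sessions-that-week, is undefined for empty
weeks and was rejected.) Users with all-zero trajectories still
participate; they simply land in the low cluster.

Clustering is Lloyd's algorithm with k-means++ initialization, best of
`restarts` runs by SSE, empty clusters repaired by reseeding from the
farthest point, fully determined by an integer seed. k is fixed at 4;
`elbow_sse()` remains as a diagnostic (it warm-starts each k from the
previous solution plus the farthest point, making the SSE sequence
nonincreasing by construction). Because raw k-means labels are
arbitrary, `canonical_labels()` fixes their meaning deterministically:
the two centroids highest in weeks 1–5 are labels 1–2 (1 = the one
still high in weeks 21–25), and of the rest the higher overall mean is
3, the lower 4; exact ties fall back to lexicographic centroid order.
This formalises the qualitative cluster matching across windows; for
borderline centroids, a different but defensible matching could result.

Profiles `m-d-e-l` combine one canonical label per window (256
possibilities). `top_profiles()` ranks profiles with at least
`min_members` users by mean outcome (ties: larger membership, then
lexicographic id); `cluster_proportions()` sums member counts by window
position and reports integer-rounded percentages. Fed with the bundled
published top-ten rankings (`published_top_profiles()`), it reproduces
the published aggregation cell for cell — that check is in the test
suite. Note the `min_members = 50` floor presumes a cohort of
thousands; at a few hundred simulated users essentially no profile
reaches 50 and the floor should be lowered.

## The synthetic generator

`simulate_events()` emulates the statistical structure the analysis
assumes, with ground truth returned alongside:

* accounts opened uniformly over a configured calendar year;
* a pooled daily meditation probability following a two-parameter
  logistic-in-time decay from `p_day1` at d = 1 to
  `p_day1 (1 − decay_target)` at d = 180 — the published engagement
  curves are nonparametric, and this is the simplest monotone shape
  sufficient for recovery tests — continued past day 180 by a slow
  exponential taper;
* per-window *archetypes* (sustained-high, high-decaying, moderate,
  low — stylised cluster prototypes) drawn from a configurable mix.
  Archetypes drive *where* sessions land: window choice follows the
  archetype curves' time-varying weights, and a static per-user
  intensity (normalised to mean 1 under the mix) scales overall
  engagement. Keeping the intensity static leaves the pooled decay
  equal to `decay_target` by construction, so pipeline recovery has a
  closed-form target; the cost is that a user's *overall* rate never
  decays faster than the pooled curve, only their window allocation
  does;
* geometric churn from day 181 (`churn_rate`, default 0.004/day):
  permanent abandonment, giving the day-of-last-session outcome a
  realistic spread without distorting the modelled 180-day window;
* uniform within-window start times (no published within-day
  distribution exists to copy), truncated-lognormal durations (median
  11 min), Bernoulli completion flags, at most 3 meditation sessions
  per day, and a Poisson stream of non-meditation sessions that feeds
  the eligibility count.

Calibration was fixed once from the published anchors: `p_day1 = 0.55`
(just over 50% on day 1), `decay_target = 0.66` (the pooled −66.5%
change), archetype mix (0.10, 0.20, 0.35, 0.35) echoing the reported
dominance of low-engagement trajectories, horizon 730 days. Seeding is
a master seed with deterministic per-user substreams, so enlarging the
cohort never reshuffles existing users, and a fixed seed reproduces the
log byte for byte. A separate *regression-recovery mode*
(`simulate_regression()`) draws features directly and builds the
outcome from known coefficients, for coverage checks of the OLS stage.

What the generator does **not** emulate: notification effects, weekday
and seasonal cycles, within-user autocorrelation beyond the daily
Bernoulli draws, correlated archetypes across windows, or any
morning-specific *causal* advantage in outcomes. Passing recovery tests
therefore demonstrates that the pipeline measures what it claims on
data with the assumed structure — not that the substantive conclusions
would replicate on real logs.

## Numerical choices and degenerate inputs

* IRLS weights floored at 1e-6; fitted probabilities clamped away from
  0/1 in deviance evaluation; intercept variance bounded in
  [1e-8, 100].
* Percent change is an error when p̂(1) = 0 (cannot happen through the
  logistic link).
* Zero-session users: features undefined (NA), excluded listwise and
  counted; LS/M67 are computed only for users with at least one
  qualifying session; panels still include all requested users as
  all-zero rows.
* Empty top-profile lists (possible at small cohorts with the default
  membership floor) aggregate to an empty proportion table rather than
  an error.
* Exact k-means ties and centroid-summary ties are broken
  lexicographically and logged.

## Problem sizes

The bundled checks run at sizes chosen to make Monte-Carlo bounds
sharp but desk-friendly: calibration checks at 120–500 users, the
flat-limit recovery at 500 users × 180 days, coefficient-recovery
coverage over 100 replicates of 2,000 users, clustering recovery at
120–200 trajectories, and end-to-end pipeline runs at 60–300 users.
The implementation itself scales linearly in panel rows and has been
run at tens of thousands of sessions per fit.

## Known limitations

* The random-intercept update is a PQL-style fixed point, adequate for
  curve estimation but not for inference on the variance component; no
  confidence bands are produced for the smooth.
* LS ignores censoring at the data pull; survival-style alternatives
  are out of scope.
* The canonical relabelling may not replicate borderline qualitative
  cluster matchings.
* The eligibility rule, window boundaries and month conventions are
  fixed to the analysed design; other designs need new constants, not
  new code paths.
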