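# meditod

Does *when* people meditate predict whether they *keep* meditating?
`meditod` is an R package for analysing timestamped meditation-app event
logs to answer that question. It implements, as reusable and tested
components, the full analysis pipeline behind a time-of-day (TOD) habit
study: session filtering, per-user timing features, daily-probability
curves, outcome regressions, and trajectory-profile clustering — plus a
seeded synthetic event-log generator, so the whole pipeline can be
exercised and validated without access to proprietary app data.

It is aimed at behavioural and mHealth researchers working with app
engagement logs (one row per session: user, timestamp, session type,
completed flag, duration).

## The measures and models

**Time-of-day windows.** The clock is split into four half-open windows:
morning [04:00, 10:00), midday [10:00, 16:00), evening [16:00, 22:00) and
late night [22:00, 04:00). A user's *TOD preference* is the proportion
vector *P* = (x_morning, x_midday, x_evening, x_late_night) of their
completed 3–60-minute meditation sessions starting in each window.

**Temporal consistency** is the Shannon entropy of that distribution, in
nats:

    H = − Σᵢ P(xᵢ) · ln P(xᵢ),   with 0 · ln 0 := 0

H = 0 means all sessions fall in one window (perfect consistency);
H = ln 4 ≈ 1.386 means no preference at all.

**Outcomes.** Short-term maintenance M67 is the number of qualifying
sessions in months six and seven of the account (days 151–210); long-term
maintenance LS is the enrollment day of the last observed session. The
account-creation day of year (ACD, 1–365) corrects LS for unequal
observation horizons.

**Daily probability model.** The probability of meditating on enrollment
day *d* = 1…180 is fitted by a penalized logistic additive model with a
per-user random intercept,

    logit P(yᵤd = 1) = f(d) + bᵤ,

where *f* is an 8-knot cubic regression spline (cyclic or natural) with a
curvature penalty, and the bᵤ enter as a ridge penalty (the standard
mixed-model-as-penalty identity), all solved by penalized IRLS with GCV
smoothing selection. The decay summary is the percent change
100·(p̂(180) − p̂(1))/p̂(1), overall, per window, and within outcome
quartiles.

**Outcome regressions.** Per window *w*, OLS of each outcome on the
session count *n*, entropy *H*, and the window proportion T_w (plus ACD
for LS), with standardized coefficients β = B·sd(x)/sd(y). The four T_w
sum to one, which is exactly why each window gets its own model — the
joint design is rank-deficient, and the package refuses to fit it
silently.

**Trajectory profiles.** Each user's first 25 weeks are converted to four
weekly probability trajectories (active days in window / 7), clustered
per window by k-means (k = 4, k-means++ initialization, seeded), labels
canonicalised by shape (1 sustained-high, 2 high-then-decaying,
3 moderate, 4 low), and combined into an `m-d-e-l` profile — one of
4⁴ = 256. Profiles are ranked by mean outcome, and the top profiles'
member counts are aggregated into weighted per-window cluster
proportions.

## Worked example

```r
library(meditod)
sim <- simulate_events(sim_config(n_users = 300, seed = 42))
run <- run_pipeline(sim$events, run_config(gamm_subsets = "all", min_members = 5))
print(run)
```

    Meditation-app engagement analysis run
      input rows: 67474   eligible users: 300   qualifying sessions: 31907
      cohort: 300 users   tables: summary, gamm_change, regressions, cluster_sizes, top_profiles, cluster_proportions

The event log holds 67,474 sessions of nine types; 300 users meet the
eligibility rule (≥ 8 app uses in the first 60 days), and 31,907 sessions
survive the meditation filters (type Meditation, completed, 3–60 min).

```r
subset(run$tables$gamm_change, subset == "all")
```

         window subset n_users     p1   p180 pct_change
            any    all     300 0.4791 0.1421      -70.3
        morning    all     300 0.1215 0.0338      -72.2
         midday    all     300 0.0941 0.0357      -62.1
        evening    all     300 0.1051 0.0354      -66.3
     late_night    all     300 0.1108 0.0269      -75.7

Users start with a ~0.48 daily probability of meditating, decaying by
~70% over 180 days (the generator's configured decay is 66%; per-window
curves are noisier at this cohort size).

```r
head(subset(run$tables$regressions, outcome == "m67" & tod == "morning"), 3)
```

     outcome     tod  predictor     B      SE    beta        p n_obs
         m67 morning n_sessions 0.170 0.00876 0.79506 7.04e-55   300
         m67 morning    entropy 0.316 1.29249 0.00991 8.07e-01   300
         m67 morning   tod_prop 2.934 1.20912 0.08822 1.59e-02   300

Each extra session in the first 180 days predicts ~0.17 more sessions in
months 6–7; a shift from never to always meditating in the morning
(T: 0 → 1) predicts ~2.9 more.

```r
run$tables$cluster_sizes
```

         window cluster_1 cluster_2 cluster_3 cluster_4
        morning        42        62        92       104
         midday        43        60        78       119
        evening        22        53       102       123
     late_night        37        82        56       125

The published per-window cluster aggregation is reproducible directly
from the printed profile rankings bundled with the package:

```r
cluster_proportions(published_top_profiles("ls"))
```

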