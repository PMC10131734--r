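#' Pipeline configuration
#'
#' All tunable settings of [run_pipeline()] in one validated list. Every
#' default is the setting the analysis is defined with; the exceptions a
#' user may want are the feature window (180 vs 60 days) and the spline
#' wrap (the Table-2-shaped decay summaries default to the non-cyclic
#' smooth, since a cyclic wrap on the enrollment axis pins the day-180
#' probability to the day-1 level).
#'
#' @param year study year of account creation.
#' @param min_uses,eligibility_window_days early-engagement eligibility:
#'   at least `min_uses` app uses within the first
#'   `eligibility_window_days` days.
#' @param feature_window_days window for the timing features and session
#'   count: 180 (default) or 60.
#' @param m67_convention month convention for the short-term outcome.
#' @param n_days days modelled by the daily-probability fits.
#' @param n_knots,cyclic,lambda spline settings for [fit_gamm()].
#' @param gamm_windows,gamm_subsets which window/subset fits to run.
#' @param weeks,k,restarts,min_members,top_k trajectory-clustering
#'   settings.
#' @param seed integer seed for the clustering stage.
#' @return an object of class `run_config`.
#' @export
run_config <- function(year = 2017L,
                       min_uses = 8L, eligibility_window_days = 60L,
                       feature_window_days = 180L,
                       m67_convention = "fixed30",
                       n_days = 180L, n_knots = 8L, cyclic = FALSE,
                       lambda = NULL,
                       gamm_windows = c("any", TOD_LEVELS),
                       gamm_subsets = c("all", "m67_bottom", "m67_top",
                                        "ls_bottom", "ls_top"),
                       weeks = 25L, k = 4L, restarts = 8L,
                       min_members = 50L, top_k = 10L, seed = 17L) {
  if (!feature_window_days %in% c(60L, 180L))
    stopf("feature_window_days must be 60 or 180")
  gamm_windows <- match.arg(gamm_windows, c("any", TOD_LEVELS),
                            several.ok = TRUE)
  gamm_subsets <- match.arg(gamm_subsets,
                            c("all", "m67_bottom", "m67_top",
                              "ls_bottom", "ls_top"), several.ok = TRUE)
  structure(list(year = as.integer(year), min_uses = as.integer(min_uses),
                 eligibility_window_days = as.integer(eligibility_window_days),
                 feature_window_days = as.integer(feature_window_days),
                 m67_convention = m67_convention,
                 n_days = as.integer(n_days), n_knots = as.integer(n_knots),
                 cyclic = cyclic, lambda = lambda,
                 gamm_windows = gamm_windows, gamm_subsets = gamm_subsets,
                 weeks = as.integer(weeks), k = as.integer(k),
                 restarts = as.integer(restarts),
                 min_members = as.integer(min_members),
                 top_k = as.integer(top_k), seed = as.integer(seed)),
            class = "run_config")
}

#' Summary statistics for the per-user measures
#'
#' Mean and standard deviation (n - 1 denominator) of the four time-of-day
#' proportions, the timing entropy, and the two outcomes, over users with
#' defined values.
#'
#' @param features a [user_features()] table.
#' @return data frame with columns `measure`, `mean`, `sd`.
#' @export
summary_stats <- function(features) {
  if (!nrow(features)) stopf("empty features table")
  cols <- c("p_morning", "p_midday", "p_evening", "p_late_night",
            "entropy", "m67", "ls")
  data.frame(measure = cols,
             mean = vapply(cols, function(c) mean(features[[c]], na.rm = TRUE),
                           numeric(1)),
             sd = vapply(cols, function(c) sd(features[[c]], na.rm = TRUE),
                         numeric(1)),
             row.names = NULL)
}

subset_users <- function(features, subset) {
  switch(subset,
         all = features$user_id,
         m67_bottom = quartile_subset(features, "m67", "bottom"),
         m67_top = quartile_subset(features, "m67", "top"),
         ls_bottom = quartile_subset(features, "ls", "bottom"),
         ls_top = quartile_subset(features, "ls", "top"))
}

#' Run the full engagement analysis pipeline
#'
#' Orchestrates ingest, features, the daily-probability fits, the
#' per-window outcome regressions and the trajectory-clustering stage on
#' one event log, returning every table-shaped output plus a manifest that
#' fully determines the run (configuration, seed and the row-count funnel
#' at each filter stage). Deterministic: the same log and configuration
#' always give identical output.
#'
#' @param events an event log (data frame) or a path to an event-log CSV.
#' @param config a [run_config()].
#' @return an object of class `meditod_run`: a list with `features`,
#'   `tables` (`summary`, `gamm_change`, `regressions`, `cluster_sizes`,
#'   `top_profiles`, `cluster_proportions`), `curves`, `profiles` and
#'   `manifest`.
#' @export
run_pipeline <- function(events, config = run_config()) {
  if (is.character(events)) events <- read_event_log(events)
  stage <- "ingest"
  res <- tryCatch({
    log <- validate_event_log(events)
    n_input <- nrow(log)
    elig <- eligible_users(log, config$min_uses,
                           config$eligibility_window_days)
    if (length(elig) == 0L) stopf("no eligible users")
    log <- log[log$user_id %in% elig, , drop = FALSE]
    sessions_all <- meditation_sessions(log, max_day = NULL)
    sessions_feat <- meditation_sessions(log,
                                         max_day = config$feature_window_days)
    sessions_180 <- meditation_sessions(log, max_day = config$n_days)

    stage <- "features"
    features <- suppressMessages(
      user_features(sessions_feat, sessions_all, year = config$year,
                    m67_convention = config$m67_convention))

    stage <- "gamm"
    cohort <- features$user_id
    curves <- list()
    change <- list()
    for (subset in config$gamm_subsets) {
      users <- subset_users(features, subset)
      for (window in config$gamm_windows) {
        panel <- build_daily_panel(sessions_180, window = window,
                                   users = users, n_days = config$n_days)
        fit <- fit_gamm(panel, n_knots = config$n_knots,
                        cyclic = config$cyclic, lambda = config$lambda)
        key <- paste(window, subset, sep = ".")
        curves[[key]] <- data.frame(window = window, subset = subset,
                                    d = seq_len(config$n_days),
                                    p_hat = fit$curve)
        change[[key]] <- data.frame(window = window, subset = subset,
                                    n_users = length(users),
                                    p1 = fit$curve[1L],
                                    p180 = fit$curve[config$n_days],
                                    pct_change = percent_change(fit))
      }
    }

    stage <- "regression"
    regressions <- suppressMessages(tod_regressions(features))

    stage <- "trajectories"
    traj <- weekly_tod_matrix(sessions_all, users = cohort,
                              weeks = config$weeks)
    assignments <- list()
    sizes <- list()
    for (w in seq_along(TOD_LEVELS)) {
      km <- kmeans_trajectories(traj[, , w], k = config$k,
                                seed = config$seed + w,
                                restarts = config$restarts)
      map <- canonical_labels(km)
      lab <- map[km$cluster]
      assignments[[TOD_LEVELS[w]]] <- lab
      sizes[[w]] <- data.frame(window = TOD_LEVELS[w],
                               t(tabulate(lab, config$k)))
    }
    cluster_sizes <- do.call(rbind, sizes)
    names(cluster_sizes)[-1L] <- paste0("cluster_", seq_len(config$k))
    profiles <- build_profiles(assignments, user_id = cohort)
    tops <- list()
    props <- list()
    for (outcome in c("m67", "ls")) {
      top <- top_profiles(profiles, features, outcome_col = outcome,
                          min_members = config$min_members,
                          top_k = config$top_k)
      cp <- cluster_proportions(top)
      tops[[outcome]] <- cbind(outcome = rep(outcome, nrow(top)), top)
      props[[outcome]] <- cbind(outcome = rep(outcome, nrow(cp)), cp)
    }

    manifest <- list(
      config = config[setdiff(names(config), NULL)],
      funnel = list(n_rows_input = n_input,
                    n_users_input = length(unique(events$user_id)),
                    n_eligible_users = length(elig),
                    n_rows_eligible = nrow(log),
                    n_meditation_sessions = nrow(sessions_all),
                    n_feature_window_sessions = nrow(sessions_feat),
                    n_cohort_users = length(cohort),
                    n_dropped_featureless = attr(features, "n_dropped")))

    structure(list(features = features,
                   tables = list(summary = summary_stats(features),
                                 gamm_change = do.call(rbind, change),
                                 regressions = regressions,
                                 cluster_sizes = cluster_sizes,
                                 top_profiles = do.call(rbind, tops),
                                 cluster_proportions = do.call(rbind, props)),
                   curves = do.call(rbind, curves),
                   profiles = profiles,
                   manifest = manifest),
              class = "meditod_run")
  }, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  for (tb in res$tables) rownames(tb) <- NULL
  res
}

#' @export
print.meditod_run <- function(x, ...) {
  f <- x$manifest$funnel
  cat("Meditation-app engagement analysis run\n")
  cat(sprintf("  input rows: %d   eligible users: %d   qualifying sessions: %d\n",
              f$n_rows_input, f$n_eligible_users, f$n_meditation_sessions))
  cat(sprintf("  cohort: %d users   tables: %s\n", f$n_cohort_users,
              paste(names(x$tables), collapse = ", ")))
  invisible(x)
}

#' Write a pipeline run to disk
#'
#' Writes every table, the per-day probability curves and the JSON
#' manifest under `dir`.
#'
#' @param run a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(run$tables))
    write.csv(run$tables[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  write.csv(run$curves, file.path(dir, "curves.csv"), row.names = FALSE)
  write.csv(run$features, file.path(dir, "features.csv"), row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
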