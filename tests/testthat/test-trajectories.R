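test_that("weekly trajectories are active-day proportions per window", {
  log <- evt("a", "2017-01-01", "2017-01-01 07:00:00")
  s <- meditation_sessions(log)
  m <- weekly_tod_matrix(s, users = "a")
  expect_equal(dim(m), c(1L, 25L, 4L))
  expect_equal(m[1, 1, "morning"], 1 / 7)
  expect_equal(sum(m), 1 / 7)
  # meditating at 07:00 every day fills the whole morning column
  daily <- do.call(make_log, lapply(1:175, function(i)
    evt("b", "2017-01-01",
        format(as.POSIXct("2017-01-01 07:00:00", tz = "UTC") + (i - 1) * 86400,
               "%Y-%m-%d %H:%M:%S"))))
  m2 <- weekly_tod_matrix(meditation_sessions(daily), users = "b")
  expect_equal(unname(m2[1, , "morning"]), rep(1, 25))
  expect_equal(sum(m2[1, , c("midday", "evening", "late_night")]), 0)
})

test_that("weekly trajectories match a brute-force day-by-day tally", {
  sim <- fixture_sim()
  s <- meditation_sessions(sim$events)
  users <- sort(unique(s$user_id))[1:25]
  m <- weekly_tod_matrix(s, users = users)
  s$win <- as.character(tod_window(s$start))
  for (u in sample(users, 5)) {
    su <- s[s$user_id == u & s$d <= 175, ]
    for (w in 1:25) for (v in seq_along(c("morning", "midday", "evening", "late_night"))) {
      lab <- c("morning", "midday", "evening", "late_night")[v]
      days <- unique(su$d[su$win == lab & su$d >= 7 * (w - 1) + 1 & su$d <= 7 * w])
      expect_equal(m[u, w, lab], length(days) / 7)
    }
  }
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(abs(m * 7 - round(m * 7)) < 1e-12))
})

test_that("k = 1 reduces to the mean and SSE matches recomputation", {
  ab <- archetype_bundles()
  km1 <- kmeans_trajectories(ab$x, k = 1, seed = 2)
  expect_equal(km1$centers[1, ], colMeans(ab$x), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(km1$sse, sum(sweep(ab$x, 2, colMeans(ab$x))^2), tolerance = 1e-10)
  km <- kmeans_trajectories(ab$x, k = 4, seed = 2)
  # SSE equals the sum of squared distances to assigned centroids
  sse <- sum((ab$x - km$centers[km$cluster, ])^2)
  expect_equal(km$sse, sse, tolerance = 1e-10)
  # every point sits with its nearest centroid
  d2 <- vapply(1:4, function(j) rowSums(sweep(ab$x, 2, km$centers[j, ])^2),
               numeric(nrow(ab$x)))
  expect_equal(km$cluster, unname(max.col(-d2, ties.method = "first")))
  # determinism and input checks
  expect_identical(km$cluster, kmeans_trajectories(ab$x, 4, seed = 2)$cluster)
  expect_error(kmeans_trajectories(ab$x[c(1, 1, 1), ], k = 4), "distinct")
})

test_that("clustering is as good as an independent k-means implementation", {
  ab <- archetype_bundles()
  km <- kmeans_trajectories(ab$x, k = 4, seed = 5, restarts = 10)
  ref <- meditod:::with_seed(6,
    stats::kmeans(ab$x, centers = 4, nstart = 20, iter.max = 50))
  expect_lte(km$sse, ref$tot.withinss * (1 + 1e-8))
})

test_that("the SSE elbow is monotone and bends at the true cluster count", {
  ab <- archetype_bundles()
  es <- elbow_sse(ab$x, k_max = 6, seed = 8)
  expect_true(all(diff(es$sse) <= 1e-8))
  rel_drop <- -diff(es$sse) / es$sse[-nrow(es)]
  expect_true((which.max(rel_drop) + 1) %in% 3:5)
  # with one cluster per point the SSE vanishes
  small <- ab$x[c(1, 45, 90, 140), ]
  es0 <- elbow_sse(small, k_max = 4, seed = 9, restarts = 3)
  expect_lt(es0$sse[4], 1e-20)
})

test_that("canonical labels order centroids by shape", {
  centers <- rbind(rep(0.8, 25),
                   0.8 * exp(-0.2 * (0:24)),
                   rep(0.4, 25),
                   rep(0.05, 25))
  model <- structure(list(centers = centers, cluster = c(1L, 2L, 3L, 4L),
                          sse = 0, k = 4L), class = "meditod_kmeans")
  expect_equal(canonical_labels(model), c(1L, 2L, 3L, 4L))
  # permuting centroid order permutes the map but not the semantics
  perm <- c(3L, 1L, 4L, 2L)
  model2 <- structure(list(centers = centers[perm, ],
                           cluster = match(model$cluster, perm),
                           sse = 0, k = 4L), class = "meditod_kmeans")
  map1 <- canonical_labels(model)
  map2 <- canonical_labels(model2)
  expect_identical(map1[model$cluster], map2[model2$cluster])
  expect_error(canonical_labels(structure(list(k = 3L), class = "meditod_kmeans")),
               "k = 4")
})

test_that("canonical labels recover archetype identity across seeds", {
  ab <- archetype_bundles(n_per = 30)
  hits <- vapply(1:10, function(s) {
    km <- kmeans_trajectories(ab$x, 4, seed = 100 + s, restarts = 5)
    lab <- canonical_labels(km)[km$cluster]
    mean(lab == ab$labels)
  }, numeric(1))
  expect_gte(mean(hits >= 0.95), 0.95)
})

test_that("profiles combine one canonical label per window", {
  asg <- list(morning = c(1L, 2L), midday = c(4L, 2L),
              evening = c(4L, 2L), late_night = c(3L, 2L))
  prof <- build_profiles(asg, user_id = c("a", "b"))
  expect_equal(prof$profile, c("1-4-4-3", "2-2-2-2"))
  expect_error(build_profiles(asg[1:3]), "late_night")
  expect_error(build_profiles(list(morning = 5L, midday = 1L, evening = 1L,
                                   late_night = 1L)), "invalid cluster label")
  # the profile space has exactly 4^4 = 256 elements
  grid <- expand.grid(m = 1:4, d = 1:4, e = 1:4, l = 1:4)
  all_prof <- build_profiles(list(morning = grid$m, midday = grid$d,
                                  evening = grid$e, late_night = grid$l))
  expect_equal(length(unique(all_prof$profile)), 256L)
})

test_that("top profiles enforce the membership floor and ranking order", {
  profs <- data.frame(
    user_id = as.character(1:151),
    m = 1L, d = 1L, e = 1L,
    l = rep(c(1L, 2L, 3L), times = c(49, 50, 52)))
  profs$profile <- paste(profs$m, profs$d, profs$e, profs$l, sep = "-")
  out <- rep(c(100, 10, 20), times = c(49, 50, 52))
  expect_warning(top <- top_profiles(profs, out, min_members = 50, top_k = 10),
                 "returning all")
  # the 49-member profile has the best mean but is excluded
  expect_false("1-1-1-1" %in% top$profile)
  expect_equal(top$profile, c("1-1-1-3", "1-1-1-2"))
  # ranking matches a brute-force sort on random fixtures
  ws <- meditod:::with_seed
  rnd <- ws(50, data.frame(
    profile = sample(apply(expand.grid(1:4, 1:4), 1, paste, collapse = "-"),
                     500, TRUE),
    out = rnorm(500)))
  rnd$profile <- paste(rnd$profile, "1-1", sep = "-")
  profs2 <- data.frame(user_id = as.character(1:500),
                       profile = rnd$profile)
  top2 <- suppressWarnings(top_profiles(profs2, rnd$out, min_members = 20,
                                        top_k = 5))
  agg <- aggregate(rnd$out, list(profile = rnd$profile),
                   function(v) c(n = length(v), m = mean(v)))
  agg <- data.frame(profile = agg$profile, n = agg$x[, "n"], m = agg$x[, "m"])
  agg <- agg[agg$n >= 20, ]
  agg <- agg[order(-agg$m, -agg$n, agg$profile), ]
  expect_equal(top2$profile, head(agg$profile, 5))
  expect_equal(top2$mean_outcome, head(agg$m, 5))
})

test_that("cluster proportions aggregate member counts by window position", {
  single <- data.frame(profile = "3-3-3-3", n = 52L)
  cp <- cluster_proportions(single)
  expect_equal(cp$n[cp$cluster == 3], rep(52L, 4))
  expect_equal(cp$pct[cp$cluster == 3], rep(100L, 4))
  expect_equal(sum(cp$n), 4 * 52L)
  # totals are preserved within every window
  top <- published_top_profiles("m67")
  cp2 <- cluster_proportions(top)
  expect_equal(as.numeric(tapply(cp2$n, cp2$window, sum)),
               rep(sum(top$n), 4))
})
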