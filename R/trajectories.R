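#' Weekly time-of-day trajectories
#'
#' Stratifies each user's first `weeks * 7` enrollment days into weeks
#' (week `w` covers days `7(w-1)+1` to `7w`) and computes, per week and
#' time-of-day window, the proportion of the week's seven days with at
#' least one qualifying session starting in that window — a weekly
#' probability of meditating in the window.
#'
#' @param sessions a session table; days beyond `weeks * 7` are ignored.
#' @param users user ids to include (default: users present in
#'   `sessions`). Users with no qualifying session get all-zero
#'   trajectories — they still belong to the cohort.
#' @param weeks number of weeks (default 25, covering days 1-175).
#' @return numeric array `users x weeks x 4` (window order morning,
#'   midday, evening, late_night), entries in \[0, 1\].
#' @export
weekly_tod_matrix <- function(sessions, users = NULL, weeks = 25L) {
  users <- users %||% sort(unique(sessions$user_id))
  if (length(users) == 0L) stopf("empty user set")
  weeks <- as.integer(weeks)
  out <- array(0, dim = c(length(users), weeks, 4L),
               dimnames = list(users, paste0("w", seq_len(weeks)), TOD_LEVELS))
  sel <- sessions$d <= weeks * 7L & sessions$user_id %in% users
  s <- sessions[sel, , drop = FALSE]
  if (nrow(s)) {
    act <- unique(data.frame(u = match(s$user_id, users),
                             d = s$d,
                             w = as.integer(tod_window(s$start))))
    wk <- (act$d - 1L) %/% 7L + 1L
    cnt <- table(factor(act$u, levels = seq_along(users)),
                 factor(wk, levels = seq_len(weeks)),
                 factor(act$w, levels = 1:4))
    out[] <- as.numeric(cnt) / 7
  }
  out
}

sq_dist_to <- function(x, centers) {
  # n x k matrix of squared Euclidean distances
  d2 <- matrix(0, nrow(x), nrow(centers))
  for (j in seq_len(nrow(centers)))
    d2[, j] <- rowSums(sweep(x, 2L, centers[j, ], "-")^2)
  d2
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  if (k > 1L) for (j in 2:k) {
    d2 <- apply(sq_dist_to(x, centers[seq_len(j - 1L), , drop = FALSE]), 1L, min)
    if (sum(d2) <= 0) {
      centers[j, ] <- x[sample.int(n, 1L), ]
    } else {
      centers[j, ] <- x[sample.int(n, 1L, prob = d2), ]
    }
  }
  centers
}

lloyd <- function(x, centers, max_iter = 100L) {
  n <- nrow(x)
  k <- nrow(centers)
  assign_old <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    d2 <- sq_dist_to(x, centers)
    assign_new <- max.col(-d2, ties.method = "first")
    # repair empty clusters by reseeding from the point farthest from its centroid
    repeat {
      sizes <- tabulate(assign_new, k)
      if (all(sizes > 0L)) break
      far <- which.max(d2[cbind(seq_len(n), assign_new)])
      empty <- which(sizes == 0L)[1L]
      centers[empty, ] <- x[far, ]
      assign_new[far] <- empty
      d2 <- sq_dist_to(x, centers)
      assign_new <- max.col(-d2, ties.method = "first")
      assign_new[far] <- empty
    }
    if (identical(assign_new, assign_old)) break
    assign_old <- assign_new
    for (j in seq_len(k))
      centers[j, ] <- colMeans(x[assign_new == j, , drop = FALSE])
  }
  d2 <- sq_dist_to(x, centers)
  assign_new <- max.col(-d2, ties.method = "first")
  sse <- sum(d2[cbind(seq_len(n), assign_new)])
  list(centers = centers, cluster = assign_new, sse = sse)
}

#' k-means clustering of weekly trajectories
#'
#' Lloyd's algorithm with k-means++ initialization, keeping the best of
#' `restarts` runs by total within-cluster sum of squared error (SSE).
#' Empty clusters are repaired by reseeding from the point farthest from
#' its assigned centroid. Deterministic for a fixed seed; the caller's RNG
#' state is untouched.
#'
#' @param x numeric matrix, one trajectory per row.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param restarts independent initializations (default 10).
#' @param extra_inits optional list of center matrices to try as
#'   additional warm starts (used by [elbow_sse()]).
#' @return an object of class `meditod_kmeans`: `centers` (`k` rows),
#'   `cluster` assignments, `sse`, `k`.
#' @export
kmeans_trajectories <- function(x, k, seed = 1L, restarts = 10L,
                                extra_inits = NULL) {
  x <- as.matrix(x)
  if (nrow(unique(x)) < k)
    stopf("fewer distinct trajectories (%d) than clusters (%d)",
          nrow(unique(x)), k)
  best <- with_seed(seed, {
    best <- NULL
    inits <- c(lapply(seq_len(restarts), function(i) kmeanspp_init(x, k)),
               extra_inits)
    for (init in inits) {
      run <- lloyd(x, init)
      if (is.null(best) || run$sse < best$sse) best <- run
    }
    best
  })
  structure(list(centers = best$centers, cluster = best$cluster,
                 sse = best$sse, k = as.integer(k), seed = as.integer(seed)),
            class = "meditod_kmeans")
}

#' @export
print.meditod_kmeans <- function(x, ...) {
  cat(sprintf("k-means trajectory clustering: k = %d, n = %d, SSE = %.4f\n",
              x$k, length(x$cluster), x$sse))
  cat("  cluster sizes:", paste(tabulate(x$cluster, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' Elbow diagnostic: SSE as a function of k
#'
#' Runs the clustering protocol for `k = 1..k_max` under one seed. Each
#' `k` also warm-starts from the previous best solution plus the farthest
#' point as an extra centroid, which makes the SSE sequence nonincreasing
#' by construction.
#'
#' @param x trajectory matrix.
#' @param k_max largest number of clusters (>= 2).
#' @param seed integer seed.
#' @param restarts initializations per `k`.
#' @return data frame with columns `k` and `sse`.
#' @export
elbow_sse <- function(x, k_max, seed = 1L, restarts = 5L) {
  if (k_max < 2L) stopf("k_max must be at least 2")
  x <- as.matrix(x)
  out <- numeric(k_max)
  prev <- NULL
  for (k in seq_len(k_max)) {
    extra <- NULL
    if (!is.null(prev)) {
      d2 <- sq_dist_to(x, prev$centers)
      far <- which.max(d2[cbind(seq_len(nrow(x)), prev$cluster)])
      extra <- list(rbind(prev$centers, x[far, ]))
    }
    prev <- kmeans_trajectories(x, k, seed = seed + k, restarts = restarts,
                                extra_inits = extra)
    out[k] <- prev$sse
  }
  data.frame(k = seq_len(k_max), sse = out)
}

#' Canonical cluster labels
#'
#' Relabels the four centroids deterministically by shape so labels mean
#' the same thing in every window: the two centroids with the highest
#' early mean (weeks 1-5) are labels 1 and 2, the one with the higher late
#' mean (weeks 21-25) taking label 1 (sustained-high) and the other label
#' 2 (high-then-decaying); of the remaining two, the higher overall mean
#' is label 3 (moderate) and the lower label 4 (low). Exact ties are
#' broken by lexicographic centroid comparison, with a message.
#'
#' @param model a `meditod_kmeans` fit with `k = 4`.
#' @return integer vector of length 4: `map[i]` is the canonical label of
#'   centroid `i`.
#' @export
canonical_labels <- function(model) {
  if (model$k != 4L) stopf("canonical labels are defined for k = 4")
  cen <- model$centers
  nw <- ncol(cen)
  early <- rowMeans(cen[, seq_len(min(5L, nw)), drop = FALSE])
  late <- rowMeans(cen[, seq.int(max(1L, nw - 4L), nw), drop = FALSE])
  overall <- rowMeans(cen)
  lex <- do.call(order, as.data.frame(-cen))
  if (anyDuplicated(early) || anyDuplicated(overall))
    message("exact tie among centroid summaries; broken lexicographically")
  ord_early <- order(-early, lex)
  high <- ord_early[1:2]
  rest <- ord_early[3:4]
  lab1 <- high[order(-late[high], lex[high])][1L]
  lab2 <- setdiff(high, lab1)
  lab3 <- rest[order(-overall[rest], lex[rest])][1L]
  lab4 <- setdiff(rest, lab3)
  map <- integer(4L)
  map[c(lab1, lab2, lab3, lab4)] <- 1:4
  map
}

#' Four-component time-of-day trajectory profiles
#'
#' Combines one canonical cluster label per window into the `m-d-e-l`
#' profile string (morning-midday-evening-late night), one of the
#' `4^4 = 256` possible profiles.
#'
#' @param assignments named list with elements `morning`, `midday`,
#'   `evening`, `late_night`: canonical labels (1-4) per user, all the
#'   same length and user order, with user ids as names or accompanied by
#'   `user_id`.
#' @param user_id optional character vector of user ids.
#' @return data frame with columns `user_id`, `m`, `d`, `e`, `l`,
#'   `profile`.
#' @export
build_profiles <- function(assignments, user_id = NULL) {
  missing <- setdiff(TOD_LEVELS, names(assignments))
  if (length(missing))
    stopf("missing window assignment(s): %s", paste(missing, collapse = ", "))
  lens <- lengths(assignments[TOD_LEVELS])
  if (length(unique(lens)) != 1L)
    stopf("window assignments differ in length")
  labs <- lapply(TOD_LEVELS, function(w) {
    a <- as.integer(assignments[[w]])
    if (anyNA(a) || any(a < 1L | a > 4L))
      stopf("invalid cluster label in window %s", w)
    a
  })
  user_id <- user_id %||% names(assignments[[TOD_LEVELS[1L]]]) %||%
    as.character(seq_len(lens[[1L]]))
  out <- data.frame(user_id = user_id, m = labs[[1L]], d = labs[[2L]],
                    e = labs[[3L]], l = labs[[4L]],
                    stringsAsFactors = FALSE)
  out$profile <- paste(out$m, out$d, out$e, out$l, sep = "-")
  out
}

#' Top trajectory profiles by mean outcome
#'
#' Among profiles with at least `min_members` users, the `top_k` with the
#' highest mean outcome, in descending order; ties are broken by member
#' count (larger first) and then lexicographic profile id.
#'
#' @param profiles a [build_profiles()] data frame.
#' @param outcome numeric outcome per user, aligned with `profiles`
#'   (or a features table with a `user_id` column and the `outcome_col`).
#' @param outcome_col column name when `outcome` is a features table.
#' @param min_members minimum profile size (default 50).
#' @param top_k number of profiles to return (default 10); if fewer
#'   qualify, all are returned with a warning.
#' @return data frame with columns `profile`, `n`, `mean_outcome`.
#' @export
top_profiles <- function(profiles, outcome, outcome_col = NULL,
                         min_members = 50L, top_k = 10L) {
  if (is.data.frame(outcome)) {
    stopifnot(!is.null(outcome_col))
    outcome <- outcome[[outcome_col]][match(profiles$user_id, outcome$user_id)]
  }
  if (length(outcome) != nrow(profiles))
    stopf("outcome must align with the profile table")
  agg <- aggregate(outcome, by = list(profile = profiles$profile),
                   FUN = function(v) c(n = length(v), mean = mean(v)))
  tab <- data.frame(profile = agg$profile, n = agg$x[, "n"],
                    mean_outcome = agg$x[, "mean"], stringsAsFactors = FALSE)
  tab <- tab[tab$n >= min_members, , drop = FALSE]
  tab <- tab[order(-tab$mean_outcome, -tab$n, tab$profile), , drop = FALSE]
  if (nrow(tab) < top_k)
    warnf("only %d profile(s) have at least %d members; returning all",
          nrow(tab), min_members)
  out <- head(tab, top_k)
  rownames(out) <- NULL
  out
}

#' Weighted cluster proportions of a top-profile list
#'
#' For each window position of the profiles, sums the member counts by
#' that position's canonical cluster label and expresses them as integer
#' percentages of the total top-profile membership.
#'
#' @param top a data frame with columns `profile` and `n` (for example a
#'   [top_profiles()] result).
#' @return data frame with columns `window`, `cluster`, `n`, `pct`;
#'   within each window the counts sum to the total membership.
#' @export
cluster_proportions <- function(top) {
  stopifnot(all(c("profile", "n") %in% names(top)))
  if (nrow(top) == 0L)
    return(data.frame(window = character(0), cluster = integer(0),
                      n = integer(0), pct = integer(0),
                      stringsAsFactors = FALSE))
  digits <- do.call(rbind, strsplit(top$profile, "-", fixed = TRUE))
  if (ncol(digits) != 4L) stopf("profiles must have four components")
  digits <- matrix(as.integer(digits), ncol = 4L)
  total <- sum(top$n)
  rows <- list()
  for (w in seq_len(4L)) {
    counts <- vapply(1:4, function(cl) sum(top$n[digits[, w] == cl]), numeric(1))
    rows[[w]] <- data.frame(window = TOD_LEVELS[w], cluster = 1:4,
                            n = as.integer(counts),
                            pct = as.integer(round(100 * counts / total)),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
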