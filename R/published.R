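#' Reference top-profile rankings from a large published cohort
#'
#' The top-ten four-component trajectory profiles, with member counts and
#' mean outcome, reported by a published analysis of a large commercial
#' meditation-app cohort (about 15,000 users). These printed rankings are
#' useful as fixed inputs for the weighted cluster-proportion aggregation:
#' feeding them to [cluster_proportions()] reproduces the published
#' per-window cluster counts exactly.
#'
#' @param outcome `"m67"` (sessions in months six and seven) or `"ls"`
#'   (day of last session).
#' @return data frame with columns `profile`, `n`, `mean_outcome`.
#' @examples
#' cluster_proportions(published_top_profiles("ls"))
#' @export
published_top_profiles <- function(outcome = c("m67", "ls")) {
  outcome <- match.arg(outcome)
  if (outcome == "m67") {
    data.frame(
      profile = c("3-3-3-3", "1-4-4-3", "3-4-4-1", "3-4-3-3", "1-3-4-4",
                  "3-3-4-3", "3-3-3-4", "1-4-3-4", "4-4-1-3", "4-3-3-3"),
      n = c(52L, 53L, 68L, 81L, 250L, 58L, 191L, 87L, 220L, 103L),
      mean_outcome = c(41.3, 38.2, 33.1, 33.1, 30.2, 29.6, 29.1, 28.3,
                       27.3, 27.3),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      profile = c("1-4-4-3", "3-3-3-3", "3-4-3-3", "2-3-3-4", "4-4-3-1",
                  "3-4-3-4", "4-1-3-4", "4-3-3-3", "1-4-3-4", "4-3-1-4"),
      n = c(53L, 52L, 81L, 69L, 190L, 113L, 159L, 103L, 87L, 105L),
      mean_outcome = c(962.2, 958.6, 933.3, 909.9, 902.6, 900.3, 891.1,
                       891.0, 881.3, 875.4),
      stringsAsFactors = FALSE)
  }
}
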