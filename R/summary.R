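#' Summarize one session into the three scratch metrics
#'
#' The three per-session metrics of the monitor: scratch time (cumulative
#' bout duration in the window), number of scratch bouts, and number of
#' scratch events, plus bout counts per 5-min bin for time-course plots.
#' Bins are half-open `[k*bin_s, (k+1)*bin_s)` and a bout belongs to the bin
#' containing its onset, so the bin counts always sum to the bout count.
#'
#' @param bouts Bout table ([segment_bouts()] output or compatible).
#' @param events Event table ([group_events()] output or compatible).
#' @param window_s Analysis window in seconds (default 30 min).
#' @param bin_s Bin width in seconds; must divide `window_s`.
#' @param animal_id Optional identifier carried into the output.
#' @return A one-row `data.frame` with `animal_id`, `scratch_time_s`,
#'   `n_bouts`, `n_events`, `window_s` and `bin_1 ... bin_K` columns.
#' @export
summarize_session <- function(bouts, events, window_s = 1800, bin_s = 300,
                              animal_id = NA_character_) {
  if (window_s %% bin_s != 0) stop("bad binning: window_s not divisible by bin_s")
  n_bins <- window_s %/% bin_s
  keep <- bouts$onset_s < window_s
  bouts <- bouts[keep, , drop = FALSE]
  events <- events[events$onset_s < window_s, , drop = FALSE]

  bin_counts <- integer(n_bins)
  if (nrow(bouts) > 0L) {
    bin_idx <- floor(bouts$onset_s / bin_s) + 1L
    tab <- table(factor(bin_idx, levels = seq_len(n_bins)))
    bin_counts <- as.integer(tab)
  }
  scratch_time <- sum(pmin(bouts$offset_s, window_s) - bouts$onset_s)

  out <- data.frame(
    animal_id = animal_id,
    scratch_time_s = scratch_time,
    n_bouts = nrow(bouts),
    n_events = nrow(events),
    window_s = window_s
  )
  for (k in seq_len(n_bins)) out[[paste0("bin_", k)]] <- bin_counts[k]
  out
}

#' Pearson correlation matrix of the three scratch metrics
#'
#' Across animals, scratch time, bout count and event count are essentially
#' redundant readouts of the same behavior; this computes their 3x3 Pearson
#' correlation matrix.
#'
#' @param summaries `data.frame` with columns `scratch_time_s`, `n_bouts`,
#'   `n_events`, one row per animal (at least 3 rows, each metric with
#'   nonzero variance).
#' @return Symmetric 3x3 correlation matrix with unit diagonal.
#' @export
correlate_metrics <- function(summaries) {
  m <- as.matrix(summaries[, c("scratch_time_s", "n_bouts", "n_events")])
  if (nrow(m) < 3L) stop("need >= 3 summaries")
  if (any(apply(m, 2, stats::sd) == 0)) stop("degenerate metric: zero variance")
  stats::cor(m)
}
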