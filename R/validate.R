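#' Score detected bouts against ground truth
#'
#' One-to-one greedy matching of detected bouts to ground-truth bouts by
#' midpoint distance: candidate pairs within `match_tolerance_s` are matched
#' closest-first, each bout used at most once. Unmatched detected bouts are
#' false positives, unmatched truth bouts false negatives. The positive
#' predictive value (PPV) is TP/(TP+FP), sensitivity TP/(TP+FN).
#'
#' @param detected Bout table from [segment_bouts()].
#' @param truth Ground-truth annotation from [simulate_session()] (or a
#'   bout table from [truth_bout_table()]).
#' @param match_tolerance_s Maximal midpoint distance (s) for a match.
#' @return List with `tp`, `fp`, `fn`, `ppv`, `sensitivity`,
#'   `match_tolerance_s`.
#' @export
validate_detection <- function(detected, truth, match_tolerance_s = 0.5) {
  tb <- if (is.data.frame(truth)) truth else truth_bout_table(truth)
  det_mid <- (detected$onset_s + detected$offset_s) / 2
  tru_mid <- tb$mid_s

  n_det <- length(det_mid)
  n_tru <- length(tru_mid)
  tp <- 0L
  if (n_det > 0L && n_tru > 0L) {
    d <- abs(outer(det_mid, tru_mid, "-"))
    cand <- which(d <= match_tolerance_s, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used_det <- logical(n_det)
      used_tru <- logical(n_tru)
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_det[i] && !used_tru[j]) {
          used_det[i] <- TRUE
          used_tru[j] <- TRUE
          tp <- tp + 1L
        }
      }
    }
  }
  fp <- n_det - tp
  fn <- n_tru - tp
  list(
    tp = tp, fp = fp, fn = fn,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    match_tolerance_s = match_tolerance_s
  )
}

#' Run the seeded detector-validation suite
#'
#' Simulates a batch of full sessions (default parameters include both
#' locomotion and grooming confounders and baseline noise), runs the
#' detector on each, matches detected bouts to ground truth, and pools
#' TP/FP/FN across sessions into one PPV and sensitivity — the in-silico
#' analogue of validating the monitor against video-scored manual counts.
#'
#' @param seeds Integer vector of session seeds (one session each).
#' @param signal_args Named list of overrides passed to [signal_params()]
#'   (the seed is supplied per session).
#' @param detector A [detector_params()] object.
#' @param match_tolerance_s Matching tolerance in seconds.
#' @return List with `per_session` (data.frame: seed, tp, fp, fn, ppv),
#'   `pooled` (tp, fp, fn, ppv, sensitivity).
#' @export
run_validation_suite <- function(seeds = 1:20,
                                 signal_args = list(),
                                 detector = detector_params(),
                                 match_tolerance_s = 0.5) {
  rows <- vector("list", length(seeds))
  for (k in seq_along(seeds)) {
    sp <- do.call(signal_params, c(signal_args, list(seed = seeds[k])))
    ses <- simulate_session(sp)
    det <- detect_scratching(ses$trace, detector)
    v <- validate_detection(det$bouts, ses$truth, match_tolerance_s)
    rows[[k]] <- data.frame(seed = seeds[k], tp = v$tp, fp = v$fp,
                            fn = v$fn, ppv = v$ppv)
  }
  per_session <- do.call(rbind, rows)
  tp <- sum(per_session$tp); fp <- sum(per_session$fp); fn <- sum(per_session$fn)
  list(
    per_session = per_session,
    pooled = list(
      tp = tp, fp = fp, fn = fn,
      ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_
    )
  )
}
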