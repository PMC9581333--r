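#' Detector settings for scratch-beat extraction
#'
#' The detector discriminates scratching from other movement by its
#' oscillation frequency: beats are cycle peaks of the 10--20 Hz band-passed
#' trace whose analytic-signal envelope clears an amplitude threshold, and a
#' run of beats only counts as a bout if every inter-beat interval lies in
#' the band and the intervals' coefficient of variation is at most
#' `cv_max` (40% by default).
#'
#' @param band Length-2 numeric, scratch band `[f_lo, f_hi]` in Hz.
#' @param cv_max Maximal inter-beat-interval CV within one bout (fraction).
#' @param min_beats_per_bout Minimum beats per bout; at least 3, the smallest
#'   run with a defined interval CV.
#' @param event_gap_s Maximal gap (s) between consecutive bouts of one
#'   paw-lift event. Must exceed one beat period (`1/f_lo`).
#' @param interval_tol_s Measurement-resolution allowance (s) on the
#'   in-band inter-beat-interval test: beat times live on the sampling grid,
#'   so a measured interval can differ from the true one by up to one sample
#'   period. Default 0.005 s, one sample at 200 Hz.
#' @param amp_threshold_k Envelope threshold as a multiple of the robust
#'   baseline noise scale (1.4826 x MAD of the band-passed trace).
#' @param analysis_window_s Length of the analysis window (s); nothing past
#'   it is returned.
#' @return An object of class `detector_params`.
#' @export
detector_params <- function(band = c(10, 20),
                            cv_max = 0.40,
                            min_beats_per_bout = 3L,
                            event_gap_s = 1.0,
                            amp_threshold_k = 5,
                            analysis_window_s = 1800,
                            interval_tol_s = 0.005) {
  p <- list(band = as.numeric(band), cv_max = cv_max,
            min_beats_per_bout = as.integer(min_beats_per_bout),
            event_gap_s = event_gap_s, amp_threshold_k = amp_threshold_k,
            analysis_window_s = analysis_window_s,
            interval_tol_s = interval_tol_s)
  stopifnot(
    length(p$band) == 2L, p$band[1] < p$band[2], p$band[1] > 0,
    p$cv_max > 0, p$min_beats_per_bout >= 3L,
    p$amp_threshold_k > 0, p$analysis_window_s > 0,
    p$interval_tol_s >= 0
  )
  if (p$event_gap_s <= 1 / p$band[1]) {
    stop("event_gap_s must exceed one beat period (1/f_lo)")
  }
  structure(p, class = "detector_params")
}

#' Detect scratch beats in an induction-current trace
#'
#' Zero-phase band-pass (Butterworth, order 2, filtered forward and backward)
#' over the scratch band, envelope as the magnitude of the analytic signal,
#' threshold at `amp_threshold_k` times the MAD-based noise scale of the
#' band-passed trace, then cycle-peak picking with minimum separation
#' `1/(2 f_hi)`. Returned beat times are sorted, deduplicated and clipped to
#' the analysis window.
#'
#' @param trace `data.frame(time_s, signal)`, uniformly sampled with
#'   `sampling rate >= 4 * f_hi`.
#' @param params A [detector_params()] object.
#' @return Numeric vector of beat times in seconds.
#' @export
detect_beats <- function(trace, params = detector_params()) {
  stopifnot(is.data.frame(trace), all(c("time_s", "signal") %in% names(trace)))
  if (nrow(trace) < 8L) stop("bad trace: too short")
  dt <- diff(trace$time_s)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * stats::median(dt)) {
    stop("bad trace: non-uniform sampling")
  }
  fs <- 1 / stats::median(dt)
  if (fs < 4 * params$band[2]) stop("undersampled")

  x <- trace$signal
  if (all(x == 0)) return(numeric(0))

  bf <- signal::butter(2, params$band / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)

  env <- Mod(analytic_signal(xf))
  # 1.4826 * MAD of the band-passed trace: robust to sparse bursts. On
  # (near-)noiseless traces the MAD collapses to ~0 and the threshold would
  # admit filter ringing between bursts (~3% of burst amplitude), so floor
  # the scale at 2% of the band-passed peak.
  scale <- max(stats::mad(xf), 0.02 * max(abs(xf)))
  thr <- params$amp_threshold_k * scale

  min_sep <- max(1L, floor(fs / (2 * params$band[2])))
  pk <- pracma::findpeaks(xf, minpeakdistance = min_sep,
                          minpeakheight = thr / 2, sortstr = FALSE)
  if (is.null(pk)) return(numeric(0))
  idx <- pk[, 2]
  idx <- idx[env[idx] > thr]
  beats <- sort(trace$time_s[idx])
  beats[beats <= params$analysis_window_s]
}

# Analytic signal via FFT: zero out negative frequencies, double positives.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Segment detected beats into scratch bouts
#'
#' Greedy left-to-right run construction: a run extends while the next
#' inter-beat interval lies in `[1/f_hi, 1/f_lo]`. Runs shorter than
#' `min_beats_per_bout` are discarded. A surviving run whose interval CV
#' (sample SD over mean) exceeds `cv_max` is split at the interval most
#' deviant from the run's median interval (leftmost on ties) and both halves
#' are re-evaluated recursively.
#'
#' @param beats Sorted numeric vector of beat times (s).
#' @param params A [detector_params()] object.
#' @return `data.frame(onset_s, offset_s, n_beats, mean_freq_hz, interval_cv)`
#'   with one row per bout; the per-bout beat times are kept in the
#'   `beats` attribute (a list, same order as rows).
#' @export
segment_bouts <- function(beats, params = detector_params()) {
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      n_beats = integer(0), mean_freq_hz = numeric(0),
                      interval_cv = numeric(0))
  attr(empty, "beats") <- list()
  if (length(beats) < params$min_beats_per_bout) return(empty)
  stopifnot(!is.unsorted(beats))

  iv_lo <- 1 / params$band[2] - params$interval_tol_s
  iv_hi <- 1 / params$band[1] + params$interval_tol_s
  iv <- diff(beats)
  in_band <- iv >= iv_lo & iv <= iv_hi
  # beat 1 opens run 1; an out-of-band interval before beat i opens a new run
  runs <- split(beats, cumsum(c(1L, !in_band)))

  kept <- list()
  for (r in runs) {
    if (length(r) < params$min_beats_per_bout) next
    kept <- c(kept, split_run_by_cv(r, params))
  }
  if (length(kept) == 0L) return(empty)

  out <- do.call(rbind, lapply(kept, function(b) {
    ivb <- diff(b)
    data.frame(onset_s = b[1], offset_s = b[length(b)],
               n_beats = length(b), mean_freq_hz = 1 / mean(ivb),
               interval_cv = stats::sd(ivb) / mean(ivb))
  }))
  o <- order(out$onset_s)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "beats") <- kept[o]
  out
}

# Recursive CV-based splitting of one in-band run of beats.
split_run_by_cv <- function(run, params) {
  if (length(run) < params$min_beats_per_bout) return(list())
  iv <- diff(run)
  cv <- stats::sd(iv) / mean(iv)
  if (cv <= params$cv_max) return(list(run))
  dev <- abs(iv - stats::median(iv))
  i <- which.max(dev)  # which.max is leftmost on ties
  c(split_run_by_cv(run[seq_len(i)], params),
    split_run_by_cv(run[seq(i + 1L, length(run))], params))
}

#' Group bouts into paw-lift scratch events
#'
#' One scratch event spans one or more bouts executed between a single paw
#' lift and paw-down; in the induction signal alone the lift is not
#' observable, so consecutive bouts separated by at most `event_gap_s` are
#' merged into one event.
#'
#' @param bouts Bout table from [segment_bouts()], sorted, non-overlapping.
#' @param params A [detector_params()] object.
#' @return `data.frame(onset_s, offset_s, n_bouts)`, one row per event.
#' @export
group_events <- function(bouts, params = detector_params()) {
  if (nrow(bouts) == 0L) {
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      n_bouts = integer(0)))
  }
  if (is.unsorted(bouts$onset_s)) {
    stop("invalid segmentation: bouts not sorted")
  }
  if (nrow(bouts) > 1L &&
      any(bouts$onset_s[-1] < bouts$offset_s[-nrow(bouts)])) {
    stop("invalid segmentation: overlapping bouts")
  }
  gap <- c(Inf, bouts$onset_s[-1] - bouts$offset_s[-nrow(bouts)])
  ev_id <- cumsum(gap > params$event_gap_s)
  onset <- tapply(bouts$onset_s, ev_id, min)
  offset <- tapply(bouts$offset_s, ev_id, max)
  nb <- tapply(bouts$onset_s, ev_id, length)
  data.frame(onset_s = as.numeric(onset), offset_s = as.numeric(offset),
             n_bouts = as.integer(nb))
}

#' Run the full detector on a trace
#'
#' Convenience wrapper: [detect_beats()], [segment_bouts()],
#' [group_events()] in sequence.
#'
#' @inheritParams detect_beats
#' @return List with `beats`, `bouts`, `events`.
#' @export
detect_scratching <- function(trace, params = detector_params()) {
  beats <- detect_beats(trace, params)
  bouts <- segment_bouts(beats, params)
  events <- group_events(bouts, params)
  list(beats = beats, bouts = bouts, events = events)
}
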