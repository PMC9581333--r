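#' Simulate one induction-current scratch session with exact ground truth
#'
#' Emulates the decision variables of a coil-based scratch monitor: every
#' scratch beat is one paw oscillation cycle, so a bout appears in the trace
#' as an amplitude-modulated oscillation burst whose positive peaks fall
#' exactly on the ground-truth beat times. Inter-beat intervals are jittered
#' around the bout's base period but clamped inside the scratch band, and any
#' bout whose interval CV would exceed 40% has its jitter shrunk, so every
#' emitted bout is detectable by construction under default detector
#' settings. Confounder bursts (locomotion, grooming) are placed in the gaps
#' between scratch events and rendered in their sub-10-Hz bands; Gaussian
#' baseline noise is added last.
#'
#' @param params A [signal_params()] object.
#' @return A list with components:
#'   \describe{
#'     \item{trace}{`data.frame(time_s, signal)` of length
#'       `round(sampling_rate * duration_s)`, time starting at 0 (injection).}
#'     \item{truth}{Ground-truth annotation: `events` (each with `lift_s`,
#'       `down_s` and `bouts`, each bout an ordered vector `beat_times_s`)
#'       and `confounder_intervals` (`onset_s`, `offset_s`, `kind`).}
#'   }
#' @examples
#' p <- signal_params(duration_s = 60, n_events = 3, seed = 7)
#' s <- simulate_session(p)
#' nrow(s$trace)             # 60 s * 200 Hz
#' length(s$truth$events)    # 3
#' @export
simulate_session <- function(params) {
  stopifnot(inherits(params, "signal_params"))
  set.seed(params$seed)
  fs <- params$sampling_rate
  n <- round(fs * params$duration_s)

  schedule <- schedule_events(params)
  confs <- schedule_confounders(params, schedule$event_spans)

  sig <- numeric(n)
  tt <- (seq_len(n) - 1) / fs
  for (ev in schedule$events) {
    for (bt in ev$bouts) {
      sig <- sig + render_bout(bt$beat_times_s, fs, n, params$bout_amplitude)
    }
  }
  for (cf in confs) {
    sig <- sig + render_confounder(cf, fs, n)
  }
  if (params$noise_sd > 0) {
    sig <- sig + stats::rnorm(n, 0, params$noise_sd)
  }

  truth <- list(
    events = lapply(schedule$events, function(ev) {
      list(lift_s = ev$lift_s, down_s = ev$down_s,
           bouts = lapply(ev$bouts, function(b) list(beat_times_s = b$beat_times_s)))
    }),
    confounder_intervals = lapply(confs, function(cf) {
      list(onset_s = cf$onset_s, offset_s = cf$offset_s, kind = cf$kind)
    })
  )
  list(trace = data.frame(time_s = tt, signal = sig), truth = truth)
}

# Draw one bout's beat times (relative to 0 = first beat). Intervals are the
# bout's base period jittered with CV beat_jitter_cv, clamped 2 ms inside the
# band so measured intervals stay in-band after sample quantization, then
# shrunk about their mean if the sample CV exceeds 0.38 (5% inside the 40%
# bout rule) -- clamping alone does not bound the CV of short bouts.
draw_bout_beats <- function(params) {
  f <- stats::runif(1, params$beat_freq_range[1], params$beat_freq_range[2])
  n_beats <- sample(seq(params$beats_per_bout_range[1],
                        params$beats_per_bout_range[2]), 1L)
  iv <- (1 / f) * (1 + stats::rnorm(n_beats - 1L, 0, params$beat_jitter_cv))
  lo <- 1 / params$beat_freq_range[2] + 0.002
  hi <- 1 / params$beat_freq_range[1] - 0.002
  iv <- pmin(pmax(iv, lo), hi)
  m <- mean(iv)
  cv <- stats::sd(iv) / m
  if (is.finite(cv) && cv > 0.38) {
    iv <- m + (iv - m) * (0.38 / cv)
  }
  c(0, cumsum(iv))
}

# Build the full event schedule; absolute times. Events are separated by at
# least `min_event_gap_s` (1.5 s > the 1 s event-gap threshold, so detected
# events are separable) plus a random share of the remaining slack.
schedule_events <- function(params, min_event_gap_s = 1.5, edge_s = 1) {
  if (params$n_events == 0L) {
    return(list(events = list(), event_spans = matrix(numeric(0), ncol = 2)))
  }
  protos <- lapply(seq_len(params$n_events), function(i) {
    n_bouts <- sample(seq(params$bouts_per_event_range[1],
                          params$bouts_per_event_range[2]), 1L)
    bouts <- lapply(seq_len(n_bouts), function(j) draw_bout_beats(params))
    gaps <- if (n_bouts > 1L) {
      stats::runif(n_bouts - 1L, params$intra_event_gap_s[1],
                   params$intra_event_gap_s[2])
    } else numeric(0)
    list(bouts = bouts, gaps = gaps)
  })
  durations <- vapply(protos, function(pr) {
    spans <- vapply(pr$bouts, function(b) max(b) + bout_pad(b, "both"),
                    numeric(1))
    sum(spans) + sum(pr$gaps)
  }, numeric(1))

  slack <- params$duration_s - 2 * edge_s - sum(durations) -
    min_event_gap_s * (params$n_events - 1L)
  if (slack < 0) stop("schedule infeasible: events do not fit in duration_s")
  w <- stats::runif(params$n_events + 1L)
  extra <- slack * w / sum(w)

  events <- vector("list", params$n_events)
  cursor <- edge_s + extra[1]
  spans <- matrix(0, nrow = params$n_events, ncol = 2)
  for (i in seq_len(params$n_events)) {
    pr <- protos[[i]]
    bouts <- vector("list", length(pr$bouts))
    b_cursor <- cursor
    for (j in seq_along(pr$bouts)) {
      rel <- pr$bouts[[j]]
      start_pad <- bout_pad(rel, "start")
      bouts[[j]] <- list(beat_times_s = rel + b_cursor + start_pad)
      b_cursor <- b_cursor + max(rel) + bout_pad(rel, "both")
      if (j < length(pr$bouts)) b_cursor <- b_cursor + pr$gaps[j]
    }
    spans[i, ] <- c(cursor, b_cursor)
    events[[i]] <- list(
      lift_s = cursor, down_s = b_cursor, bouts = bouts
    )
    cursor <- b_cursor + min_event_gap_s + extra[i + 1L]
  }
  list(events = events, event_spans = spans)
}

# Half-cycle padding of the rendered burst on either side of the beat span.
bout_pad <- function(beat_times_rel, which = c("start", "end", "both")) {
  which <- match.arg(which)
  iv <- diff(beat_times_rel)
  switch(which,
         start = iv[1] / 2,
         end = iv[length(iv)] / 2,
         both = (iv[1] + iv[length(iv)]) / 2)
}

#' Ground-truth bout intervals as a table
#'
#' Flattens the events -> bouts -> beat-times hierarchy into one row per
#' bout. `onset_s`/`offset_s` are the rendered burst support (first beat
#' minus half the first cycle, last beat plus half the last cycle);
#' `mid_s` is the support midpoint used when matching detections.
#'
#' @param truth Ground-truth annotation from [simulate_session()].
#' @return `data.frame(event, bout, onset_s, offset_s, mid_s, n_beats)`.
#' @export
truth_bout_table <- function(truth) {
  rows <- list()
  for (i in seq_along(truth$events)) {
    ev <- truth$events[[i]]
    for (j in seq_along(ev$bouts)) {
      b <- ev$bouts[[j]]$beat_times_s
      onset <- b[1] - bout_pad(b, "start")
      offset <- b[length(b)] + bout_pad(b, "end")
      rows[[length(rows) + 1L]] <- data.frame(
        event = i, bout = j, onset_s = onset, offset_s = offset,
        mid_s = (onset + offset) / 2, n_beats = length(b)
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(event = integer(0), bout = integer(0),
                      onset_s = numeric(0), offset_s = numeric(0),
                      mid_s = numeric(0), n_beats = integer(0)))
  }
  do.call(rbind, rows)
}

# Render one bout as a continuous-phase oscillation: phase is piecewise
# linear with a positive peak (phase pi/2 mod 2*pi) at every beat time, with
# half-cycle raised-cosine ramps before the first and after the last beat.
render_bout <- function(beat_times, fs, n, amplitude) {
  iv <- diff(beat_times)
  t0 <- beat_times[1] - iv[1] / 2
  t1 <- beat_times[length(beat_times)] + iv[length(iv)] / 2
  i0 <- max(1L, floor(t0 * fs) + 1L)
  i1 <- min(n, ceiling(t1 * fs) + 1L)
  if (i0 > i1) return(numeric(n))
  tt <- (seq(i0, i1) - 1) / fs

  knots_t <- c(t0, beat_times, t1)
  knots_phi <- c(pi / 2 - pi, pi / 2 + 2 * pi * (seq_along(beat_times) - 1),
                 pi / 2 + 2 * pi * (length(beat_times) - 1) + pi)
  phi <- stats::approx(knots_t, knots_phi, xout = tt, rule = 2)$y

  env <- rep(1, length(tt))
  ramp_in <- tt < beat_times[1]
  env[ramp_in] <- 0.5 * (1 - cos(pi * (tt[ramp_in] - t0) / (iv[1] / 2)))
  ramp_out <- tt > beat_times[length(beat_times)]
  env[ramp_out] <- 0.5 * (1 + cos(pi * (tt[ramp_out] -
    beat_times[length(beat_times)]) / (iv[length(iv)] / 2)))
  env[tt < t0 | tt > t1] <- 0

  out <- numeric(n)
  out[seq(i0, i1)] <- amplitude * env * sin(phi)
  out
}

# Place confounder bursts in the silent gaps between scratch events
# (rejection sampling with a 0.5 s guard band around events).
schedule_confounders <- function(params, event_spans, max_tries = 60L) {
  out <- list()
  if (length(params$confounders) == 0L) return(out)
  guard <- 0.5
  occupied <- event_spans
  for (cf in params$confounders) {
    n_burst <- stats::rpois(1, cf$rate_per_min * params$duration_s / 60)
    for (b in seq_len(n_burst)) {
      dur <- stats::runif(1, cf$duration_range_s[1], cf$duration_range_s[2])
      freq <- stats::runif(1, cf$freq_range[1], cf$freq_range[2])
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        onset <- stats::runif(1, 0, max(params$duration_s - dur, 0))
        clash <- nrow(occupied) > 0 &&
          any(onset < occupied[, 2] + guard & onset + dur > occupied[, 1] - guard)
        if (!clash) { placed <- TRUE; break }
      }
      if (!placed) next
      occupied <- rbind(occupied, c(onset, onset + dur))
      out[[length(out) + 1L]] <- list(
        kind = cf$kind, onset_s = onset, offset_s = onset + dur,
        freq_hz = freq, amplitude = cf$amplitude
      )
    }
  }
  out
}

# A confounder burst is a Hann-windowed sinusoid in its own band.
render_confounder <- function(cf, fs, n) {
  i0 <- max(1L, floor(cf$onset_s * fs) + 1L)
  i1 <- min(n, ceiling(cf$offset_s * fs) + 1L)
  if (i0 > i1) return(numeric(n))
  tt <- (seq(i0, i1) - 1) / fs
  u <- (tt - cf$onset_s) / (cf$offset_s - cf$onset_s)
  u <- pmin(pmax(u, 0), 1)
  env <- 0.5 * (1 - cos(2 * pi * u))
  out <- numeric(n)
  out[seq(i0, i1)] <- cf$amplitude * env * sin(2 * pi * cf$freq_hz * (tt - cf$onset_s))
  out
}
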