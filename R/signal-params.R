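#' Parameters for simulated induction-current sessions
#'
#' Bundles every knob of the scratch-session simulator. A session is a
#' 30-min single-channel induction-current trace in which hind-paw scratch
#' beats (one paw oscillation cycle each, 10--20 Hz within a bout) are
#' grouped into bouts, bouts into paw-lift events, on top of baseline noise
#' and sub-10-Hz locomotion/grooming confounders.
#'
#' @param sampling_rate Sampling rate in Hz. Must be at least four times the
#'   top of `beat_freq_range` so the oscillation is resolvable.
#' @param duration_s Session length in seconds (default one 30-min window).
#' @param beat_freq_range Length-2 numeric, the scratch band `[f_lo, f_hi]`
#'   in Hz. Every bout's instantaneous beat frequency stays inside it.
#' @param beat_jitter_cv Coefficient of variation of the inter-beat-interval
#'   jitter within a bout, as a fraction in `[0, 1)`.
#' @param beats_per_bout_range Integer pair, inclusive range of beats per bout.
#' @param bouts_per_event_range Integer pair, inclusive range of bouts per
#'   paw-lift event.
#' @param intra_event_gap_s Length-2 numeric, uniform range (seconds) of the
#'   silent gap between consecutive bouts of one event. Must stay below the
#'   detector's event-gap threshold for the event hierarchy to be recoverable.
#' @param n_events Number of scratch events in the session.
#' @param confounders List of confounder specs as built by
#'   [confounder_spec()]; defaults to one locomotion and one grooming class.
#' @param noise_sd Standard deviation of the additive Gaussian baseline noise,
#'   in signal units.
#' @param bout_amplitude Peak amplitude of a rendered scratch burst, in signal
#'   units.
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   traces and annotations.
#'
#' @return An object of class `signal_params` (a validated list).
#' @seealso [simulate_session()]
#' @export
signal_params <- function(sampling_rate = 200,
                          duration_s = 1800,
                          beat_freq_range = c(10, 20),
                          beat_jitter_cv = 0.15,
                          beats_per_bout_range = c(4L, 30L),
                          bouts_per_event_range = c(1L, 5L),
                          intra_event_gap_s = c(0.2, 0.8),
                          n_events = 40L,
                          confounders = default_confounders(),
                          noise_sd = 0.1,
                          bout_amplitude = 1,
                          seed = 1L) {
  p <- list(
    sampling_rate = sampling_rate,
    duration_s = duration_s,
    beat_freq_range = as.numeric(beat_freq_range),
    beat_jitter_cv = beat_jitter_cv,
    beats_per_bout_range = as.integer(beats_per_bout_range),
    bouts_per_event_range = as.integer(bouts_per_event_range),
    intra_event_gap_s = as.numeric(intra_event_gap_s),
    n_events = as.integer(n_events),
    confounders = confounders,
    noise_sd = noise_sd,
    bout_amplitude = bout_amplitude,
    seed = as.integer(seed)
  )
  validate_signal_params(p)
  structure(p, class = "signal_params")
}

validate_signal_params <- function(p) {
  stopifnot(
    length(p$beat_freq_range) == 2L,
    p$beat_freq_range[1] < p$beat_freq_range[2],
    p$duration_s > 0,
    p$beat_jitter_cv >= 0, p$beat_jitter_cv < 1,
    p$noise_sd >= 0, p$bout_amplitude >= 0,
    p$n_events >= 0,
    length(p$beats_per_bout_range) == 2L,
    p$beats_per_bout_range[1] >= 3L,
    p$beats_per_bout_range[1] <= p$beats_per_bout_range[2],
    length(p$bouts_per_event_range) == 2L,
    p$bouts_per_event_range[1] >= 1L,
    p$bouts_per_event_range[1] <= p$bouts_per_event_range[2],
    length(p$intra_event_gap_s) == 2L,
    p$intra_event_gap_s[1] > 0,
    p$intra_event_gap_s[1] <= p$intra_event_gap_s[2]
  )
  if (p$sampling_rate < 4 * p$beat_freq_range[2]) {
    stop("undersampled: sampling_rate must be >= 4 * upper beat frequency")
  }
  for (cf in p$confounders) {
    stopifnot(
      is.list(cf), cf$kind %in% c("locomotion", "grooming"),
      length(cf$freq_range) == 2L, cf$freq_range[1] < cf$freq_range[2],
      cf$rate_per_min >= 0, cf$amplitude >= 0
    )
  }
  invisible(p)
}

#' Describe one class of non-scratch confounder activity
#'
#' Confounders are rendered as amplitude-modulated sinusoidal bursts below the
#' scratch band: locomotion at 1--4 Hz and high amplitude, grooming at
#' 5--8 Hz and medium amplitude, so the 10--20 Hz band discriminator is the
#' operative filter.
#'
#' @param kind `"locomotion"` or `"grooming"`.
#' @param freq_range Length-2 numeric, burst frequency range in Hz.
#' @param rate_per_min Expected number of bursts per minute (Poisson).
#' @param amplitude Peak burst amplitude in signal units.
#' @param duration_range_s Length-2 numeric, uniform range of burst length.
#' @return A list usable in the `confounders` field of [signal_params()].
#' @export
confounder_spec <- function(kind,
                            freq_range,
                            rate_per_min,
                            amplitude,
                            duration_range_s = c(1, 3)) {
  list(kind = kind, freq_range = as.numeric(freq_range),
       rate_per_min = rate_per_min, amplitude = amplitude,
       duration_range_s = as.numeric(duration_range_s))
}

#' Default confounder repertoire (locomotion + grooming)
#' @return List of two confounder specs.
#' @export
default_confounders <- function() {
  list(
    confounder_spec("locomotion", c(1, 4), rate_per_min = 2, amplitude = 2),
    confounder_spec("grooming",   c(5, 8), rate_per_min = 2, amplitude = 1)
  )
}
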