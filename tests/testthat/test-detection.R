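test_that("all-zero and malformed traces are handled", {
  tr <- data.frame(time_s = (0:5999) / 200, signal = 0)
  expect_identical(detect_beats(tr), numeric(0))

  bad <- data.frame(time_s = sort(runif(1000, 0, 5)), signal = rnorm(1000))
  expect_error(detect_beats(bad), "bad trace")

  slow <- data.frame(time_s = (0:999) / 50, signal = rnorm(1000))
  expect_error(detect_beats(slow), "undersampled")
})

test_that("a clean 10-beat 15 Hz bout yields exactly 10 beats within 10 ms", {
  s <- single_bout_session(freq_hz = 15, n_beats = 10)
  beats <- detect_beats(s$trace)
  expect_length(beats, 10)
  expect_true(all(abs(beats - s$beat_times) <= 0.010))
})

test_that("out-of-band activity alone produces no beats", {
  fs <- 200
  n <- 30 * fs
  tt <- (seq_len(n) - 1) / fs
  for (f in c(3, 7)) {   # locomotion- and grooming-band bursts
    sig <- numeric(n)
    idx <- tt >= 10 & tt <= 13
    u <- (tt[idx] - 10) / 3
    sig[idx] <- 2 * 0.5 * (1 - cos(2 * pi * u)) * sin(2 * pi * f * (tt[idx] - 10))
    tr <- data.frame(time_s = tt, signal = sig + rnorm(n, 0, 0.1))
    det <- detect_scratching(tr, detector_params(analysis_window_s = 30))
    expect_equal(nrow(det$bouts), 0)
  }
})

test_that("perfectly periodic beats form one zero-CV bout", {
  beats <- seq(0, by = 1 / 15, length.out = 10)
  b <- segment_bouts(beats)
  expect_equal(nrow(b), 1)
  expect_equal(b$interval_cv, 0)
  expect_equal(b$n_beats, 10)
  expect_equal(b$mean_freq_hz, 15)
})

test_that("alternating 52/98 ms intervals stay one bout (CV below 0.40)", {
  iv <- rep(c(0.052, 0.098), length.out = 9)
  beats <- c(0, cumsum(iv))
  cv <- sd(iv) / mean(iv)          # direct arithmetic oracle
  expect_lt(cv, 0.40)
  b <- segment_bouts(beats)
  expect_equal(nrow(b), 1)
  expect_equal(b$interval_cv, cv, tolerance = 1e-12)
})

test_that("an out-of-band interval breaks a run into two bouts", {
  iv <- c(0.060, 0.060, 0.060, 0.200, 0.060, 0.060, 0.060)
  beats <- c(0, cumsum(iv))
  b <- segment_bouts(beats)
  expect_equal(nrow(b), 2)
  expect_equal(b$n_beats, c(4L, 4L))
})

test_that("runs over the CV cap are split at the most deviant interval", {
  # two stable regimes joined by one aberrant in-band interval
  iv <- c(rep(0.055, 6), 0.098, rep(0.056, 6))
  beats <- c(0, cumsum(iv))
  stopifnot(sd(iv) / mean(iv) < 0.40)   # within cap: stays together
  expect_equal(nrow(segment_bouts(beats)), 1)

  p_tight <- detector_params(cv_max = 0.10)
  b <- segment_bouts(beats, p_tight)
  expect_equal(nrow(b), 2)
  expect_true(all(b$interval_cv <= 0.10))
  expect_equal(b$n_beats, c(7L, 7L))   # split at the 0.098 interval
})

test_that("lowering cv_max never increases the number of retained beats", {
  # tightening the CV rule forces more splits; every split keeps subsets of
  # the run's beats and discards sub-minimum fragments, so the total number
  # of beats inside bouts can only shrink (bout counts may transiently rise
  # when one run splits into two valid halves)
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    iv <- runif(n, 0.05, 0.1)
    if (runif(1) < 0.5) iv[sample(n, 2)] <- runif(2, 0.15, 0.4)
    beats <- c(0, cumsum(iv))
    grid <- c(0.6, 0.4, 0.25, 0.15, 0.08)
    n_beats <- vapply(grid, function(cv) {
      b <- segment_bouts(beats, detector_params(cv_max = cv))
      sum(b$n_beats)
    }, numeric(1))
    expect_true(all(diff(n_beats) <= 0))
    # and every retained bout honors the cap it was segmented under
    for (cv in grid) {
      b <- segment_bouts(beats, detector_params(cv_max = cv))
      if (nrow(b) > 0) expect_true(all(b$interval_cv <= cv + 1e-12))
    }
  }
})

test_that("beat/bout/event hierarchy partitions and nests", {
  s <- simulate_session(signal_params(duration_s = 300, n_events = 8, seed = 4))
  det <- detect_scratching(s$trace, detector_params(analysis_window_s = 300))
  bouts <- det$bouts
  events <- det$events
  expect_lte(nrow(events), nrow(bouts))
  expect_lte(nrow(bouts), length(det$beats))
  expect_equal(sum(events$n_bouts), nrow(bouts))
  # every beat in at most one bout
  all_bout_beats <- unlist(attr(bouts, "beats"))
  expect_false(any(duplicated(all_bout_beats)))
  # every bout inside exactly one event
  for (i in seq_len(nrow(bouts))) {
    inside <- events$onset_s <= bouts$onset_s[i] &
      events$offset_s >= bouts$offset_s[i]
    expect_equal(sum(inside), 1)
  }
})

test_that("event grouping follows the gap threshold", {
  bouts <- data.frame(onset_s = c(10, 11, 13.5), offset_s = c(10.5, 11.5, 14),
                      n_beats = 5L, mean_freq_hz = 15, interval_cv = 0.1)
  ev <- group_events(bouts)   # gaps 0.5 and 2.0 at threshold 1.0
  expect_equal(nrow(ev), 2)
  expect_equal(ev$n_bouts, c(2L, 1L))
  expect_equal(ev$onset_s, c(10, 13.5))

  one <- group_events(bouts[1, ])
  expect_equal(nrow(one), 1)
  expect_equal(c(one$onset_s, one$offset_s), c(10, 10.5))

  none <- group_events(bouts[0, ])
  expect_equal(nrow(none), 0)

  bad <- data.frame(onset_s = c(10, 10.3), offset_s = c(10.5, 10.8),
                    n_beats = 5L, mean_freq_hz = 15, interval_cv = 0.1)
  expect_error(group_events(bad), "invalid segmentation")
})

test_that("nothing extends past the analysis window", {
  p <- detector_params(analysis_window_s = 120)
  s <- simulate_session(signal_params(duration_s = 300, n_events = 8, seed = 6))
  det <- detect_scratching(s$trace, p)
  expect_true(all(det$beats <= 120))
  expect_true(all(det$bouts$offset_s <= 120))
  expect_true(all(det$events$offset_s <= 120))
})

test_that("validation counts match a direct counting oracle", {
  s <- simulate_session(clean_params(seed = 2))
  det <- detect_scratching(s$trace)
  v <- validate_detection(det$bouts, s$truth)
  expect_equal(v$ppv, 1.0)
  expect_equal(v$sensitivity, 1.0)

  # add 2 spurious bouts far from any truth bout
  spur <- data.frame(onset_s = c(50, 55), offset_s = c(50.3, 55.3),
                     n_beats = 4L, mean_freq_hz = 15, interval_cv = 0.05)
  padded <- rbind(det$bouts[, names(spur)], spur)
  v2 <- validate_detection(padded, s$truth)
  nt <- nrow(truth_bout_table(s$truth))
  expect_equal(v2$tp, nt)
  expect_equal(v2$fp, 2)
  expect_equal(v2$ppv, nt / (nt + 2))
  expect_equal(v2$sensitivity, 1.0)
})

test_that("pure-noise traces yield essentially no false bouts", {
  total <- 0
  for (sd in 1:50) {
    p <- signal_params(duration_s = 300, n_events = 0, confounders = list(),
                       seed = sd)
    s <- simulate_session(p)
    det <- detect_scratching(s$trace, detector_params(analysis_window_s = 300))
    total <- total + nrow(det$bouts)
  }
  expect_lte(total, 1)
})

test_that("noiseless round trip recovers ground-truth bout counts exactly", {
  for (sd in 1:20) {
    s <- simulate_session(clean_params(seed = sd, duration_s = 240, n_events = 6))
    det <- detect_scratching(s$trace, detector_params(analysis_window_s = 240))
    expect_equal(nrow(det$bouts), nrow(truth_bout_table(s$truth)))
  }
})
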