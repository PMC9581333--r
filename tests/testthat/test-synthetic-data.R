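test_that("null session gives an all-zero trace and empty truth", {
  p <- signal_params(duration_s = 30, n_events = 0, noise_sd = 0,
                     confounders = list(), seed = 1)
  s <- simulate_session(p)
  expect_equal(nrow(s$trace), 30 * 200)
  expect_true(all(s$trace$signal == 0))
  expect_length(s$truth$events, 0)
  expect_length(s$truth$confounder_intervals, 0)
})

test_that("trace length, determinism and schedule feasibility", {
  p <- signal_params(duration_s = 45, n_events = 4, seed = 42)
  s1 <- simulate_session(p)
  s2 <- simulate_session(p)
  expect_identical(s1$trace, s2$trace)
  expect_identical(s1$truth, s2$truth)
  expect_equal(nrow(s1$trace), round(45 * 200))

  s3 <- simulate_session(signal_params(duration_s = 45, n_events = 4, seed = 43))
  expect_false(identical(s1$trace$signal, s3$trace$signal))

  expect_error(simulate_session(signal_params(duration_s = 20, n_events = 50)),
               "schedule infeasible")
})

test_that("generated bouts satisfy the CV and band invariants by construction", {
  p <- signal_params(seed = 1)
  s <- simulate_session(p)
  f_rng <- p$beat_freq_range
  for (ev in s$truth$events) {
    for (b in ev$bouts) {
      bt <- b$beat_times_s
      expect_true(all(diff(bt) > 0))
      iv <- diff(bt)
      expect_lte(sd(iv) / mean(iv), 0.40)
      expect_true(all(1 / iv >= f_rng[1] & 1 / iv <= f_rng[2]))
      expect_gte(bt[1], ev$lift_s)
      expect_lte(bt[length(bt)], ev$down_s)
    }
  }
  # events ordered and non-overlapping
  lifts <- vapply(s$truth$events, `[[`, numeric(1), "lift_s")
  downs <- vapply(s$truth$events, `[[`, numeric(1), "down_s")
  expect_true(all(lifts[-1] > downs[-length(downs)]))
})

test_that("a pure 15 Hz bout renders with its spectral peak at 15 Hz", {
  s <- single_bout_session(freq_hz = 15, n_beats = 10)
  tb <- truth_bout_table(s$truth)
  idx <- which(s$trace$time_s >= tb$onset_s & s$trace$time_s <= tb$offset_s)
  pg <- spec.pgram(ts(s$trace$signal[idx], frequency = 200),
                   taper = 0, plot = FALSE, detrend = FALSE)
  f_peak <- pg$freq[which.max(pg$spec)]
  expect_lt(abs(f_peak - 15), 0.5)
})

test_that("rendered burst support matches the annotated bout interval", {
  s <- simulate_session(clean_params(seed = 5))
  tb <- truth_bout_table(s$truth)
  x <- s$trace$signal
  tt <- s$trace$time_s
  for (i in seq_len(nrow(tb))) {
    on_idx <- which(tt >= tb$onset_s[i] - 0.05 & tt < tb$onset_s[i] - 1 / 200)
    # strictly before the annotated onset (outside any other bout) it is 0
    prev_off <- if (i > 1) tb$offset_s[i - 1] else 0
    on_idx <- on_idx[tt[on_idx] > prev_off + 1 / 200]
    if (length(on_idx) > 0) expect_true(all(abs(x[on_idx]) < 1e-9))
    # within one sample of the onset the burst has started
    inside <- which(tt >= tb$onset_s[i] + 1 / 200 & tt <= tb$offset_s[i] - 1 / 200)
    expect_gt(max(abs(x[inside])), 0.1)
  }
})

test_that("confounder bursts stay in their bands and off the events", {
  p <- signal_params(seed = 9)
  s <- simulate_session(p)
  spans <- do.call(rbind, lapply(s$truth$events, function(ev) c(ev$lift_s, ev$down_s)))
  for (cf in s$truth$confounder_intervals) {
    expect_true(cf$kind %in% c("locomotion", "grooming"))
    overlap <- any(cf$onset_s < spans[, 2] & cf$offset_s > spans[, 1])
    expect_false(overlap)
  }
})

test_that("cohort simulation is reproducible and respects the layout", {
  spec <- cohort_spec(seed = 2)
  co1 <- simulate_cohort(spec)
  co2 <- simulate_cohort(spec)
  expect_identical(co1, co2)
  expect_true(all(co1$bouts >= 0))
  expect_true(all(co1$bouts == floor(co1$bouts)))
  # repeated measures: each animal appears at every dose of its pruritogen
  for (id in unique(co1$animal_id)) {
    doses <- co1$dose_fold[co1$animal_id == id]
    expect_setequal(doses, c(0.3, 1, 3, 10))
  }
  # dose order of the protocol: 3, 1, 10, 0.3 on days 1, 3, 5, 8
  expect_equal(unique(co1$day[co1$dose_fold == 3]), 1)
  expect_equal(unique(co1$day[co1$dose_fold == 0.3]), 8)
  expect_error(cohort_spec(n_per_group = 1), "degenerate group")
})

test_that("degenerate dispersion collapses counts to the rounded mean", {
  mt <- data.frame(strain = "C57", pruritogen = "histamine", dose_fold = c(0.3, 1, 3, 10),
                   mean_bouts = 406.4, sem = 1e-12, n = 6, source = "synthetic-default")
  spec <- cohort_spec(strains = "C57", pruritogens = "histamine",
                      mean_table = mt, n_per_group = 5, seed = 1)
  co <- simulate_cohort(spec)
  expect_true(all(co$bouts == 406))
})

test_that("negative binomial counts match their target moments", {
  set.seed(99)
  x <- scratchquant:::draw_counts(1e5, mu = 100, sd_cell = sqrt(200),
                                  model = "negative_binomial")
  expect_lt(abs(mean(x) - 100) / 100, 0.02)
  expect_lt(abs(var(x) - 200) / 200, 0.05)
})

test_that("group means and SDs converge to spec values (law of large numbers)", {
  mt <- default_group_table()
  cell <- mt[mt$strain == "C57" & mt$pruritogen == "histamine" & mt$dose_fold == 3, ]
  spec <- cohort_spec(strains = "C57", pruritogens = "histamine",
                      n_per_group = 1e4, seed = 7)
  co <- simulate_cohort(spec)
  v <- co$bouts[co$dose_fold == 3]
  sd_target <- cell$sem * sqrt(cell$n)
  expect_lt(abs(mean(v) - cell$mean_bouts) / cell$mean_bouts, 0.02)
  expect_lt(abs(sd(v) - sd_target) / sd_target, 0.02)
})

test_that("the lognormal-rounded count model hits its mean too", {
  mt <- default_group_table()
  spec <- cohort_spec(strains = "C57", pruritogens = "histamine",
                      n_per_group = 1e4, count_model = "lognormal_rounded",
                      seed = 8)
  co <- simulate_cohort(spec)
  v <- co$bouts[co$dose_fold == 3]
  expect_lt(abs(mean(v) - 406) / 406, 0.02)
})
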