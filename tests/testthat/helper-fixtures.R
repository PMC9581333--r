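# Shared fixtures: small, fast parameter sets used across test files.

# Short clean session: no noise, no confounders.
clean_params <- function(seed = 1, duration_s = 60, n_events = 3, ...) {
  signal_params(duration_s = duration_s, n_events = n_events,
                noise_sd = 0, confounders = list(), seed = seed, ...)
}

# A session with exactly one bout of n beats at a fixed frequency.
single_bout_session <- function(freq_hz = 15, n_beats = 10, duration_s = 30,
                                noise_sd = 0, fs = 200) {
  beat_times <- 5 + (seq_len(n_beats) - 1) / freq_hz
  n <- round(fs * duration_s)
  sig <- scratchquant:::render_bout(beat_times, fs, n, amplitude = 1)
  if (noise_sd > 0) sig <- sig + rnorm(n, 0, noise_sd)
  truth <- list(
    events = list(list(
      lift_s = beat_times[1] - 0.1,
      down_s = beat_times[n_beats] + 0.1,
      bouts = list(list(beat_times_s = beat_times))
    )),
    confounder_intervals = list()
  )
  list(trace = data.frame(time_s = (seq_len(n) - 1) / fs, signal = sig),
       truth = truth, beat_times = beat_times)
}

# Independent sums-of-squares oracle for a balanced within-only RM design:
# explicit group-mean decomposition into subject, within and residual SS.
rm_anova_ss_oracle <- function(y, subject, within) {
  s <- factor(subject); w <- factor(within)
  gm <- mean(y)
  k <- nlevels(w); n <- nlevels(s)
  ss_subj <- k * sum((tapply(y, s, mean) - gm)^2)
  ss_within <- n * sum((tapply(y, w, mean) - gm)^2)
  ss_total <- sum((y - gm)^2)
  ss_res <- ss_total - ss_subj - ss_within
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  F <- (ss_within / df1) / (ss_res / df2)
  list(F = F, df1 = df1, df2 = df2,
       p = pf(F, df1, df2, lower.tail = FALSE),
       ms_error = ss_res / df2)
}

# Full-enumeration oracle for the two-sided two-sample Wilcoxon p-value
# (no ties): distribution of U over all choose(n, na) rank assignments.
wilcoxon_enum_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ranks <- seq_len(na + nb)
  sets <- utils::combn(na + nb, na)
  us <- apply(sets, 2, function(ix) sum(ranks[ix]) - na * (na + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# Exhaustive letter-display oracle for a small number of levels: every
# maximal mutually-non-significant subset must share a letter, and no
# significant pair may share one.
letters_consistent_with_posthoc <- function(lets, pairs, alpha = 0.05) {
  shared <- function(i, j) {
    any(strsplit(lets[i], "")[[1]] %in% strsplit(lets[j], "")[[1]])
  }
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$level_i[r]; j <- pairs$level_j[r]
    if (pairs$p_adj[r] <= alpha && shared(i, j)) return(FALSE)
    if (pairs$p_adj[r] > alpha && !shared(i, j)) return(FALSE)
  }
  TRUE
}
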