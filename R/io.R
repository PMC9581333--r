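#' Read and write the interchange formats
#'
#' Traces are two-column CSV (`time_s,signal`, header row, time strictly
#' increasing from 0); ground truth is a JSON file with the
#' events -> bouts -> beat-times hierarchy plus confounder intervals; cohort
#' tables are CSV in the [simulate_cohort()] schema; bout/event tables are
#' TSV with half-open `[onset_s, offset_s)` intervals. All files are UTF-8
#' with '.' as decimal separator.
#'
#' @param trace,path,truth,cohort,bouts,events See individual functions.
#' @name scratch_io
NULL

#' @rdname scratch_io
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(all(c("time_s", "signal") %in% names(trace)))
  utils::write.csv(trace[, c("time_s", "signal")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname scratch_io
#' @export
read_trace_csv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!identical(trimws(header), "time_s,signal")) {
    stop("schema mismatch: trace CSV must have header 'time_s,signal'")
  }
  tr <- utils::read.csv(path)
  if (nrow(tr) > 0 && (tr$time_s[1] != 0 || is.unsorted(tr$time_s, strictly = TRUE))) {
    stop("schema mismatch: time_s must increase strictly from 0")
  }
  tr
}

#' @rdname scratch_io
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname scratch_io
#' @export
read_ground_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = FALSE)
  tr$events <- lapply(tr$events, function(ev) {
    ev$bouts <- lapply(ev$bouts, function(b) {
      list(beat_times_s = as.numeric(unlist(b$beat_times_s)))
    })
    ev$lift_s <- as.numeric(ev$lift_s)
    ev$down_s <- as.numeric(ev$down_s)
    ev
  })
  tr
}

#' @rdname scratch_io
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname scratch_io
#' @export
read_cohort_csv <- function(path) {
  co <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "strain", "sex", "pruritogen", "dose_fold", "day", "bouts")
  if (!all(need %in% names(co))) {
    stop("schema mismatch: cohort CSV missing columns ",
         paste(setdiff(need, names(co)), collapse = ", "))
  }
  co
}

#' @rdname scratch_io
#' @export
write_bout_tsv <- function(bouts, path) {
  utils::write.table(
    bouts[, c("onset_s", "offset_s", "n_beats", "mean_freq_hz", "interval_cv")],
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname scratch_io
#' @export
write_event_tsv <- function(events, path) {
  utils::write.table(events[, c("onset_s", "offset_s", "n_bouts")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble, write and read a run configuration
#'
#' A run configuration captures every threshold of a pipeline run (detector
#' parameters, signal parameters, statistical options, seed) and round-trips
#' losslessly through YAML. Each default carries a provenance tag:
#' `"study"` for values stated by the source protocol (band, CV rule, fence
#' multiplier, alpha) and `"chosen"` for artifact-level choices.
#'
#' @param detector [detector_params()] object.
#' @param signal [signal_params()] object.
#' @param stats_options Named list; defaults cover `alpha`,
#'   `normality_method`, `quantile_convention`, `pool_sexes`.
#' @param seed Integer seed.
#' @param out_dir Output directory recorded for the run.
#' @return Object of class `run_config`.
#' @export
run_config <- function(detector = detector_params(),
                       signal = signal_params(),
                       stats_options = list(alpha = 0.05,
                                            normality_method = "shapiro_wilk",
                                            quantile_convention = "type7",
                                            pool_sexes = TRUE),
                       seed = 1L, out_dir = ".") {
  structure(list(
    detector = unclass(detector),
    signal = unclass(signal),
    stats_options = stats_options,
    seed = as.integer(seed),
    out_dir = out_dir,
    provenance = list(
      band = "study", cv_max = "study", fence_k = "study", alpha = "study",
      sampling_rate = "chosen", event_gap_s = "chosen",
      amp_threshold_k = "chosen", min_beats_per_bout = "chosen",
      confounders = "chosen", noise_sd = "chosen", n_events = "chosen"
    )
  ), class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Hash of a run configuration
#'
#' MD5 of the YAML serialization; stamped into output file headers so every
#' result file is traceable to the exact configuration that produced it.
#'
#' @param config A `run_config` object.
#' @return Character scalar (32-hex MD5).
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Write a result table with a config-hash comment header
#'
#' @param df Data frame to write.
#' @param path Output CSV path.
#' @param config `run_config` the table was produced under.
#' @export
write_result_csv <- function(df, path, config) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# config_md5: ", config_hash(config)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
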