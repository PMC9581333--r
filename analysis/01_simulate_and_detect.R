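#!/usr/bin/env Rscript
# Step 1: simulate one default 30-min session, run the detector on it, and
# write the trace, ground truth and detected bout/event tables.

library(scratchquant)

dir.create("results", showWarnings = FALSE)
cfg <- run_config(seed = 1L, out_dir = "results")

ses <- simulate_session(signal_params(seed = cfg$seed))
det <- detect_scratching(ses$trace)
tb <- truth_bout_table(ses$truth)
v <- validate_detection(det$bouts, ses$truth)

write_trace_csv(ses$trace, "results/session_trace.csv")
write_ground_truth(ses$truth, "results/session_truth.json")
write_bout_tsv(det$bouts, "results/session_bouts.tsv")
write_event_tsv(det$events, "results/session_events.tsv")
write_run_config(cfg, "results/run_config.yml")

cat(sprintf("session (seed %d): %d ground-truth bouts in %d events\n",
            cfg$seed, nrow(tb), length(ses$truth$events)))
cat(sprintf("detector: %d beats -> %d bouts -> %d events; PPV %.3f, sensitivity %.3f\n",
            length(det$beats), nrow(det$bouts), nrow(det$events),
            v$ppv, v$sensitivity))
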