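#!/usr/bin/env Rscript
# Step 2: detector validation against ground truth. 20 seeded 30-min
# sessions with locomotion and grooming confounders and baseline noise;
# detected bouts are matched to truth at 0.5 s and TP/FP/FN pooled into one
# positive predictive value and sensitivity.

library(scratchquant)

dir.create("results", showWarnings = FALSE)
cfg <- run_config(seed = 1L, out_dir = "results")

vs <- run_validation_suite(seeds = 1:20)
write_result_csv(vs$per_session, "results/validation_per_session.csv", cfg)

cat("per-session PPV range:",
    sprintf("%.3f-%.3f", min(vs$per_session$ppv), max(vs$per_session$ppv)), "\n")
cat(sprintf("pooled over %d sessions: PPV %.4f, sensitivity %.4f (%d TP, %d FP, %d FN)\n",
            nrow(vs$per_session), vs$pooled$ppv, vs$pooled$sensitivity,
            vs$pooled$tp, vs$pooled$fp, vs$pooled$fn))
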