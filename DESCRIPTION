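Package: scratchquant
Title: Automated Quantification and Dose-Response Analysis of Rodent Scratching Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of scratch bouts in induction-current recordings from
    magnet-implanted mice, and the downstream behavioral statistics. Scratch
    beats are extracted as 10-20 Hz oscillation cycles by band-pass filtering
    and envelope thresholding, assembled into bouts under an inter-beat-interval
    coefficient-of-variation rule, and grouped into paw-lift events. Companion
    simulators generate traces with exact ground-truth annotations and
    strain-by-pruritogen-by-dose cohort tables, so the detector can be scored by
    positive predictive value and the statistical workflow (Tukey-fence outlier
    removal, normality screening, repeated-measures ANOVA with Tukey HSD and a
    Wilcoxon fallback, dose-response summaries, cross-strain peak ratios and
    potency ranking with compact letter displays) can be exercised end to end
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    jsonlite,
    yaml,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
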