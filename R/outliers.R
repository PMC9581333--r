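#' Remove outliers by 2.2 x IQR Tukey fences
#'
#' Single-pass fences at `Q1 - k*IQR` and `Q3 + k*IQR` with `k = 2.2`
#' (Hoaglin--Iglewicz). Quartiles use linear-interpolation quantiles
#' (type 7) by default; `quartiles = "hinges"` switches to Tukey hinges
#' (`fivenum`). No re-fencing after removal.
#'
#' @param values Numeric vector, at least 4 values.
#' @param k Fence multiplier (default 2.2).
#' @param quartiles `"type7"` (linear interpolation) or `"hinges"`.
#' @return List with `kept`, `removed`, `fences` (length-2 numeric).
#' @export
remove_outliers <- function(values, k = 2.2, quartiles = c("type7", "hinges")) {
  quartiles <- match.arg(quartiles)
  if (length(values) < 4L) stop("too few for fences: need >= 4 values")
  q <- if (quartiles == "type7") {
    stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  } else {
    stats::fivenum(values)[c(2, 4)]
  }
  iqr <- q[2] - q[1]
  fences <- c(q[1] - k * iqr, q[2] + k * iqr)
  out <- values < fences[1] | values > fences[2]
  list(kept = values[!out], removed = values[out], fences = fences)
}

#' Apply per-cell outlier removal to a cohort table
#'
#' Fences are computed and applied independently within every
#' strain x pruritogen x dose cell; rows outside the fences are dropped.
#' Cells with fewer than 4 observations are left untouched.
#'
#' @param cohort Cohort table ([simulate_cohort()] schema).
#' @param value Name of the measured column (default `"bouts"`).
#' @inheritParams remove_outliers
#' @return The cohort table without outlying rows.
#' @export
remove_outliers_by_cell <- function(cohort, value = "bouts", k = 2.2,
                                    quartiles = c("type7", "hinges")) {
  quartiles <- match.arg(quartiles)
  cell <- interaction(cohort$strain, cohort$pruritogen, cohort$dose_fold,
                      drop = TRUE)
  keep <- rep(TRUE, nrow(cohort))
  for (cl in levels(cell)) {
    idx <- which(cell == cl)
    if (length(idx) < 4L) next
    v <- cohort[[value]][idx]
    res <- remove_outliers(v, k = k, quartiles = quartiles)
    keep[idx] <- v >= res$fences[1] & v <= res$fences[2]
  }
  cohort[keep, , drop = FALSE]
}
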