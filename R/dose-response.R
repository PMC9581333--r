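#' Build a dose--response summary table
#'
#' Per strain x pruritogen x dose cell: mean, SEM and n of the measured
#' response (outlier removal is assumed to have been applied per cell
#' beforehand, see [remove_outliers_by_cell()]). The peak dose of every
#' strain x pruritogen curve is the dose with the largest cell mean, ties
#' resolved to the lowest dose. Cells with a single animal get `sem = NA`
#' and are flagged rather than silently reported as 0.
#'
#' @param cohort Cohort table in long format ([simulate_cohort()] schema).
#' @param value Name of the response column (default `"bouts"`).
#' @param expected_doses Optional numeric vector; if given, every
#'   strain x pruritogen curve must have a non-empty cell at each of these
#'   doses.
#' @return `data.frame(strain, pruritogen, dose_fold, n, mean, sem,
#'   sem_defined, is_peak)`, class `dose_response`.
#' @export
build_dose_response <- function(cohort, value = "bouts", expected_doses = NULL) {
  cells <- unique(cohort[, c("strain", "pruritogen", "dose_fold")])
  cells <- cells[order(cells$strain, cells$pruritogen, cells$dose_fold), ]
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- cohort$strain == cells$strain[i] &
      cohort$pruritogen == cells$pruritogen[i] &
      cohort$dose_fold == cells$dose_fold[i]
    v <- cohort[[value]][sel]
    if (length(v) == 0L) stop("missing group: empty cell")
    rows[[i]] <- data.frame(
      strain = cells$strain[i], pruritogen = cells$pruritogen[i],
      dose_fold = cells$dose_fold[i], n = length(v), mean = mean(v),
      sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
      sem_defined = length(v) > 1L
    )
  }
  out <- do.call(rbind, rows)

  if (!is.null(expected_doses)) {
    curves <- unique(out[, c("strain", "pruritogen")])
    for (i in seq_len(nrow(curves))) {
      have <- out$dose_fold[out$strain == curves$strain[i] &
                              out$pruritogen == curves$pruritogen[i]]
      if (!all(expected_doses %in% have)) stop("missing group: absent dose cell")
    }
  }

  out$is_peak <- FALSE
  curves <- unique(out[, c("strain", "pruritogen")])
  for (i in seq_len(nrow(curves))) {
    idx <- which(out$strain == curves$strain[i] &
                   out$pruritogen == curves$pruritogen[i])
    mx <- max(out$mean[idx])
    peak <- idx[out$mean[idx] == mx]
    peak <- peak[which.min(out$dose_fold[peak])]   # ties -> lowest dose
    out$is_peak[peak] <- TRUE
  }
  rownames(out) <- NULL
  class(out) <- c("dose_response", "data.frame")
  out
}

#' As-is dose--response table from a group-mean table
#'
#' Wraps an already-summarized mean table (e.g. [default_group_table()])
#' into the [build_dose_response()] output schema so ratio and ranking
#' reports can run directly on printed group means.
#'
#' @param mean_table Table in the [default_group_table()] schema.
#' @return A `dose_response` table.
#' @export
dose_response_from_means <- function(mean_table) {
  out <- data.frame(
    strain = mean_table$strain, pruritogen = mean_table$pruritogen,
    dose_fold = mean_table$dose_fold, n = mean_table$n,
    mean = mean_table$mean_bouts, sem = mean_table$sem, sem_defined = TRUE
  )
  out$is_peak <- FALSE
  curves <- unique(out[, c("strain", "pruritogen")])
  for (i in seq_len(nrow(curves))) {
    idx <- which(out$strain == curves$strain[i] &
                   out$pruritogen == curves$pruritogen[i])
    mx <- max(out$mean[idx])
    peak <- idx[out$mean[idx] == mx]
    peak <- peak[which.min(out$dose_fold[peak])]
    out$is_peak[peak] <- TRUE
  }
  class(out) <- c("dose_response", "data.frame")
  out
}

#' Cross-strain peak-response ratio report
#'
#' For each pruritogen, takes the peak (max-over-dose) mean response in each
#' strain and expresses the resistant strain's peak as a percentage of the
#' sensitive strain's (`percent = 100 * peak_c3h / peak_c57`), together with
#' the reciprocal fold difference (`fold = peak_c57 / peak_c3h`). Raw values
#' are reported alongside the rounded ones used in prose (nearest-integer
#' percent, one-decimal fold).
#'
#' @param dr_ref `dose_response` table of the reference (sensitive) strain.
#' @param dr_cmp `dose_response` table of the comparison (resistant) strain.
#' @return `data.frame(pruritogen, peak_ref, peak_cmp, percent_raw, percent,
#'   fold_raw, fold)`.
#' @export
peak_ratio_report <- function(dr_ref, dr_cmp) {
  prs <- unique(dr_ref$pruritogen)
  rows <- list()
  for (pr in prs) {
    if (!pr %in% dr_cmp$pruritogen) stop("both tables must cover the pruritogen: ", pr)
    pk_ref <- max(dr_ref$mean[dr_ref$pruritogen == pr])
    pk_cmp <- max(dr_cmp$mean[dr_cmp$pruritogen == pr])
    if (pk_ref <= 0) stop("undefined ratio: zero reference peak for ", pr)
    rows[[pr]] <- data.frame(
      pruritogen = pr, peak_ref = pk_ref, peak_cmp = pk_cmp,
      percent_raw = 100 * pk_cmp / pk_ref,
      percent = round(100 * pk_cmp / pk_ref),
      fold_raw = pk_ref / pk_cmp,
      fold = round(pk_ref / pk_cmp, 1)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank pruritogens by potency with homogeneous-mean letters
#'
#' Each animal contributes its grand mean response across all doses; the
#' pruritogens are ranked by the group grand means (descending) and compared
#' by a one-way ANOVA across pruritogens on the per-animal grand means with
#' Tukey HSD, summarized as a compact letter display (shared letter =
#' homogeneous means).
#'
#' @param cohort Cohort table for one strain.
#' @param value Response column name.
#' @param alpha Significance level for the letter display.
#' @return `data.frame(pruritogen, grand_mean, n, rank, letters)` ordered by
#'   rank, with the Tukey HSD pair table in attribute `pairs`.
#' @export
rank_pruritogens <- function(cohort, value = "bouts", alpha = 0.05) {
  if (length(unique(cohort$pruritogen)) < 2L) stop("need >= 2 pruritogens")
  per_animal <- stats::aggregate(
    cohort[[value]],
    by = list(pruritogen = cohort$pruritogen, animal_id = cohort$animal_id),
    FUN = mean
  )
  names(per_animal)[3] <- "grand_mean"

  g <- factor(per_animal$pruritogen)
  fit <- stats::aov(grand_mean ~ g, data = per_animal)
  ms_error <- stats::deviance(fit) / stats::df.residual(fit)
  means <- tapply(per_animal$grand_mean, g, mean)
  ns <- as.integer(table(g))
  th <- tukey_hsd(means = means, n = ns, ms_error = ms_error,
                  df_error = stats::df.residual(fit), alpha = alpha)

  out <- data.frame(
    pruritogen = names(means), grand_mean = as.numeric(means), n = ns,
    letters = unname(th$letters)
  )
  out <- out[order(-out$grand_mean), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out <- out[, c("pruritogen", "grand_mean", "n", "rank", "letters")]
  attr(out, "pairs") <- th$pairs
  out
}
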