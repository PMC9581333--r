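#' Normality screening for one group
#'
#' Either Shapiro--Wilk (`stats::shapiro.test`) or the Lilliefors variant of
#' the Kolmogorov--Smirnov test with estimated mean and SD
#' (`nortest::lillie.test`). Both screens are offered because dose--response
#' workflows in this field report either; the default is Shapiro--Wilk.
#'
#' @param values Numeric vector, n >= 4, non-constant.
#' @param method `"shapiro_wilk"` or `"ks_lilliefors"`.
#' @return List with `statistic`, `p`, `method`.
#' @export
test_normality <- function(values, method = c("shapiro_wilk", "ks_lilliefors")) {
  method <- match.arg(method)
  if (length(values) < 4L) stop("need >= 4 values")
  if (stats::sd(values) == 0) stop("degenerate sample: constant input")
  ht <- if (method == "shapiro_wilk") {
    stats::shapiro.test(values)
  } else {
    nortest::lillie.test(values)
  }
  list(statistic = unname(ht$statistic), p = unname(ht$p.value), method = method)
}

#' Fraction of normally distributed groups, as a percentage
#'
#' Reporting utility for normality screens across many groups,
#' e.g. 47 normal groups out of 53 gives 88.68%.
#'
#' @param n_normal Number of groups passing the normality screen.
#' @param n_total Total number of groups screened.
#' @return Percentage (0--100), unrounded.
#' @export
normality_percent <- function(n_normal, n_total) {
  stopifnot(n_total > 0, n_normal >= 0, n_normal <= n_total)
  100 * n_normal / n_total
}

#' Screen every cell of a cohort table for normality
#'
#' @param cohort Cohort table ([simulate_cohort()] schema).
#' @param value Measured column name.
#' @param alpha Significance level of the screen.
#' @inheritParams test_normality
#' @return `data.frame(strain, pruritogen, dose_fold, n, statistic, p,
#'   normal)` with one row per cell (cells with n < 4 or constant values are
#'   skipped), plus attributes `n_normal`, `n_total`, `percent_normal`.
#' @export
screen_normality <- function(cohort, value = "bouts",
                             method = c("shapiro_wilk", "ks_lilliefors"),
                             alpha = 0.05) {
  method <- match.arg(method)
  cells <- unique(cohort[, c("strain", "pruritogen", "dose_fold")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- cohort$strain == cells$strain[i] &
      cohort$pruritogen == cells$pruritogen[i] &
      cohort$dose_fold == cells$dose_fold[i]
    v <- cohort[[value]][sel]
    if (length(v) < 4L || stats::sd(v) == 0) next
    ht <- test_normality(v, method)
    rows[[length(rows) + 1L]] <- data.frame(
      strain = cells$strain[i], pruritogen = cells$pruritogen[i],
      dose_fold = cells$dose_fold[i], n = length(v),
      statistic = ht$statistic, p = ht$p, normal = ht$p > alpha
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "n_normal") <- sum(out$normal)
  attr(out, "n_total") <- nrow(out)
  attr(out, "percent_normal") <- normality_percent(sum(out$normal), nrow(out))
  out
}
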