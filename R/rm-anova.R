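#' Repeated-measures ANOVA on a cohort table
#'
#' Classical univariate repeated-measures ANOVA with dose as the
#' within-subject factor: total variation is partitioned into subject,
#' within-factor and residual (subject x dose) sums of squares, and each
#' mouse serves as its own control across the four test days. Optionally a
#' between-subject factor (strain) is crossed with dose. Only complete
#' cases are analyzed: a subject that lost a dose to outlier removal is
#' dropped entirely. No sphericity correction is applied by default; the
#' Greenhouse--Geisser adjustment is available for within-only designs.
#'
#' @param data Cohort-style `data.frame` in long format.
#' @param value Name of the response column (default `"bouts"`).
#' @param within Name of the within-subject factor column (default
#'   `"dose_fold"`).
#' @param subject Name of the subject identifier column (default
#'   `"animal_id"`).
#' @param between Optional name of a between-subject factor column
#'   (e.g. `"strain"`), or `NULL`.
#' @param gg_correction If `TRUE` (within-only designs), Greenhouse--Geisser
#'   adjust the within-factor degrees of freedom.
#' @return An object of class `rm_anova`: list with `table` (term, df1, df2,
#'   F, p, and `p_gg` if requested), `ms_error`, `df_error`, `means`
#'   (within-level cell means), `n_per_level`, `n_subjects`, `data`
#'   (complete cases), and the design column names.
#' @export
rm_anova <- function(data, value = "bouts", within = "dose_fold",
                     subject = "animal_id", between = NULL,
                     gg_correction = FALSE) {
  d <- data.frame(
    y = as.numeric(data[[value]]),
    w = factor(data[[within]]),
    s = factor(data[[subject]])
  )
  if (!is.null(between)) d$b <- factor(data[[between]])
  d <- d[stats::complete.cases(d), , drop = FALSE]

  # complete cases: keep subjects observed exactly once at every within level
  k <- nlevels(d$w)
  tab <- table(d$s, d$w)
  complete <- rownames(tab)[apply(tab, 1, function(r) all(r == 1L))]
  d <- d[d$s %in% complete, , drop = FALSE]
  d$s <- droplevels(d$s)
  if (nlevels(d$s) < 2L) stop("underpowered design: fewer than 2 complete subjects")
  if (k < 2L) stop("underpowered design: fewer than 2 within levels")

  fit <- if (is.null(between)) {
    stats::aov(y ~ w + Error(s), data = d)
  } else {
    stats::aov(y ~ b * w + Error(s), data = d)
  }
  st <- summary(fit)

  pull <- function(stratum_tab, rowname) {
    tt <- stratum_tab[[1]]
    i <- match(rowname, trimws(rownames(tt)))
    c(df = tt[i, "Df"], ss = tt[i, "Sum Sq"], ms = tt[i, "Mean Sq"],
      F = if ("F value" %in% colnames(tt)) tt[i, "F value"] else NA_real_,
      p = if ("Pr(>F)" %in% colnames(tt)) tt[i, "Pr(>F)"] else NA_real_)
  }
  within_tab <- st[["Error: Within"]]
  res <- pull(within_tab, "Residuals")

  rows <- list()
  wrow <- pull(within_tab, "w")
  rows[[within]] <- data.frame(term = within, df1 = wrow["df"],
                               df2 = res["df"], F = wrow["F"], p = wrow["p"])
  if (!is.null(between)) {
    btab <- st[["Error: s"]]
    brow <- pull(btab, "b")
    bres <- pull(btab, "Residuals")
    rows[[between]] <- data.frame(term = between, df1 = brow["df"],
                                  df2 = bres["df"], F = brow["F"], p = brow["p"])
    irow <- pull(within_tab, "b:w")
    rows[["interaction"]] <- data.frame(
      term = paste0(between, ":", within), df1 = irow["df"],
      df2 = res["df"], F = irow["F"], p = irow["p"])
  }
  out_tab <- do.call(rbind, rows)
  rownames(out_tab) <- NULL

  if (gg_correction) {
    if (!is.null(between)) stop("Greenhouse-Geisser offered for within-only designs")
    eps <- gg_epsilon(d)
    out_tab$eps_gg <- NA_real_
    out_tab$p_gg <- NA_real_
    i <- out_tab$term == within
    out_tab$eps_gg[i] <- eps
    out_tab$p_gg[i] <- stats::pf(out_tab$F[i], eps * out_tab$df1[i],
                                 eps * out_tab$df2[i], lower.tail = FALSE)
  }

  means <- tapply(d$y, d$w, mean)
  structure(list(
    table = out_tab,
    ms_error = unname(res["ms"]), df_error = unname(res["df"]),
    means = means, n_per_level = as.integer(table(d$w)),
    n_subjects = nlevels(d$s), data = d,
    value = value, within = within, subject = subject, between = between
  ), class = "rm_anova")
}

# Greenhouse-Geisser epsilon from the double-centered within-subject
# covariance matrix.
gg_epsilon <- function(d) {
  Y <- tapply(d$y, list(d$s, d$w), mean)
  S <- stats::cov(Y)
  k <- ncol(S)
  Sc <- sweep(S, 1, rowMeans(S))
  Sc <- sweep(Sc, 2, colMeans(S))
  Sc <- Sc + mean(S)
  sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (", x$n_subjects, " complete subjects, ",
      length(x$means), " within levels)\n", sep = "")
  print(x$table, row.names = FALSE)
  cat("Residual MS:", format(x$ms_error), "on", x$df_error, "df\n")
  invisible(x)
}
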