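#' Default strain x pruritogen x dose group-mean table
#'
#' Per-cell mean scratch-bout counts, SEMs and group sizes for the two
#' strains (scratch-sensitive C57BL/6J, resistant C3H/HeJ), seven
#' pruritogens and four dose folds. Cells whose values were reported in the
#' source study carry `source = "printed"`; the remaining cells are
#' synthetic defaults (log-dose interpolation between printed anchors where
#' bracketed, curve-shape-consistent fill otherwise, SEM defaulting to 25%
#' of the mean) flagged `source = "synthetic-default"` — they parameterize
#' simulations but carry no evidential weight.
#'
#' @return `data.frame(strain, pruritogen, dose_fold, mean_bouts, sem, n,
#'   source)`.
#' @export
default_group_table <- function() {
  path <- system.file("extdata", "default_group_means.csv",
                      package = "scratchquant", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Specify a simulated cohort
#'
#' Defines the strain x pruritogen x dose design of a simulated cohort in
#' the study's repeated-measures layout: each animal is tested at every dose
#' of its pruritogen on separate days (dose order 3, 1, 10, 0.3-fold on days
#' 1, 3, 5, 8, lowest dose last to expose sensitization).
#'
#' @param strains Character vector of strains to include.
#' @param pruritogens Character vector of pruritogens to include.
#' @param dose_folds Numeric, ascending dose folds.
#' @param n_per_group Animals per strain x pruritogen group; `NULL` uses the
#'   group sizes of `mean_table`. Must be >= 2.
#' @param mean_table Group-mean table in the [default_group_table()] schema.
#' @param sex_ratio Fraction of females per group.
#' @param count_model `"negative_binomial"` (overdispersed counts, the
#'   default) or `"lognormal_rounded"`.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(strains = c("C57", "C3H"),
                        pruritogens = unique(default_group_table()$pruritogen),
                        dose_folds = c(0.3, 1, 3, 10),
                        n_per_group = NULL,
                        mean_table = default_group_table(),
                        sex_ratio = 0.5,
                        count_model = c("negative_binomial", "lognormal_rounded"),
                        seed = 1L) {
  count_model <- match.arg(count_model)
  stopifnot(
    !is.unsorted(dose_folds), all(dose_folds > 0),
    all(mean_table$mean_bouts >= 0), all(mean_table$sem > 0),
    sex_ratio >= 0, sex_ratio <= 1
  )
  if (!is.null(n_per_group) && n_per_group < 2) stop("degenerate group: n_per_group < 2")
  structure(list(
    strains = strains, pruritogens = pruritogens, dose_folds = dose_folds,
    n_per_group = n_per_group, mean_table = mean_table,
    sex_ratio = sex_ratio, count_model = count_model, seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Dose order of the experimental protocol: test day by dose fold.
dose_day <- function(dose_fold) {
  unname(c(`3` = 1L, `1` = 3L, `10` = 5L, `0.3` = 8L)[as.character(dose_fold)])
}

#' Simulate a per-animal cohort table
#'
#' One row per animal x dose in repeated-measures layout. Bout counts are
#' drawn independently per cell from the spec's count model matched to the
#' cell's mean and SD (SD = SEM * sqrt(n) of the mean table). Event counts
#' and scratch time are derived from the bout count with multiplicative
#' noise, mirroring how the three session metrics share one underlying
#' behavioral driver.
#'
#' @param spec A [cohort_spec()] object.
#' @return `data.frame(animal_id, strain, sex, pruritogen, dose_fold, day,
#'   bouts, events, scratch_time_s)`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  mt <- spec$mean_table
  rows <- list()
  for (st in spec$strains) {
    for (pr in spec$pruritogens) {
      cells <- mt[mt$strain == st & mt$pruritogen == pr &
                    mt$dose_fold %in% spec$dose_folds, , drop = FALSE]
      if (nrow(cells) == 0L) next
      n <- if (is.null(spec$n_per_group)) cells$n[1] else spec$n_per_group
      if (n < 2) stop("degenerate group: n < 2")
      n_f <- round(n * spec$sex_ratio)
      sexes <- sample(c(rep("f", n_f), rep("m", n - n_f)))
      ids <- sprintf("%s_%s_%02d", st, gsub("[^A-Za-z0-9]", "", pr), seq_len(n))
      for (d in sort(spec$dose_folds)) {
        cell <- cells[cells$dose_fold == d, , drop = FALSE]
        if (nrow(cell) == 0L) next
        mu <- cell$mean_bouts
        sd_cell <- cell$sem * sqrt(cell$n)
        counts <- draw_counts(n, mu, sd_cell, spec$count_model)
        bpe <- stats::runif(n, 2, 4)             # bouts per event
        dur <- pmax(stats::rnorm(n, 1.1, 0.15), 0.3)  # mean bout duration (s)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = ids, strain = st, sex = sexes, pruritogen = pr,
          dose_fold = d, day = dose_day(d),
          bouts = counts,
          events = as.integer(pmax(round(counts / bpe), as.integer(counts > 0))),
          scratch_time_s = pmin(counts * dur, 1800)
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Draw n counts with the given mean and SD under the chosen count model.
# Degenerate dispersion collapses to round(mean); a variance at or below the
# mean has no negative-binomial parameterization and falls back to Poisson.
draw_counts <- function(n, mu, sd_cell, model) {
  if (sd_cell <= 1e-8) return(rep(round(mu), n))
  v <- sd_cell^2
  if (model == "negative_binomial") {
    if (v > mu) {
      size <- mu^2 / (v - mu)
      stats::rnbinom(n, mu = mu, size = size)
    } else {
      stats::rpois(n, mu)
    }
  } else {
    sdlog2 <- log(1 + v / mu^2)
    meanlog <- log(mu) - sdlog2 / 2
    pmax(round(stats::rlnorm(n, meanlog, sqrt(sdlog2))), 0)
  }
}
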