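#' Tukey HSD post hoc comparisons with compact letter display
#'
#' Studentized-range adjusted p-values for all level pairs, using the
#' repeated-measures residual mean square as error term (Tukey--Kramer
#' standard error for unequal n). Levels are then labeled with a compact
#' letter display: levels sharing a letter have homogeneous means (no
#' pairwise difference at `alpha`).
#'
#' @param fit An [rm_anova()] object, or `NULL` if the pieces are passed
#'   directly.
#' @param means Named numeric vector of level means (taken from `fit` when
#'   given).
#' @param n Integer vector of per-level sample sizes (recycled).
#' @param ms_error Error mean square (must be positive).
#' @param df_error Error degrees of freedom.
#' @param alpha Significance level for the letter display.
#' @return List with `pairs` (`data.frame(level_i, level_j, diff, q, p_adj)`)
#'   and `letters` (named character vector per level).
#' @export
tukey_hsd <- function(fit = NULL, means = NULL, n = NULL,
                      ms_error = NULL, df_error = NULL, alpha = 0.05) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "rm_anova"))
    means <- fit$means
    n <- fit$n_per_level
    ms_error <- fit$ms_error
    df_error <- fit$df_error
  }
  if (is.null(ms_error) || ms_error <= 0) stop("invalid error term: ms_error <= 0")
  k <- length(means)
  stopifnot(k >= 2L, df_error > 0)
  n <- rep_len(n, k)
  lev <- names(means)
  if (is.null(lev)) lev <- as.character(seq_len(k))

  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(ms_error / 2 * (1 / n[i] + 1 / n[j]))
    q <- abs(means[i] - means[j]) / se
    data.frame(level_i = lev[i], level_j = lev[j],
               diff = unname(means[i] - means[j]), q = unname(q),
               p_adj = stats::ptukey(q, nmeans = k, df = df_error,
                                     lower.tail = FALSE))
  })
  pairs_df <- do.call(rbind, rows)
  rownames(pairs_df) <- NULL

  nonsig <- matrix(TRUE, k, k, dimnames = list(lev, lev))
  for (r in seq_len(nrow(pairs_df))) {
    ns <- pairs_df$p_adj[r] > alpha
    nonsig[pairs_df$level_i[r], pairs_df$level_j[r]] <- ns
    nonsig[pairs_df$level_j[r], pairs_df$level_i[r]] <- ns
  }
  list(pairs = pairs_df, letters = compact_letters(means, nonsig))
}

#' Compact letter display from a non-significance relation
#'
#' Levels are sorted by decreasing mean; every maximal set of consecutive
#' levels that are all mutually non-significant receives one letter, and a
#' level's label is the concatenation of the letters of the sets containing
#' it. With a distance-monotone post hoc test the non-significant sets are
#' contiguous in mean order, so maximal runs cover all homogeneous sets.
#'
#' @param means Named numeric vector of level means.
#' @param nonsig Logical k x k matrix, `TRUE` where a pair is not
#'   significantly different (dimnames must name the levels).
#' @return Named character vector of letter labels, in the order of `means`.
#' @export
compact_letters <- function(means, nonsig) {
  lev <- names(means)
  ord <- order(-means)
  k <- length(lev)
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k) {
      block <- ord[i:(j + 1)]
      if (all(nonsig[block, block])) j <- j + 1 else break
    }
    runs[[length(runs) + 1L]] <- i:j
  }
  # drop runs contained in another
  maximal <- runs[!vapply(seq_along(runs), function(a) {
    any(vapply(seq_along(runs), function(b) {
      b != a && all(runs[[a]] %in% runs[[b]])
    }, logical(1)))
  }, logical(1))]
  maximal <- unique(maximal)

  labels <- stats::setNames(rep("", k), lev[ord])
  for (m in seq_along(maximal)) {
    lt <- letters[(m - 1) %% 26 + 1]
    if (m > 26) lt <- paste0(lt, (m - 1) %/% 26)
    for (i in maximal[[m]]) {
      labels[i] <- paste0(labels[i], lt)
    }
  }
  labels[lev]
}
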