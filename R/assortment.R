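#' Pearson correlation of paired scores
#'
#' Plain product-moment correlation, with explicit failure on degenerate
#' input rather than an `NA` surprise downstream.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return Correlation in `[-1, 1]`, or `NA` with attribute `reason` when
#'   undefined (too short or constant input).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    return(structure(NA_real_, reason = "fewer than 3 complete pairs"))
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(structure(NA_real_, reason = "constant input"))
  stats::cor(x, y)
}

#' Fisher-z confidence interval for a correlation
#'
#' `z = atanh(r)` is approximately normal with standard error
#' `1 / sqrt(n - 3)`; the interval is `tanh(z -+ z_alpha / sqrt(n - 3))`.
#' This reproduces, at 2-decimal rounding, the intervals printed alongside
#' spouse-PC correlations in the family studies this package emulates.
#'
#' @param r correlation with `|r| < 1` (`|r| = 1` returns the degenerate
#'   interval `(r, r)` with a warning).
#' @param n number of pairs, `n >= 4`.
#' @param level confidence level (default 0.95).
#' @return Numeric `c(ci_low, ci_high)`.
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  if (n < 4) stop("need n >= 4 for a Fisher-z interval")
  if (abs(r) > 1) stop("|r| > 1")
  if (abs(r) == 1) {
    warning("|r| = 1: degenerate interval")
    return(c(ci_low = r, ci_high = r))
  }
  z <- atanh(r)
  hw <- qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  c(ci_low = tanh(z - hw), ci_high = tanh(z + hw))
}

#' Two-sided p-value for a correlation (t-test)
#'
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` referred to a Student t
#' distribution with `n - 2` degrees of freedom.
#'
#' @param r correlation, `|r| <= 1` (`|r| = 1` gives p = 0 exactly).
#' @param n number of pairs, `n >= 3`.
#' @return Two-sided p-value.
#' @export
correlation_pvalue <- function(r, n) {
  if (n < 3) stop("need n >= 3")
  if (abs(r) > 1) stop("|r| > 1")
  if (abs(r) == 1) return(0)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * pt(abs(t), df = n - 2, lower.tail = FALSE)
}

#' Per-PC spouse correlation table
#'
#' The workhorse behind the publication-style summary: for each stratum
#' and each requested PC, the Pearson correlation between husbands' and
#' wives' scores (husband scores are the x vector by convention), with a
#' Fisher-z confidence interval and a t-test p-value. Strata with fewer
#' than 4 pairs get an `NA` interval and are flagged in `note`.
#'
#' @param pairs a `spouse_pair_set`, or a named list of them (one table row
#'   block per stratum). A bare pair set is treated as stratum `"all"`.
#' @param pc a `pc_result` whose score rows cover the pair members; pairs
#'   with either member missing from the scores are dropped and counted in
#'   attribute `n_dropped_no_scores`.
#' @param pcs integer PC indices (default 1:6).
#' @param level confidence level for the intervals.
#' @return A `correlation_table` data.frame with columns `stratum`, `pc`,
#'   `n_pairs`, `r`, `ci_low`, `ci_high`, `p_value`, `note`.
#' @export
spouse_pc_table <- function(pairs, pc, pcs = 1:6, level = 0.95) {
  if (inherits(pairs, "spouse_pair_set")) pairs <- list(all = pairs)
  stopifnot(is.list(pairs), !is.null(names(pairs)))
  pcs <- pcs[pcs <= ncol(pc$scores)]
  if (!length(pcs)) stop("no requested PC present in the score matrix")
  dropped <- 0L
  rows <- list()
  for (st in names(pairs)) {
    p <- pairs[[st]]
    have <- p$male_id %in% rownames(pc$scores) & p$female_id %in% rownames(pc$scores)
    dropped <- dropped + sum(!have)
    p <- p[have, , drop = FALSE]
    for (j in pcs) {
      x <- pc$scores[p$male_id, j]
      y <- pc$scores[p$female_id, j]
      n <- nrow(p)
      r <- pearson_r(x, y)
      note <- ""
      if (is.na(r)) {
        note <- attr(r, "reason") %||% "undefined"
        ci <- c(NA_real_, NA_real_); pv <- NA_real_
      } else if (n < 4) {
        note <- "fewer than 4 pairs: no CI"
        ci <- c(NA_real_, NA_real_)
        pv <- correlation_pvalue(r, n)
      } else {
        ci <- fisher_ci(r, n, level)
        pv <- correlation_pvalue(r, n)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, pc = j, n_pairs = n, r = as.numeric(r),
        ci_low = ci[[1]], ci_high = ci[[2]], p_value = pv, note = note,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("correlation_table", "data.frame")
  attr(out, "n_dropped_no_scores") <- dropped
  attr(out, "level") <- level
  out
}
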