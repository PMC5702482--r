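#' Random within-ethnicity heterosexual pairing
#'
#' Within each ethnicity group, males and females are independently
#' shuffled and matched positionally without replacement, producing
#' `min(n_male, n_female)` pairs per group. Leftover singles are dropped
#' and counted; a group containing only one sex contributes zero pairs,
#' with a warning. Individuals of unknown sex must be removed from the
#' candidate table beforehand (see [null_candidates()]).
#'
#' @param candidates data.frame with columns `individual_id`, `sex`
#'   (`"male"`/`"female"`), `group` (ethnicity label).
#' @param seed optional integer seed.
#' @return data.frame `male_id`, `female_id`, `group`, with attribute
#'   `n_dropped`.
#' @export
random_pairing <- function(candidates, seed = NULL) {
  stopifnot(all(c("individual_id", "sex", "group") %in% names(candidates)))
  if (!all(candidates$sex %in% c("male", "female")))
    stop("candidates must have sex 'male' or 'female' only")
  if (!is.null(seed)) set.seed(seed)
  out <- list(); n_drop <- 0L
  for (g in unique(candidates$group)) {
    males <- candidates$individual_id[candidates$group == g & candidates$sex == "male"]
    females <- candidates$individual_id[candidates$group == g & candidates$sex == "female"]
    if (!length(males) || !length(females)) {
      warning(sprintf("group '%s' has a single sex; contributes no pairs", g))
      n_drop <- n_drop + length(males) + length(females)
      next
    }
    k <- min(length(males), length(females))
    n_drop <- n_drop + length(males) + length(females) - 2L * k
    ms <- if (length(males) == 1L) males else sample(males)
    fs <- if (length(females) == 1L) females else sample(females)
    out[[length(out) + 1L]] <- data.frame(male_id = ms[seq_len(k)],
                                          female_id = fs[seq_len(k)],
                                          group = g, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(male_id = character(), female_id = character(), group = character())
  rownames(res) <- NULL
  attr(res, "n_dropped") <- n_drop
  res
}

#' Candidate pool for the pairing null
#'
#' Convenience builder: restricts a pedigree to one generation, attaches an
#' ethnicity label per individual, and drops unknown-sex or unlabeled
#' individuals (counts attached as attribute `n_excluded`).
#'
#' @param pedigree a [pedigree_table()].
#' @param labels named character vector (individual id -> ethnicity label),
#'   e.g. from [assign_quadrant_labels()]; `"unassigned"` and `NA` are
#'   excluded.
#' @param generation optional generation label to restrict to.
#' @return data.frame `individual_id`, `sex`, `group`.
#' @export
null_candidates <- function(pedigree, labels, generation = NULL) {
  df <- data.frame(individual_id = pedigree$individual_id, sex = pedigree$sex,
                   generation = pedigree$generation, stringsAsFactors = FALSE)
  if (!is.null(generation)) df <- df[df$generation %in% generation, , drop = FALSE]
  df$group <- unname(labels[df$individual_id])
  n0 <- nrow(df)
  df <- df[df$sex %in% c("male", "female") & !is.na(df$group) &
             df$group != "unassigned", c("individual_id", "sex", "group")]
  rownames(df) <- NULL
  attr(df, "n_excluded") <- n0 - nrow(df)
  df
}

#' Null distribution of spouse-PC correlations under random pairing
#'
#' Repeats [random_pairing()] `n_replicates` times; in each replicate the
#' per-PC Pearson correlation is computed over all groups' pairs pooled,
#' and the replicate values are summarized by their mean and the empirical
#' 2.5th / 97.5th percentiles (order statistics with linear interpolation).
#'
#' @param candidates data.frame as for [random_pairing()].
#' @param pc a `pc_result` covering every candidate.
#' @param pcs integer PC indices (default `1:2`).
#' @param n_replicates number of replicates (default 1000).
#' @param seed integer seed; the whole summary is reproducible from it.
#' @param level quantile-interval coverage (default 0.95).
#' @return An object of class `null_summary`: data.frame `summary`
#'   (`pc`, `mean_r`, `quantile_low`, `quantile_high`), matrix
#'   `replicates` (`n_replicates` x length(pcs)), `n_pairs_per_replicate`,
#'   `n_replicates`, `seed`.
#' @export
null_distribution <- function(candidates, pc, pcs = 1:2, n_replicates = 1000L,
                              seed = 1L, level = 0.95) {
  miss <- setdiff(candidates$individual_id, rownames(pc$scores))
  if (length(miss))
    stop("candidates without scores: ", paste(head(miss, 5), collapse = ", "))
  if (any(pcs > ncol(pc$scores))) stop("requested PC beyond score columns")
  set.seed(seed)
  reps <- matrix(NA_real_, n_replicates, length(pcs),
                 dimnames = list(NULL, paste0("PC", pcs)))
  n_pairs <- NA_integer_
  for (b in seq_len(n_replicates)) {
    pr <- suppressWarnings(random_pairing(candidates))
    if (nrow(pr) < 4L)
      stop(sprintf("replicate %d produced %d pooled pairs (< 4): check the pool", b, nrow(pr)))
    if (b == 1L) n_pairs <- nrow(pr)
    xs <- pc$scores[pr$male_id, pcs, drop = FALSE]
    ys <- pc$scores[pr$female_id, pcs, drop = FALSE]
    for (j in seq_along(pcs)) reps[b, j] <- pearson_r(xs[, j], ys[, j])
  }
  alpha <- (1 - level) / 2
  qs <- apply(reps, 2, quantile, probs = c(alpha, 1 - alpha), type = 7, names = FALSE)
  summ <- data.frame(pc = pcs, mean_r = colMeans(reps),
                     quantile_low = qs[1, ], quantile_high = qs[2, ])
  rownames(summ) <- NULL
  structure(list(summary = summ, replicates = reps,
                 n_pairs_per_replicate = n_pairs,
                 n_replicates = n_replicates, seed = seed, level = level),
            class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf("<null_summary> %d replicates, %d pairs each\n",
              x$n_replicates, x$n_pairs_per_replicate))
  print(x$summary)
  invisible(x)
}

#' Compare observed spouse correlations to the pairing null
#'
#' For each PC present in both inputs: the observed r, the null mean and
#' quantile interval, a flag `exceeds_null` (observed r strictly above the
#' upper quantile), and the empirical exceedance proportion (fraction of
#' null replicates at or above the observed r).
#'
#' @param observed a `correlation_table` (one stratum) from
#'   [spouse_pc_table()].
#' @param null a `null_summary` from [null_distribution()].
#' @return data.frame `pc`, `observed_r`, `null_mean`, `quantile_low`,
#'   `quantile_high`, `exceeds_null`, `exceedance`.
#' @export
compare_observed_to_null <- function(observed, null) {
  pcs <- null$summary$pc
  obs_pcs <- unique(observed$pc)
  if (!setequal(intersect(pcs, obs_pcs), pcs))
    stop("PCs in the null are missing from the observed table")
  rows <- lapply(seq_along(pcs), function(i) {
    j <- pcs[i]
    o <- observed[observed$pc == j, , drop = FALSE]
    if (nrow(o) != 1) stop("observed table must have exactly one row per PC")
    data.frame(pc = j, observed_r = o$r,
               null_mean = null$summary$mean_r[i],
               quantile_low = null$summary$quantile_low[i],
               quantile_high = null$summary$quantile_high[i],
               exceeds_null = o$r > null$summary$quantile_high[i],
               exceedance = mean(null$replicates[, i] >= o$r))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
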