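#' Identify spouse pairs from a pedigree via in-common children
#'
#' A couple (father, mother) is emitted when at least one child record
#' names both of them, both have pedigree rows with consistent sexes, and
#' both are genotyped. Multiple children of the same couple collapse to one
#' pair carrying the child count. When an individual parented children with
#' two partners (remarriage), only the pair with more in-common children is
#' kept (ties broken by the lexicographically smaller partner id), so no
#' individual appears in two pairs.
#'
#' Exclusions are counted in the attribute `exclusions`: children with a
#' missing parent sentinel, parents without a pedigree row, sex-inconsistent
#' parent records, ungenotyped parents, and remarriage conflicts.
#'
#' @param pedigree a [pedigree_table()].
#' @param genotyped_ids character vector of genotyped individual ids.
#' @return A `spouse_pair_set` data.frame: `male_id`, `female_id`,
#'   `generation` (the parents'), `site_male`, `site_female`,
#'   `n_common_children`.
#' @export
find_spouse_pairs <- function(pedigree, genotyped_ids) {
  stopifnot(inherits(pedigree, "pedigree_table"))
  excl <- c(missing_parent = 0L, parent_not_in_pedigree = 0L,
            sex_inconsistent = 0L, not_genotyped = 0L, remarriage = 0L)
  idx <- setNames(seq_len(nrow(pedigree)), pedigree$individual_id)

  kids <- pedigree[pedigree$father_id != "0" | pedigree$mother_id != "0", , drop = FALSE]
  cand <- list()
  for (i in seq_len(nrow(kids))) {
    f <- kids$father_id[i]; m <- kids$mother_id[i]
    if (f == "0" || m == "0") { excl["missing_parent"] <- excl["missing_parent"] + 1L; next }
    fi <- idx[f]; mi <- idx[m]
    if (is.na(fi) || is.na(mi)) { excl["parent_not_in_pedigree"] <- excl["parent_not_in_pedigree"] + 1L; next }
    if (pedigree$sex[fi] == "female" || pedigree$sex[mi] == "male") {
      excl["sex_inconsistent"] <- excl["sex_inconsistent"] + 1L; next
    }
    if (!(f %in% genotyped_ids) || !(m %in% genotyped_ids)) {
      excl["not_genotyped"] <- excl["not_genotyped"] + 1L; next
    }
    cand[[length(cand) + 1L]] <- c(f, m)
  }
  if (!length(cand)) {
    out <- new_spouse_pair_set(data.frame(male_id = character(), female_id = character(),
                                          generation = character(), site_male = character(),
                                          site_female = character(),
                                          n_common_children = integer()))
    attr(out, "exclusions") <- excl
    return(out)
  }
  key <- vapply(cand, paste, "", collapse = "\r")
  tab <- table(key)
  uniq <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
  df <- data.frame(male_id = uniq[, 1], female_id = uniq[, 2],
                   n_common_children = as.integer(tab), stringsAsFactors = FALSE)

  # first-spouse rule: more children wins, then smaller partner id
  df <- df[order(-df$n_common_children, df$male_id, df$female_id), , drop = FALSE]
  used <- character(0)
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (df$male_id[i] %in% used || df$female_id[i] %in% used) {
      excl["remarriage"] <- excl["remarriage"] + 1L
      next
    }
    keep[i] <- TRUE
    used <- c(used, df$male_id[i], df$female_id[i])
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$male_id, df$female_id), , drop = FALSE]

  fi <- idx[df$male_id]; mi <- idx[df$female_id]
  gen_f <- pedigree$generation[fi]; gen_m <- pedigree$generation[mi]
  mism <- !is.na(gen_f) & !is.na(gen_m) & gen_f != gen_m
  if (any(mism))
    warning(sprintf("%d pair(s) with differing parent generation labels; using the father's", sum(mism)))
  df$generation <- ifelse(is.na(gen_f), gen_m, gen_f)
  df$site_male <- pedigree$site[fi]
  df$site_female <- pedigree$site[mi]
  out <- new_spouse_pair_set(df)
  attr(out, "exclusions") <- excl
  out
}

#' Assign PC-quadrant ethnicity labels
#'
#' Using sign-oriented scores (see [orient_signs()]): `"East"` iff
#' PC1 < 0 and PC2 < 0, `"North"` iff PC1 > 0 and PC2 < 0, otherwise
#' `"unassigned"`. A score of exactly zero on PC1 or PC2 yields
#' `"unassigned"` and is counted in attribute `n_zero_scores`.
#'
#' @param pc an oriented `pc_result` with at least two score columns.
#' @return Named character vector (individual id -> label).
#' @export
assign_quadrant_labels <- function(pc) {
  if (ncol(pc$scores) < 2L) stop("need at least PC1 and PC2")
  p1 <- pc$scores[, 1]; p2 <- pc$scores[, 2]
  lab <- rep("unassigned", length(p1))
  lab[p1 < 0 & p2 < 0] <- "East"
  lab[p1 > 0 & p2 < 0] <- "North"
  n_zero <- sum((p1 == 0 | p2 == 0))
  if (n_zero) am_log("assign_quadrant_labels: %d exact-zero score(s) left unassigned", n_zero)
  out <- setNames(lab, rownames(pc$scores))
  attr(out, "n_zero_scores") <- n_zero
  out
}

#' Stratify spouse pairs by a tag, with an exclude-site complement
#'
#' Splits a pair set into disjoint subsets by `generation` or `site`
#' (pairs whose members disagree on site fall in `"mixed"`; missing tags in
#' `"unknown"`, with a warning). When `exclude_site` is given, an
#' additional subset `excluding-<site>` holds every pair in which *neither*
#' member was enrolled at that site.
#'
#' @param pairs a `spouse_pair_set`.
#' @param by `"generation"` or `"site"`.
#' @param exclude_site optional site label to form the complement subset.
#' @return Named list of `spouse_pair_set` subsets; the `by`-subsets are
#'   disjoint and their sizes sum to `nrow(pairs)`.
#' @export
stratify_pairs <- function(pairs, by = c("generation", "site"), exclude_site = NULL) {
  by <- match.arg(by)
  tag <- if (by == "generation") {
    pairs$generation
  } else {
    ifelse(is.na(pairs$site_male) | is.na(pairs$site_female), NA_character_,
           ifelse(pairs$site_male == pairs$site_female, pairs$site_male, "mixed"))
  }
  unknown <- is.na(tag)
  if (any(unknown)) {
    warning(sprintf("%d pair(s) with unknown %s put in an 'unknown' bucket", sum(unknown), by))
    tag[unknown] <- "unknown"
  }
  out <- lapply(split(seq_len(nrow(pairs)), tag), function(i) pairs[i, , drop = FALSE])
  if (!is.null(exclude_site)) {
    keep <- !(pairs$site_male %in% exclude_site) & !(pairs$site_female %in% exclude_site)
    out[[paste0("excluding-", exclude_site)]] <- pairs[keep, , drop = FALSE]
  }
  lapply(out, function(p) { class(p) <- c("spouse_pair_set", "data.frame"); p })
}
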