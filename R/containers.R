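#' Genotype matrix container
#'
#' Holds a samples x SNPs dosage matrix together with its SNP map and sample
#' identifiers. Dosages count copies of `allele2` (the alternate/minor
#' orientation recorded in the map) and are 0, 1, 2 or `NA` for missing;
#' missingness is always represented by `NA`, never by a numeric sentinel.
#'
#' @param dosages integer matrix, samples in rows, SNPs in columns; values
#'   in \{0, 1, 2, NA\}.
#' @param sample_ids character vector of unique sample identifiers, one per
#'   row of `dosages`.
#' @param snp_map data.frame with one row per SNP and columns `chrom`,
#'   `id`, `pos` (1-based), `allele1`, `allele2`. SNP `id`s must be unique.
#' @return An object of class `genotype_matrix`.
#' @examples
#' g <- genotype_matrix(matrix(c(0L, 1L, 2L, NA), 2, 2),
#'                      c("s1", "s2"),
#'                      data.frame(chrom = 1L, id = c("rs1", "rs2"),
#'                                 pos = c(100L, 200L),
#'                                 allele1 = "A", allele2 = "G"))
#' n_samples(g); n_snps(g)
#' @export
genotype_matrix <- function(dosages, sample_ids, snp_map) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  stopifnot(is.character(sample_ids), length(sample_ids) == nrow(dosages))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ", paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  req <- c("chrom", "id", "pos", "allele1", "allele2")
  if (!all(req %in% names(snp_map)))
    stop("snp_map must have columns ", paste(req, collapse = ", "))
  if (nrow(snp_map) != ncol(dosages))
    stop("snp_map rows (", nrow(snp_map), ") != dosage columns (", ncol(dosages), ")")
  if (anyDuplicated(snp_map$id))
    stop("duplicate SNP ids")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA")
  rownames(dosages) <- sample_ids
  colnames(dosages) <- snp_map$id
  structure(list(dosages = dosages, sample_ids = sample_ids,
                 snp_map = as.data.frame(snp_map, stringsAsFactors = FALSE)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs, %.2f%% missing\n",
              n_samples(x), n_snps(x),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param g a `genotype_matrix`.
#' @export
n_samples <- function(g) nrow(g$dosages)

#' @rdname genotype_matrix
#' @export
n_snps <- function(g) ncol(g$dosages)

#' Subset a genotype matrix by SNP index or by sample id
#'
#' @param g a `genotype_matrix`.
#' @param snps integer or logical index into SNP columns (map order).
#' @param samples character sample ids or integer/logical row index.
#' @return A new `genotype_matrix`.
#' @export
subset_genotypes <- function(g, snps = NULL, samples = NULL) {
  d <- g$dosages
  map <- g$snp_map
  ids <- g$sample_ids
  if (!is.null(snps)) {
    d <- d[, snps, drop = FALSE]
    map <- map[snps, , drop = FALSE]
    rownames(map) <- NULL
  }
  if (!is.null(samples)) {
    if (is.character(samples)) {
      miss <- setdiff(samples, ids)
      if (length(miss)) stop("unknown sample ids: ", paste(head(miss, 5), collapse = ", "))
      samples <- match(samples, ids)
    }
    d <- d[samples, , drop = FALSE]
    ids <- ids[samples]
  }
  genotype_matrix(d, ids, map)
}

#' Combine two genotype matrices over the same SNP map
#'
#' @param a,b `genotype_matrix` objects sharing an identical SNP map.
#' @return A `genotype_matrix` with the samples of `a` followed by `b`.
#' @export
rbind_genotypes <- function(a, b) {
  if (!identical(a$snp_map$id, b$snp_map$id))
    stop("SNP maps differ; cannot combine")
  genotype_matrix(rbind(a$dosages, b$dosages), c(a$sample_ids, b$sample_ids), a$snp_map)
}

#' Pedigree table
#'
#' Per-individual pedigree records. Required columns are `family_id` and
#' `individual_id`; `father_id` and `mother_id` use the sentinel `"0"` when
#' unknown, `sex` is one of `"male"`, `"female"`, `"unknown"`. Optional
#' metadata columns `generation`, `site` and `ethnicity` are carried along
#' (filled with `NA` when absent).
#'
#' @param df data.frame of per-individual records.
#' @return A data.frame of class `pedigree_table` with canonical columns.
#' @export
pedigree_table <- function(df) {
  req <- c("family_id", "individual_id")
  if (!all(req %in% names(df))) stop("pedigree needs family_id and individual_id")
  opt <- c(father_id = "0", mother_id = "0", sex = "unknown",
           generation = NA_character_, site = NA_character_,
           ethnicity = NA_character_)
  for (nm in names(opt)) if (!nm %in% names(df)) df[[nm]] <- opt[[nm]]
  df <- df[, c(req, names(opt))]
  for (nm in names(df)) df[[nm]] <- as.character(df[[nm]])
  df$sex[is.na(df$sex)] <- "unknown"
  if (!all(df$sex %in% c("male", "female", "unknown")))
    stop("sex must be male, female or unknown")
  key <- paste(df$family_id, df$individual_id)
  if (anyDuplicated(key))
    stop("individual_id must be unique within family")
  rownames(df) <- NULL
  class(df) <- c("pedigree_table", "data.frame")
  df
}
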