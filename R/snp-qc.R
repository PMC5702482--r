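#' Quality-control parameters for SNP selection
#'
#' Defaults follow common GWAS practice for ancestry PCA: SNPs must have a
#' call rate strictly above 0.95 and a minor allele frequency strictly
#' above 0.05, then pairwise LD pruning runs in 50-SNP windows advancing 5
#' SNPs at a time, removing the later SNP of any kept pair with
#' r-squared above 0.30.
#'
#' @param min_call_rate fraction in (0, 1); SNPs kept iff call rate
#'   strictly exceeds it.
#' @param min_maf fraction in (0, 1); SNPs kept iff MAF strictly exceeds it.
#' @param prune_window window size in SNPs.
#' @param prune_step window advance in SNPs; must not exceed the window.
#' @param max_r2 dosage r-squared threshold in (0, 1).
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(min_call_rate = 0.95, min_maf = 0.05,
                      prune_window = 50L, prune_step = 5L, max_r2 = 0.30) {
  stopifnot(min_call_rate > 0, min_call_rate < 1,
            min_maf > 0, min_maf < 1,
            max_r2 > 0, max_r2 < 1)
  prune_window <- as.integer(prune_window); prune_step <- as.integer(prune_step)
  if (!(prune_window >= prune_step && prune_step >= 1L))
    stop("need prune_window >= prune_step >= 1")
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 prune_window = prune_window, prune_step = prune_step,
                 max_r2 = max_r2), class = "qc_params")
}

#' Call-rate filter
#'
#' A SNP is kept iff its fraction of non-missing calls strictly exceeds
#' `min_call_rate` (a SNP at exactly the threshold is removed).
#'
#' @param genotypes a [genotype_matrix()].
#' @param min_call_rate threshold in (0, 1).
#' @return Integer vector of kept SNP column indices.
#' @export
call_rate_filter <- function(genotypes, min_call_rate = 0.95) {
  if (n_samples(genotypes) == 0L || n_snps(genotypes) == 0L)
    stop("empty genotype matrix")
  cr <- colMeans(!is.na(genotypes$dosages))
  unname(which(cr > min_call_rate))
}

#' Minor-allele-frequency filter
#'
#' MAF is `min(p, 1 - p)` with `p` = mean observed dosage / 2, computed
#' over non-missing calls. A SNP is kept iff MAF strictly exceeds
#' `min_maf`; all-missing SNPs are removed and counted in attribute
#' `n_all_missing`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param min_maf threshold in (0, 1).
#' @return Integer vector of kept SNP column indices.
#' @export
maf_filter <- function(genotypes, min_maf = 0.05) {
  p <- colMeans(genotypes$dosages, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  all_missing <- is.nan(p)
  kept <- unname(which(!all_missing & maf > min_maf))
  attr(kept, "n_all_missing") <- sum(all_missing)
  kept
}

#' Dosage r-squared between two SNPs
#'
#' Squared Pearson correlation of dosage vectors over samples non-missing
#' in both (composite LD, as computed by PLINK's `--indep-pairwise`).
#' Returns `NA` when fewer than two overlapping samples exist or either
#' vector is constant on the overlap.
#'
#' @param x,y dosage vectors of equal length.
#' @return r-squared in `[0, 1]`, or `NA` when undefined.
#' @export
dosage_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  xs <- x[ok]; ys <- y[ok]
  if (stats::var(xs) == 0 || stats::var(ys) == 0) return(NA_real_)
  stats::cor(xs, ys)^2
}

# Exact pairwise-complete r^2 for all column pairs of a dosage block, via
# crossproducts of the zero-filled data and the missingness mask (BLAS-fast,
# identical to per-pair complete-case Pearson r^2 up to floating point).
pairwise_r2_matrix <- function(d) {
  M <- (!is.na(d)) * 1
  Z <- d; Z[is.na(Z)] <- 0
  N <- crossprod(M)
  SX <- crossprod(Z, M)          # SX[j,k] = sum over joint samples of x_j
  SXY <- crossprod(Z)
  SXX <- crossprod(Z^2, M)
  SY <- t(SX); SYY <- t(SXX)
  cv <- SXY - SX * SY / N
  vx <- SXX - SX^2 / N
  vy <- SYY - SY^2 / N
  r2 <- cv^2 / (vx * vy)
  tol <- 1e-9 * pmax(N, 1)
  r2[N < 2 | vx <= tol | vy <= tol] <- NA_real_
  r2
}

#' Windowed LD pruning
#'
#' Greedy pruning in map order, per chromosome: a window of
#' `prune_window` SNPs is scanned; among currently-kept SNPs every pair is
#' checked in order and when r-squared exceeds `max_r2` the *later* SNP is
#' removed; the window then advances by `prune_step` positions (counted in
#' original map order, kept or not) until it reaches the chromosome end.
#' After completion no within-window pair of kept SNPs exceeds the
#' threshold. Undefined r-squared (constant SNP on the overlap) never
#' causes removal and is counted in attribute `n_undefined_r2`.
#'
#' @param genotypes a [genotype_matrix()] with SNPs ordered by
#'   (chromosome, position).
#' @param params a [qc_params()].
#' @return Integer vector of kept SNP column indices (ascending), with
#'   attribute `n_undefined_r2`.
#' @export
ld_prune <- function(genotypes, params = qc_params()) {
  d <- genotypes$dosages
  chrom <- genotypes$snp_map$chrom
  pos <- genotypes$snp_map$pos
  r <- rle(as.character(chrom))
  if (anyDuplicated(r$values))
    stop("SNPs must be grouped by chromosome")
  if (any(unlist(tapply(pos, factor(chrom, levels = r$values), is.unsorted, na.rm = TRUE))))
    stop("SNP positions must be non-decreasing within each chromosome")
  w <- params$prune_window; s <- params$prune_step; thr <- params$max_r2
  keep <- rep(TRUE, ncol(d))
  n_undef <- 0L
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    mlen <- length(idx)
    # windows overlap by (w - s)/w, so precompute the chromosome's r2 matrix
    # once when it fits; fall back to per-window computation otherwise
    whole <- mlen <= 3000L
    R2 <- if (whole) pairwise_r2_matrix(d[, idx, drop = FALSE]) else NULL
    start <- 1L
    repeat {
      end <- min(start + w - 1L, mlen)
      win <- idx[start:end]
      wk <- win[keep[win]]
      if (length(wk) >= 2L) {
        r2 <- if (whole) {
          R2[match(wk, idx), match(wk, idx), drop = FALSE]
        } else {
          pairwise_r2_matrix(d[, wk, drop = FALSE])
        }
        n_undef <- n_undef + sum(is.na(r2[upper.tri(r2)]))
        alive <- rep(TRUE, length(wk))
        for (i in seq_len(length(wk) - 1L)) {
          if (!alive[i]) next
          for (j in (i + 1L):length(wk)) {
            if (!alive[j]) next
            if (!is.na(r2[i, j]) && r2[i, j] > thr) alive[j] <- FALSE
          }
        }
        keep[wk[!alive]] <- FALSE
      }
      if (end >= mlen) break
      start <- start + s
    }
  }
  kept <- which(keep)
  attr(kept, "n_undefined_r2") <- as.integer(n_undef)
  kept
}

#' Full SNP QC pipeline: call rate, MAF, LD pruning
#'
#' Applies the three stages in their fixed order and reports counts in and
#' out of each stage.
#'
#' @param genotypes a [genotype_matrix()].
#' @param params a [qc_params()].
#' @return list with `genotypes` (filtered [genotype_matrix()]), `kept`
#'   (column indices into the input), and `report` (a data.frame of
#'   per-stage counts).
#' @export
snp_qc <- function(genotypes, params = qc_params()) {
  n0 <- n_snps(genotypes)
  k1 <- call_rate_filter(genotypes, params$min_call_rate)
  g1 <- subset_genotypes(genotypes, snps = k1)
  k2 <- maf_filter(g1, params$min_maf)
  g2 <- subset_genotypes(g1, snps = k2)
  k3 <- ld_prune(g2, params)
  g3 <- subset_genotypes(g2, snps = k3)
  kept <- k1[k2][k3]
  report <- data.frame(stage = c("call_rate", "maf", "ld_prune"),
                       n_in = c(n0, length(k1), length(k2)),
                       n_out = c(length(k1), length(k2), length(k3)))
  am_log("snp_qc: %d -> %d -> %d -> %d SNPs", n0, length(k1), length(k2), length(k3))
  list(genotypes = g3, kept = kept, report = report)
}
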