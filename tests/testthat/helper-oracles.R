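# Independent oracles and fixture builders. Everything here is deliberately
# written from first principles (loops, definitions) and never calls the
# package code paths it is used to check.

# Hudson-type two-population FST estimator (ratio of sums over SNPs).
# d1, d2: dosage matrices (individuals x SNPs), no missing values.
hudson_fst <- function(d1, d2) {
  n1 <- 2 * nrow(d1); n2 <- 2 * nrow(d2)   # haploid sample sizes
  p1 <- colSums(d1) / n1
  p2 <- colSums(d2) / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- den > 0
  sum(num[ok]) / sum(den[ok])
}

# Dense brute-force PCA of the sample covariance X X' / M via SVD of X.
brute_force_pca <- function(X, k) {
  sv <- svd(X)
  list(eigenvalues = sv$d^2 / ncol(X),
       scores = sv$u[, seq_len(k), drop = FALSE])
}

# Pearson correlation straight from the definition (no stats::cor).
brute_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Exhaustive post-hoc verifier for LD pruning: largest r^2 among kept pairs
# that co-occur inside any window of `window` consecutive map positions.
max_kept_window_r2 <- function(dosages, chrom, kept, window) {
  worst <- 0
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    for (start in seq_along(idx)) {
      win <- idx[start:min(start + window - 1L, length(idx))]
      wk <- intersect(win, kept)
      if (length(wk) < 2) next
      for (a in seq_len(length(wk) - 1L)) for (b in (a + 1L):length(wk)) {
        x <- dosages[, wk[a]]; y <- dosages[, wk[b]]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 2 || var(x[ok]) == 0 || var(y[ok]) == 0) next
        r2 <- brute_pearson(x[ok], y[ok])^2
        if (r2 > worst) worst <- r2
      }
    }
  }
  worst
}

# 200-SNP single-chromosome fixture with planted correlated blocks:
# independent binomial SNPs, then some columns duplicated (with flip noise)
# next to their source so windows contain high-LD pairs.
make_ld_fixture <- function(n = 120, m = 200, n_blocks = 8, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.2, 0.8)
  d <- sapply(p, function(pp) rbinom(n, 2, pp))
  for (b in seq_len(n_blocks)) {
    src <- sample(seq_len(m - 4), 1)
    len <- sample(2:4, 1)
    for (j in seq_len(len)) {
      col <- d[, src]
      flip <- runif(n) < 0.05            # slight noise, r^2 stays ~ 0.9
      col[flip] <- 2L - col[flip]
      d[, src + j] <- col
    }
  }
  storage.mode(d) <- "integer"
  map <- data.frame(chrom = 1L, id = sprintf("s%03d", seq_len(m)),
                    pos = seq_len(m) * 1000L, allele1 = "A", allele2 = "G",
                    stringsAsFactors = FALSE)
  genotype_matrix(d, sprintf("i%03d", seq_len(n)), map)
}

# Tiny complete genotype matrix from an explicit dosage matrix.
toy_genotypes <- function(d) {
  d <- as.matrix(d); storage.mode(d) <- "integer"
  genotype_matrix(d, sprintf("s%d", seq_len(nrow(d))),
                  data.frame(chrom = 1L, id = sprintf("m%d", seq_len(ncol(d))),
                             pos = seq_len(ncol(d)) * 100L,
                             allele1 = "A", allele2 = "G",
                             stringsAsFactors = FALSE))
}

# Hand-rolled pc_result for tests that only need scores.
toy_pc <- function(scores) {
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  assortmate:::new_pc_result(scores = scores,
                             eigenvalues = rev(sort(abs(rnorm(ncol(scores))))) + 1,
                             k = ncol(scores))
}

# Small simulated cohort used by several files.
small_cohort <- function(seed = 42, endogamy_founder = 1, endogamy_offspring = 0.4,
                         couples = 40, snps = 800, n_subpops = 2,
                         children = function(n) 1L + rpois(n, 1)) {
  simulate_cohort(sim_config(n_subpops = n_subpops, fst = 0.01,
                             n_founder_couples_per_pop = couples, n_snps = snps,
                             endogamy_founder = endogamy_founder,
                             endogamy_offspring = endogamy_offspring,
                             n_children_per_couple = children,
                             missing_rate = 0.02, seed = seed))
}
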