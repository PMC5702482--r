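new_pc_result <- function(scores, eigenvalues, k,
                          variance_within_top = NA_real_, K = NA_integer_) {
  structure(list(scores = scores, eigenvalues = eigenvalues,
                 n_components_retained = k,
                 variance_within_top = variance_within_top, K = K),
            class = "pc_result")
}

#' @export
print.pc_result <- function(x, ...) {
  cat(sprintf("<pc_result> %d samples x %d PCs; top eigenvalues: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(signif(head(x$eigenvalues, 5), 4), collapse = ", ")))
  if (!is.na(x$variance_within_top))
    cat(sprintf("  first %d PCs explain %.1f%% of the variance in the first %d\n",
                x$n_components_retained, 100 * x$variance_within_top, x$K))
  invisible(x)
}

#' Patterson normalization of a genotype matrix
#'
#' The standard smartpca scaling: per SNP `j`, with `p = mean observed
#' dosage / 2`, observed entries become `(g - 2p) / sqrt(p (1 - p))` and
#' missing entries become 0 (mean imputation after centering), giving each
#' SNP drift-comparable weight. Monomorphic and all-missing SNPs are
#' dropped first; their indices are attached as attribute `dropped`.
#'
#' @param genotypes a [genotype_matrix()].
#' @return Numeric samples x SNPs matrix with attribute `dropped` (column
#'   indices of the input removed before normalization).
#' @export
patterson_normalize <- function(genotypes) {
  d <- genotypes$dosages
  p <- colMeans(d, na.rm = TRUE) / 2
  drop <- which(is.nan(p) | p <= 0 | p >= 1)
  names(drop) <- NULL
  if (length(drop)) {
    am_log("patterson_normalize: dropping %d monomorphic/all-missing SNPs", length(drop))
    d <- d[, -drop, drop = FALSE]
    p <- p[-drop]
  }
  if (!length(p)) stop("no polymorphic SNPs left to normalize")
  X <- sweep(d, 2L, 2 * p, "-")
  X <- sweep(X, 2L, sqrt(p * (1 - p)), "/")
  X[is.na(X)] <- 0
  attr(X, "dropped") <- drop
  X
}

#' Principal component analysis of a normalized genotype matrix
#'
#' Computes eigenvalues and sample scores of the sample-sample covariance
#' `X X' / M` (M = number of SNPs). Scores are unit-norm eigenvectors; the
#' decomposition is deterministic up to column sign (see [orient_signs()]
#' for fixing a convention). Requested components beyond the matrix rank
#' are truncated with a warning.
#'
#' @param X normalized samples x SNPs matrix (from
#'   [patterson_normalize()]).
#' @param k number of components to retain as scores (default 8).
#' @param K denominator rank for the variance-explained summary
#'   (default 30): the fraction of the top-`K` eigenvalue mass carried by
#'   the first `k` components.
#' @return A `pc_result`: `scores` (samples x k, rownames = sample ids),
#'   `eigenvalues` (all non-negative eigenvalues, descending),
#'   `n_components_retained`, `variance_within_top`, `K`.
#' @export
run_pca <- function(X, k = 8L, K = 30L) {
  n <- nrow(X); m <- ncol(X)
  if (n < 2L) stop("need at least two samples")
  kmax <- min(n - 1L, m)
  if (k > kmax) {
    warning(sprintf("k = %d exceeds rank bound %d; truncating", k, kmax))
    k <- kmax
  }
  G <- tcrossprod(X) / m
  ee <- eigen(G, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  vals <- vals[seq_len(kmax)]
  scores <- ee$vectors[, seq_len(k), drop = FALSE]
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_len(k))
  vw <- tryCatch(suppressWarnings(variance_explained_topk(vals, k, K)),
                 error = function(e) NA_real_)
  new_pc_result(scores, vals, k, vw, as.integer(min(K, length(vals))))
}

#' Variance captured by the first k of the top K components
#'
#' Sum of the first `k` eigenvalues divided by the sum of the first `K`.
#' When fewer than `K` eigenvalues are available all of them are used,
#' with a warning.
#'
#' @param eigenvalues non-negative eigenvalues, descending.
#' @param k numerator rank.
#' @param K denominator rank, `K >= k`.
#' @return Fraction in `(0, 1]`.
#' @export
variance_explained_topk <- function(eigenvalues, k = 8L, K = 30L) {
  if (K < k) stop("need K >= k")
  if (length(eigenvalues) < K) {
    warning(sprintf("only %d eigenvalues available; using all as denominator",
                    length(eigenvalues)))
    K <- length(eigenvalues)
  }
  if (k > length(eigenvalues)) stop("k exceeds number of eigenvalues")
  den <- sum(eigenvalues[seq_len(K)])
  if (den <= 0) stop("non-positive eigenvalue mass")
  sum(eigenvalues[seq_len(k)]) / den
}

#' Fix PC sign conventions using an anchor group
#'
#' Eigenvector signs are arbitrary; downstream quadrant rules (e.g. "East
#' European: PC1 < 0 and PC2 < 0") need a fixed orientation. Each listed
#' PC is flipped, if necessary, so the anchor group's mean score has the
#' requested sign. An anchor mean of exactly zero leaves the PC unflipped
#' with a warning.
#'
#' @param pc a `pc_result`.
#' @param anchor_ids sample ids of the anchor group (non-empty subset of
#'   the score rownames).
#' @param conventions named numeric vector: names are PC column indices,
#'   values are the desired sign (-1 or +1) of the anchor mean. Default
#'   `c("1" = -1, "2" = -1)` (anchor sits in the lower-left quadrant).
#' @return The `pc_result` with flipped columns; attribute `flipped` lists
#'   the PC indices that were negated.
#' @export
orient_signs <- function(pc, anchor_ids, conventions = c(`1` = -1, `2` = -1)) {
  if (!length(anchor_ids)) stop("anchor group is empty")
  miss <- setdiff(anchor_ids, rownames(pc$scores))
  if (length(miss)) stop("anchor ids absent from scores: ", paste(head(miss, 5), collapse = ", "))
  flipped <- integer(0)
  for (nm in names(conventions)) {
    j <- as.integer(nm)
    if (j > ncol(pc$scores)) stop("convention names a PC beyond the retained columns")
    m <- mean(pc$scores[anchor_ids, j])
    if (m == 0) {
      warning(sprintf("anchor mean on PC%d is exactly 0; leaving sign unchanged", j))
      next
    }
    if (sign(m) != sign(conventions[[nm]])) {
      pc$scores[, j] <- -pc$scores[, j]
      flipped <- c(flipped, j)
    }
  }
  if (length(flipped)) am_log("orient_signs: flipped PC %s", paste(flipped, collapse = ", "))
  attr(pc, "flipped") <- flipped
  pc
}

#' Scree table
#'
#' Deterministic tabulation of eigenvalues for scree plotting: component
#' index, eigenvalue, and cumulative fraction of the total (ending at 1).
#'
#' @param eigenvalues non-negative eigenvalues, descending.
#' @return data.frame with columns `component`, `eigenvalue`,
#'   `cumulative_fraction`.
#' @export
scree_table <- function(eigenvalues) {
  if (!length(eigenvalues)) stop("no eigenvalues")
  data.frame(component = seq_along(eigenvalues),
             eigenvalue = eigenvalues,
             cumulative_fraction = cumsum(eigenvalues) / sum(eigenvalues))
}

#' QC + normalize + PCA convenience wrapper
#'
#' @param genotypes a [genotype_matrix()].
#' @param params a [qc_params()].
#' @param k,K as in [run_pca()].
#' @return list with `pc` (a `pc_result`), `qc` (the [snp_qc()] result).
#' @export
pc_from_genotypes <- function(genotypes, params = qc_params(), k = 8L, K = 30L) {
  qc <- snp_qc(genotypes, params)
  X <- patterson_normalize(qc$genotypes)
  list(pc = run_pca(X, k = k, K = K), qc = qc)
}
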