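test_that("patterson_normalize: hand arithmetic, imputation, centering, drops", {
  g <- toy_genotypes(cbind(c(0L, 1L, 2L),       # p = 0.5 -> (-2, 0, 2)
                           c(0L, 0L, 0L),       # monomorphic -> dropped
                           c(1L, NA, 1L)))      # p = 0.5, NA -> 0
  X <- patterson_normalize(g)
  expect_identical(attr(X, "dropped"), 2L)
  expect_equal(unname(X[, 1]), c(-2, 0, 2))     # (g - 2p)/sqrt(p(1-p)), p = .5
  expect_equal(X[2, 2], 0)                      # mean imputation after centering
  expect_equal(unname(colMeans(patterson_normalize(
    toy_genotypes(matrix(rbinom(600, 2, 0.4), 30))))), rep(0, 20), tolerance = 1e-12)
  expect_error(patterson_normalize(toy_genotypes(matrix(0L, 4, 2))), "polymorphic")
})

test_that("run_pca matches a brute-force SVD oracle up to sign", {
  set.seed(31)
  for (dims in list(c(5, 4), c(20, 40), c(50, 100))) {
    X <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    X <- sweep(X, 2, colMeans(X))               # centered like real input
    rownames(X) <- sprintf("s%d", seq_len(dims[1]))
    k <- min(dims) - 1L
    pc <- run_pca(X, k = k, K = k)
    bf <- brute_force_pca(X, k)
    expect_equal(pc$eigenvalues[seq_len(k)], bf$eigenvalues[seq_len(k)],
                 tolerance = 1e-8)
    expect_equal(abs(pc$scores), abs(bf$scores), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("pc_result invariants: descending non-negative eigenvalues, orthogonal scores", {
  set.seed(32)
  X <- matrix(rnorm(60 * 200), 60)
  rownames(X) <- sprintf("s%d", 1:60)
  pc <- run_pca(X, k = 10, K = 30)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  expect_true(all(pc$eigenvalues >= 0))
  cp <- crossprod(pc$scores)
  expect_equal(cp, diag(10), tolerance = 1e-8, ignore_attr = TRUE)
  expect_lte(length(pc$eigenvalues), 59L)        # k <= n - 1
})

test_that("run_pca handles rank truncation, duplicates and cluster structure", {
  set.seed(33)
  X <- matrix(rnorm(4 * 10), 4)
  rownames(X) <- sprintf("s%d", 1:4)
  expect_warning(pc <- run_pca(X, k = 8, K = 8), "truncating")
  expect_identical(ncol(pc$scores), 3L)

  Xd <- rbind(X, X[2, , drop = FALSE])
  rownames(Xd) <- sprintf("s%d", 1:5)
  pcd <- run_pca(Xd, k = 3, K = 3)
  expect_equal(pcd$scores[2, ], pcd$scores[5, ], tolerance = 1e-8,
               ignore_attr = TRUE)

  # two separated clusters: PC1 splits them, eigenvalue1 dominates
  Xc <- rbind(matrix(rnorm(20 * 30, mean = 2), 20),
              matrix(rnorm(20 * 30, mean = -2), 20))
  Xc <- sweep(Xc, 2, colMeans(Xc))
  rownames(Xc) <- sprintf("s%d", 1:40)
  pcc <- run_pca(Xc, k = 2, K = 2)
  expect_gt(pcc$eigenvalues[1], pcc$eigenvalues[2])
  expect_true(all(sign(pcc$scores[1:20, 1]) != sign(pcc$scores[21:40, 1])))
})

test_that("variance_explained_topk: arithmetic, limits, monotonicity in k", {
  expect_equal(variance_explained_topk(c(4, 3, 2, 1), 2, 4), 0.7)
  expect_equal(variance_explained_topk(c(4, 3, 2, 1), 4, 4), 1.0)
  expect_warning(v <- variance_explained_topk(c(4, 3), 1, 30), "available")
  expect_equal(v, 4 / 7)
  expect_error(variance_explained_topk(c(4, 3), 3, 2), "K >= k")
  expect_error(variance_explained_topk(c(0, 0), 1, 2), "non-positive")
  set.seed(34)
  for (i in 1:5) {
    ev <- rev(sort(rexp(30)))
    fr <- vapply(1:30, function(k) variance_explained_topk(ev, k, 30), 0)
    expect_true(all(diff(fr) >= 0))
  }
})

test_that("orient_signs: identity, involution, by-construction anchoring", {
  sc <- matrix(c(-1, -2, 3, -1, -3, 2), 3, 2,
               dimnames = list(c("a", "b", "c"), c("PC1", "PC2")))
  pc <- toy_pc(sc)
  anchored <- orient_signs(pc, c("a", "b"))   # anchor means already negative
  expect_equal(anchored$scores, pc$scores)
  expect_length(attr(anchored, "flipped"), 0)

  pc_neg <- pc; pc_neg$scores[, 1] <- -pc_neg$scores[, 1]
  expect_equal(orient_signs(pc_neg, c("a", "b"))$scores, anchored$scores)

  expect_error(orient_signs(pc, character(0)), "empty")
  expect_error(orient_signs(pc, "zz"), "absent")
  pc0 <- toy_pc(matrix(c(-1, -2, 5, -5), 2, 2, dimnames = list(c("a", "b"), NULL)))
  expect_warning(orient_signs(pc0, c("a", "b")), "exactly 0")

  co <- small_cohort(seed = 44, couples = 30, snps = 600)
  pr <- pc_from_genotypes(co$genotypes, k = 2, K = 10)
  east <- names(co$truth$subpop)[co$truth$subpop == 1]
  east <- intersect(east, rownames(pr$pc$scores))
  oriented <- orient_signs(pr$pc, east)
  expect_lt(mean(oriented$scores[east, 1]), 0)
  expect_lt(mean(oriented$scores[east, 2]), 0)
})

test_that("scree_table tabulates cumulative fractions consistently", {
  st <- scree_table(c(4, 3, 2, 1))
  expect_equal(st$cumulative_fraction, c(0.4, 0.7, 0.9, 1.0))
  expect_equal(scree_table(5)$cumulative_fraction, 1.0)
  ev <- rev(sort(rexp(12)))
  st <- scree_table(ev)
  for (k in c(1, 4, 9))
    expect_equal(st$cumulative_fraction[k],
                 variance_explained_topk(ev, k, length(ev)))
})

test_that("two-subpopulation structure is linearly separable on PC1", {
  freqs <- sample_subpop_freqs(runif(3000, 0.1, 0.9), fst = 0.01, n_subpops = 2, seed = 35)
  fnd <- simulate_founders(freqs, n_per_pop = 200, seed = 36)
  pc <- run_pca(patterson_normalize(fnd$genotypes), k = 2, K = 10)
  p1 <- pc$scores[, 1]
  lab <- fnd$subpop
  thr <- sort(p1)
  acc <- max(vapply(thr, function(t) {
    pred <- ifelse(p1 <= t, 1L, 2L)
    max(mean(pred == lab), mean((3L - pred) == lab))
  }, 0))
  expect_gte(acc, 0.99)
})
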