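test_that("sample_subpop_freqs: limiting case, shapes and Beta variance", {
  p <- c(0.2, 0.5, 0.8)
  f0 <- sample_subpop_freqs(p, fst = 0, n_subpops = 3)
  expect_identical(dim(f0), c(3L, 3L))
  expect_true(all(f0 == matrix(rep(p, each = 3), 3)))

  expect_error(sample_subpop_freqs(c(0, 0.5), 0.1, 2), "inside")
  expect_error(sample_subpop_freqs(c(0.5, 1), 0.1, 2), "inside")
  expect_error(sample_subpop_freqs(0.5, 1, 2), "fst")

  # Var(p_k) = F p (1 - p): p = 0.3, F = 0.01 -> 0.0021
  draws <- sample_subpop_freqs(rep(0.3, 10000), fst = 0.01, n_subpops = 5, seed = 11)
  expect_equal(var(as.vector(draws)), 0.01 * 0.3 * 0.7, tolerance = 0.05)
  expect_equal(mean(draws), 0.3, tolerance = 0.01)
})

test_that("simulate_founders: boundary frequencies, binomial moments, sex balance", {
  freqs <- matrix(c(1, 0, 0.5), nrow = 1)
  fnd <- simulate_founders(freqs, n_per_pop = 50, seed = 3)
  expect_true(all(fnd$genotypes$dosages[, 1] == 2L))
  expect_true(all(fnd$genotypes$dosages[, 2] == 0L))
  expect_equal(sum(fnd$sex == "male"), 25L)

  fnd2 <- simulate_founders(matrix(rep(0.5, 20), nrow = 1), n_per_pop = 5000, seed = 4)
  d <- fnd2$genotypes$dosages
  expect_equal(mean(d), 1.0, tolerance = 0.02)
  expect_equal(mean(d == 1L), 0.5, tolerance = 0.02)   # heterozygosity
})

test_that("simulated differentiation is recovered by the Hudson estimator", {
  freqs <- sample_subpop_freqs(runif(2000, 0.1, 0.9), fst = 0.05, n_subpops = 2, seed = 9)
  fnd <- simulate_founders(freqs, n_per_pop = 200, seed = 10)
  d1 <- fnd$genotypes$dosages[fnd$subpop == 1, ]
  d2 <- fnd$genotypes$dosages[fnd$subpop == 2, ]
  expect_equal(hudson_fst(d1, d2), 0.05, tolerance = 0.2)  # +-20% relative

  # and at the simulator's default scale of differentiation
  freqs <- sample_subpop_freqs(runif(2000, 0.1, 0.9), fst = 0.01, n_subpops = 2, seed = 12)
  fnd <- simulate_founders(freqs, n_per_pop = 300, seed = 13)
  expect_equal(hudson_fst(fnd$genotypes$dosages[fnd$subpop == 1, ],
                          fnd$genotypes$dosages[fnd$subpop == 2, ]),
               0.01, tolerance = 0.2)
})

test_that("mate_generation: endogamy dial, truth flags, leftovers", {
  n <- 300
  subpop <- setNames(rep(1:3, each = n), sprintf("i%03d", seq_len(3 * n)))
  sex <- setNames(rep(c("male", "female"), length.out = 3 * n), names(subpop))

  full <- mate_generation(subpop, sex, endogamy = 1, seed = 1)
  expect_true(all(full$same_subpop))
  expect_true(all(full$endogamous))

  none <- mate_generation(subpop, sex, endogamy = 0, seed = 2)
  expect_false(any(none$endogamous))
  # random mating across 3 equal groups: ~1/3 same-group by chance (3 SE band)
  expect_lt(abs(mean(none$same_subpop) - 1 / 3), 3 * sqrt(2 / 9 / nrow(none)))

  half <- mate_generation(subpop, sex, endogamy = 0.5, seed = 3)
  p_hat <- mean(half$endogamous)
  se <- sqrt(0.25 / nrow(half))
  expect_lt(abs(p_hat - 0.5), 3 * se)

  expect_error(mate_generation(subpop, sex, endogamy = 1.2), "endogamy")
  expect_error(mate_generation(subpop[1], sex[1], 0.5), "male")

  # unbalanced sexes leave a logged remainder
  sx <- setNames(c(rep("male", 5), rep("female", 2)), letters[1:7])
  sp <- setNames(rep(1L, 7), letters[1:7])
  pr <- mate_generation(sp, sx, endogamy = 1, seed = 4)
  expect_equal(nrow(pr), 2L)
  expect_equal(attr(pr, "n_dropped"), 3L)
})

test_that("breed_offspring: deterministic homozygote crosses and Punnett ratios", {
  g <- toy_genotypes(rbind(c(2L, 0L, 1L), c(2L, 0L, 1L)))
  pairs <- assortmate:::new_spouse_pair_set(
    data.frame(male_id = "s1", female_id = "s2", generation = "founder"))
  off <- breed_offspring(pairs, g, n_children = 20000, seed = 5)
  d <- off$genotypes$dosages
  expect_true(all(d[, 1] == 2L))
  expect_true(all(d[, 2] == 0L))
  frq <- tabulate(d[, 3] + 1L, 3) / nrow(d)
  expect_equal(frq, c(0.25, 0.5, 0.25), tolerance = 0.05)

  bad <- assortmate:::new_spouse_pair_set(
    data.frame(male_id = "nope", female_id = "s2", generation = "founder"))
  expect_error(breed_offspring(bad, g), "ungenotyped")
})

test_that("apply_missingness masks at the requested rate", {
  g <- toy_genotypes(matrix(rbinom(1e5, 2, 0.5), 500, 200))
  expect_identical(apply_missingness(g, 0), g)
  gm <- apply_missingness(g, 0.5, seed = 6)
  expect_equal(mean(is.na(gm$dosages)), 0.5, tolerance = 0.02)
  # rate 0.04 -> per-SNP call rate ~0.96, most SNPs survive the 0.95 filter
  gs <- apply_missingness(g, 0.04, seed = 7)
  expect_gt(length(call_rate_filter(gs, 0.95)) / n_snps(gs), 0.5)
  expect_error(apply_missingness(g, 1), "missing_rate")
})

test_that("cohort invariants: Mendelian consistency, pair sexes, determinism", {
  cfg <- sim_config(n_subpops = 2, fst = 0.02, n_founder_couples_per_pop = 15,
                    n_snps = 120, endogamy_founder = 0.8, endogamy_offspring = 0.5,
                    missing_rate = 0, seed = 99)
  co <- simulate_cohort(cfg)

  ped <- co$pedigree
  d <- co$genotypes$dosages
  kids <- ped[ped$generation == "offspring", ]
  feasible <- function(gp) if (gp == 0L) 0L else if (gp == 2L) 1L else c(0L, 1L)
  for (i in seq_len(nrow(kids))) {
    gc <- d[kids$individual_id[i], ]
    gf <- d[kids$father_id[i], ]
    gm <- d[kids$mother_id[i], ]
    ok <- vapply(seq_along(gc), function(j)
      any(outer(feasible(gf[j]), feasible(gm[j]), `+`) == gc[j]), logical(1))
    expect_true(all(ok))
  }

  sex <- setNames(ped$sex, ped$individual_id)
  tp <- co$truth$pairs
  expect_true(all(sex[tp$male_id] == "male"))
  expect_true(all(sex[tp$female_id] == "female"))
  # every offspring's parents exist in the pedigree
  expect_true(all(kids$father_id %in% ped$individual_id))
  expect_true(all(kids$mother_id %in% ped$individual_id))

  co2 <- simulate_cohort(cfg)
  expect_identical(co$genotypes$dosages, co2$genotypes$dosages)
  expect_identical(as.data.frame(co$pedigree), as.data.frame(co2$pedigree))
  expect_identical(co$truth, co2$truth)
})

test_that("sim_config validates its domain", {
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(endogamy_founder = -0.1), "probabilities")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(n_subpops = 0), "n_subpops")
  expect_error(sim_config(freq_range = c(0, 0.9)))
})
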