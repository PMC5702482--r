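ped_df <- function(...) pedigree_table(data.frame(..., stringsAsFactors = FALSE))

trio <- function(extra_kids = 0) {
  kids <- data.frame(family_id = "f1",
                     individual_id = sprintf("kid%d", seq_len(1 + extra_kids)),
                     father_id = "dad", mother_id = "mom", sex = "unknown",
                     generation = "offspring", stringsAsFactors = FALSE)
  parents <- data.frame(family_id = "f1", individual_id = c("dad", "mom"),
                        father_id = "0", mother_id = "0",
                        sex = c("male", "female"), generation = "founder",
                        stringsAsFactors = FALSE)
  pedigree_table(rbind(parents, kids))
}

test_that("find_spouse_pairs: trio, dedup over children, missing parents", {
  p <- find_spouse_pairs(trio(), genotyped_ids = c("dad", "mom"))
  expect_identical(nrow(p), 1L)
  expect_identical(p$male_id, "dad")
  expect_identical(p$female_id, "mom")
  expect_identical(p$generation, "founder")
  expect_identical(p$n_common_children, 1L)

  p4 <- find_spouse_pairs(trio(extra_kids = 3), c("dad", "mom"))
  expect_identical(nrow(p4), 1L)
  expect_identical(p4$n_common_children, 4L)

  half <- ped_df(family_id = "f", individual_id = c("dad", "kid"),
                 father_id = c("0", "dad"), mother_id = c("0", "0"),
                 sex = c("male", "unknown"))
  p0 <- find_spouse_pairs(half, c("dad", "kid"))
  expect_identical(nrow(p0), 0L)
  expect_identical(attr(p0, "exclusions")[["missing_parent"]], 1L)
})

test_that("find_spouse_pairs counts its exclusion reasons", {
  ped <- ped_df(family_id = "f",
                individual_id = c("dad", "mom", "kid1", "kid2"),
                father_id = c("0", "0", "mom", "ghost"),
                mother_id = c("0", "0", "dad", "mom"),
                sex = c("male", "female", "unknown", "unknown"))
  # kid1 swaps parents' roles -> sex-inconsistent; kid2's father has no row
  p <- find_spouse_pairs(ped, c("dad", "mom"))
  ex <- attr(p, "exclusions")
  expect_identical(ex[["sex_inconsistent"]], 1L)
  expect_identical(ex[["parent_not_in_pedigree"]], 1L)
  expect_identical(nrow(p), 0L)

  # ungenotyped parent excludes the pair
  p2 <- find_spouse_pairs(trio(), genotyped_ids = "dad")
  expect_identical(nrow(p2), 0L)
  expect_identical(attr(p2, "exclusions")[["not_genotyped"]], 1L)
})

test_that("remarriage keeps the pair with more children, ties lexicographic", {
  ped <- ped_df(family_id = "f",
                individual_id = c("dad", "w1", "w2", "k1", "k2", "k3"),
                father_id = c("0", "0", "0", "dad", "dad", "dad"),
                mother_id = c("0", "0", "0", "w1", "w2", "w2"),
                sex = c("male", "female", "female", rep("unknown", 3)))
  p <- find_spouse_pairs(ped, c("dad", "w1", "w2"))
  expect_identical(nrow(p), 1L)
  expect_identical(p$female_id, "w2")          # two children beat one
  expect_identical(attr(p, "exclusions")[["remarriage"]], 1L)

  ped_tie <- ped_df(family_id = "f",
                    individual_id = c("dad", "w1", "w2", "k1", "k2"),
                    father_id = c("0", "0", "0", "dad", "dad"),
                    mother_id = c("0", "0", "0", "w2", "w1"),
                    sex = c("male", "female", "female", "unknown", "unknown"))
  pt <- find_spouse_pairs(ped_tie, c("dad", "w1", "w2"))
  expect_identical(pt$female_id, "w1")         # tie -> smaller partner id
})

test_that("pair extraction is invariant to pedigree row order", {
  co <- small_cohort(seed = 11, couples = 15, snps = 60)
  base <- find_spouse_pairs(co$pedigree, co$genotypes$sample_ids)
  for (s in 1:3) {
    set.seed(s)
    shuf <- co$pedigree[sample(nrow(co$pedigree)), ]
    class(shuf) <- class(co$pedigree)
    p <- find_spouse_pairs(shuf, co$genotypes$sample_ids)
    expect_identical(as.data.frame(p), as.data.frame(base))
  }
})

test_that("quadrant labels follow the oriented PC1/PC2 sign rules", {
  sc <- rbind(east = c(-1, -1), north = c(1, -1), southish = c(0.5, 0.5),
              boundary = c(0, -1))
  lab <- assign_quadrant_labels(toy_pc(sc))
  expect_identical(unname(lab["east"]), "East")
  expect_identical(unname(lab["north"]), "North")
  expect_identical(unname(lab["southish"]), "unassigned")
  expect_identical(unname(lab["boundary"]), "unassigned")
  expect_identical(attr(lab, "n_zero_scores"), 1L)
  expect_error(assign_quadrant_labels(toy_pc(matrix(1, 2, 1))), "PC2")
})

test_that("stratification partitions pairs and builds the exclude-site complement", {
  co <- small_cohort(seed = 12, couples = 25, snps = 60)
  pairs <- find_spouse_pairs(co$pedigree, co$genotypes$sample_ids)
  st <- stratify_pairs(pairs, by = "generation")
  expect_identical(sum(vapply(st, nrow, 0L)), nrow(pairs))
  expect_true(all(st$founder$generation == "founder"))

  ex <- stratify_pairs(pairs, by = "generation", exclude_site = "siteB")
  comp <- ex[["excluding-siteB"]]
  expect_true(all(comp$site_male != "siteB" & comp$site_female != "siteB"))
  expect_identical(nrow(comp),
                   sum(pairs$site_male != "siteB" & pairs$site_female != "siteB"))

  # excluding an absent site is the identity
  ex2 <- stratify_pairs(pairs, by = "generation", exclude_site = "nowhere")
  expect_identical(as.data.frame(ex2[["excluding-nowhere"]]),
                   as.data.frame(pairs))

  # per-generation truth counts from the simulator are recovered exactly
  expect_identical(nrow(st$founder),
                   sum(co$truth$pairs$generation == "founder"))
  expect_identical(nrow(st$offspring),
                   sum(co$truth$pairs$generation == "offspring"))
})
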