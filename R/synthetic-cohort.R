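#' Simulation configuration for a two-generation structured cohort
#'
#' Describes a cohort of several subpopulations with small pairwise
#' differentiation (Balding-Nichols model), a founder generation paired
#' into couples with a tunable endogamy probability, and one offspring
#' generation bred by Mendelian transmission and paired the same way.
#'
#' @param n_subpops number of subpopulations (>= 1).
#' @param freq_range interval for ancestral allele frequencies; frequencies
#'   are drawn uniformly on it. Default `c(0.1, 0.9)`.
#' @param fst Balding-Nichols differentiation parameter in `[0, 1)`.
#' @param n_founder_couples_per_pop founder couples per subpopulation; the
#'   simulator creates twice as many founders per subpopulation, half male
#'   and half female.
#' @param n_snps number of unlinked SNPs.
#' @param endogamy_founder,endogamy_offspring probability in `[0, 1]` that a
#'   pairing event is constrained to be within-subpopulation; with the
#'   complementary probability the partner is drawn at random from the whole
#'   remaining pool (random mating, which may still land within-group by
#'   chance).
#' @param n_children_per_couple either a single non-negative integer (every
#'   couple has that many children) or a function `f(n)` returning `n`
#'   non-negative integer child counts. Default `function(n) 1L + rpois(n, 2)`
#'   (mean 3, no childless couples), a plausible completed family size for
#'   pre-war birth cohorts.
#' @param missing_rate per-entry probability a genotype call is missing.
#' @param sites named probability vector; each founder couple (and all its
#'   descendants) is assigned an enrollment site by one multinomial draw.
#' @param seed integer RNG seed; fixed seed implies a bit-identical cohort.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subpops = 2L,
                       freq_range = c(0.1, 0.9),
                       fst = 0.01,
                       n_founder_couples_per_pop = 100L,
                       n_snps = 2000L,
                       endogamy_founder = 0.9,
                       endogamy_offspring = 0.4,
                       n_children_per_couple = function(n) 1L + rpois(n, 2),
                       missing_rate = 0.02,
                       sites = c(siteA = 0.5, siteB = 0.5),
                       seed = 1L) {
  stopifnot(n_subpops >= 1, n_founder_couples_per_pop >= 1, n_snps >= 1)
  if (fst < 0 || fst >= 1) stop("fst must be in [0, 1)")
  for (p in c(endogamy_founder, endogamy_offspring, missing_rate))
    if (p < 0 || p > 1) stop("probabilities must be in [0, 1]")
  if (missing_rate >= 1) stop("missing_rate must be < 1")
  stopifnot(length(freq_range) == 2, freq_range[1] > 0, freq_range[2] < 1,
            freq_range[1] <= freq_range[2])
  if (is.numeric(n_children_per_couple)) {
    k <- as.integer(n_children_per_couple)
    stopifnot(k >= 0)
    n_children_per_couple <- function(n) rep(k, n)
  }
  stopifnot(is.function(n_children_per_couple))
  if (is.null(names(sites)) || any(sites < 0) || sum(sites) <= 0)
    stop("sites must be a named non-negative probability vector")
  structure(list(n_subpops = as.integer(n_subpops), freq_range = freq_range,
                 fst = fst,
                 n_founder_couples_per_pop = as.integer(n_founder_couples_per_pop),
                 n_snps = as.integer(n_snps),
                 endogamy_founder = endogamy_founder,
                 endogamy_offspring = endogamy_offspring,
                 n_children_per_couple = n_children_per_couple,
                 missing_rate = missing_rate,
                 sites = sites / sum(sites),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw subpopulation allele frequencies under the Balding-Nichols model
#'
#' Each subpopulation's frequency at SNP j is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` where `p` is the ancestral frequency and
#' `F` the differentiation parameter, so that `E = p` and
#' `Var = F p (1 - p)`. `fst = 0` returns the ancestral frequencies
#' unchanged (the Beta degenerates to a point mass).
#'
#' @param p_anc numeric vector of ancestral frequencies, strictly in (0, 1).
#' @param fst differentiation parameter in `[0, 1)`.
#' @param n_subpops number of subpopulations.
#' @param seed optional integer seed.
#' @return `n_subpops` x `length(p_anc)` matrix of frequencies.
#' @export
sample_subpop_freqs <- function(p_anc, fst, n_subpops, seed = NULL) {
  if (any(p_anc <= 0) || any(p_anc >= 1))
    stop("ancestral frequencies must be strictly inside (0, 1)")
  if (fst < 0 || fst >= 1) stop("fst must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  m <- length(p_anc)
  if (fst == 0)
    return(matrix(rep(p_anc, each = n_subpops), nrow = n_subpops))
  scale <- (1 - fst) / fst
  a <- rep(p_anc * scale, each = n_subpops)
  b <- rep((1 - p_anc) * scale, each = n_subpops)
  matrix(rbeta(n_subpops * m, a, b), nrow = n_subpops)
}

new_spouse_pair_set <- function(df) {
  need <- c("male_id", "female_id", "generation", "site_male", "site_female",
            "n_common_children")
  for (nm in setdiff(need, names(df))) df[[nm]] <- if (nm == "n_common_children") NA_integer_ else NA_character_
  df <- df[, need]
  rownames(df) <- NULL
  class(df) <- c("spouse_pair_set", "data.frame")
  df
}

#' Simulate founder genotypes
#'
#' Dosages at SNP j for an individual of subpopulation k are
#' `Binomial(2, p[k, j])`; sexes are assigned half male / half female per
#' subpopulation.
#'
#' @param freqs subpopulation x SNP frequency matrix (from
#'   [sample_subpop_freqs()]).
#' @param n_per_pop individuals per subpopulation (even numbers give exact
#'   sex balance).
#' @param snp_map optional SNP map; generated if omitted.
#' @param seed optional integer seed.
#' @param id_prefix prefix for generated individual ids.
#' @return list with `genotypes` (a [genotype_matrix()]), `subpop` (integer
#'   vector) and `sex` (character vector), both named by individual id.
#' @export
simulate_founders <- function(freqs, n_per_pop, snp_map = NULL, seed = NULL,
                              id_prefix = "g1") {
  if (any(freqs < 0) || any(freqs > 1))
    stop("frequencies must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  K <- nrow(freqs); m <- ncol(freqs)
  n <- K * n_per_pop
  subpop <- rep(seq_len(K), each = n_per_pop)
  ids <- sprintf("%s_p%d_%04d", id_prefix, subpop,
                 unlist(lapply(seq_len(K), function(k) seq_len(n_per_pop))))
  d <- matrix(0L, n, m)
  for (k in seq_len(K)) {
    rows <- which(subpop == k)
    d[rows, ] <- matrix(rbinom(length(rows) * m, 2L, rep(freqs[k, ], each = length(rows))),
                        nrow = length(rows))
  }
  sex <- unlist(lapply(seq_len(K), function(k)
    rep(c("male", "female"), length.out = n_per_pop)))
  if (is.null(snp_map)) snp_map <- default_snp_map(m)
  g <- genotype_matrix(d, ids, snp_map)
  list(genotypes = g, subpop = setNames(subpop, ids), sex = setNames(sex, ids))
}

# evenly spread m SNPs over 22 autosomes with increasing positions
default_snp_map <- function(m) {
  chrom <- sort(rep_len(1:22, m))
  pos <- integer(m)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- seq(10000L, by = 5000L, length.out = length(idx))
  }
  data.frame(chrom = chrom, id = sprintf("rs%06d", seq_len(m)), pos = pos,
             allele1 = "A", allele2 = "G", stringsAsFactors = FALSE)
}

#' Pair individuals into couples with a tunable endogamy probability
#'
#' Males are visited in random order. For each male a Bernoulli draw with
#' probability `endogamy` decides whether the pairing event is endogamous:
#' if so, a partner is drawn uniformly from remaining females of the same
#' subpopulation; otherwise the partner is drawn uniformly from all
#' remaining females (random mating, which can still be within-group by
#' chance). Sampling is without replacement; individuals whose required
#' candidate set is empty, and leftover singles, are dropped and counted.
#' Same-family pairings are excluded when `family` is supplied.
#'
#' @param subpop integer subpopulation labels named by individual id.
#' @param sex character `"male"`/`"female"` labels named by individual id.
#' @param endogamy probability in `[0, 1]`.
#' @param family optional family labels named by id; partners must differ.
#' @param generation generation tag stored on the produced pairs.
#' @param seed optional integer seed.
#' @return A `spouse_pair_set` data.frame with truth columns `endogamous`
#'   (the Bernoulli draw) and `same_subpop` (label comparison), plus
#'   attribute `n_dropped` (unmatched individuals).
#' @export
mate_generation <- function(subpop, sex, endogamy, family = NULL,
                            generation = "founder", seed = NULL) {
  if (endogamy < 0 || endogamy > 1) stop("endogamy must be in [0, 1]")
  stopifnot(!is.null(names(subpop)), identical(names(subpop), names(sex)))
  if (!is.null(seed)) set.seed(seed)
  males <- names(sex)[sex == "male"]
  females <- names(sex)[sex == "female"]
  if (!length(males) || !length(females))
    stop("need at least one male and one female")
  males <- sample(males)
  avail <- rep(TRUE, length(females)); names(avail) <- females
  out <- vector("list", length(males))
  n_drop <- 0L
  for (i in seq_along(males)) {
    m <- males[i]
    cand <- females[avail[females]]
    if (!is.null(family)) cand <- cand[family[cand] != family[m]]
    endog <- runif(1) < endogamy
    if (endog) cand <- cand[subpop[cand] == subpop[m]]
    if (!length(cand)) { n_drop <- n_drop + 1L; next }
    f <- if (length(cand) == 1L) cand else sample(cand, 1L)
    avail[f] <- FALSE
    out[[i]] <- data.frame(male_id = m, female_id = f,
                           endogamous = endog,
                           same_subpop = subpop[m] == subpop[f],
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(male_id = character(), female_id = character(),
                                      endogamous = logical(), same_subpop = logical())
  n_drop <- n_drop + sum(avail)
  am_log("mate_generation: %d pairs, %d individuals left unmatched", nrow(out), n_drop)
  out$generation <- generation
  res <- new_spouse_pair_set(out)
  res$endogamous <- out$endogamous
  res$same_subpop <- out$same_subpop
  attr(res, "n_dropped") <- as.integer(n_drop)
  res
}

#' Breed offspring by Mendelian transmission at unlinked SNPs
#'
#' Each child receives one allele from each parent independently per SNP:
#' a parent with dosage `g` transmits the alternate allele with probability
#' `g / 2`.
#'
#' @param pairs a `spouse_pair_set` (male_id, female_id).
#' @param genotypes parental [genotype_matrix()]; must be complete (no
#'   missing calls) and contain every parent.
#' @param n_children integer vector (recycled) or function `f(n)` giving the
#'   number of children per couple.
#' @param seed optional integer seed.
#' @param id_prefix prefix for child ids.
#' @return list with `genotypes` (children, possibly 0 rows), `father`,
#'   `mother` (character vectors per child) and `sex` (random 50/50).
#' @export
breed_offspring <- function(pairs, genotypes, n_children = 1L, seed = NULL,
                            id_prefix = "g2") {
  if (!is.null(seed)) set.seed(seed)
  unknown <- setdiff(c(pairs$male_id, pairs$female_id), genotypes$sample_ids)
  if (length(unknown))
    stop("pair references ungenotyped individual: ", paste(head(unknown, 5), collapse = ", "))
  if (anyNA(genotypes$dosages))
    stop("parental genotypes must be complete before breeding")
  nc <- if (is.function(n_children)) n_children(nrow(pairs)) else rep_len(as.integer(n_children), nrow(pairs))
  stopifnot(all(nc >= 0))
  total <- sum(nc)
  m <- n_snps(genotypes)
  d <- matrix(0L, total, m)
  father <- character(total); mother <- character(total)
  row <- 0L
  D <- genotypes$dosages
  for (i in seq_len(nrow(pairs))) {
    if (nc[i] == 0L) next
    pf <- D[pairs$male_id[i], ] / 2
    pm <- D[pairs$female_id[i], ] / 2
    for (j in seq_len(nc[i])) {
      row <- row + 1L
      d[row, ] <- rbinom(m, 1L, pf) + rbinom(m, 1L, pm)
      father[row] <- pairs$male_id[i]
      mother[row] <- pairs$female_id[i]
    }
  }
  ids <- sprintf("%s_%05d", id_prefix, seq_len(total))
  g <- genotype_matrix(d, ids, genotypes$snp_map)
  sex <- setNames(ifelse(runif(total) < 0.5, "male", "female"), ids)
  list(genotypes = g, father = setNames(father, ids), mother = setNames(mother, ids),
       sex = sex)
}

#' Mask genotype calls at random
#'
#' Each entry is set to missing independently with probability
#' `missing_rate`, emulating imperfect call rates.
#'
#' @param genotypes a [genotype_matrix()].
#' @param missing_rate probability in `[0, 1)`.
#' @param seed optional integer seed.
#' @return A `genotype_matrix` with masked entries.
#' @export
apply_missingness <- function(genotypes, missing_rate, seed = NULL) {
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (missing_rate == 0) return(genotypes)
  if (!is.null(seed)) set.seed(seed)
  d <- genotypes$dosages
  mask <- runif(length(d)) < missing_rate
  d[mask] <- NA_integer_
  genotype_matrix(d, genotypes$sample_ids, genotypes$snp_map)
}

#' Simulate a full two-generation cohort
#'
#' Runs the whole generative model described by a [sim_config()]: ancestral
#' frequencies, Balding-Nichols subpopulation frequencies, founders,
#' founder pairing with `endogamy_founder`, Mendelian offspring, offspring
#' pairing with `endogamy_offspring` (avoiding full siblings), one
#' ungenotyped linking child per offspring couple (so offspring couples are
#' discoverable from the pedigree by the in-common-children rule), and
#' random missingness. Offspring of mixed couples inherit the subpopulation
#' label of one parent chosen at random and are flagged `admixed`.
#'
#' @param config a [sim_config()].
#' @return list of class `cohort_dataset` with elements `genotypes`
#'   ([genotype_matrix()], founders + offspring), `pedigree`
#'   ([pedigree_table()], includes ungenotyped linking children), and
#'   `truth` (list: `pairs` with per-pair endogamy flags, `subpop` per
#'   individual, `admixed` flags).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_snps
  p_anc <- runif(m, config$freq_range[1], config$freq_range[2])
  freqs <- sample_subpop_freqs(p_anc, config$fst, config$n_subpops)
  fnd <- simulate_founders(freqs, 2L * config$n_founder_couples_per_pop)

  founder_pairs <- mate_generation(fnd$subpop, fnd$sex, config$endogamy_founder,
                                   generation = "founder")
  # couple-level enrollment site, inherited by descendants
  site_names <- names(config$sites)
  couple_site <- site_names[sample.int(length(site_names), nrow(founder_pairs),
                                       replace = TRUE, prob = config$sites)]
  founder_pairs$site_male <- couple_site
  founder_pairs$site_female <- couple_site

  off <- breed_offspring(founder_pairs, fnd$genotypes,
                         n_children = config$n_children_per_couple)
  pair_of_father <- setNames(seq_len(nrow(founder_pairs)), founder_pairs$male_id)
  off_couple <- pair_of_father[off$father]
  # child subpop label: father's and mother's agree for endogamous-by-label
  # couples; otherwise one parent's label at random (flagged admixed)
  sp_f <- fnd$subpop[off$father]; sp_m <- fnd$subpop[off$mother]
  pick_f <- runif(length(sp_f)) < 0.5
  off_subpop <- ifelse(sp_f == sp_m, sp_f, ifelse(pick_f, sp_f, sp_m))
  names(off_subpop) <- names(off$father)
  admixed <- setNames(sp_f != sp_m, names(off$father))
  off_family <- setNames(off$father, names(off$father)) # full-sib exclusion key

  offspring_pairs <- mate_generation(off_subpop, off$sex, config$endogamy_offspring,
                                     family = off_family, generation = "offspring")
  offspring_pairs$site_male <- couple_site[off_couple[match(offspring_pairs$male_id, names(off_couple))]]
  offspring_pairs$site_female <- couple_site[off_couple[match(offspring_pairs$female_id, names(off_couple))]]

  geno <- rbind_genotypes(fnd$genotypes, off$genotypes)
  geno <- apply_missingness(geno, config$missing_rate)

  founder_fam <- setNames(sprintf("fam_%04d", seq_len(nrow(founder_pairs))),
                          founder_pairs$male_id)
  ped <- rbind(
    data.frame(family_id = ifelse(names(fnd$subpop) %in% names(founder_fam),
                                  founder_fam[names(fnd$subpop)],
                                  paste0("solo_", names(fnd$subpop))),
               individual_id = names(fnd$subpop),
               father_id = "0", mother_id = "0",
               sex = unname(fnd$sex),
               generation = "founder",
               site = NA_character_,
               ethnicity = paste0("pop", fnd$subpop),
               stringsAsFactors = FALSE),
    data.frame(family_id = unname(founder_fam[off$father]),
               individual_id = names(off$father),
               father_id = unname(off$father), mother_id = unname(off$mother),
               sex = unname(off$sex),
               generation = "offspring",
               site = NA_character_,
               ethnicity = paste0("pop", unname(off_subpop)),
               stringsAsFactors = FALSE))
  # spouses share the couple's family and site
  ped$family_id[match(founder_pairs$female_id, ped$individual_id)] <-
    founder_fam[founder_pairs$male_id]
  ped$site[match(founder_pairs$male_id, ped$individual_id)] <- couple_site
  ped$site[match(founder_pairs$female_id, ped$individual_id)] <- couple_site
  idx_off <- match(names(off$father), ped$individual_id)
  ped$site[idx_off] <- couple_site[off_couple]

  # one ungenotyped linking child per offspring couple
  if (nrow(offspring_pairs)) {
    link <- data.frame(family_id = sprintf("fam2_%04d", seq_len(nrow(offspring_pairs))),
                       individual_id = sprintf("g3_%05d", seq_len(nrow(offspring_pairs))),
                       father_id = offspring_pairs$male_id,
                       mother_id = offspring_pairs$female_id,
                       sex = "unknown", generation = "grandchild",
                       site = offspring_pairs$site_male,
                       ethnicity = NA_character_, stringsAsFactors = FALSE)
    ped <- rbind(ped, link)
  }

  subpop_all <- c(fnd$subpop, off_subpop)
  truth_pairs <- rbind(
    cbind(as.data.frame(founder_pairs), stringsAsFactors = FALSE),
    cbind(as.data.frame(offspring_pairs), stringsAsFactors = FALSE))
  structure(list(genotypes = geno,
                 pedigree = pedigree_table(ped),
                 truth = list(pairs = truth_pairs,
                              subpop = subpop_all,
                              admixed = admixed)),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d genotyped individuals, %d SNPs, %d pedigree rows, %d true pairs\n",
              n_samples(x$genotypes), n_snps(x$genotypes), nrow(x$pedigree),
              nrow(x$truth$pairs)))
  invisible(x)
}
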