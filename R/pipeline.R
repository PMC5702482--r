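#' Pipeline configuration
#'
#' Bundles every stage's settings. Exactly one of `simulate` (a
#' [sim_config()]) or `inputs` (paths `ped`, `map`, `fam`) must be given.
#' Per-stage seeds are derived deterministically from `seed` by hashing
#' stage names, so adding a stage never perturbs earlier streams.
#'
#' @param simulate optional [sim_config()] for simulate mode.
#' @param inputs optional named list of paths: `ped`, `map`, `fam`.
#' @param qc a [qc_params()].
#' @param k,K retained PCs and variance-denominator rank (see [run_pca()]).
#' @param pcs PC indices for the spouse correlation table.
#' @param null_pcs PC indices for the pairing null.
#' @param n_null_replicates null replicates (default 1000).
#' @param null_generation generation whose individuals form the null pool.
#' @param null_group `"quadrant"` (PC1/PC2 quadrant labels) or
#'   `"ethnicity"` (the pedigree's ethnicity column).
#' @param exclude_site optional site label for the complement analysis.
#' @param anchor `"auto"` (simulate mode: the first subpopulation anchors
#'   the East quadrant), a character vector of anchor sample ids, or `NULL`
#'   to skip sign orientation.
#' @param out_dir output directory (created if absent).
#' @param seed master integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, inputs = NULL, qc = qc_params(),
                            k = 8L, K = 30L, pcs = 1:6, null_pcs = 1:2,
                            n_null_replicates = 1000L,
                            null_generation = "offspring",
                            null_group = c("quadrant", "ethnicity"),
                            exclude_site = NULL, anchor = "auto",
                            out_dir = "assortmate-out", seed = 1L) {
  if (is.null(simulate) == is.null(inputs))
    stop("provide exactly one of 'simulate' or 'inputs'")
  if (!is.null(simulate)) stopifnot(inherits(simulate, "sim_config"))
  if (!is.null(inputs)) {
    if (!all(c("ped", "map", "fam") %in% names(inputs)))
      stop("inputs needs paths 'ped', 'map' and 'fam'")
    missing_files <- !vapply(unlist(inputs[c("ped", "map", "fam")]), file.exists, logical(1))
    if (any(missing_files)) stop("input file(s) not found")
  }
  structure(list(simulate = simulate, inputs = inputs, qc = qc,
                 k = as.integer(k), K = as.integer(K), pcs = pcs,
                 null_pcs = null_pcs,
                 n_null_replicates = as.integer(n_null_replicates),
                 null_generation = null_generation,
                 null_group = match.arg(null_group),
                 exclude_site = exclude_site, anchor = anchor,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

# FNV-1a-style 32-bit string hash folded into a small offset
stage_seed <- function(master, stage) {
  h <- 2166136261 %% 2^31
  for (b in utf8ToInt(stage)) h <- ((bitwXor(h, b)) * 16777619) %% 2^31
  as.integer((master %% 1000003L) * 1000L + h %% 1000L)
}

write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Run the whole pipeline
#'
#' Composes every stage end to end: cohort acquisition (simulation or
#' PED/MAP + FAM input), SNP QC, PCA with sign orientation, spouse-pair
#' identification, per-stratum correlation tables (including the
#' exclude-site variant when configured), the random within-ethnicity
#' pairing null with observed-vs-null comparison, and plot-ready per-pair
#' PC1/PC2 scatter data. All artifacts are TSV files under
#' `config$out_dir`; a JSON manifest records package version, config hash,
#' derived seeds and output checksums, sufficient to re-run
#' bit-identically.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results (`cohort`,
#'   `qc`, `pc`, `pairs`, `strata`, `correlations`, `null`, `comparison`,
#'   `manifest_path`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  seeds <- list(simulate = stage_seed(config$seed, "simulate"),
                null = stage_seed(config$seed, "null"))

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$seed <- seeds$simulate
    cohort <- simulate_cohort(sim)
    genotypes <- cohort$genotypes
    pedigree <- cohort$pedigree
  } else {
    io <- read_ped_map(config$inputs$ped, config$inputs$map)
    genotypes <- io$genotypes
    pedigree <- read_fam(config$inputs$fam)
    cohort <- NULL
  }
  if (n_samples(genotypes) == 0L) stop("stage input: empty cohort")

  qc <- snp_qc(genotypes, config$qc)
  write_tsv(qc$report, out("qc_report.tsv"), "SNP QC: counts in/out per stage")
  writeLines(qc$genotypes$snp_map$id, out("kept_snps.txt"))

  X <- patterson_normalize(qc$genotypes)
  pc <- run_pca(X, k = config$k, K = config$K)
  anchor_ids <- config$anchor
  if (identical(anchor_ids, "auto")) {
    anchor_ids <- if (!is.null(cohort))
      names(cohort$truth$subpop)[cohort$truth$subpop == 1] else NULL
  }
  if (!is.null(anchor_ids))
    pc <- orient_signs(pc, intersect(anchor_ids, rownames(pc$scores)))
  write_scores(pc, out("scores.tsv"))
  write_tsv(scree_table(pc$eigenvalues), out("scree.tsv"),
            "eigenvalues of the sample covariance, descending")

  pairs <- find_spouse_pairs(pedigree, genotyped_ids = genotypes$sample_ids)
  if (!nrow(pairs)) stop("stage pairs: no spouse pairs identified")
  write_tsv(as.data.frame(pairs), out("pairs.tsv"),
            "spouse pairs identified by in-common children")

  strata <- stratify_pairs(pairs, by = "generation",
                           exclude_site = config$exclude_site)
  strata <- c(list(all = pairs), strata)
  corr <- spouse_pc_table(strata, pc, pcs = config$pcs)
  write_tsv(corr, out("correlations.tsv"),
            "spouse Pearson correlations per PC; Fisher-z CIs; t-test p-values")
  writeLines(render_summary_table(corr), out("summary_table.tsv"))

  scatter <- do.call(rbind, lapply(names(strata), function(st) {
    p <- strata[[st]]
    ok <- p$male_id %in% rownames(pc$scores) & p$female_id %in% rownames(pc$scores)
    p <- p[ok, , drop = FALSE]
    data.frame(stratum = st,
               male_id = p$male_id, female_id = p$female_id,
               male_pc1 = pc$scores[p$male_id, 1], female_pc1 = pc$scores[p$female_id, 1],
               male_pc2 = pc$scores[p$male_id, 2], female_pc2 = pc$scores[p$female_id, 2])
  }))
  write_tsv(scatter, out("pair_scatter.tsv"),
            "per-pair PC1/PC2 scores (plot-ready; one row per spouse pair)")

  labels <- if (config$null_group == "quadrant") {
    assign_quadrant_labels(pc)
  } else {
    setNames(pedigree$ethnicity, pedigree$individual_id)
  }
  cand <- null_candidates(pedigree, labels, generation = config$null_generation)
  cand <- cand[cand$individual_id %in% rownames(pc$scores), , drop = FALSE]
  nul <- comparison <- NULL
  if (nrow(cand) >= 8L && length(unique(cand$group)) >= 1L) {
    nul <- tryCatch(
      null_distribution(cand, pc, pcs = config$null_pcs,
                        n_replicates = config$n_null_replicates, seed = seeds$null),
      error = function(e) { warning("null stage skipped: ", conditionMessage(e)); NULL })
  }
  if (!is.null(nul)) {
    write_tsv(nul$summary, out("null_summary.tsv"),
              sprintf("random within-ethnicity pairing null: %d replicates, %d pairs each",
                      nul$n_replicates, nul$n_pairs_per_replicate))
    obs_stratum <- if (config$null_generation %in% corr$stratum)
      config$null_generation else "all"
    comparison <- compare_observed_to_null(
      corr[corr$stratum == obs_stratum & corr$pc %in% config$null_pcs, , drop = FALSE], nul)
    write_tsv(comparison, out("null_comparison.tsv"),
              paste0("observed (stratum '", obs_stratum, "') vs pairing null"))
  }

  cfg_file <- tempfile()
  dput(config[setdiff(names(config), c("simulate", "inputs"))], cfg_file)
  outputs <- list.files(config$out_dir, full.names = FALSE)
  outputs <- setdiff(outputs, "manifest.json")
  manifest <- list(package = "assortmate",
                   version = as.character(packageVersion("assortmate")),
                   master_seed = config$seed, stage_seeds = seeds,
                   config_hash = unname(tools::md5sum(cfg_file)),
                   outputs = as.list(setNames(
                     unname(tools::md5sum(file.path(config$out_dir, outputs))),
                     outputs)))
  unlink(cfg_file)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort = cohort, qc = qc, pc = pc, pairs = pairs,
                 strata = strata, correlations = corr, null = nul,
                 comparison = comparison,
                 manifest_path = out("manifest.json")))
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

format_corr_cell <- function(r, lo, hi) {
  if (is.na(r)) return("NA")
  if (is.na(lo) || is.na(hi))
    return(sprintf("%.2f (NA; NA)", round_half_up(r)))
  sprintf("%.2f (%.2f; %.2f)", round_half_up(r), round_half_up(lo), round_half_up(hi))
}

parse_corr_cell <- function(cell) {
  m <- regmatches(cell, regexec("^(-?[0-9.]+) \\((-?[0-9.]+); (-?[0-9.]+)\\)$", cell))[[1]]
  if (length(m) != 4) stop("unparseable correlation cell: ", cell)
  as.numeric(m[2:4])
}

#' Render a publication-shaped summary table
#'
#' One column per stratum; a descriptive row of pair counts (plus medians
#' and ranges of any numeric metadata supplied), then one row per PC with
#' cells `r (ci_low; ci_high)` rounded half-up to two decimals. Full
#' precision lives in the machine-readable correlation TSV, not here.
#'
#' @param corr a `correlation_table` from [spouse_pc_table()].
#' @param metadata optional named list: per stratum, a data.frame of
#'   numeric per-pair metadata columns (e.g. birth year) to summarize as
#'   `median (min-max)`; missing entries render as `NA`.
#' @return Character vector of TSV lines.
#' @export
render_summary_table <- function(corr, metadata = NULL) {
  strata <- unique(corr$stratum)
  pcs <- sort(unique(corr$pc))
  header <- paste(c("", strata), collapse = "\t")
  npairs <- vapply(strata, function(st)
    as.character(corr$n_pairs[corr$stratum == st][1]), "")
  lines <- c(header, paste(c("N spouse pairs", npairs), collapse = "\t"))
  meta_cols <- unique(unlist(lapply(metadata, names)))
  for (mc in meta_cols) {
    cells <- vapply(strata, function(st) {
      md <- metadata[[st]]
      if (is.null(md) || !mc %in% names(md) || all(is.na(md[[mc]]))) return("NA")
      v <- md[[mc]][!is.na(md[[mc]])]
      sprintf("%g (%g-%g)", stats::median(v), min(v), max(v))
    }, "")
    lines <- c(lines, paste(c(mc, cells), collapse = "\t"))
  }
  for (j in pcs) {
    cells <- vapply(strata, function(st) {
      row <- corr[corr$stratum == st & corr$pc == j, , drop = FALSE]
      if (!nrow(row)) return("NA")
      format_corr_cell(row$r, row$ci_low, row$ci_high)
    }, "")
    lines <- c(lines, paste(c(sprintf("Cor PC%d", j), cells), collapse = "\t"))
  }
  lines
}
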