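#' Read PLINK text PED/MAP files
#'
#' Parses the classic whitespace-delimited PLINK text format. Each PED row
#' is `FID IID FATHER MOTHER SEX PHENO` followed by two allele symbols per
#' SNP; `0 0` denotes a missing call. Allele pairs are collapsed to a
#' dosage counting the *counted allele*: `allele2` from a 6-column MAP
#' (`chrom id cm pos allele1 allele2` extension), else the lexicographically
#' second allele observed at that SNP. Monomorphic SNPs without map alleles
#' get dosage 0 everywhere and a map `allele2` of `NA`.
#'
#' Malformed input is rejected with the offending line number: ragged rows,
#' duplicated individual ids, or allele symbols outside `A C G T 0 1 2`.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @return list with `genotypes` (a [genotype_matrix()]) and `pedigree`
#'   (a [pedigree_table()] built from the six leading PED columns).
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  ncol_map <- unique(lengths(map_tok))
  if (length(ncol_map) != 1 || !ncol_map %in% c(4L, 6L))
    stop("MAP must have 4 or 6 columns on every line")
  mm <- do.call(rbind, map_tok)
  snp_map <- data.frame(chrom = mm[, 1], id = mm[, 2],
                        pos = as.integer(mm[, 4]),
                        allele1 = if (ncol_map == 6L) mm[, 5] else NA_character_,
                        allele2 = if (ncol_map == 6L) mm[, 6] else NA_character_,
                        stringsAsFactors = FALSE)
  m <- nrow(snp_map)

  ped_lines <- readLines(ped_path)
  keep <- nzchar(trimws(ped_lines))
  ped_tok <- strsplit(trimws(ped_lines[keep]), "[ \t]+")
  lineno <- which(keep)
  expected <- 6L + 2L * m
  fam <- character(length(ped_tok)); iid <- character(length(ped_tok))
  fat <- character(length(ped_tok)); mot <- character(length(ped_tok))
  sex <- character(length(ped_tok))
  al1 <- matrix(NA_character_, length(ped_tok), m)
  al2 <- matrix(NA_character_, length(ped_tok), m)
  ok_sym <- c("A", "C", "G", "T", "0", "1", "2")
  for (i in seq_along(ped_tok)) {
    tok <- ped_tok[[i]]
    if (length(tok) != expected)
      stop(sprintf("PED line %d: expected %d fields, found %d",
                   lineno[i], expected, length(tok)))
    fam[i] <- tok[1]; iid[i] <- tok[2]; fat[i] <- tok[3]; mot[i] <- tok[4]
    sex[i] <- c("1" = "male", "2" = "female")[tok[5]] %||% "unknown"
    if (is.na(sex[i])) sex[i] <- "unknown"
    alleles <- tok[-(1:6)]
    bad <- !alleles %in% ok_sym
    if (any(bad))
      stop(sprintf("PED line %d: invalid allele symbol '%s'",
                   lineno[i], alleles[which(bad)[1]]))
    al1[i, ] <- alleles[c(TRUE, FALSE)]
    al2[i, ] <- alleles[c(FALSE, TRUE)]
  }
  if (anyDuplicated(iid))
    stop(sprintf("PED line %d: duplicate individual id '%s'",
                 lineno[which(duplicated(iid))[1]], iid[duplicated(iid)][1]))

  dos <- matrix(NA_integer_, length(iid), m)
  for (j in seq_len(m)) {
    a <- al1[, j]; b <- al2[, j]
    half_missing <- xor(a == "0", b == "0")
    if (any(half_missing))
      stop(sprintf("SNP %s: half-missing genotype (one allele '0')", snp_map$id[j]))
    miss <- a == "0"
    counted <- snp_map$allele2[j]
    if (is.na(counted)) {
      obs <- sort(unique(c(a[!miss], b[!miss])))
      snp_map$allele1[j] <- if (length(obs)) obs[1] else NA_character_
      counted <- if (length(obs) >= 2) obs[2] else NA_character_
      snp_map$allele2[j] <- counted
    }
    if (is.na(counted)) {
      dos[!miss, j] <- 0L   # monomorphic with unknown alternate
    } else {
      dos[, j] <- (a == counted) + (b == counted)
      dos[miss, j] <- NA_integer_
    }
  }
  g <- genotype_matrix(dos, iid, snp_map)
  ped <- pedigree_table(data.frame(family_id = fam, individual_id = iid,
                                   father_id = fat, mother_id = mot, sex = sex,
                                   stringsAsFactors = FALSE))
  list(genotypes = g, pedigree = ped)
}

#' Write PLINK text PED/MAP files
#'
#' Inverse of [read_ped_map()]. The MAP is written with 6 columns
#' (`chrom id 0 pos allele1 allele2`) so the counted-allele orientation
#' round-trips exactly. Missing dosages become `0 0`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param pedigree optional [pedigree_table()] supplying family/parent/sex
#'   fields for the six leading PED columns; unknown individuals get
#'   placeholder values.
#' @param ped_path,map_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(genotypes, ped_path, map_path, pedigree = NULL) {
  map <- genotypes$snp_map
  a1 <- ifelse(is.na(map$allele1), "A", map$allele1)
  a2 <- ifelse(is.na(map$allele2), "G", map$allele2)
  writeLines(paste(map$chrom, map$id, 0, map$pos, a1, a2, sep = "\t"), map_path)

  d <- genotypes$dosages
  ids <- genotypes$sample_ids
  if (!is.null(pedigree)) {
    idx <- match(ids, pedigree$individual_id)
  } else idx <- rep(NA_integer_, length(ids))
  fam <- ifelse(is.na(idx), ids, pedigree$family_id[idx])
  fat <- ifelse(is.na(idx), "0", pedigree$father_id[idx])
  mot <- ifelse(is.na(idx), "0", pedigree$mother_id[idx])
  sex <- ifelse(is.na(idx), "0",
                c(male = "1", female = "2", unknown = "0")[pedigree$sex[idx]])
  sex[is.na(sex)] <- "0"
  con <- file(ped_path, "w"); on.exit(close(con))
  for (i in seq_along(ids)) {
    g <- d[i, ]
    first <- ifelse(is.na(g), "0", ifelse(g >= 1, a2, a1))
    second <- ifelse(is.na(g), "0", ifelse(g == 2, a2, a1))
    writeLines(paste(c(fam[i], ids[i], fat[i], mot[i], sex[i], "-9",
                       rbind(first, second)), collapse = "\t"), con)
  }
  invisible(c(ped_path, map_path))
}

#' Read a minimal VCF into a genotype matrix
#'
#' Supports plain-text VCF 4.x with GT calls only. `0/0` maps to 0, `0/1`
#' and `1/0` to 1, `1/1` to 2 and `./.` to missing; `|`-phased separators
#' are accepted. Multi-allelic records are skipped with a warning and the
#' skip count is attached as attribute `n_skipped`.
#'
#' @param vcf_path path to an uncompressed VCF file.
#' @return A [genotype_matrix()] (dosage counts the ALT allele).
#' @export
read_vcf_minimal <- function(vcf_path) {
  lines <- readLines(vcf_path)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1) stop("missing #CHROM header line")
  samples <- strsplit(lines[hdr], "\t")[[1]][-(1:9)]
  if (!length(samples)) stop("VCF has no sample columns")
  body <- lines[-seq_len(hdr)]
  body <- body[!startsWith(body, "#")]
  rows <- strsplit(body, "\t")
  n_skipped <- 0L
  dos <- list(); map <- list()
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) < 9 + length(samples))
      stop(sprintf("VCF record %d: too few fields", i))
    if (grepl(",", f[5], fixed = TRUE) || f[5] == "." ) {
      n_skipped <- n_skipped + 1L
      next
    }
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_idx <- match("GT", fmt)
    if (is.na(gt_idx)) stop(sprintf("VCF record %d: no GT in FORMAT", i))
    gt <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE), `[`, "", gt_idx)
    gt <- gsub("|", "/", gt, fixed = TRUE)
    val <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L, "./." = NA_integer_)[gt]
    unknown <- is.na(val) & gt != "./."
    if (any(unknown))
      stop(sprintf("VCF record %d: unparseable GT '%s'", i, gt[which(unknown)[1]]))
    dos[[length(dos) + 1L]] <- val
    map[[length(map) + 1L]] <- data.frame(
      chrom = f[1], id = if (f[3] == ".") sprintf("%s_%s", f[1], f[2]) else f[3],
      pos = as.integer(f[2]), allele1 = f[4], allele2 = f[5],
      stringsAsFactors = FALSE)
  }
  if (n_skipped > 0L)
    warning(sprintf("skipped %d multi-allelic record(s)", n_skipped))
  if (!length(dos)) stop("no biallelic records in VCF")
  g <- genotype_matrix(do.call(cbind, dos), samples, do.call(rbind, map))
  attr(g, "n_skipped") <- n_skipped
  g
}

#' Write / read PC scores as an eigenvalue-headed TSV
#'
#' The format is EIGENSOFT-evec-like: a first line
#' `#eigvals: e1 e2 ... ek`, then one row per sample of
#' `sample_id score1 ... scorek`. Values are written with 15 significant
#' digits so a round trip is the identity to at least 12.
#'
#' @param pc a `pc_result` (see [run_pca()]).
#' @param path output path.
#' @return `write_scores()` invisibly returns `path`; `read_scores()`
#'   returns a `pc_result` (scores, eigenvalues for the stored components).
#' @export
write_scores <- function(pc, path) {
  k <- ncol(pc$scores)
  if (k < 1) stop("no score columns to write")
  ev <- format(pc$eigenvalues[seq_len(k)], digits = 15, scientific = TRUE)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("#eigvals:", ev), collapse = "\t"), con)
  body <- apply(format(pc$scores, digits = 15, scientific = TRUE), 1, paste,
                collapse = "\t")
  writeLines(paste(rownames(pc$scores), body, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#eigvals:"))
    stop("score file must start with an '#eigvals:' header")
  ev <- as.numeric(strsplit(lines[1], "\t")[[1]][-1])
  if (!length(ev) || anyNA(ev)) stop("malformed eigenvalue header")
  rows <- strsplit(lines[-1], "\t")
  nfield <- unique(lengths(rows))
  if (length(nfield) != 1 || nfield != length(ev) + 1L)
    stop("score rows do not match the eigenvalue header length")
  ids <- vapply(rows, `[`, "", 1)
  sc <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  rownames(sc) <- ids
  colnames(sc) <- paste0("PC", seq_along(ev))
  new_pc_result(scores = sc, eigenvalues = ev, k = length(ev))
}

#' Write / read an extended FAM-style pedigree TSV
#'
#' Tab-separated with a header: `family_id individual_id father_id
#' mother_id sex phenotype generation site ethnicity`. Sex is coded
#' 1 = male, 2 = female, 0 = unknown; missing parents are `"0"`; empty
#' metadata is `NA`.
#'
#' @param pedigree a [pedigree_table()].
#' @param path file path.
#' @return `write_fam()` invisibly returns `path`; `read_fam()` returns a
#'   [pedigree_table()].
#' @export
write_fam <- function(pedigree, path) {
  out <- data.frame(family_id = pedigree$family_id,
                    individual_id = pedigree$individual_id,
                    father_id = pedigree$father_id,
                    mother_id = pedigree$mother_id,
                    sex = c(male = 1L, female = 2L, unknown = 0L)[pedigree$sex],
                    phenotype = -9L,
                    generation = pedigree$generation,
                    site = pedigree$site,
                    ethnicity = pedigree$ethnicity,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_fam
#' @export
read_fam <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = "NA")
  if (!all(c("family_id", "individual_id") %in% names(df)))
    stop("FAM TSV needs family_id and individual_id columns")
  sex_code <- c(`1` = "male", `2` = "female", `0` = "unknown")
  if ("sex" %in% names(df)) df$sex <- unname(sex_code[df$sex])
  df$phenotype <- NULL
  pedigree_table(df)
}
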