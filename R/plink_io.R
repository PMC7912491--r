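#' Read PLINK text genotypes with a sample sheet
#'
#' Parses whitespace-delimited PLINK `.ped`/`.map` files plus a tab-separated
#' sample sheet (`sample_id`, `type`, `population`) into a [geno_set()].
#' Alleles coded "0" are missing (PLINK convention). Per SNP, the observed
#' alleles are recorded in lexicographic order as `allele_a` and
#' `allele_b` (so the coding does not depend on sample order); calls
#' become the dosage of `allele_b`. SNPs mapped outside autosomes
#' 1..24 (sex chromosomes, unplaced scaffolds) are dropped on read. An
#' unsorted map is sorted by (chromosome, position) and the call columns
#' are permuted identically.
#'
#' @param ped_path path to the `.ped` file (6 leading columns, then two
#'   allele columns per SNP).
#' @param map_path path to the `.map` file (chromosome, snp_id, cM,
#'   position).
#' @param sample_sheet_path path to the TSV sample sheet with a header.
#' @param max_chromosome highest autosome number retained (default 24).
#' @return A [geno_set()].
#' @export
read_plink_text <- function(ped_path, map_path, sample_sheet_path,
                            max_chromosome = 24L) {
  for (f in c(ped_path, map_path, sample_sheet_path)) {
    if (!file.exists(f)) stop("file not found: ", f)
  }
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  nfield <- lengths(map_tok)
  if (any(nfield < 4)) {
    stop("malformed .map line ", which(nfield < 4)[1], ": expected 4 fields")
  }
  chrom <- suppressWarnings(as.integer(vapply(map_tok, `[[`, "", 1L)))
  snp_id <- vapply(map_tok, `[[`, "", 2L)
  pos <- suppressWarnings(as.numeric(vapply(map_tok, `[[`, "", 4L)))
  if (anyNA(pos)) {
    stop("malformed .map line ", which(is.na(pos))[1], ": bad position")
  }
  keep <- !is.na(chrom) & chrom >= 1L & chrom <= max_chromosome
  n_snps_all <- length(snp_id)

  sheet <- utils::read.delim(sample_sheet_path, header = TRUE,
                             stringsAsFactors = FALSE)
  req <- c("sample_id", "type", "population")
  if (!all(req %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(sheet$sample_id)) stop("duplicated sample ids in sheet")

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n_samp <- length(ped_lines)
  exp_tok <- 6L + 2L * n_snps_all
  ids <- character(n_samp)
  # allele calls as characters, samples x (2*snps)
  amat <- matrix(NA_character_, n_samp, 2L * n_snps_all)
  for (i in seq_len(n_samp)) {
    tok <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(tok) != exp_tok) {
      stop("malformed .ped line ", i, ": expected ", exp_tok,
           " fields, found ", length(tok))
    }
    ids[i] <- tok[2L]
    amat[i, ] <- tok[-(1:6)]
  }
  unknown <- setdiff(ids, sheet$sample_id)
  if (length(unknown)) {
    stop("sample(s) in .ped absent from sample sheet: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  samples <- sheet[match(ids, sheet$sample_id), req, drop = FALSE]
  rownames(samples) <- NULL

  a1 <- amat[, 2L * seq_len(n_snps_all) - 1L, drop = FALSE]
  a2 <- amat[, 2L * seq_len(n_snps_all), drop = FALSE]
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA
  calls <- matrix(NA_integer_, n_samp, n_snps_all)
  allele_a <- rep(NA_character_, n_snps_all)
  allele_b <- rep(NA_character_, n_snps_all)
  for (j in seq_len(n_snps_all)) {
    obs <- c(a1[, j], a2[, j])
    al <- sort(unique(obs[!is.na(obs)]))
    if (length(al) > 2) {
      stop("SNP ", snp_id[j], " has more than two alleles: ",
           paste(al, collapse = ","))
    }
    if (length(al) == 0) next
    allele_a[j] <- al[1]
    if (length(al) == 2) allele_b[j] <- al[2]
    d1 <- ifelse(is.na(a1[, j]), NA_integer_,
                 as.integer(!is.na(allele_b[j]) & a1[, j] == allele_b[j]))
    d2 <- ifelse(is.na(a2[, j]), NA_integer_,
                 as.integer(!is.na(allele_b[j]) & a2[, j] == allele_b[j]))
    calls[, j] <- ifelse(is.na(d1) | is.na(d2), NA_integer_, d1 + d2)
  }
  map <- data.frame(snp_id = snp_id, chromosome = chrom,
                    position_bp = as.integer(pos),
                    allele_a = allele_a, allele_b = allele_b,
                    stringsAsFactors = FALSE)
  map <- map[keep, , drop = FALSE]
  calls <- calls[, keep, drop = FALSE]
  geno_set(calls, map, samples)
}

#' Write a genotype set as PLINK text files
#'
#' Emits `.ped`/`.map` files (and optionally the sample sheet) that
#' round-trip through [read_plink_text()]. Missing calls are written as
#' "0 0"; monomorphic SNPs use `allele_a` for both alleles.
#'
#' @param g a [geno_set()].
#' @param prefix output path prefix; writes `<prefix>.ped`, `<prefix>.map`
#'   and `<prefix>.samples.tsv`.
#' @return Invisibly, the vector of paths written.
#' @export
write_plink_text <- function(g, prefix) {
  stopifnot(inherits(g, "geno_set"))
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  sheet_path <- paste0(prefix, ".samples.tsv")
  utils::write.table(
    data.frame(g$map$chromosome, g$map$snp_id, 0, g$map$position_bp),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  aa <- ifelse(is.na(g$map$allele_a), "A", g$map$allele_a)
  ab <- ifelse(is.na(g$map$allele_b), aa, g$map$allele_b)
  n <- nrow(g$calls)
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    cl <- g$calls[i, ]
    h1 <- ifelse(is.na(cl), "0", ifelse(cl >= 1, ab, aa))
    h2 <- ifelse(is.na(cl), "0", ifelse(cl == 2, ab, aa))
    pair <- as.vector(rbind(h1, h2))
    writeLines(paste(c(g$samples$sample_id[i], g$samples$sample_id[i],
                       "0", "0", "0", "-9", pair), collapse = " "), con)
  }
  utils::write.table(g$samples, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(ped_path, map_path, sheet_path))
}
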