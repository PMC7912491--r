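#' Genotype set container
#'
#' A `geno_set` bundles a diploid biallelic genotype call matrix with its
#' genomic map and sample metadata. Calls are coded as the dosage of the
#' B allele: 0 = homozygous A, 1 = heterozygous, 2 = homozygous B,
#' `NA` = missing. Rows are samples, columns are SNPs; row names are
#' sample ids and column names SNP ids.
#'
#' @param calls integer matrix (samples x SNPs) with entries 0/1/2/NA.
#' @param map data.frame with columns `snp_id`, `chromosome` (integer,
#'   autosomes 1..24), `position_bp` (1-based), `allele_a`, `allele_b`.
#'   Must be sorted by (chromosome, position) with strictly increasing
#'   positions within a chromosome.
#' @param samples data.frame with columns `sample_id`, `type`
#'   (e.g. "river"/"swamp") and `population`.
#'
#' @return An object of class `geno_set`: a list with elements `calls`,
#'   `map` and `samples`.
#' @export
geno_set <- function(calls, map, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(is.data.frame(map), is.data.frame(samples))
  req_map <- c("snp_id", "chromosome", "position_bp", "allele_a", "allele_b")
  if (!all(req_map %in% names(map))) {
    stop("map must have columns: ", paste(req_map, collapse = ", "))
  }
  req_s <- c("sample_id", "type", "population")
  if (!all(req_s %in% names(samples))) {
    stop("samples must have columns: ", paste(req_s, collapse = ", "))
  }
  if (nrow(calls) != nrow(samples)) {
    stop("calls has ", nrow(calls), " rows but samples has ", nrow(samples))
  }
  if (ncol(calls) != nrow(map)) {
    stop("calls has ", ncol(calls), " columns but map has ", nrow(map), " SNPs")
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2)) stop("calls must be 0, 1, 2 or NA")
  o <- order(map$chromosome, map$position_bp)
  if (!identical(o, seq_len(nrow(map)))) {
    map <- map[o, , drop = FALSE]
    calls <- calls[, o, drop = FALSE]
  }
  dup <- stats::ave(map$position_bp, map$chromosome,
                    FUN = function(x) c(1L, diff(x)))
  if (any(dup <= 0)) stop("map positions must be strictly increasing within a chromosome")
  if (anyDuplicated(samples$sample_id)) stop("duplicated sample ids")
  if (anyDuplicated(map$snp_id)) stop("duplicated SNP ids")
  rownames(map) <- NULL
  rownames(samples) <- NULL
  dimnames(calls) <- list(samples$sample_id, map$snp_id)
  structure(list(calls = calls, map = map, samples = samples),
            class = "geno_set")
}

#' @export
print.geno_set <- function(x, ...) {
  cat("geno_set: ", nrow(x$calls), " samples x ", ncol(x$calls), " SNPs on ",
      length(unique(x$map$chromosome)), " chromosome(s)\n", sep = "")
  tt <- table(x$samples$type)
  cat("  types: ", paste(names(tt), tt, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Subset a genotype set by samples and/or SNPs
#'
#' @param g a [geno_set()].
#' @param samples logical/integer/character index into samples (optional).
#' @param snps logical/integer/character index into SNPs (optional).
#' @return A `geno_set` restricted to the selected rows and columns.
#' @export
subset_geno <- function(g, samples = NULL, snps = NULL) {
  stopifnot(inherits(g, "geno_set"))
  calls <- g$calls
  map <- g$map
  samp <- g$samples
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, samp$sample_id)
    calls <- calls[samples, , drop = FALSE]
    samp <- samp[samples, , drop = FALSE]
  }
  if (!is.null(snps)) {
    if (is.character(snps)) snps <- match(snps, map$snp_id)
    calls <- calls[, snps, drop = FALSE]
    map <- map[snps, , drop = FALSE]
  }
  geno_set(calls, map, samp)
}

# per-SNP B-allele frequency from non-missing calls; NaN when nothing called
.allele_freq <- function(calls) {
  colMeans(calls, na.rm = TRUE) / 2
}

# per-SNP minor allele frequency
.maf <- function(calls) {
  p <- .allele_freq(calls)
  pmin(p, 1 - p)
}

#' Mapped genome length of a genotype set
#'
#' Sum over chromosomes of the span between the first and last mapped SNP.
#' This is the default denominator for [froh()]-style genome coverage.
#'
#' @param g a [geno_set()] or a map data.frame.
#' @return Total mapped length in base pairs.
#' @export
genome_length <- function(g) {
  map <- if (inherits(g, "geno_set")) g$map else g
  spans <- tapply(map$position_bp, map$chromosome,
                  function(x) max(x) - min(x))
  sum(as.numeric(spans))
}
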