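#' Exact test for Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on the heterozygote count conditional on the
#' observed allele counts: the p-value is the sum of the probabilities of
#' all heterozygote counts whose conditional probability does not exceed
#' that of the observed count.
#'
#' @param n_aa count of A/A homozygotes.
#' @param n_ab count of heterozygotes.
#' @param n_bb count of B/B homozygotes.
#' @return p-value in \[0, 1\]; 1 for monomorphic input (only one
#'   configuration possible).
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("need at least one genotype")
  n_a <- 2L * n_aa + n_ab   # rarer-or-not A allele count
  n_b <- 2L * n_bb + n_ab
  n_minor <- min(n_a, n_b)
  if (n_minor == 0) return(1)
  # possible heterozygote counts share the parity of the minor allele count
  hets <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  # log P(n_het | allele counts) up to a constant:
  #   log n! - log n_hom_a! - log n_het! - log n_hom_b! + n_het log 2
  hom_a <- (n_a - hets) / 2
  hom_b <- (n_b - hets) / 2
  logp <- hets * log(2) - lgamma(hom_a + 1) - lgamma(hets + 1) -
    lgamma(hom_b + 1)
  logp <- logp - max(logp)
  pr <- exp(logp)
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Quality-control parameters
#'
#' @param min_sample_call_rate minimum fraction of non-missing calls per
#'   sample (default 0.95).
#' @param min_snp_call_rate minimum fraction of non-missing calls per SNP
#'   (default 0.95).
#' @param min_maf minimum minor allele frequency, computed from
#'   non-missing calls (default 0.01).
#' @param hwe_p_threshold SNPs with a Hardy-Weinberg exact-test p-value
#'   strictly below this are removed; `NULL` (default) disables the filter.
#' @param require_polymorphic_in optional type label; SNPs monomorphic
#'   (MAF = 0) within that type's retained samples are removed.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_sample_call_rate = 0.95,
                      min_snp_call_rate = 0.95,
                      min_maf = 0.01,
                      hwe_p_threshold = NULL,
                      require_polymorphic_in = NULL) {
  for (v in c(min_sample_call_rate, min_snp_call_rate, min_maf,
              hwe_p_threshold)) {
    if (!is.null(v) && (v < 0 || v > 1)) stop("thresholds must be in [0, 1]")
  }
  structure(list(min_sample_call_rate = min_sample_call_rate,
                 min_snp_call_rate = min_snp_call_rate,
                 min_maf = min_maf,
                 hwe_p_threshold = hwe_p_threshold,
                 require_polymorphic_in = require_polymorphic_in),
            class = "qc_params")
}

.hwe_p_by_snp <- function(calls) {
  apply(calls, 2, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(1)
    hwe_exact_p(sum(x == 0L), sum(x == 1L), sum(x == 2L))
  })
}

#' Apply quality control to a genotype set
#'
#' Filters are applied in order: (1) samples with call rate below
#' `min_sample_call_rate`; then, on the retained samples, (2) SNPs with
#' call rate below `min_snp_call_rate` or MAF below `min_maf`; (3) the
#' optional Hardy-Weinberg exact-test filter; (4) the optional
#' polymorphic-within-type filter. Re-running on its own output is a
#' no-op.
#'
#' @param g a [geno_set()].
#' @param params a [qc_params()].
#' @return A list with elements `geno` (the filtered [geno_set()]) and
#'   `report` (a `qc_report` itemizing removals per filter).
#' @export
apply_qc <- function(g, params = qc_params()) {
  stopifnot(inherits(g, "geno_set"))
  if (nrow(g$calls) == 0 || ncol(g$calls) == 0) stop("empty dataset")

  sample_cr <- rowMeans(!is.na(g$calls))
  keep_samp <- sample_cr >= params$min_sample_call_rate
  removed_samples <- g$samples$sample_id[!keep_samp]
  if (!any(keep_samp)) stop("empty dataset: all samples removed by call rate")
  g1 <- subset_geno(g, samples = keep_samp)

  snp_cr <- colMeans(!is.na(g1$calls))
  maf <- .maf(g1$calls)
  fail_cr <- snp_cr < params$min_snp_call_rate
  fail_maf <- !fail_cr & (is.nan(maf) | maf < params$min_maf)
  keep_snp <- !fail_cr & !fail_maf

  fail_hwe <- rep(FALSE, ncol(g1$calls))
  if (!is.null(params$hwe_p_threshold)) {
    idx <- which(keep_snp)
    p <- .hwe_p_by_snp(g1$calls[, idx, drop = FALSE])
    fail_hwe[idx] <- p < params$hwe_p_threshold
    keep_snp <- keep_snp & !fail_hwe
  }

  fail_poly <- rep(FALSE, ncol(g1$calls))
  if (!is.null(params$require_polymorphic_in)) {
    in_type <- g1$samples$type == params$require_polymorphic_in
    if (!any(in_type)) {
      stop("type absent from sample sheet: ", params$require_polymorphic_in)
    }
    idx <- which(keep_snp)
    maf_t <- .maf(g1$calls[in_type, idx, drop = FALSE])
    fail_poly[idx] <- is.nan(maf_t) | maf_t == 0
    keep_snp <- keep_snp & !fail_poly
  }

  if (!any(keep_snp)) stop("empty dataset: all SNPs removed")
  g2 <- subset_geno(g1, snps = keep_snp)
  report <- structure(list(
    n_samples_in = nrow(g$calls),
    n_snps_in = ncol(g$calls),
    n_samples_removed = sum(!keep_samp),
    removed_samples = removed_samples,
    n_snps_removed = ncol(g$calls) - sum(keep_snp),
    n_snps_removed_call_rate = sum(fail_cr),
    n_snps_removed_maf = sum(fail_maf),
    n_snps_removed_hwe = sum(fail_hwe),
    n_snps_removed_monomorphic = sum(fail_poly),
    retained_samples = g2$samples$sample_id,
    retained_snps = g2$map$snp_id), class = "qc_report")
  list(geno = g2, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat("  samples: ", x$n_samples_in, " in, ", x$n_samples_removed,
      " removed (call rate)\n", sep = "")
  cat("  SNPs:    ", x$n_snps_in, " in, ", x$n_snps_removed, " removed (",
      x$n_snps_removed_call_rate, " call rate, ",
      x$n_snps_removed_maf, " MAF, ",
      x$n_snps_removed_hwe, " HWE, ",
      x$n_snps_removed_monomorphic, " monomorphic-in-type)\n", sep = "")
  invisible(x)
}

#' Build the joint and type-specific analysis datasets
#'
#' From a genotype set that already passed the joint sample/SNP
#' call-rate and MAF QC, construct: `all` — both types, restricted to
#' SNPs polymorphic (both alleles observed) among the swamp-type samples,
#' mitigating array ascertainment bias, with no Hardy-Weinberg filter;
#' `river` / `swamp` — one type's samples with call-rate and MAF filters
#' re-applied within type plus a Hardy-Weinberg exact-test filter.
#'
#' @param g a QCed [geno_set()] containing both types.
#' @param types character vector of length 2: the type labels, the second
#'   being the ascertainment-limited type used for the polymorphism
#'   restriction (default `c("river", "swamp")`).
#' @param min_snp_call_rate,min_maf within-type re-filter thresholds.
#' @param hwe_p_threshold Hardy-Weinberg p-value threshold for the
#'   type-specific datasets (default 1e-5).
#' @return A list with `geno_set` elements `all`, `river`, `swamp` (named
#'   after `types`) and the matching `qc_report`s in `reports`.
#' @export
build_datasets <- function(g, types = c("river", "swamp"),
                           min_snp_call_rate = 0.95, min_maf = 0.01,
                           hwe_p_threshold = 1e-5) {
  stopifnot(inherits(g, "geno_set"), length(types) == 2)
  for (tp in types) {
    if (!any(g$samples$type == tp)) stop("type absent from sample sheet: ", tp)
  }
  qc_all <- apply_qc(g, qc_params(min_sample_call_rate = 0,
                                  min_snp_call_rate = 0, min_maf = 0,
                                  require_polymorphic_in = types[2]))
  per_type <- lapply(types, function(tp) {
    gt <- subset_geno(g, samples = g$samples$type == tp)
    apply_qc(gt, qc_params(min_sample_call_rate = 0,
                           min_snp_call_rate = min_snp_call_rate,
                           min_maf = min_maf,
                           hwe_p_threshold = hwe_p_threshold))
  })
  out <- list(all = qc_all$geno,
              per_type[[1]]$geno, per_type[[2]]$geno)
  names(out)[2:3] <- types
  reports <- list(all = qc_all$report, per_type[[1]]$report,
                  per_type[[2]]$report)
  names(reports)[2:3] <- types
  out$reports <- reports
  out
}
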