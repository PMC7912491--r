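#' Per-animal ROH summaries and genomic inbreeding
#'
#' For each animal: the number of runs, mean run length, total run length,
#' and the ROH-based inbreeding coefficient
#' \eqn{F_{ROH}(t) = \sum_{ROH : length > t} length / L} where \eqn{L} is
#' the total genome length. Thresholds are strict (">"), so `t = 0`
#' uses every run. Animals with zero runs are included with zeros.
#'
#' @param rohs ROH data.frame from [detect_roh()].
#' @param sample_ids character vector of all animals to report (so that
#'   ROH-free animals appear); defaults to the animals present in `rohs`.
#' @param genome_length_bp denominator for the covered fraction; use
#'   [genome_length()] of the dataset the runs were detected on.
#' @param thresholds_bp numeric vector of minimum-length thresholds
#'   (default `c(0, 2e6, 4e6, 8e6)`, reported as `froh_all`,
#'   `froh_gt2mb`, ...).
#' @return data.frame with one row per animal.
#' @export
summarize_animals <- function(rohs, sample_ids = unique(rohs$sample_id),
                              genome_length_bp,
                              thresholds_bp = c(0, 2e6, 4e6, 8e6)) {
  stopifnot(genome_length_bp > 0)
  if (any(thresholds_bp < 0)) stop("thresholds must be non-negative")
  idx <- match(rohs$sample_id, sample_ids)
  if (anyNA(idx)) stop("rohs contain samples absent from sample_ids")
  n <- length(sample_ids)
  n_roh <- tabulate(idx, nbins = n)
  sum_len <- numeric(n)
  s <- tapply(rohs$length_bp, idx, sum)
  sum_len[as.integer(names(s))] <- s
  out <- data.frame(sample_id = sample_ids, n_roh = n_roh,
                    sum_length_bp = sum_len,
                    mean_length_mb = ifelse(n_roh > 0,
                                            sum_len / n_roh / 1e6, 0),
                    stringsAsFactors = FALSE)
  for (t in thresholds_bp) {
    cov <- numeric(n)
    keep <- rohs$length_bp > t
    s <- tapply(rohs$length_bp[keep], idx[keep], sum)
    cov[as.integer(names(s))] <- s
    nm <- if (t == 0) "froh_all" else
      paste0("froh_gt", format(t / 1e6, trim = TRUE, drop0trailing = TRUE), "mb")
    out[[nm]] <- cov / genome_length_bp
  }
  out
}

.length_class_breaks <- c(1, 2, 4, 8, 16, Inf)
.length_class_labels <- c("1-2 Mb", "2-4 Mb", "4-8 Mb", "8-16 Mb", ">16 Mb")

#' Classify ROH into the standard length classes
#'
#' Bins runs into the five classes usually reported for livestock panels
#' (1 < Mb <= 2; 2 < Mb <= 4; 4 < Mb <= 8; 8 < Mb <= 16; > 16 Mb), with
#' upper-inclusive boundaries; a run of exactly 1 Mb falls in the first
#' class.
#'
#' @param rohs ROH data.frame.
#' @param group_by name of the column to tabulate by (e.g. "type");
#'   `NULL` for a single overall column.
#' @return data.frame of counts, classes as rows, one column per group.
#' @export
classify_lengths <- function(rohs, group_by = "type") {
  mb <- rohs$length_bp / 1e6
  if (any(mb < 1)) stop("ROH shorter than 1 Mb present")
  cls <- cut(mb, breaks = .length_class_breaks,
             labels = .length_class_labels,
             include.lowest = TRUE, right = TRUE)
  if (is.null(group_by)) {
    grp <- factor(rep("all", nrow(rohs)))
  } else {
    grp <- factor(rohs[[group_by]])
  }
  tab <- table(class = cls, group = grp)
  out <- data.frame(class = rownames(tab), stringsAsFactors = FALSE)
  for (gname in colnames(tab)) out[[gname]] <- as.integer(tab[, gname])
  out
}

#' Count total and unique ROH
#'
#' A unique run is a distinct (chromosome, start, end) coordinate
#' signature, counted once regardless of how many animals carry it.
#'
#' @param rohs ROH data.frame.
#' @return A list with `total`, `unique` and `shared`: a data.frame of
#'   signatures with the number of carrying animals, the carrier ids and
#'   their populations, sorted by carrier count (for "most frequently
#'   detected ROH" tables).
#' @export
count_unique <- function(rohs) {
  if (!nrow(rohs)) {
    return(list(total = 0L, unique = 0L,
                shared = data.frame(chromosome = integer(),
                                    start_bp = numeric(), end_bp = numeric(),
                                    n_animals = integer(),
                                    sample_ids = character(),
                                    populations = character())))
  }
  key <- paste(rohs$chromosome, rohs$start_bp, rohs$end_bp, sep = ":")
  sp <- split(seq_len(nrow(rohs)), key)
  shared <- data.frame(
    chromosome = vapply(sp, function(i) rohs$chromosome[i[1]], numeric(1)),
    start_bp = vapply(sp, function(i) rohs$start_bp[i[1]], numeric(1)),
    end_bp = vapply(sp, function(i) rohs$end_bp[i[1]], numeric(1)),
    n_animals = vapply(sp, function(i) length(unique(rohs$sample_id[i])),
                       integer(1)),
    sample_ids = vapply(sp, function(i)
      paste(unique(rohs$sample_id[i]), collapse = ","), character(1)),
    populations = vapply(sp, function(i) {
      if (is.null(rohs$population)) "" else
        paste(unique(rohs$population[i]), collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE)
  shared <- shared[order(-shared$n_animals, shared$chromosome,
                         shared$start_bp), , drop = FALSE]
  rownames(shared) <- NULL
  list(total = nrow(rohs), unique = length(sp), shared = shared)
}

#' Per-chromosome ROH distribution
#'
#' Counts and mean lengths per chromosome per group, plus the mean
#' within-run inter-SNP distance per length class (run span divided by
#' `n_snps - 1`), a diagnostic for short-ROH reliability at a given panel
#' density.
#'
#' @param rohs ROH data.frame.
#' @param group_by grouping column name (default "type"); `NULL` for
#'   overall.
#' @return A list with `per_chromosome` (chromosome x group counts and
#'   mean lengths) and `snp_spacing` (mean within-run SNP spacing in kb
#'   per length class per group).
#' @export
chromosome_distribution <- function(rohs, group_by = "type") {
  grp <- if (is.null(group_by)) rep("all", nrow(rohs)) else rohs[[group_by]]
  grp <- factor(grp)
  chrom <- factor(rohs$chromosome)
  cnt <- table(chromosome = chrom, group = grp)
  mlen <- tapply(rohs$length_bp / 1e6, list(chrom, grp), mean)
  per_chr <- data.frame(chromosome = as.integer(rownames(cnt)),
                        stringsAsFactors = FALSE)
  for (gname in colnames(cnt)) {
    per_chr[[paste0("n_", gname)]] <- as.integer(cnt[, gname])
    per_chr[[paste0("mean_length_mb_", gname)]] <- as.numeric(mlen[, gname])
  }
  mb <- rohs$length_bp / 1e6
  cls <- cut(mb, breaks = .length_class_breaks,
             labels = .length_class_labels,
             include.lowest = TRUE, right = TRUE)
  spacing_kb <- ifelse(rohs$n_snps > 1,
                       rohs$length_bp / (rohs$n_snps - 1) / 1000, NA)
  sp <- tapply(spacing_kb, list(cls, grp), mean, na.rm = TRUE)
  spacing <- data.frame(class = rownames(sp), stringsAsFactors = FALSE)
  for (gname in colnames(sp)) {
    spacing[[paste0("spacing_kb_", gname)]] <- as.numeric(sp[, gname])
  }
  list(per_chromosome = per_chr, snp_spacing = spacing)
}

#' Group-level ROH summary table
#'
#' Aggregates per-animal summaries to group means and standard deviations
#' (total and unique run counts, runs per animal, run length, F_ROH per
#' threshold), mirroring the descriptive tables of a ROH study report.
#'
#' @param rohs ROH data.frame with a `type` (or other grouping) column.
#' @param samples sample metadata data.frame (`sample_id`, grouping
#'   column).
#' @param genome_length_bp denominator for F_ROH.
#' @param group_by grouping column name (default "type").
#' @return data.frame with one row per group and one for "all".
#' @export
group_roh_table <- function(rohs, samples, genome_length_bp,
                            group_by = "type") {
  per_animal <- summarize_animals(rohs, samples$sample_id, genome_length_bp)
  grp <- samples[[group_by]][match(per_animal$sample_id, samples$sample_id)]
  groups <- c(sort(unique(as.character(grp))), "all")
  rows <- lapply(groups, function(gname) {
    in_g <- if (gname == "all") rep(TRUE, nrow(per_animal)) else grp == gname
    rg <- rohs[rohs$sample_id %in% per_animal$sample_id[in_g], , drop = FALSE]
    uq <- count_unique(rg)
    pa <- per_animal[in_g, , drop = FALSE]
    data.frame(group = gname,
               n_animals = sum(in_g),
               total_roh = uq$total,
               unique_roh = uq$unique,
               mean_n_roh = mean(pa$n_roh), sd_n_roh = stats::sd(pa$n_roh),
               mean_length_mb = if (nrow(rg)) mean(rg$length_bp) / 1e6 else 0,
               sd_length_mb = if (nrow(rg)) stats::sd(rg$length_bp) / 1e6 else 0,
               mean_froh_all = mean(pa$froh_all),
               sd_froh_all = stats::sd(pa$froh_all),
               mean_froh_gt2mb = mean(pa$froh_gt2mb),
               sd_froh_gt2mb = stats::sd(pa$froh_gt2mb),
               mean_froh_gt4mb = mean(pa$froh_gt4mb),
               sd_froh_gt4mb = stats::sd(pa$froh_gt4mb),
               mean_froh_gt8mb = mean(pa$froh_gt8mb),
               sd_froh_gt8mb = stats::sd(pa$froh_gt8mb),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
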