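#' Per-animal ROH membership matrix
#'
#' Logical samples x SNPs matrix: entry is `TRUE` when the SNP position
#' falls inside (inclusive endpoints) at least one detected run of that
#' animal.
#'
#' @param rohs ROH data.frame from [detect_roh()].
#' @param g the [geno_set()] the runs were detected on.
#' @return logical matrix with the dimnames of `g$calls`.
#' @export
roh_incidence <- function(rohs, g) {
  stopifnot(inherits(g, "geno_set"))
  inc <- matrix(FALSE, nrow(g$calls), ncol(g$calls),
                dimnames = dimnames(g$calls))
  if (!nrow(rohs)) return(inc)
  row_of <- match(rohs$sample_id, g$samples$sample_id)
  if (anyNA(row_of)) stop("rohs contain samples absent from the geno_set")
  chr_idx <- split(seq_len(nrow(g$map)), g$map$chromosome)
  for (k in seq_len(nrow(rohs))) {
    sel <- chr_idx[[as.character(rohs$chromosome[k])]]
    pos <- g$map$position_bp[sel]
    j <- sel[pos >= rohs$start_bp[k] & pos <= rohs$end_bp[k]]
    if (length(j)) inc[row_of[k], j] <- TRUE
  }
  inc
}

#' Per-SNP ROH incidence track
#'
#' For each SNP, the number (and percentage) of animals carrying that SNP
#' inside a run, overall and per type — the scan statistic for ROH-island
#' detection.
#'
#' @param rohs ROH data.frame.
#' @param g the [geno_set()] the runs were detected on.
#' @param incidence optional precomputed [roh_incidence()] matrix.
#' @return data.frame aligned to `g$map` with columns `snp_id`,
#'   `chromosome`, `position_bp`, `count`, `percent` and per-type
#'   `count_<type>` / `percent_<type>`.
#' @export
snp_roh_counts <- function(rohs, g, incidence = NULL) {
  if (is.null(incidence)) incidence <- roh_incidence(rohs, g)
  out <- data.frame(snp_id = g$map$snp_id,
                    chromosome = g$map$chromosome,
                    position_bp = g$map$position_bp,
                    count = as.integer(colSums(incidence)),
                    stringsAsFactors = FALSE)
  out$percent <- out$count / nrow(incidence) * 100
  for (tp in sort(unique(g$samples$type))) {
    rows <- g$samples$type == tp
    cnt <- as.integer(colSums(incidence[rows, , drop = FALSE]))
    out[[paste0("count_", tp)]] <- cnt
    out[[paste0("percent_", tp)]] <- cnt / sum(rows) * 100
  }
  out
}

#' Flag significant SNPs in the incidence track
#'
#' The significance threshold is the empirical `quantile` (nearest-rank
#' convention, zeros included) of the per-SNP counts; SNPs with a count
#' strictly greater than the threshold are flagged — the "top 1%" rule.
#' With tied counts everywhere nothing exceeds the percentile and nothing
#' is flagged.
#'
#' @param track data.frame from [snp_roh_counts()].
#' @param quantile percentile defining the threshold (default 0.99).
#' @return `track` with columns `threshold` and logical `significant`.
#' @export
significant_snps <- function(track, quantile = 0.99) {
  stopifnot(nrow(track) > 0, quantile > 0, quantile <= 1)
  sorted <- sort(track$count)
  k <- max(1L, ceiling(quantile * length(sorted)))
  thr <- sorted[k]
  track$threshold <- thr
  track$significant <- track$count > thr
  track
}

#' Assemble ROH islands from flagged SNPs
#'
#' Significant SNPs on one chromosome are chained while consecutive
#' significant SNPs are at most `max_gap_bp` apart; chains with fewer
#' than `min_snps` members are discarded. The island span runs from the
#' first to the last member SNP.
#'
#' @param track flagged track from [significant_snps()].
#' @param max_gap_bp maximum distance between consecutive member SNPs
#'   (default 1e6).
#' @param min_snps minimum member SNPs per island (default 2).
#' @return data.frame with one row per island: `island_id`, `chromosome`,
#'   `start_bp`, `end_bp`, `length_bp`, `n_snps`, `snp_ids`.
#' @export
assemble_islands <- function(track, max_gap_bp = 1e6, min_snps = 2L) {
  sig <- track[track$significant, , drop = FALSE]
  empty <- data.frame(island_id = integer(), chromosome = integer(),
                      start_bp = numeric(), end_bp = numeric(),
                      length_bp = numeric(), n_snps = integer(),
                      snp_ids = character(), stringsAsFactors = FALSE)
  if (!nrow(sig)) return(empty)
  sig <- sig[order(sig$chromosome, sig$position_bp), , drop = FALSE]
  new_chain <- c(TRUE, diff(sig$position_bp) > max_gap_bp |
                   diff(as.integer(factor(sig$chromosome))) != 0)
  chain <- cumsum(new_chain)
  sp <- split(seq_len(nrow(sig)), chain)
  sp <- sp[vapply(sp, length, integer(1)) >= min_snps]
  if (!length(sp)) return(empty)
  out <- do.call(rbind, lapply(sp, function(i) {
    data.frame(chromosome = sig$chromosome[i[1]],
               start_bp = min(sig$position_bp[i]),
               end_bp = max(sig$position_bp[i]),
               n_snps = length(i),
               snp_ids = paste(sig$snp_id[i], collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chromosome, out$start_bp), , drop = FALSE]
  out$length_bp <- out$end_bp - out$start_bp
  out$island_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("island_id", "chromosome", "start_bp", "end_bp", "length_bp",
          "n_snps", "snp_ids")]
}

#' Annotate ROH islands with F_ST, odds-ratio and incidence summaries
#'
#' For each island: mean and SD over member SNPs of the raw F_ST, of the
#' per-SNP logistic odds ratios (non-finite ORs from separated SNPs are
#' excluded), and of the per-type incidence percentages; plus the
#' chromosome-wide mean F_ST of the island's chromosome for contrast.
#'
#' @param islands data.frame from [assemble_islands()].
#' @param track incidence track (with per-type percent columns) aligned
#'   to the map.
#' @param fst optional data.frame from [fst_per_snp()] (`snp_id`, `fst`).
#' @param logistic optional data.frame from [roh_logistic()] (`snp_id`,
#'   `odds_ratio`).
#' @return `islands` with summary columns appended.
#' @export
island_summary <- function(islands, track, fst = NULL, logistic = NULL) {
  if (!nrow(islands)) return(islands)
  member <- strsplit(islands$snp_ids, ",", fixed = TRUE)
  get <- function(tab, col, ids) {
    v <- tab[[col]][match(ids, tab$snp_id)]
    if (anyNA(match(ids, tab$snp_id))) {
      stop("island member SNP missing from the ", col, " track")
    }
    v
  }
  ptype_cols <- grep("^percent_", names(track), value = TRUE)
  for (pc in ptype_cols) {
    islands[[paste0("mean_", pc)]] <- vapply(member, function(ids)
      mean(get(track, pc, ids)), numeric(1))
  }
  islands$mean_snp_roh_percent <- vapply(member, function(ids)
    mean(get(track, "percent", ids)), numeric(1))
  if (!is.null(fst)) {
    islands$mean_fst <- vapply(member, function(ids)
      mean(get(fst, "fst", ids)), numeric(1))
    islands$sd_fst <- vapply(member, function(ids)
      stats::sd(get(fst, "fst", ids)), numeric(1))
    chr_mean <- tapply(fst$fst, track$chromosome[match(fst$snp_id,
                                                       track$snp_id)],
                       mean, na.rm = TRUE)
    islands$chromosome_mean_fst <-
      as.numeric(chr_mean[as.character(islands$chromosome)])
  }
  if (!is.null(logistic)) {
    islands$mean_or <- vapply(member, function(ids) {
      v <- get(logistic, "odds_ratio", ids)
      v <- v[is.finite(v)]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    islands$sd_or <- vapply(member, function(ids) {
      v <- get(logistic, "odds_ratio", ids)
      v <- v[is.finite(v)]
      if (length(v) > 1) stats::sd(v) else NA_real_
    }, numeric(1))
  }
  islands
}
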