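#' Run the full ROH characterization pipeline
#'
#' Executes the complete workflow on a genotype panel: joint QC, the
#' three analysis datasets (joint/ascertainment-filtered plus the two
#' type-specific sets), ROH detection on each, per-animal and group
#' statistics, ROH-island scanning, the ROH-coded genomic relationship
#' matrix with eigen-analysis, and — on the joint dataset — the per-SNP
#' F_ST/LOWESS scan and the logistic regression of ROH membership on
#' type. Every table is written as a TSV under `out_dir` together with a
#' run log of parameters and stage counts.
#'
#' @param geno a [geno_set()], or `NULL` to read from files.
#' @param ped_path,map_path,sample_sheet_path PLINK text inputs, used
#'   when `geno` is `NULL`.
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param qc a [qc_params()] for the joint QC.
#' @param roh a [roh_params()].
#' @param types the two type labels, the second being the
#'   ascertainment-limited type (default `c("river", "swamp")`).
#' @param grm_threshold_bp minimum run length for code 2 in the ROH
#'   coding (default 4e6).
#' @param island_quantile significance percentile for the incidence
#'   track (default 0.99).
#' @param island_max_gap_bp,island_min_snps island chaining parameters.
#' @param lowess_span,lowess_iterations LOWESS parameters for the F_ST
#'   scan.
#' @param fst_n_sd outlier threshold in SDs on the smoothed F_ST
#'   (default 3).
#' @return Invisibly, a nested result bundle: `qc`, `datasets`, and per
#'   dataset `rohs`, `animal_summary`, `group_table`, `length_classes`,
#'   `unique_roh`, `track`, `islands`, `grm`, `eigen`; plus `fst` and
#'   `logistic` for the joint dataset.
#' @export
run_roh_pipeline <- function(geno = NULL, ped_path = NULL, map_path = NULL,
                             sample_sheet_path = NULL, out_dir = NULL,
                             qc = qc_params(), roh = roh_params(),
                             types = c("river", "swamp"),
                             grm_threshold_bp = 4e6,
                             island_quantile = 0.99,
                             island_max_gap_bp = 1e6,
                             island_min_snps = 2L,
                             lowess_span = 0.05, lowess_iterations = 3L,
                             fst_n_sd = 3) {
  if (is.null(geno)) {
    geno <- read_plink_text(ped_path, map_path, sample_sheet_path)
  }
  log_lines <- c(sprintf("rohscan %s",
                         as.character(utils::packageVersion("rohscan"))),
                 sprintf("input: %d samples x %d SNPs", nrow(geno$calls),
                         ncol(geno$calls)))
  emit <- function(tab, name) {
    if (!is.null(out_dir)) {
      utils::write.table(tab, file.path(out_dir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  qc_res <- apply_qc(geno, qc)
  log_lines <- c(log_lines, sprintf(
    "joint QC: %d samples removed, %d SNPs removed -> %d x %d",
    qc_res$report$n_samples_removed, qc_res$report$n_snps_removed,
    nrow(qc_res$geno$calls), ncol(qc_res$geno$calls)))
  emit(data.frame(filter = c("samples_call_rate", "snp_call_rate",
                             "snp_maf", "snp_hwe", "snp_monomorphic"),
                  removed = c(qc_res$report$n_samples_removed,
                              qc_res$report$n_snps_removed_call_rate,
                              qc_res$report$n_snps_removed_maf,
                              qc_res$report$n_snps_removed_hwe,
                              qc_res$report$n_snps_removed_monomorphic)),
       "qc_report")

  ds <- build_datasets(qc_res$geno, types = types)
  bundle <- list(qc = qc_res, datasets = ds, results = list())
  for (nm in c("all", types)) {
    g <- ds[[nm]]
    log_lines <- c(log_lines, sprintf("%s dataset: %d samples x %d SNPs",
                                      nm, nrow(g$calls), ncol(g$calls)))
    rohs <- detect_roh(g, roh)
    gl <- genome_length(g)
    anim <- summarize_animals(rohs, g$samples$sample_id, gl)
    gtab <- group_roh_table(rohs, g$samples, gl)
    lct <- if (nrow(rohs)) classify_lengths(rohs, "type") else NULL
    uq <- count_unique(rohs)
    inc <- roh_incidence(rohs, g)
    track <- significant_snps(snp_roh_counts(rohs, g, incidence = inc),
                              quantile = island_quantile)
    isl <- assemble_islands(track, max_gap_bp = island_max_gap_bp,
                            min_snps = island_min_snps)
    coded <- roh_recode(g, rohs, threshold_bp = grm_threshold_bp)
    grm <- build_grm(coded)
    eig <- eigen_scores(grm, g$samples)
    res <- list(geno = g, rohs = rohs, genome_length_bp = gl,
                animal_summary = anim, group_table = gtab,
                length_classes = lct, unique_roh = uq,
                incidence = inc, track = track, islands = isl,
                grm = grm, eigen = eig)
    if (nm == "all") {
      fst <- fst_per_snp(g, group_by = "type")
      fst <- lowess_track(fst, "fst", span = lowess_span,
                          iterations = lowess_iterations)
      fst <- call_outliers(fst, "fst_smooth", n_sd = fst_n_sd)
      logi <- roh_logistic(inc, g$samples$type, map = g$map)
      isl <- island_summary(isl, track, fst = fst, logistic = logi)
      res$fst <- fst
      res$logistic <- logi
      res$islands <- isl
      res$or_summary <- rbind(
        cbind(data.frame(subset = "all_snps"), or_summary(logi)),
        cbind(data.frame(subset = "significant_snps"),
              or_summary(logi, subset = track$significant)))
      emit(fst, paste0(nm, "_fst"))
      emit(logi, paste0(nm, "_logistic"))
      emit(res$or_summary, paste0(nm, "_or_summary"))
      log_lines <- c(log_lines, sprintf(
        "%s: %d F_ST outliers, %d logistic-significant SNPs", nm,
        sum(fst$outlier, na.rm = TRUE), sum(logi$significant)))
    }
    emit(rohs, paste0(nm, "_roh"))
    emit(anim, paste0(nm, "_animal_summary"))
    emit(gtab, paste0(nm, "_group_table"))
    if (!is.null(lct)) emit(lct, paste0(nm, "_length_classes"))
    emit(utils::head(uq$shared, 10), paste0(nm, "_top_shared_roh"))
    emit(track, paste0(nm, "_snp_roh_track"))
    emit(isl, paste0(nm, "_islands"))
    emit(cbind(data.frame(sample_id = rownames(grm$G)),
               as.data.frame(grm$G)), paste0(nm, "_grm"))
    emit(data.frame(component = seq_along(eig$values),
                    eigenvalue = eig$values,
                    percent_variance = eig$percent_variance),
         paste0(nm, "_eigenvalues"))
    if (!is.null(eig$population_means)) {
      emit(eig$population_means, paste0(nm, "_eigen_population_means"))
    }
    log_lines <- c(log_lines, sprintf(
      "%s: %d ROH (%d unique), %d significant SNPs, %d islands", nm,
      uq$total, uq$unique, sum(track$significant), nrow(isl)))
    bundle$results[[nm]] <- res
  }
  if (!is.null(out_dir)) {
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(bundle)
}
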