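#' Per-SNP Wright F_ST between two groups
#'
#' For each SNP with at least one called genotype per group, the
#' two-population Wright/Nei fixation index
#' \eqn{F_{ST} = (H_T - H_S) / H_T}, with
#' \eqn{H_S = (2 p_1 (1 - p_1) + 2 p_2 (1 - p_2)) / 2} and
#' \eqn{H_T = 2 \bar p (1 - \bar p)} where \eqn{\bar p} is the unweighted
#' mean of the two group frequencies. \eqn{H_T = 0} gives F_ST = 0. SNPs
#' missing all calls in one group are reported `NA`.
#'
#' @param g a [geno_set()].
#' @param group_by sample metadata column defining the two groups
#'   (default "type").
#' @return data.frame aligned to the map: `snp_id`, `chromosome`,
#'   `position_bp`, per-group frequencies `p_<group>`, `fst`.
#' @export
fst_per_snp <- function(g, group_by = "type") {
  stopifnot(inherits(g, "geno_set"))
  labels <- g$samples[[group_by]]
  groups <- sort(unique(labels))
  if (length(groups) != 2) {
    stop("exactly two groups required, found ", length(groups))
  }
  p1 <- .allele_freq(g$calls[labels == groups[1], , drop = FALSE])
  p2 <- .allele_freq(g$calls[labels == groups[2], , drop = FALSE])
  pb <- (p1 + p2) / 2
  ht <- 2 * pb * (1 - pb)
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  fst <- ifelse(ht == 0, 0, (ht - hs) / ht)
  fst[is.nan(p1) | is.nan(p2)] <- NA
  out <- data.frame(snp_id = g$map$snp_id, chromosome = g$map$chromosome,
                    position_bp = g$map$position_bp,
                    stringsAsFactors = FALSE)
  out[[paste0("p_", groups[1])]] <- p1
  out[[paste0("p_", groups[2])]] <- p2
  out$fst <- fst
  out
}

#' LOWESS smoothing of a per-SNP track
#'
#' Cleveland's locally weighted scatterplot smoothing (tricube-weighted
#' local linear regression with robustifying iterations), applied within
#' each chromosome against SNP position. Chromosomes with fewer than
#' three non-missing values pass through unchanged.
#'
#' @param track data.frame with `chromosome`, `position_bp` and the value
#'   column.
#' @param value name of the column to smooth (default "fst").
#' @param span fraction of within-chromosome points used per local fit
#'   (default 0.05).
#' @param iterations robustifying iterations (default 3).
#' @return `track` with a `<value>_smooth` column appended.
#' @export
lowess_track <- function(track, value = "fst", span = 0.05,
                         iterations = 3L) {
  y <- track[[value]]
  out <- rep(NA_real_, length(y))
  for (chr in unique(track$chromosome)) {
    sel <- which(track$chromosome == chr & !is.na(y))
    if (length(sel) < 3) {
      out[sel] <- y[sel]
      next
    }
    sm <- stats::lowess(track$position_bp[sel], y[sel], f = span,
                        iter = iterations, delta = 0)
    out[sel] <- sm$y
  }
  track[[paste0(value, "_smooth")]] <- out
  track
}

#' Flag outlier SNPs on a smoothed track
#'
#' The threshold is mean + 3 SD of the smoothed values over all SNPs
#' (one-sided, upper: the outliers of interest are high-differentiation
#' SNPs); SNPs strictly above it are flagged.
#'
#' @param track data.frame with the smoothed column.
#' @param value smoothed column name (default "fst_smooth").
#' @param n_sd number of standard deviations (default 3).
#' @return `track` with columns `outlier_threshold` and logical
#'   `outlier`.
#' @export
call_outliers <- function(track, value = "fst_smooth", n_sd = 3) {
  v <- track[[value]]
  thr <- mean(v, na.rm = TRUE) + n_sd * stats::sd(v, na.rm = TRUE)
  track$outlier_threshold <- thr
  track$outlier <- !is.na(v) & v > thr
  track
}

#' Per-SNP logistic regression of ROH membership on group
#'
#' For each SNP, the binary indicator "animal carries this SNP inside a
#' run" is regressed on the group label:
#' \eqn{\log(p / (1 - p)) = \beta_0 + \beta_{type}}, fitted by
#' iteratively reweighted least squares on the aggregated 2x2 table.
#' The odds ratio is \eqn{\exp(\beta_{type})} for the second group versus
#' the first, with a two-sided Wald p-value. Complete separation (a group
#' with all-0 or all-1 membership) is flagged; the OR is reported as the
#' limit (0 or Inf) and the p-value is `NA`.
#'
#' @param incidence logical membership matrix from [roh_incidence()]
#'   (samples x SNPs).
#' @param labels group label per sample (two levels; the first sorted
#'   level is the reference).
#' @param map optional map data.frame supplying `snp_id`, `chromosome`,
#'   `position_bp` for the output.
#' @param p_threshold significance flag threshold (default 0.01).
#' @return data.frame per SNP: `beta0`, `beta_type`, `odds_ratio`,
#'   `p_value`, `significant`, `separated`.
#' @export
roh_logistic <- function(incidence, labels, map = NULL,
                         p_threshold = 0.01) {
  groups <- sort(unique(labels))
  if (length(groups) != 2) {
    stop("exactly two groups required, found ", length(groups))
  }
  in2 <- labels == groups[2]
  n1 <- sum(!in2); n2 <- sum(in2)
  if (n1 == 0 || n2 == 0) stop("a group has no samples")
  k1 <- colSums(incidence[!in2, , drop = FALSE])
  k2 <- colSums(incidence[in2, , drop = FALSE])
  n_snp <- ncol(incidence)
  beta0 <- beta1 <- pval <- rep(NA_real_, n_snp)
  or <- rep(NA_real_, n_snp)
  sep <- k1 == 0 | k1 == n1 | k2 == 0 | k2 == n2
  grp <- factor(c(groups[1], groups[2]), levels = groups)
  for (j in which(!sep)) {
    fit <- stats::glm(cbind(c(k1[j], k2[j]), c(n1 - k1[j], n2 - k2[j])) ~ grp,
                      family = stats::binomial(),
                      control = stats::glm.control(epsilon = 1e-10,
                                                   maxit = 50))
    cf <- summary(fit)$coefficients
    beta0[j] <- cf[1, 1]
    beta1[j] <- cf[2, 1]
    or[j] <- exp(cf[2, 1])
    pval[j] <- cf[2, 4]
  }
  if (any(sep)) {
    p1 <- k1[sep] / n1; p2 <- k2[sep] / n2
    odds1 <- p1 / (1 - p1); odds2 <- p2 / (1 - p2)
    or[sep] <- ifelse(odds2 == odds1, 1, odds2 / odds1)
  }
  out <- data.frame(beta0 = beta0, beta_type = beta1, odds_ratio = or,
                    p_value = pval,
                    significant = !is.na(pval) & pval < p_threshold,
                    separated = sep, stringsAsFactors = FALSE)
  if (!is.null(map)) {
    out <- cbind(map[, c("snp_id", "chromosome", "position_bp")], out)
  } else if (!is.null(colnames(incidence))) {
    out <- cbind(data.frame(snp_id = colnames(incidence),
                            stringsAsFactors = FALSE), out)
  }
  rownames(out) <- NULL
  out
}

#' Summary of per-SNP odds ratios
#'
#' Mean and SD of the finite odds ratios, overall and optionally over a
#' subset (e.g. the significant island SNPs), with the count of excluded
#' non-finite (separated) SNPs.
#'
#' @param logistic data.frame from [roh_logistic()].
#' @param subset optional logical vector selecting a SNP subset.
#' @return one-row data.frame: `n`, `n_excluded`, `mean_or`, `sd_or`.
#' @export
or_summary <- function(logistic, subset = NULL) {
  v <- logistic$odds_ratio
  if (!is.null(subset)) v <- v[subset]
  fin <- is.finite(v)
  data.frame(n = sum(fin), n_excluded = sum(!fin),
             mean_or = mean(v[fin]), sd_or = stats::sd(v[fin]))
}
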