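#' Recode genotypes by ROH membership
#'
#' Produces the identical-by-state ROH coding: 0 = heterozygous,
#' 1 = homozygous not inside a qualifying run, 2 = homozygous inside a
#' run of the same animal longer than `threshold_bp`; missing stays
#' missing. Coding is per animal — another animal's run never affects a
#' genotype.
#'
#' @param g a [geno_set()].
#' @param rohs ROH data.frame from [detect_roh()] on `g`.
#' @param threshold_bp minimum run length for code 2 (default 4e6).
#' @return integer matrix (samples x SNPs) with entries 0/1/2/NA.
#' @export
roh_recode <- function(g, rohs, threshold_bp = 4e6) {
  stopifnot(inherits(g, "geno_set"))
  long <- rohs[rohs$length_bp > threshold_bp, , drop = FALSE]
  inc <- roh_incidence(long, g)
  hom <- g$calls == 0L | g$calls == 2L
  coded <- matrix(NA_integer_, nrow(g$calls), ncol(g$calls),
                  dimnames = dimnames(g$calls))
  coded[!is.na(hom) & !hom] <- 0L
  coded[!is.na(hom) & hom] <- 1L
  coded[!is.na(hom) & hom & inc] <- 2L
  coded
}

#' Genomic relationship matrix from a coded genotype matrix
#'
#' VanRaden-style first method applied to the coded matrix: column
#' frequencies `p_i` are half the column means of the codes over
#' non-missing entries; `Z = codes - 2 p_i`; missing entries are set to 0
#' after centering; `G = Z Z' / (2 sum p_i (1 - p_i))`. Degenerate columns
#' (`p_i` 0 or 1, or no data) are excluded from numerator and denominator.
#'
#' @param coded numeric matrix (samples x SNPs) of codes in 0/1/2/NA —
#'   either raw dosages or the ROH coding of [roh_recode()].
#' @return A list of class `grm` with elements `G` (n x n symmetric
#'   matrix), `p` (the frequencies used) and `denominator`.
#' @export
build_grm <- function(coded) {
  coded <- as.matrix(coded)
  if (nrow(coded) < 2) stop("need at least two samples")
  p <- colMeans(coded, na.rm = TRUE) / 2
  use <- is.finite(p) & p > 0 & p < 1
  if (!any(use)) stop("all columns degenerate: denominator would be zero")
  m <- coded[, use, drop = FALSE]
  p <- p[use]
  z <- sweep(m, 2, 2 * p)
  z[is.na(z)] <- 0
  denom <- 2 * sum(p * (1 - p))
  g <- tcrossprod(z) / denom
  structure(list(G = g, p = p, denominator = denom), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm: ", nrow(x$G), " x ", ncol(x$G), ", ", length(x$p),
      " informative SNPs, denominator ", format(x$denominator), "\n",
      sep = "")
  invisible(x)
}

#' Eigen-analysis of a genomic relationship matrix
#'
#' Full symmetric eigen-decomposition with eigenvalues sorted descending.
#' Percent variance per component is eigenvalue / trace x 100 (summing to
#' 100 over all components). Each eigenvector's sign is fixed so its
#' largest-magnitude coefficient is positive. When sample metadata is
#' supplied, per-population means of the leading eigenvector coefficients
#' are returned for structure plots.
#'
#' @param g_mat an n x n symmetric matrix, or a `grm` from [build_grm()].
#' @param samples optional data.frame (`sample_id`, `type`, `population`)
#'   aligned to the matrix rows.
#' @param n_scores number of leading eigenvectors summarized per
#'   population (default 3).
#' @return A list of class `grm_eigen`: `values`, `vectors`,
#'   `percent_variance`, and (with metadata) `scores` and
#'   `population_means`.
#' @export
eigen_scores <- function(g_mat, samples = NULL, n_scores = 3L) {
  if (inherits(g_mat, "grm")) g_mat <- g_mat$G
  if (!isSymmetric(unname(g_mat), tol = 1e-8)) {
    stop("matrix is not symmetric")
  }
  e <- eigen((g_mat + t(g_mat)) / 2, symmetric = TRUE)
  # eigen() already sorts descending; fix signs
  for (j in seq_len(ncol(e$vectors))) {
    k <- which.max(abs(e$vectors[, j]))
    if (e$vectors[k, j] < 0) e$vectors[, j] <- -e$vectors[, j]
  }
  pct <- e$values / sum(e$values) * 100
  out <- list(values = e$values, vectors = e$vectors,
              percent_variance = pct)
  if (!is.null(samples)) {
    n_scores <- min(n_scores, ncol(e$vectors))
    sc <- data.frame(sample_id = samples$sample_id,
                     type = samples$type,
                     population = samples$population,
                     stringsAsFactors = FALSE)
    for (j in seq_len(n_scores)) sc[[paste0("ev", j)]] <- e$vectors[, j]
    pm <- stats::aggregate(sc[paste0("ev", seq_len(n_scores))],
                           by = list(type = sc$type,
                                     population = sc$population),
                           FUN = mean)
    out$scores <- sc
    out$population_means <- pm
  }
  class(out) <- "grm_eigen"
  out
}
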