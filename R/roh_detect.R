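#' Detection parameters for runs of homozygosity
#'
#' Defaults are the rule set used for medium-density panels: a run must
#' contain at least 15 SNPs, span at least 1 Mb, have no gap between
#' consecutive SNPs larger than 1 Mb, and contain no heterozygous or
#' missing genotypes. Sliding windows are not used; runs are exact maximal
#' stretches of qualifying calls. The heterozygote/missing allowances can
#' be raised to emulate more permissive rule sets.
#'
#' @param min_snps minimum number of SNPs in a run (default 15).
#' @param min_length_bp minimum span in bp, last minus first SNP position
#'   (default 1e6).
#' @param max_gap_bp maximum distance between consecutive SNPs inside a
#'   run (default 1e6); a larger gap terminates the run even if both
#'   flanking calls are homozygous.
#' @param max_het maximum heterozygous calls allowed inside a run
#'   (default 0).
#' @param max_missing maximum missing calls allowed inside a run
#'   (default 0).
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(min_snps = 15L, min_length_bp = 1e6,
                       max_gap_bp = 1e6, max_het = 0L, max_missing = 0L) {
  stopifnot(min_snps >= 0, min_length_bp >= 0, max_gap_bp >= 0,
            max_het >= 0, max_missing >= 0)
  structure(list(min_snps = as.integer(min_snps),
                 min_length_bp = as.numeric(min_length_bp),
                 max_gap_bp = as.numeric(max_gap_bp),
                 max_het = as.integer(max_het),
                 max_missing = as.integer(max_missing)),
            class = "roh_params")
}

# maximal windows over one gap-delimited stretch, with het/missing budgets.
# Returns matrix with columns l, r (indices into the stretch); a window is
# maximal when it cannot be extended either way without breaking a budget.
.max_windows <- function(is_het, is_miss, max_het, max_missing) {
  n <- length(is_het)
  if (n == 0L) return(NULL)
  lefts <- integer(n)
  l <- 1L; nh <- 0L; nm <- 0L
  for (r in seq_len(n)) {
    nh <- nh + is_het[r]; nm <- nm + is_miss[r]
    while (nh > max_het || nm > max_missing) {
      nh <- nh - is_het[l]; nm <- nm - is_miss[l]
      l <- l + 1L
    }
    lefts[r] <- l
  }
  keep <- if (n > 1L) c(lefts[-1L] > lefts[-n], TRUE) else TRUE
  r <- which(keep)
  l <- lefts[r]
  ok <- l <= r
  cbind(l = l[ok], r = r[ok])
}

#' Detect runs of homozygosity for one sample
#'
#' Scans one genotype row chromosome by chromosome. The chromosome is
#' first split wherever the distance between consecutive mapped SNPs
#' exceeds `max_gap_bp`; within each stretch, maximal windows containing
#' at most `max_het` heterozygous and `max_missing` missing calls are
#' located, then filtered by `min_snps` and `min_length_bp`. With the
#' default zero allowances this reduces to maximal runs of consecutive
#' homozygous, non-missing calls.
#'
#' @param calls_row integer vector of 0/1/2/NA calls aligned to `map`.
#' @param map map data.frame as in [geno_set()], sorted by
#'   (chromosome, position).
#' @param params a [roh_params()].
#' @param sample_id id recorded in the output (default "S1").
#' @return data.frame with columns `sample_id`, `chromosome`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_bp` (= `end_bp - start_bp`).
#' @export
detect_roh_sample <- function(calls_row, map, params = roh_params(),
                              sample_id = "S1") {
  if (length(calls_row) != nrow(map)) {
    stop("calls_row length ", length(calls_row),
         " does not match map with ", nrow(map), " SNPs")
  }
  out <- vector("list", 0L)
  for (chr in unique(map$chromosome)) {
    sel <- which(map$chromosome == chr)
    pos <- map$position_bp[sel]
    x <- calls_row[sel]
    # split at gaps exceeding the allowance
    brk <- which(diff(pos) > params$max_gap_bp)
    starts <- c(1L, brk + 1L)
    ends <- c(brk, length(sel))
    for (k in seq_along(starts)) {
      idx <- starts[k]:ends[k]
      xm <- x[idx]
      w <- .max_windows(as.integer(!is.na(xm) & xm == 1L),
                        as.integer(is.na(xm)),
                        params$max_het, params$max_missing)
      if (is.null(w) || nrow(w) == 0L) next
      sb <- pos[idx[w[, "l"]]]
      eb <- pos[idx[w[, "r"]]]
      ns <- w[, "r"] - w[, "l"] + 1L
      len <- eb - sb
      ok <- ns >= params$min_snps & len >= params$min_length_bp
      if (any(ok)) {
        out[[length(out) + 1L]] <- data.frame(
          sample_id = sample_id, chromosome = chr,
          start_bp = sb[ok], end_bp = eb[ok],
          n_snps = as.integer(ns[ok]), length_bp = as.numeric(len[ok]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sample_id = character(), chromosome = integer(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer(), length_bp = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chromosome, res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Detect runs of homozygosity for every sample in a genotype set
#'
#' @param g a [geno_set()].
#' @param params a [roh_params()].
#' @return data.frame of runs, ordered by (sample, chromosome, start),
#'   with sample `type` and `population` attached.
#' @export
detect_roh <- function(g, params = roh_params()) {
  stopifnot(inherits(g, "geno_set"))
  res <- lapply(seq_len(nrow(g$calls)), function(i) {
    detect_roh_sample(g$calls[i, ], g$map, params,
                      sample_id = g$samples$sample_id[i])
  })
  res <- do.call(rbind, res)
  res$type <- g$samples$type[match(res$sample_id, g$samples$sample_id)]
  res$population <-
    g$samples$population[match(res$sample_id, g$samples$sample_id)]
  rownames(res) <- NULL
  res
}
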