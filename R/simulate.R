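#' Configuration for the synthetic genotype generator
#'
#' Defaults emulate a two-type water-buffalo-style SNP-array study:
#' 24 autosomes of 100 Mb carrying 2000 SNPs each (about 1 SNP / 50 kb,
#' comparable to a ~47 K panel over ~2.4 Gb), 185 + 153 animals split
#' over 15 + 13 populations, a two-level drift model (ancestral
#' frequencies Uniform(0.05, 0.5); type frequencies Balding-Nichols
#' around the ancestral value with `f_drift_type`; population frequencies
#' Balding-Nichols around the type value with `f_drift_pop`), a fraction
#' of SNPs forced monomorphic in the second type (array ascertainment
#' bias), and per-animal planted autozygous segments with an exponential
#' length mixture. `f_drift_type = 0.48` is calibrated so the realized
#' mean per-SNP F_ST between types is about 0.2.
#'
#' @param n_chromosomes number of autosomes (default 24).
#' @param chromosome_length_bp length of each autosome (default 1e8).
#' @param snps_per_chromosome markers per autosome (default 2000).
#' @param pop_sizes named list with one integer vector per type giving
#'   the per-population sample sizes; defaults to 185 river / 153 swamp
#'   animals over 15 / 13 populations.
#' @param f_drift_type Balding-Nichols drift of each type from the
#'   ancestral frequency (default 0.48).
#' @param f_drift_pop drift of each population from its type frequency
#'   (default 0.05).
#' @param swamp_monomorphic_fraction fraction of SNPs forced monomorphic
#'   in the second type (default 0.6).
#' @param roh_rate mean planted autozygous segments per animal (Poisson);
#'   either one number or one per type, emulating the higher autozygosity
#'   of the second (swamp-like) type (default `c(40, 70)`).
#' @param roh_length_means,roh_length_weights exponential mixture for
#'   planted segment lengths in bp (defaults: means 2.5 and 9 Mb with
#'   weights 0.85 / 0.15 — a short/long class mixture).
#' @param island_loci optional data.frame (`chromosome`, `position_bp`)
#'   of loci where segment planting is boosted.
#' @param island_boost probability that a planted segment is centred on
#'   a random island locus instead of a uniform position (default 0.2
#'   when `island_loci` is given).
#' @param missing_rate per-call missing probability (default 1e-4, a post-QC
#'   array missingness level).
#' @param seed mandatory integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 24L,
                       chromosome_length_bp = 1e8,
                       snps_per_chromosome = 2000L,
                       pop_sizes = NULL,
                       f_drift_type = 0.48,
                       f_drift_pop = 0.05,
                       swamp_monomorphic_fraction = 0.6,
                       roh_rate = c(40, 70),
                       roh_length_means = c(2.5e6, 9e6),
                       roh_length_weights = c(0.85, 0.15),
                       island_loci = NULL,
                       island_boost = 0.2,
                       missing_rate = 1e-4,
                       seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  if (is.null(pop_sizes)) {
    pop_sizes <- list(
      river = c(30, 12, 15, 9, 10, 8, 30, 7, 8, 4, 3, 10, 15, 9, 15),
      swamp = c(15, 15, 11, 14, 12, 15, 12, 7, 8, 10, 21, 5, 8))
  }
  stopifnot(length(pop_sizes) == 2, !is.null(names(pop_sizes)))
  for (v in c(f_drift_type, f_drift_pop, swamp_monomorphic_fraction,
              missing_rate, island_boost)) {
    if (v < 0 || v > 1) stop("fractions must be in [0, 1]")
  }
  stopifnot(chromosome_length_bp > 0, all(roh_length_means > 0),
            all(roh_length_weights >= 0), all(roh_rate >= 0),
            length(roh_rate) %in% c(1L, 2L))
  if (!is.null(island_loci)) {
    if (any(island_loci$position_bp < 1 |
            island_loci$position_bp > chromosome_length_bp |
            island_loci$chromosome < 1 |
            island_loci$chromosome > n_chromosomes)) {
      stop("island locus outside chromosome span")
    }
  }
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length_bp = chromosome_length_bp,
                 snps_per_chromosome = as.integer(snps_per_chromosome),
                 pop_sizes = pop_sizes,
                 f_drift_type = f_drift_type,
                 f_drift_pop = f_drift_pop,
                 swamp_monomorphic_fraction = swamp_monomorphic_fraction,
                 roh_rate = roh_rate,
                 roh_length_means = roh_length_means,
                 roh_length_weights = roh_length_weights /
                   sum(roh_length_weights),
                 island_loci = island_loci,
                 island_boost = island_boost,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Balding-Nichols draws, one per element of p, with drift f; degenerate
# frequencies pass through unchanged
.bn_draw <- function(p, f) {
  if (f <= 0) return(p)
  out <- p
  ok <- p > 0 & p < 1
  out[ok] <- stats::rbeta(sum(ok), p[ok] * (1 - f) / f,
                          (1 - p[ok]) * (1 - f) / f)
  out
}

#' Simulate a two-type genotype panel with planted autozygous segments
#'
#' Draws the map, the hierarchical allele frequencies, Hardy-Weinberg
#' genotypes per population, then plants per-animal autozygous segments
#' (every spanned SNP homozygous for one founder allele drawn by the
#' population frequency). Each planted segment is terminated by forcing a
#' heterozygous call at the nearest informative SNP beyond each boundary,
#' modelling the haplotype mismatch that ends a real autozygous tract and
#' making truth boundaries observable. Missing calls are masked at random
#' last.
#'
#' @param config a [sim_config()].
#' @return A list with `geno` (a [geno_set()]) and `truth`: `segments`
#'   (planted segments with observable spans: `first_snp_bp`,
#'   `last_snp_bp`, `n_snps_spanned`), `freq` (ancestral / type
#'   frequencies), `pop_freq` (per-population frequency matrix),
#'   `island_loci`, `monomorphic_forced` (logical per SNP).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nc <- config$n_chromosomes
  nsc <- config$snps_per_chromosome
  n_snp <- nc * nsc
  chrom <- rep(seq_len(nc), each = nsc)
  pos <- unlist(lapply(seq_len(nc), function(ch)
    sort(sample.int(config$chromosome_length_bp, nsc))))
  map <- data.frame(snp_id = sprintf("snp%d_%d", chrom, pos),
                    chromosome = chrom, position_bp = pos,
                    allele_a = "A", allele_b = "B",
                    stringsAsFactors = FALSE)

  types <- names(config$pop_sizes)
  p_anc <- stats::runif(n_snp, 0.05, 0.5)
  p_type <- sapply(types, function(tp)
    .bn_draw(p_anc, config$f_drift_type))
  mono <- stats::runif(n_snp) < config$swamp_monomorphic_fraction
  p_type[mono, 2] <- 0

  pops <- unlist(lapply(types, function(tp)
    sprintf("%s_P%02d", toupper(substr(tp, 1, 3)),
            seq_along(config$pop_sizes[[tp]]))))
  pop_type <- rep(types, times = lengths(config$pop_sizes))
  pop_n <- unlist(config$pop_sizes, use.names = FALSE)
  pop_freq <- matrix(0, n_snp, length(pops),
                     dimnames = list(NULL, pops))
  for (k in seq_along(pops)) {
    pt <- p_type[, match(pop_type[k], types)]
    pop_freq[, k] <- .bn_draw(pt, config$f_drift_pop)
  }

  n_samp <- sum(pop_n)
  samples <- data.frame(
    sample_id = sprintf("ind%03d", seq_len(n_samp)),
    type = rep(pop_type, times = pop_n),
    population = rep(pops, times = pop_n),
    stringsAsFactors = FALSE)
  calls <- matrix(NA_integer_, n_samp, n_snp)
  row0 <- 0L
  for (k in seq_along(pops)) {
    nk <- pop_n[k]
    pk <- pop_freq[, k]
    calls[row0 + seq_len(nk), ] <-
      matrix(stats::rbinom(nk * n_snp, 2L, rep(pk, each = nk)), nk, n_snp)
    row0 <- row0 + nk
  }

  # plant autozygous segments
  chr_idx <- split(seq_len(n_snp), chrom)
  rate <- if (length(config$roh_rate) == 1L) {
    rep(config$roh_rate, n_samp)
  } else {
    config$roh_rate[match(samples$type, types)]
  }
  n_seg <- stats::rpois(n_samp, rate)
  seg_list <- vector("list", n_samp)
  has_isl <- !is.null(config$island_loci) && nrow(config$island_loci) > 0
  for (i in seq_len(n_samp)) {
    if (n_seg[i] == 0) next
    placed <- vector("list", 0L)
    occupied <- lapply(seq_len(nc), function(ch) matrix(numeric(0), 0, 2))
    for (s in seq_len(n_seg[i])) {
      comp <- sample.int(length(config$roh_length_means), 1,
                         prob = config$roh_length_weights)
      len <- stats::rexp(1, 1 / config$roh_length_means[comp])
      for (try in 1:20) {
        if (has_isl && stats::runif(1) < config$island_boost) {
          r <- config$island_loci[sample.int(nrow(config$island_loci), 1), ]
          ch <- r$chromosome
          center <- r$position_bp
        } else {
          ch <- sample.int(nc, 1)
          center <- stats::runif(1, 1, config$chromosome_length_bp)
        }
        a <- max(1, center - len / 2)
        b <- min(config$chromosome_length_bp, center + len / 2)
        occ <- occupied[[ch]]
        # neighbouring planted segments must be separated by at least one
        # mapped SNP, otherwise they would fuse into a single detected run
        pch <- pos[chr_idx[[ch]]]
        separated <- TRUE
        if (nrow(occ)) {
          if (any(b >= occ[, 1] & a <= occ[, 2])) {
            separated <- FALSE
          } else {
            for (q in seq_len(nrow(occ))) {
              gap <- if (occ[q, 2] < a) c(occ[q, 2], a) else c(b, occ[q, 1])
              if (!any(pch > gap[1] & pch < gap[2])) separated <- FALSE
            }
          }
        }
        if (separated) {
          occupied[[ch]] <- rbind(occ, c(a, b))
          placed[[length(placed) + 1L]] <-
            data.frame(sample_id = samples$sample_id[i], chromosome = ch,
                       start_bp = a, end_bp = b,
                       stringsAsFactors = FALSE)
          break
        }
      }
    }
    if (length(placed)) seg_list[[i]] <- do.call(rbind, placed)
  }
  segments <- do.call(rbind, seg_list)
  if (is.null(segments)) {
    segments <- data.frame(sample_id = character(), chromosome = integer(),
                           start_bp = numeric(), end_bp = numeric(),
                           stringsAsFactors = FALSE)
  }

  # apply segments: homozygous founder allele per SNP; then het flanks
  if (nrow(segments)) {
    seg_row <- match(segments$sample_id, samples$sample_id)
    pop_of <- match(samples$population, pops)
    first_bp <- last_bp <- rep(NA_real_, nrow(segments))
    n_span <- integer(nrow(segments))
    for (s in seq_len(nrow(segments))) {
      sel <- chr_idx[[segments$chromosome[s]]]
      psel <- pos[sel]
      j <- sel[psel >= segments$start_bp[s] & psel <= segments$end_bp[s]]
      n_span[s] <- length(j)
      if (!length(j)) next
      first_bp[s] <- pos[j[1]]
      last_bp[s] <- pos[j[length(j)]]
      pk <- pop_freq[j, pop_of[seg_row[s]]]
      calls[seg_row[s], j] <- 2L * stats::rbinom(length(j), 1L, pk)
    }
    segments$first_snp_bp <- first_bp
    segments$last_snp_bp <- last_bp
    segments$n_snps_spanned <- n_span
    # heterozygous flanks at the nearest informative, uncovered SNP
    grp <- split(seq_len(nrow(segments)),
                 list(row = seg_row, chr = segments$chromosome),
                 drop = TRUE)
    for (gk in grp) {
      i <- seg_row[gk[1]]
      sel <- chr_idx[[segments$chromosome[gk[1]]]]
      psel <- pos[sel]
      covered <- rep(FALSE, length(sel))
      for (s in gk) {
        covered <- covered | (psel >= segments$start_bp[s] &
                                psel <= segments$end_bp[s])
      }
      pf <- pop_freq[sel, pop_of[i]]
      informative <- pf > 0 & pf < 1 & !covered
      for (s in gk) {
        if (!n_span[s]) next
        below <- which(psel < segments$start_bp[s] & informative)
        above <- which(psel > segments$end_bp[s] & informative)
        if (length(below)) calls[i, sel[max(below)]] <- 1L
        if (length(above)) calls[i, sel[min(above)]] <- 1L
      }
    }
  }

  if (config$missing_rate > 0) {
    calls[stats::runif(length(calls)) < config$missing_rate] <- NA_integer_
  }

  g <- geno_set(calls, map, samples)
  truth <- list(segments = segments,
                freq = data.frame(snp_id = map$snp_id, ancestral = p_anc,
                                  type1 = p_type[, 1], type2 = p_type[, 2],
                                  stringsAsFactors = FALSE),
                pop_freq = pop_freq,
                island_loci = config$island_loci,
                monomorphic_forced = mono)
  list(geno = g, truth = truth)
}

#' Recovery report of planted segments against detected runs
#'
#' A planted segment is "expected recoverable" when its spanned SNPs meet
#' the detection criteria (at least `min_snps` spanned SNPs, SNP span at
#' least `min_length_bp`, no internal gap above `max_gap_bp`). For each
#' such segment the best same-animal overlapping detected run is found;
#' the boundary error is the larger of the two distances between run
#' boundary and the segment's first/last spanned SNP. The segment counts
#' as recovered when both boundary errors are within one local inter-SNP
#' interval. Detected runs overlapping no planted segment of their animal
#' are counted as false discoveries.
#'
#' @param detected ROH data.frame from [detect_roh()].
#' @param truth truth list from [simulate_panel()] (or its `segments`
#'   data.frame).
#' @param map map data.frame of the panel.
#' @param params the [roh_params()] used for detection.
#' @return A list: `per_segment` (eligibility, recovery and boundary
#'   error per planted segment), `n_eligible`, `n_recovered`,
#'   `sensitivity`, `mean_boundary_error_bp`, `false_positives`.
#' @export
truth_recovery_report <- function(detected, truth, map,
                                  params = roh_params()) {
  segments <- if (is.data.frame(truth)) truth else truth$segments
  per <- segments
  n <- nrow(per)
  per$eligible <- FALSE
  per$recovered <- FALSE
  per$boundary_error_bp <- NA_real_
  chr_idx <- split(seq_len(nrow(map)), map$chromosome)
  for (s in seq_len(n)) {
    sel <- chr_idx[[as.character(per$chromosome[s])]]
    psel <- map$position_bp[sel]
    inside <- which(psel >= per$start_bp[s] & psel <= per$end_bp[s])
    if (length(inside) < params$min_snps) next
    span <- psel[inside[length(inside)]] - psel[inside[1]]
    if (span < params$min_length_bp) next
    if (length(inside) > 1 &&
        max(diff(psel[inside])) > params$max_gap_bp) next
    per$eligible[s] <- TRUE
    # allowed slack: one inter-SNP interval at each boundary
    lo <- inside[1]; hi <- inside[length(inside)]
    tol_lo <- if (lo > 1) psel[lo] - psel[lo - 1] else Inf
    tol_hi <- if (hi < length(psel)) psel[hi + 1] - psel[hi] else Inf
    d <- detected[detected$sample_id == per$sample_id[s] &
                    detected$chromosome == per$chromosome[s] &
                    detected$end_bp >= psel[lo] &
                    detected$start_bp <= psel[hi], , drop = FALSE]
    if (!nrow(d)) next
    err_lo <- abs(d$start_bp - psel[lo])
    err_hi <- abs(d$end_bp - psel[hi])
    best <- which.min(pmax(err_lo, err_hi))
    per$boundary_error_bp[s] <- max(err_lo[best], err_hi[best])
    per$recovered[s] <- err_lo[best] <= tol_lo && err_hi[best] <= tol_hi
  }
  fp <- 0L
  if (nrow(detected)) {
    for (k in seq_len(nrow(detected))) {
      tr <- segments[segments$sample_id == detected$sample_id[k] &
                       segments$chromosome == detected$chromosome[k] &
                       segments$end_bp >= detected$start_bp[k] &
                       segments$start_bp <= detected$end_bp[k], ,
                     drop = FALSE]
      if (!nrow(tr)) fp <- fp + 1L
    }
  }
  elig <- per$eligible
  list(per_segment = per,
       n_eligible = sum(elig),
       n_recovered = sum(per$recovered[elig]),
       sensitivity = if (any(elig)) mean(per$recovered[elig]) else NA_real_,
       mean_boundary_error_bp =
         mean(per$boundary_error_bp[elig], na.rm = TRUE),
       false_positives = fp)
}
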