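# Independent brute-force oracles used to cross-check the implementation.

# Exhaustive-window ROH oracle: enumerates every (i, j) window on one
# chromosome, tests the het/missing budgets and the gap rule, keeps
# maximal windows, then applies the SNP-count and length filters.
oracle_roh <- function(calls, pos, params) {
  n <- length(calls)
  het <- cumsum(!is.na(calls) & calls == 1L)
  mis <- cumsum(is.na(calls))
  gaps <- if (n > 1) diff(pos) else numeric(0)
  valid <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    js <- i:n
    nh <- het[js] - if (i > 1) het[i - 1] else 0
    nm <- mis[js] - if (i > 1) mis[i - 1] else 0
    gm <- if (i < n) c(0, cummax(gaps[i:(n - 1)])) else 0
    valid[i, js] <- nh <= params$max_het & nm <= params$max_missing &
      gm <= params$max_gap_bp
  }
  ext_left <- rbind(FALSE, valid[-n, , drop = FALSE])
  ext_right <- cbind(valid[, -1, drop = FALSE], FALSE)
  maximal <- valid & !ext_left & !ext_right
  idx <- which(maximal, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer()))
  }
  i <- idx[, 1]; j <- idx[, 2]
  ns <- j - i + 1L
  len <- pos[j] - pos[i]
  keep <- ns >= params$min_snps & len >= params$min_length_bp
  out <- data.frame(start_bp = pos[i][keep], end_bp = pos[j][keep],
                    n_snps = as.integer(ns[keep]))
  out[order(out$start_bp), , drop = FALSE]
}

# Full-enumeration HWE exact test oracle using the conditional-probability
# recurrence P(h + 2) / P(h) = 4 hom_a hom_b / ((h + 2)(h + 1)); plain
# products, no gamma functions.
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  n_minor <- min(n_a, n_b)
  if (n_minor == 0) return(1)
  hets <- seq.int(n_minor %% 2, n_minor, by = 2)
  pr <- numeric(length(hets))
  pr[1] <- 1
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1]
    hom_a <- (n_a - h) / 2
    hom_b <- (n_b - h) / 2
    pr[k] <- pr[k - 1] * 4 * hom_a * hom_b / ((h + 2) * (h + 1))
  }
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# Direct implementation of Cleveland's LOWESS (tricube local linear fit
# with bisquare robustness iterations), written from the algorithm
# definition; no interpolation shortcut.
oracle_lowess <- function(x, y, f = 2 / 3, iter = 3L) {
  n <- length(x)
  o <- order(x)
  x <- x[o]; y <- y[o]
  ns <- max(2L, min(n, floor(f * n + 1e-7)))
  rng <- x[n] - x[1]
  fit_at <- function(i, nleft, nright, rw, userw) {
    xs <- x[i]
    h <- max(xs - x[nleft], x[nright] - xs)
    h9 <- 0.999 * h; h1 <- 0.001 * h
    w <- numeric(n)
    a <- 0
    j <- nleft
    while (j <= n) {
      r <- abs(x[j] - xs)
      if (r <= h9) {
        w[j] <- if (r <= h1) 1 else (1 - (r / h)^3)^3
        if (userw) w[j] <- w[j] * rw[j]
        a <- a + w[j]
      } else if (x[j] > xs) break
      j <- j + 1
    }
    nrt <- j - 1
    if (a <= 0) return(NA_real_)
    w <- w / a
    if (h > 0) {
      aw <- sum(w[nleft:nrt] * x[nleft:nrt])
      b <- xs - aw
      cc <- sum(w[nleft:nrt] * (x[nleft:nrt] - aw)^2)
      if (sqrt(cc) > 0.001 * rng) {
        b <- b / cc
        w[nleft:nrt] <- w[nleft:nrt] * (b * (x[nleft:nrt] - aw) + 1)
      }
    }
    sum(w[nleft:nrt] * y[nleft:nrt])
  }
  rw <- rep(1, n)
  ys <- numeric(n)
  for (robust in 0:iter) {
    nleft <- 1L; nright <- ns
    for (i in seq_len(n)) {
      while (nright < n) {
        d1 <- x[i] - x[nleft]
        d2 <- x[nright + 1] - x[i]
        if (d1 <= d2) break
        nleft <- nleft + 1L
        nright <- nright + 1L
      }
      v <- fit_at(i, nleft, nright, rw, robust > 0)
      ys[i] <- if (is.na(v)) y[i] else v
    }
    if (robust == iter) break
    res <- y - ys
    cmad <- 6 * stats::median(abs(res))
    if (cmad < 1e-7 * mean(abs(y))) break
    c9 <- 0.999 * cmad; c1 <- 0.001 * cmad
    r <- abs(res)
    rw <- ifelse(r <= c1, 1,
                 ifelse(r <= c9, (1 - (r / cmad)^2)^2, 0))
  }
  list(x = x, y = ys)
}

# single-chromosome map builder for detection tests
toy_map <- function(pos, chromosome = 1L) {
  data.frame(snp_id = paste0("s", seq_along(pos)),
             chromosome = chromosome, position_bp = pos,
             allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
}

# small geno_set builder
toy_geno <- function(calls, pos = NULL, chromosome = NULL,
                     types = NULL, populations = NULL) {
  calls <- as.matrix(calls)
  n_snp <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(n_snp) * 100000
  if (is.null(chromosome)) chromosome <- rep(1L, n_snp)
  if (is.null(types)) types <- rep("river", nrow(calls))
  if (is.null(populations)) populations <- toupper(types)
  map <- data.frame(snp_id = paste0("s", seq_len(n_snp)),
                    chromosome = chromosome, position_bp = pos,
                    allele_a = "A", allele_b = "B",
                    stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = paste0("ind", seq_len(nrow(calls))),
                        type = types, population = populations,
                        stringsAsFactors = FALSE)
  geno_set(calls, map, samples)
}

# two-group geno_set whose per-group allele frequencies are realized exactly
geno_with_freqs <- function(p_river, p_swamp, n_per = 50) {
  mk <- function(p, n) {
    n_b <- round(2 * n * p)
    calls <- integer(n)
    calls[seq_len(n_b %/% 2)] <- 2L
    if (n_b %% 2 == 1) calls[n_b %/% 2 + 1] <- 1L
    calls
  }
  calls <- rbind(
    do.call(cbind, lapply(p_river, function(p) mk(p, n_per))),
    do.call(cbind, lapply(p_swamp, function(p) mk(p, n_per))))
  toy_geno(calls, types = rep(c("river", "swamp"), each = n_per))
}
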