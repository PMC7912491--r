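test_that("per-SNP incidence counts animals whose runs span each SNP", {
  pos <- seq(1e5, 3e6, by = 1e5)
  g <- toy_geno(matrix(0L, 3, length(pos)), pos = pos)
  rohs <- data.frame(sample_id = c("ind1", "ind2", "ind2"),
                     chromosome = 1L,
                     start_bp = c(5e5, 5e5, 2.5e6),
                     end_bp = c(1e6, 1e6, 2.8e6),
                     n_snps = c(6L, 6L, 4L),
                     length_bp = c(5e5, 5e5, 3e5))
  track <- snp_roh_counts(rohs, g)
  expect_equal(track$count[track$position_bp == 7e5], 2L)
  expect_equal(track$count[track$position_bp == 2e6], 0L)
  expect_equal(track$percent[track$position_bp == 7e5], 2 / 3 * 100)
  # conservation: sum of counts equals sum of spanned SNPs over runs
  n_spanned <- vapply(seq_len(nrow(rohs)), function(k)
    sum(pos >= rohs$start_bp[k] & pos <= rohs$end_bp[k]), integer(1))
  expect_equal(sum(track$count), sum(n_spanned))
})

test_that("incidence count conservation holds exactly on simulated panels", {
  cfg <- sim_config(n_chromosomes = 3, snps_per_chromosome = 700,
                    pop_sizes = list(river = c(12), swamp = c(12)),
                    roh_rate = 15, seed = 23)
  sim <- simulate_panel(cfg)
  rohs <- detect_roh(sim$geno)
  track <- snp_roh_counts(rohs, sim$geno)
  expect_identical(sum(track$count), sum(rohs$n_snps))
})

test_that("top-1% flagging uses the nearest-rank percentile with strict excess", {
  # 99 zeros and one count of 10: only that SNP exceeds the percentile
  track <- data.frame(snp_id = paste0("s", 1:100), chromosome = 1L,
                      position_bp = seq_len(100) * 1e5,
                      count = c(rep(0L, 99), 10L))
  fl <- significant_snps(track)
  expect_equal(sum(fl$significant), 1L)
  expect_true(fl$significant[100])
  # all equal counts: nothing exceeds the percentile
  track$count <- rep(7L, 100)
  expect_equal(sum(significant_snps(track)$significant), 0L)
  # random counts vs sort-and-threshold oracle
  set.seed(42)
  for (k in 1:20) {
    n <- sample(50:500, 1)
    cnt <- stats::rpois(n, 3)
    tr <- data.frame(snp_id = paste0("s", 1:n), chromosome = 1L,
                     position_bp = seq_len(n) * 1e5, count = cnt)
    got <- significant_snps(tr)
    srt <- sort(cnt)
    thr <- srt[ceiling(0.99 * n)]
    expect_equal(got$significant, cnt > thr)
  }
})

test_that("islands chain flagged SNPs with the gap and minimum-SNP rules", {
  mk_track <- function(pos_mb, sig) {
    data.frame(snp_id = paste0("s", seq_along(pos_mb)), chromosome = 1L,
               position_bp = pos_mb * 1e6, count = ifelse(sig, 10L, 0L),
               percent = 0, significant = sig)
  }
  # significant SNPs at 1.00, 1.50, 3.00 Mb: island [1.0, 1.5], singleton dropped
  tr <- mk_track(c(1, 1.5, 3), c(TRUE, TRUE, TRUE))
  isl <- assemble_islands(tr)
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$start_bp, 1e6)
  expect_equal(isl$end_bp, 1.5e6)
  expect_equal(isl$n_snps, 2L)
  # no significant SNPs
  expect_equal(nrow(assemble_islands(mk_track(c(1, 2), c(FALSE, FALSE)))), 0L)
  # two SNPs 0.03 Mb apart form a minimal island
  isl2 <- assemble_islands(mk_track(c(5, 5.03), c(TRUE, TRUE)))
  expect_equal(nrow(isl2), 1L)
  expect_equal(isl2$length_bp, 0.03e6)
  # every flagged SNP lands in exactly one island or is a dropped singleton
  set.seed(31)
  pos <- sort(runif(200, 0, 5e7))
  sig <- runif(200) < 0.2
  tr3 <- data.frame(snp_id = paste0("s", 1:200), chromosome = 1L,
                    position_bp = pos, count = 0L, significant = sig)
  isl3 <- assemble_islands(tr3)
  member <- unlist(strsplit(isl3$snp_ids, ","))
  expect_equal(anyDuplicated(member), 0L)
  expect_true(all(member %in% tr3$snp_id[sig]))
  # islands are disjoint and ordered
  if (nrow(isl3) > 1) {
    expect_true(all(isl3$start_bp[-1] > isl3$end_bp[-nrow(isl3)]))
  }
})

test_that("island summaries aggregate member-SNP tracks", {
  track <- data.frame(snp_id = paste0("s", 1:6), chromosome = 1L,
                      position_bp = seq_len(6) * 1e5,
                      count = c(9L, 9L, 9L, 0L, 0L, 0L),
                      percent = c(90, 90, 90, 0, 0, 0),
                      percent_river = c(80, 90, 100, 0, 0, 0),
                      percent_swamp = c(90, 90, 90, 0, 0, 0),
                      significant = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  isl <- assemble_islands(track)
  fst <- data.frame(snp_id = track$snp_id, fst = c(0.4, 0.4, 0.4, 0.1, 0.1, 0.1))
  logi <- data.frame(snp_id = track$snp_id,
                     odds_ratio = c(2, 4, 6, 1, 1, Inf))
  out <- island_summary(isl, track, fst = fst, logistic = logi)
  expect_equal(out$mean_fst, 0.4)
  expect_equal(out$sd_fst, 0)
  expect_equal(out$mean_or, 4)     # finite member ORs 2, 4, 6
  expect_equal(out$mean_percent_river, 90)
  expect_equal(out$chromosome_mean_fst, mean(fst$fst))
  # missing member SNP in a track errors
  expect_error(island_summary(isl, track, fst = fst[-1, ]), "missing")
  # random annotation equals brute-force aggregation
  set.seed(77)
  n <- 120
  pos <- sort(sample.int(3e7, n))
  sig <- runif(n) < 0.3
  tr <- data.frame(snp_id = paste0("m", 1:n), chromosome = 1L,
                   position_bp = pos, count = 0L, percent = runif(n) * 50,
                   significant = sig)
  isl2 <- assemble_islands(tr)
  fst2 <- data.frame(snp_id = tr$snp_id, fst = runif(n))
  out2 <- island_summary(isl2, tr, fst = fst2)
  for (k in seq_len(nrow(out2))) {
    ids <- strsplit(out2$snp_ids[k], ",")[[1]]
    expect_equal(out2$mean_fst[k], mean(fst2$fst[match(ids, fst2$snp_id)]))
    expect_equal(out2$mean_snp_roh_percent[k],
                 mean(tr$percent[match(ids, tr$snp_id)]))
  }
})
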