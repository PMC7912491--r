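write_toy_plink <- function(dir, ped_lines, map_lines, sheet_lines) {
  ped <- file.path(dir, "toy.ped")
  map <- file.path(dir, "toy.map")
  sheet <- file.path(dir, "toy.tsv")
  writeLines(ped_lines, ped)
  writeLines(map_lines, map)
  writeLines(sheet_lines, sheet)
  list(ped = ped, map = map, sheet = sheet)
}

test_that("PLINK text parsing transcribes alleles, missing calls and metadata", {
  d <- withr::local_tempdir()
  f <- write_toy_plink(
    d,
    ped_lines = c("F1 a 0 0 0 -9 A A A G 0 0",
                  "F2 b 0 0 0 -9 A G G G C C"),
    map_lines = c("1 s1 0 100", "1 s2 0 200", "2 s3 0 50"),
    sheet_lines = c("sample_id\ttype\tpopulation",
                    "a\triver\tP1", "b\tswamp\tP2"))
  g <- read_plink_text(f$ped, f$map, f$sheet)
  expect_s3_class(g, "geno_set")
  expect_equal(dim(g$calls), c(2L, 3L))
  # s1: alleles sorted A, G; dosages of G: a=0, b=1
  expect_equal(unname(g$calls[, "s1"]), c(0L, 1L))
  # s2: a is A G, b is G G; dosages of G: 1 and 2
  expect_equal(unname(g$calls[, "s2"]), c(1L, 2L))
  # s3: "0 0" is missing for a; b is C C, monomorphic -> dosage 0
  expect_equal(unname(g$calls[, "s3"]), c(NA_integer_, 0L))
  expect_equal(g$samples$type, c("river", "swamp"))
  expect_equal(g$map$chromosome, c(1L, 1L, 2L))
})

test_that("shuffled map is sorted and call columns are permuted identically", {
  d <- withr::local_tempdir()
  set.seed(11)
  n_snp <- 12
  pos <- sample.int(1e6, n_snp)
  chrom <- sample(1:2, n_snp, replace = TRUE)
  alleles <- matrix(sample(c("A A", "A G", "G G"), 2 * n_snp,
                           replace = TRUE), 2, n_snp)
  ped_lines <- vapply(1:2, function(i)
    paste(c(paste0("F", i), paste0("ind", i), "0 0 0 -9", alleles[i, ]),
          collapse = " "), character(1))
  map_lines <- sprintf("%d snp%02d 0 %d", chrom, seq_len(n_snp), pos)
  f <- write_toy_plink(d, ped_lines, map_lines,
                       c("sample_id\ttype\tpopulation",
                         "ind1\triver\tP1", "ind2\tswamp\tP2"))
  g <- read_plink_text(f$ped, f$map, f$sheet)
  expect_false(is.unsorted(g$map$chromosome))
  for (ch in unique(g$map$chromosome)) {
    expect_false(is.unsorted(g$map$position_bp[g$map$chromosome == ch]))
  }
  # brute-force re-lookup by snp_id: the calls must follow their SNP
  g0 <- read_plink_text(f$ped, f$map, f$sheet, max_chromosome = 24)
  for (j in seq_len(n_snp)) {
    id <- sprintf("snp%02d", j)
    a <- strsplit(alleles[, j], " ")
    obs <- sort(unique(unlist(a)))
    b_allele <- if (length(obs) == 2) obs[2] else NA
    expected <- vapply(a, function(p)
      if (is.na(b_allele)) 0L else sum(p == b_allele), integer(1))
    expect_equal(unname(g$calls[, id]), expected, info = id)
  }
})

test_that("malformed lines and unknown samples raise informative errors", {
  d <- withr::local_tempdir()
  f <- write_toy_plink(d,
                       ped_lines = "F1 a 0 0 0 -9 A A",   # needs 2 SNPs
                       map_lines = c("1 s1 0 100", "1 s2 0 200"),
                       sheet_lines = c("sample_id\ttype\tpopulation",
                                       "a\triver\tP1"))
  expect_error(read_plink_text(f$ped, f$map, f$sheet), "line 1")
  f2 <- write_toy_plink(d,
                        ped_lines = "F1 zz 0 0 0 -9 A A G G",
                        map_lines = c("1 s1 0 100", "1 s2 0 200"),
                        sheet_lines = c("sample_id\ttype\tpopulation",
                                        "a\triver\tP1"))
  expect_error(read_plink_text(f2$ped, f2$map, f2$sheet), "absent")
})

test_that("ped/map round-trips through write_plink_text", {
  set.seed(4)
  calls <- matrix(sample(c(0:2, NA), 5 * 20, replace = TRUE), 5, 20)
  calls[1, ] <- 0L   # anchor the A allele so orientation survives the file
  g <- toy_geno(calls, pos = sort(sample.int(5e6, 20)),
                types = rep(c("river", "swamp"), c(3, 2)))
  d <- withr::local_tempdir()
  p <- write_plink_text(g, file.path(d, "rt"))
  g2 <- read_plink_text(p[1], p[2], p[3])
  expect_equal(unname(g2$calls), unname(g$calls))
  expect_equal(g2$map$position_bp, g$map$position_bp)
  expect_equal(g2$samples, g$samples)
})

test_that("HWE exact test matches the full-enumeration oracle", {
  cases <- list(c(10, 0, 0), c(3, 5, 2), c(0, 50, 0), c(5, 1, 5),
                c(20, 20, 20), c(1, 1, 1), c(0, 1, 0), c(60, 30, 110))
  for (cs in cases) {
    expect_equal(hwe_exact_p(cs[1], cs[2], cs[3]),
                 oracle_hwe(cs[1], cs[2], cs[3]),
                 tolerance = 1e-12, info = paste(cs, collapse = ","))
  }
  set.seed(9)
  for (k in 1:50) {
    n <- sample(1:200, 1)
    x <- stats::rmultinom(1, n, prob = c(0.3, 0.4, 0.3))
    expect_equal(hwe_exact_p(x[1], x[2], x[3]),
                 oracle_hwe(x[1], x[2], x[3]),
                 tolerance = 1e-12, info = paste(x, collapse = ","))
  }
  expect_equal(hwe_exact_p(10, 0, 0), 1)
  # an all-heterozygote SNP at n = 50 is vastly out of equilibrium
  expect_lt(hwe_exact_p(0, 50, 0), 1e-5)
})

test_that("QC filters match a per-column brute-force oracle and are idempotent", {
  set.seed(21)
  n <- 10; m <- 20
  calls <- matrix(sample(0:2, n * m, replace = TRUE, prob = c(.4, .3, .3)),
                  n, m)
  calls[1, 1:4] <- NA                      # sample 1: call rate 0.5
  calls[, 2] <- c(NA, rep(0L, n - 1))      # SNP 2: monomorphic post-NA
  calls[2:n, 3] <- NA                      # SNP 3: terrible call rate
  calls[, 4] <- c(1L, rep(0L, n - 1))      # SNP 4: MAF 1/18 approximately
  g <- toy_geno(calls, types = rep(c("river", "swamp"), each = n / 2))
  res <- apply_qc(g, qc_params(min_sample_call_rate = 0.9,
                               min_snp_call_rate = 0.9, min_maf = 0.1))
  # oracle: evaluate each filter per column on the post-sample-filter matrix
  keep_s <- rowMeans(!is.na(calls)) >= 0.9
  cc <- calls[keep_s, , drop = FALSE]
  p <- colMeans(cc, na.rm = TRUE) / 2
  keep_snp <- colMeans(!is.na(cc)) >= 0.9 & pmin(p, 1 - p) >= 0.1 &
    !is.nan(p)
  expect_equal(res$report$removed_samples, "ind1")
  expect_equal(res$geno$map$snp_id, g$map$snp_id[keep_snp])
  expect_equal(res$report$n_samples_removed + nrow(res$geno$calls), n)
  expect_equal(res$report$n_snps_removed + ncol(res$geno$calls), m)
  # idempotence
  res2 <- apply_qc(res$geno, qc_params(min_sample_call_rate = 0.9,
                                       min_snp_call_rate = 0.9,
                                       min_maf = 0.1))
  expect_equal(res2$geno$calls, res$geno$calls)
  expect_equal(res2$report$n_snps_removed, 0L)
  expect_equal(res2$report$n_samples_removed, 0L)
})

test_that("a 94% call-rate sample is removed at the 0.95 threshold", {
  calls <- matrix(2L, 4, 50)
  calls[1, 1:3] <- NA          # 94% call rate
  calls[2, 1] <- 0L; calls[3, 2] <- 0L; calls[4, 3] <- 0L
  g <- toy_geno(calls)
  res <- apply_qc(g, qc_params(min_maf = 0))
  expect_false("ind1" %in% res$geno$samples$sample_id)
  expect_equal(res$report$n_samples_removed, 1L)
})

test_that("dataset construction applies the ascertainment and HWE rules", {
  set.seed(31)
  n <- 50
  calls <- matrix(stats::rbinom(n * 6, 2, 0.4), n, 6)
  swamp <- 26:50
  calls[swamp, 2] <- 0L          # SNP 2 monomorphic in swamp
  calls[, 3] <- 1L               # SNP 3 all-het: fails HWE at n = 25
  g <- toy_geno(calls, types = rep(c("river", "swamp"), each = 25))
  ds <- build_datasets(g)
  expect_false("s2" %in% ds$all$map$snp_id)      # excluded from ALL
  expect_false("s3" %in% ds$river$map$snp_id)    # HWE filter in type sets
  expect_false("s3" %in% ds$swamp$map$snp_id)
  expect_true("s3" %in% ds$all$map$snp_id)       # no HWE filter in ALL
  # sample partition
  expect_setequal(c(ds$river$samples$sample_id, ds$swamp$samples$sample_id),
                  g$samples$sample_id)
  # ALL SNPs are a subset of the swamp-polymorphic set
  sw_maf <- colMeans(g$calls[g$samples$type == "swamp",
                             match(ds$all$map$snp_id, g$map$snp_id),
                             drop = FALSE], na.rm = TRUE) / 2
  expect_true(all(pmin(sw_maf, 1 - sw_maf) > 0))
  expect_error(build_datasets(g, types = c("river", "upland")), "absent")
})

test_that("swamp-monomorphic fraction propagates to the joint dataset size", {
  cfg <- sim_config(n_chromosomes = 2, snps_per_chromosome = 600,
                    pop_sizes = list(river = c(20, 20), swamp = c(20, 20)),
                    f_drift_type = 0.05, swamp_monomorphic_fraction = 0.3,
                    roh_rate = 0, seed = 5)
  sim <- simulate_panel(cfg)
  qc <- apply_qc(sim$geno, qc_params())
  ds <- build_datasets(qc$geno)
  frac <- ncol(ds$all$calls) / ncol(qc$geno$calls)
  # about 70% of post-QC SNPs remain swamp-polymorphic (binomial slack)
  expect_gt(frac, 0.62)
  expect_lt(frac, 0.78)
})
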