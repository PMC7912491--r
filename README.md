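# rohscan

Runs of homozygosity (ROH), genomic inbreeding and ROH-based population
structure from SNP-array genotypes.

`rohscan` is aimed at population and livestock geneticists who want to
characterize structured populations — typified by the two domestic water
buffalo types, river (*Bubalus bubalis bubalis*) and swamp
(*B. b. carabanensis*) — from medium-density SNP-array data in PLINK
text format. The package covers the full workflow:

* **QC and dataset construction.** Sample/SNP call-rate and MAF filters,
  a Hardy–Weinberg exact test, and construction of three analysis sets:
  a joint set restricted to SNPs polymorphic in the under-ascertained
  type (mitigating array ascertainment bias) and two type-specific sets
  re-filtered within type.
* **Rule-based ROH detection.** A run is a maximal stretch of
  homozygous, non-missing calls with ≥ 15 SNPs, span ≥ 1 Mb and no
  inter-SNP gap > 1 Mb (all configurable, including heterozygote and
  missing-call allowances). No sliding windows — detection is exact.
* **ROH statistics.** Per-animal run counts and lengths, the five
  standard length classes, unique (coordinate-identical) runs, and the
  genomic inbreeding coefficient

  F<sub>ROH</sub>(t) = Σ<sub>ROH, length&gt;t</sub> length / L

  for thresholds t ∈ {0, 2, 4, 8} Mb, with L the mapped genome length.
* **ROH islands.** The per-SNP incidence SNP<sub>ROH</sub> (number of
  animals carrying the SNP inside a run), top-1% significance by the
  nearest-rank percentile, and gap-limited chaining of significant SNPs
  into islands.
* **ROH-coded genomic relationships.** Genotypes recoded as
  0 = heterozygous, 1 = homozygous outside, 2 = homozygous inside a run
  longer than 4 Mb, fed into a VanRaden-scaled identical-by-state
  relationship matrix G<sub>ROH</sub> = ZZ′ / 2Σp<sub>i</sub>(1−p<sub>i</sub>),
  with eigen-decomposition and per-population mean scores for structure
  plots.
* **Differentiation scans.** Per-SNP Wright F<sub>ST</sub> =
  (H<sub>T</sub> − H<sub>S</sub>)/H<sub>T</sub> between the two types,
  LOWESS smoothing along each chromosome, mean + 3 SD outlier calling;
  and a per-SNP logistic regression log(p/(1−p)) = β₀ + β<sub>type</sub>
  of ROH membership on type, with odds ratios and Wald tests.
* **Synthetic panels with ground truth.** A generator producing
  two-type, multi-population genotypes under a Balding–Nichols drift
  model with configurable ascertainment bias, planted autozygous
  segments and boosted "island" loci — every stage of the pipeline is
  testable against known truth without any data download.

## Worked example

```r
library(rohscan)

cfg <- sim_config(n_chromosomes = 4, snps_per_chromosome = 1000,
                  pop_sizes = list(river = c(15, 15), swamp = c(15, 15)),
                  island_loci = data.frame(chromosome = c(1, 2),
                                           position_bp = c(3e7, 6e7)),
                  seed = 42)
sim <- simulate_panel(cfg)
bundle <- run_roh_pipeline(geno = sim$geno, out_dir = "results")

bundle$results$all$group_table
#>   group n_animals total_roh unique_roh mean_n_roh mean_length_mb mean_froh_all mean_froh_gt4mb
#> 1 river        30       572        495       19.1           5.94         0.285           0.239
#> 2 swamp        30       525        481       17.5           5.68         0.250           0.204
#> 3   all        60      1097        939       18.3           5.82         0.268           0.221
```

On this small panel the joint dataset yields 1,097 runs (939 unique);
river animals average 19.1 runs of mean length 5.9 Mb and an all-ROH
inbreeding coefficient of 0.285, which drops to 0.239 when only runs
longer than 4 Mb are counted. The same bundle carries the incidence
track and islands (`bundle$results$all$track`, `...$islands`), the
F<sub>ST</sub> and logistic scans (`...$fst`, `...$logistic`,
`...$or_summary`) and the G<sub>ROH</sub> eigen-analysis
(`...$eigen` — here the leading component explains 4.7% of the total
variance and separates the two types). With `out_dir` set, every table
is written as a TSV plus a `run_log.txt` of stage counts.

`read_plink_text()` / `write_plink_text()` move panels in and out of
PLINK `.ped`/`.map` text files with a TSV sample sheet, and
`inst/scripts/rohscan` exposes `simulate` and `run` subcommands for
shell use.

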