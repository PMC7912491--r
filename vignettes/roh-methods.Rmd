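---
title: "Methods: ROH detection, inbreeding and ROH-based structure in rohscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH detection, inbreeding and ROH-based structure in rohscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rohscan` implements a complete runs-of-homozygosity (ROH) workflow for
two-type, multi-population SNP-array panels. This vignette documents the
models and procedures, the parameters that matter and their defaults,
the numerical conventions, and what the synthetic-data generator does
and does not emulate — hence what a passing test suite does and does not
demonstrate about real data.

## Quality control and the three analysis datasets

QC runs in a fixed order: samples with call rate < 0.95 are removed
first; then, on the retained samples, SNPs with call rate < 0.95 or
minor allele frequency < 0.01. Call rate is the fraction of non-missing
calls and MAF is computed from non-missing calls only — the standard
definitions. The initial MAF filter uses all animals jointly; a per-type
initial filter would be an alternative, but the joint filter keeps the
starting marker set identical across downstream datasets.

Three datasets are then built, reflecting how a SNP array developed
mainly from one type's sequence behaves in the other (ascertainment
bias):

* **joint ("all")** — both types, restricted to SNPs polymorphic among
  the second (under-ascertained, swamp-like) type's samples.
  "Polymorphic" means both alleles observed (MAF > 0), not a MAF ≥ 0.01
  requirement. No Hardy–Weinberg filter is applied here, since mixing
  two diverged types violates the single-population HWE premise
  (Wahlund effect).
* **type-specific** — one type's samples with the call-rate and MAF
  filters re-applied within type, plus a Hardy–Weinberg exact-test
  filter at P < 1e-5.

The HWE test is the exact conditional test on the heterozygote count
given the allele counts: the p-value sums the probabilities of all
heterozygote counts no more probable than the observed one. It is
computed in log space via `lgamma` and verified in the test suite
against a full-enumeration oracle using plain product arithmetic
(agreement to 1e-12 for n ≤ 200). Only autosomes 1–24 are read; sex
chromosomes and unplaced scaffolds are dropped at parse time.

## ROH detection

A run is a maximal window of calls on one chromosome satisfying, with
the default parameters:

1. at least 15 SNPs;
2. span (last SNP position − first SNP position) of at least 1 Mb;
3. no gap between consecutive mapped SNPs above 1 Mb — a larger gap
   terminates the run even if both flanks are homozygous, because the
   intervening interval is unobserved;
4. no heterozygous or missing calls (`max_het = 0`, `max_missing = 0`).

No sliding windows are used; detection is an exact scan. The
heterozygote/missing allowances generalize the scan to the budgeted
maximal-window problem, solved with a two-pointer sweep; with
allowances above zero, maximal windows may overlap, and all of them are
reported. `length_bp` is `end_bp - start_bp` (not +1), so a window whose
SNPs span exactly 1,000,000 bp meets the 1 Mb threshold; this convention
is applied consistently everywhere, including F_ROH.

The test suite checks the scan against an independent exhaustive-window
oracle (every (i, j) window tested for all four criteria plus
maximality) on hundreds of random chromosomes, under default and
non-default allowances.

## ROH statistics

F_ROH(t) is the summed length of an animal's runs longer than t divided
by the genome length L. Thresholds are strict (">") and reported at
t = 0, 2, 4 and 8 Mb, which makes F_ROH non-increasing in t — an
invariant under test. L defaults to the map-derived length: the sum over
chromosomes of the span between first and last mapped SNP. An
assembly-derived total length can be passed instead; the map-derived
default has the advantage of being reproducible from the input alone.

Length classes are the five conventionally reported for livestock
(1 < Mb ≤ 2, 2 < Mb ≤ 4, 4 < Mb ≤ 8, 8 < Mb ≤ 16, > 16), with
upper-inclusive boundaries; a run of exactly 1 Mb (the detection
minimum) is placed in the first class. Unique runs are distinct
(chromosome, start, end) signatures; the carriers of each signature are
reported for "most frequent ROH" tables. The per-class mean within-run
SNP spacing (span / (SNP count − 1)) is reported as a density
diagnostic: short-class runs supported by wide spacing are the ones most
likely to be false positives on sparse panels.

## ROH islands

SNP_ROH counts, per SNP, the animals with at least one run whose
[start, end] contains the SNP (inclusive). Conservation — the sum of
SNP_ROH over SNPs equals the sum of SNP counts over runs — holds exactly
and is asserted in the tests. Significance uses the empirical 99th
percentile of all counts (nearest-rank convention, zeros included) with
a strict ">", so massive tie groups at the percentile are not flagged.
Whether zero-count SNPs belong in the reference distribution is
genuinely open; they are included here (configurable via the track),
which makes the threshold conservative on sparse panels.

Islands chain significant SNPs on a chromosome while consecutive
significant SNPs are ≤ 1 Mb apart; chains of fewer than 2 SNPs are
discarded. Both values are configurable; the defaults reflect the
smallest island structure worth reporting (two markers) and the same
1 Mb contiguity scale used in detection. Island annotation attaches
member-SNP means ± SD of raw F_ST, finite odds ratios, and per-type
incidence percentages (type-specific denominators), plus the
chromosome-wide mean F_ST for contrast.

## The ROH-coded relationship matrix

Genotypes are recoded per animal: 0 = heterozygous, 1 = homozygous not
inside a qualifying run, 2 = homozygous inside a run longer than 4 Mb
(the coding threshold; configurable). The 4 Mb cut restricts code 2 to
runs long enough to indicate recent shared autozygosity rather than
ancient background homozygosity. The matrix is then scaled exactly as a
VanRaden (first-method) genomic relationship matrix: column frequencies
p_i = (column mean of codes)/2 over non-missing entries, Z = codes −
2p_i, missing entries set to 0 after centering (the standard neutral
imputation), G = ZZ′ / (2 Σ p_i(1 − p_i)), with degenerate columns
(p_i ∈ {0, 1}) excluded from numerator and denominator. The frequencies
are computed from the recoded matrix itself, not from the raw
genotypes: the recoded matrix is the object being scaled, and this keeps
the construction self-contained (a switch to external frequencies would
be a one-line change in `build_grm`).

Eigen-analysis uses the full symmetric decomposition of the n × n
matrix (n at most a few hundred, so direct decomposition is exact and
fast), eigenvalues descending, percent variance = eigenvalue / trace ×
100. Signs are fixed by making each eigenvector's largest-magnitude
coefficient positive, so plots are reproducible across platforms.
Per-population mean scores are reported because population means make
the structure far easier to read than individual clouds.

## Differentiation scans

F_ST is the two-population Wright/Nei form: with group frequencies p₁,
p₂ and p̄ their unweighted mean, F_ST = (H_T − H_S)/H_T where H_S is the
mean of the two within-group expected heterozygosities and H_T =
2p̄(1−p̄). H_T = 0 is defined as F_ST = 0. This estimator is symmetric
in the groups and needs no sample-size weights; a Weir–Cockerham
variant with sample-size weighting would be a drop-in alternative for
unbalanced designs (the per-group frequencies are already in the
output).

Smoothing is Cleveland's LOWESS — tricube-weighted local linear
regression with 3 bisquare robustness iterations — applied within each
chromosome against position, with a span of 0.05 (5% of the
chromosome's SNPs per local fit; at ~2,000 SNPs per chromosome this is
a ~100-SNP window, wide enough to suppress single-SNP noise and narrow
enough to keep island-scale signals). The implementation delegates to
`stats::lowess` with `delta = 0` (no interpolation shortcut); the test
suite verifies it at every point, to 1e-8, against an independent
direct implementation of the algorithm, and verifies exactness on
constants and on linear tracks. Outliers are smoothed values strictly
above mean + 3 SD (one-sided: only high differentiation is of
interest); chromosomes with fewer than 3 non-missing values pass
through unsmoothed.

The logistic scan regresses, per SNP, the binary "this animal carries
the SNP inside a run" on type: log(p/(1−p)) = β₀ + β_type. With a
single binary covariate the MLE is determined by the 2 × 2 table, so
the fit aggregates to two binomial rows and uses `stats::glm` (IRLS,
deviance tolerance 1e-10, ≤ 50 iterations); the identity between the
fitted odds ratio and the table cross-product ratio is asserted to
1e-6 in the tests. Complete separation (a type with all-0 or all-1
membership) is flagged, the odds ratio reported as the limit (0 or
Inf), and the p-value withheld; separated SNPs are excluded from
odds-ratio averages and their count is reported alongside.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with full ground truth:

* **Map**: 24 autosomes of 100 Mb with 2,000 uniformly placed SNPs each
  (~1 SNP / 50 kb) — comparable to a ~47 K panel on a ~2.4 Gb genome, so
  the 15-SNP and 1 Mb detection thresholds are comparably binding.
* **Samples**: 185 + 153 animals in 15 + 13 populations (the two-type
  study design).
* **Frequencies**: ancestral p ~ U(0.05, 0.5); type frequencies
  Balding–Nichols around p with F = 0.48; population frequencies
  Balding–Nichols around the type value with F = 0.05. The type-level
  F was calibrated once, by simulation of the drift model, so that the
  realized mean per-SNP F_ST between types is ≈ 0.2 (the mean of
  per-SNP ratios runs well below the F parameter itself, so the
  calibration is empirical rather than the naive (F/2)/(1−F/2)
  expectation); the realized value is itself a test assertion (±0.05).
* **Ascertainment bias**: 60% of SNPs are forced monomorphic in the
  swamp-like type, emulating an array on which only about one-third of
  the markers segregate in that type.
* **Autozygosity**: per animal, Poisson-many segments (means 40 and 70
  for the two types — the lower-/higher-autozygosity asymmetry of the
  two-type design) with lengths from an exponential mixture (means
  2.5 / 9 Mb, weights 0.85 / 0.15: a short-class-dominated
  distribution); segments are placed uniformly, or centred on supplied
  island loci with probability `island_boost`, and neighbouring
  segments of one animal must be separated by at least one mapped SNP
  (otherwise they would fuse into a single detected run and the truth
  bookkeeping would be wrong). Within a segment every SNP is homozygous
  for one founder allele drawn by its population frequency.
* **Boundary observability**: each planted segment is terminated by
  forcing a heterozygous call at the nearest informative
  (0 < p < 1, uncovered) SNP beyond each end — the haplotype mismatch
  that ends a real autozygous tract. This makes truth boundaries
  observable at map resolution, which is what allows the recovery tests
  to demand boundary errors within one inter-SNP interval.
* **Missingness**: calls are masked at random at 1e-4 — the residual
  missingness of a high-quality array after the call-rate QC that the
  pipeline itself applies.

What the generator does **not** emulate: linkage disequilibrium and
recombination (segments are planted, not coalescent), site-frequency
spectra of real arrays, genotyping error, or chromosome length
variation. Two practical consequences deserve emphasis. First, under
strong drift the independent-SNP background produces chance runs of
homozygosity at a higher rate than LD-structured real data of the same
density, so simulated per-animal run counts sit above the planted rate;
pipeline-level quantities on the default panel are therefore
structurally realistic, not numerically matched to any particular real
panel. Second, in the type affected by ascertainment bias, runs extend
across forcibly monomorphic (uninformative) markers, so boundary-exact
recovery holds on informative panels
(`swamp_monomorphic_fraction = 0`) and degrades — honestly, as it would
on a real biased array — when most markers cannot reveal
heterozygosity. The recovery guarantees in the tests (sensitivity
≥ 0.95 for segments with ≥ 20 spanned SNPs and ≥ 1.5 Mb at default
density; zero detections in the sparse low-homozygosity null regime)
are stated for the informative-panel conditions.

## Numerical choices and degenerate inputs

* Empty datasets after filtering raise explicit "empty dataset" errors;
  an all-degenerate coded matrix raises a "degenerate" error rather
  than dividing by zero.
* Re-running QC on its own output is a no-op (idempotence is tested).
* Detection is deterministic and invariant to sample order; recoding is
  idempotent and invariant to run-list order.
* Nearest-rank percentile: threshold = sorted counts at index
  ⌈0.99 n⌉; ties at the threshold are never flagged.
* The PLINK reader records alleles in lexicographic order per SNP, so
  dosage orientation is independent of sample order; orientation of
  SNPs with only one observed allele is inherently ambiguous in the
  ped format (their dosage is coded 0).
* Problem sizes in the tests are scaled to what the checks need:
  oracle comparisons run on 120–500-SNP chromosomes, pipeline-level
  properties on panels of 3–4 chromosomes × 600–2,000 SNPs and 20–60
  animals; the acceptance script runs the full 24-chromosome,
  338-animal, 48 K-SNP design.

## Known limitations

* No binary PLINK (.bed) support; text .ped/.map only.
* The logistic scan fits one SNP at a time; no multiple-testing
  correction is applied beyond the fixed P < 0.01 flag (the flag
  threshold is a parameter).
* The F_ST estimator ignores sample-size imbalance between groups by
  design; use the reported per-group frequencies if a weighted
  estimator is needed.
* Island gene-content annotation, probe remapping between assemblies,
  and mixed-model (repeatability) analyses of run length are out of
  scope.
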