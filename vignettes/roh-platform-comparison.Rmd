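---
title: "Comparing runs of homozygosity between SNP arrays and low-coverage sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing runs of homozygosity between SNP arrays and low-coverage sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohcompare)
```

## The problem

Runs of homozygosity (ROH) are contiguous genomic stretches over which an
individual's genotype calls are homozygous at every assayed site. ROH longer
than about 1 Mb predominantly arise from autozygosity — both haplotypes
inherited from a recent common ancestor — and their number (NROH), mean size
and total summed length (SROH) per individual are standard summaries of
demographic history and inbreeding.

SNP arrays assay ~2.5 M well-behaved common sites with genotyping error well
below 0.1%, and are the historical gold standard for ROH calling. Low-coverage
(~4x) whole-genome sequencing assays every position but, because often only
one of the two chromosomes is sampled at a site, systematically miscalls some
heterozygotes and homozygotes. The miscall that matters for ROH is the
*false heterozygote inside a truly autozygous segment*: each one can break a
long ROH into fragments, inflating NROH and shrinking mean size. Published
cross-platform comparisons put this false-het burden at roughly 2.4 sites per
Mb on average (from ~0.3/Mb in the cleanest populations to ~4.5/Mb in the
noisiest), against a ~99.6% overall genotype concordance between platforms.

The observational (PLINK-style) ROH scanner has a per-window heterozygote
tolerance `h` precisely to absorb such miscalls. This package implements the
scanner, the supporting QC and concordance machinery, a heterozygote-leakage
statistic for choosing `h`, and a paired-channel simulator, so that the
question "*which WGS tolerance makes array and WGS ROH statistics
comparable?*" can be asked reproducibly. On both the published concordance
numbers and the simulated data the answer is the familiar one: allow about 3
heterozygous SNPs per window in low-coverage WGS.

## The scanner

`call_roh()` reimplements the observational sliding-window algorithm:

1. **Windows.** A window of `window_snp` consecutive sites (default 50) slides
   one site at a time along each chromosome of each individual. A window is
   *homozygous* iff it contains at most `window_het` heterozygous calls
   (`h`, the parameter under study) and at most `window_missing` (5) missing
   calls.
2. **Per-site state.** A site is *in a homozygous segment* iff at least
   `window_threshold` (5%) of the windows covering it are homozygous. Near
   chromosome ends, where fewer than `window_snp` windows cover a site, the
   actual covering count is the denominator; sites covered by no window (a
   chromosome shorter than one window) are never in state.
3. **Segments.** Maximal runs of in-state sites become candidates; a run is
   split wherever two consecutive sites are more than `max_gap_kb` (1000)
   apart; boundaries are trimmed so the first and last site of a segment are
   non-heterozygous and non-missing; and a segment is kept iff it has at
   least `min_snp` (50) sites, spans at least `min_kb` (300), and carries at
   least one SNP per `density_kb_per_snp` (50) kb. The observed heterozygote
   count inside each kept segment is recorded.

The defaults are the standard parameterisation for joint array/WGS analyses.
`min_kb = 300` is the *minimum final segment length*; the density filter uses
the final segment's own SNP count and length (there is no per-window density
check). The scanner contains no randomness and no ties to break: identical
input yields byte-identical output, and an exhaustive
materialise-every-window implementation in the test suite reproduces its
segment set exactly on hundreds of randomised instances.

Two behavioural notes that matter when reasoning about results. First, the
window threshold is deliberately lenient: a *single* scattered false het is
tolerated inside a segment even at `h = 1` (it stays in state because most of
its covering windows hold only that one het); a site only leaves the
homozygous state when more than 95% of its covering windows fail, which
requires `h + 1` heterozygous calls within a couple of sites of each other.
Segment-breaking is therefore driven by *clusters* of miscalls, not by their
marginal rate. Second, boundary trimming guarantees het-free segment *ends*,
not het-free segments: observed heterozygotes inside called ROH are expected,
and quantifying them is the point of the leakage statistic below.

## Site QC

`apply_qc()` filters each population and channel independently, removing
sites with minor allele frequency strictly below 0.05 (a site at exactly 0.05
is retained) or an exact Hardy–Weinberg p-value below 0.001, plus sites with
no called genotypes. The HWE test is the two-sided exact test conditional on
the observed allele counts, computed by a log-space ratio recurrence over all
heterozygote counts of matching parity; the p-value sums the probabilities of
configurations no more probable than the observed one (no mid-p correction),
with a relative tie tolerance of 1e-7. A chi-square variant is available
behind `method = "chisq"` for comparison. The exact test agrees with a direct
enumeration oracle to better than 1e-12 for every configuration with up to
200 diploid genotypes, and is invariant under swapping the homozygote counts.
Array and WGS site lists are *not* intersected after QC; the concordance
module forms its own shared-site universe.

## Concordance decomposition

`concordance_table()` classifies every site present (by chromosome and
position) and non-missing in both channels for an individual into exactly one
of: concordant, het-by-array/hom-by-WGS, hom-by-array/het-by-WGS, or a
hom-ref/hom-alt mismatch. The comparison universe is the intersection because
percentages are only meaningful on jointly called sites. The allele-swap
(hom/hom) mismatches are reported separately and excluded from the two named
components, which therefore sum to the total discordance up to the (rare)
swap term. Percentages are averaged over individuals, not pooled over calls.
Taking the array as gold standard, the hom-array/het-WGS rate is the
*ROH-breaking error*; `roh_error_rate()` reports it per Mb of autosomal span
(2800 Mb for genome-wide human data, derived from the data's own span
otherwise). The package ships the published 20-population decomposition table
(`inst/extdata/platform_concordance_20pop.tsv`, 1000 Genomes Phase 3 and
African Genome Variation Project cohorts genotyped on the Omni 2.5-8 array
and sequenced at ~4x) and `summarize_concordance()` reproduces its headline
arithmetic: mean concordance 99.6%, components 0.1% and 0.3%, and a 6.3-fold
WGS/array heterozygote-count ratio.

## The heterozygote-leakage statistic ep(P, h)

For population `P` scanned at tolerance `h`, let `R(P,h,x,y)` be the set of
called segments with length in `[x, y)` Mb, over the bins
`{[1,1.5), [1.5,5), [5,10), [10,Inf)}`. For each bin the per-bin leakage is
the arithmetic mean over its segments of the observed heterozygote content,
and

```
ep(P,h) = 100 * sum_xy |R(P,h,x,y)| * ep_xy(P,h) / sum_xy |R(P,h,x,y)|
```

the segment-count-weighted mean across bins. Two interpretation decisions
were open:

* **Fraction, not raw count.** The per-segment content is taken as
  `nhet / nsnp`, the *fraction* of the segment's SNPs observed heterozygous.
  The magnitudes this produces (tenths of a percent) are the ones the
  statistic is reported in; the canonical consistency check is that a
  368-SNP segment carrying one het gives 1/368 = 0.27%. The raw-count
  variant remains available behind `use_count = TRUE`.
* **Pooled segments.** Bin weights `|R|` count segments pooled across the
  population's individuals, not per-individual averages.

With the fraction definition, the binned formula collapses to the unbinned
mean of per-segment fractions over all segments of at least 1 Mb — the test
suite asserts this identity, so the binning is a presentation device, not a
hidden estimator choice. Segments below 1 Mb are excluded (the bins start at
1 Mb). `ep_sweep()` evaluates the statistic across `h = 1..5`; the WGS
tolerance whose leakage matches the array channel at `h = 1` is the natural
operating point for joint analyses.

## Population comparison

`summarize_roh_individuals()` reduces a callset to per-individual NROH, mean
size and SROH over segments longer than 1 Mb (the threshold that selects
identity-by-descent segments and removes LD structure). "Mean ROH size" for a
population is the mean over individuals of per-individual means, matching the
per-individual construction of the violin plots; individuals with no
qualifying segment contribute NROH = 0 and SROH = 0 and are excluded from
mean-size comparisons. `compare_channels()` then computes, for each statistic
and each WGS tolerance, the two-sided Mann–Whitney–Wilcoxon p-value between
the array (h = 1) and WGS per-individual distributions (exact enumeration for
tie-free samples up to n = 12, normal approximation with continuity and tie
correction otherwise — both via `stats::wilcox.test`) and the Pearson
correlation of the paired per-individual values (`stats::cor.test`,
t-distribution p with n - 2 df). No multiple-testing correction is applied,
and the significance threshold for heat-map colouring is 0.05, both matching
standard practice for this analysis. `length_class_sums()` supplies the
short/medium/long (0.3–1 / 1–8 / >8 Mb) decomposition whose class sums
partition each individual's total called length.

## What the simulator emulates — and what it does not

`simulate_genotypes()` draws paired observations of one truth:

* **Sites.** WGS sites at jittered ~1.1 kb spacing (one site per ~1.1 kb, the
  observed spacing of *heterozygous* calls in genome-wide low-coverage data,
  used here as the assayed-site density of the channel); array sites are a
  positional subset at ~7.1 kb spacing, so a shared universe exists by
  construction. Four 50 Mb chromosomes and 20 individuals are the default
  study conditions — large enough for hundreds of planted tracts, small
  enough that the full workflow runs in seconds.
* **Background genotypes.** Per-site allele frequencies uniform on
  [0.05, 0.5] (the post-QC spectrum), genotypes drawn independently under
  Hardy–Weinberg. Linkage disequilibrium is deliberately not modelled: the
  analysis targets ROH > 1 Mb under a 50-SNP minimum, chance homozygous runs
  of that scale are vanishingly improbable under independence at these
  densities, and the >1 Mb threshold exists precisely to remove LD effects.
* **Autozygosity.** Planted non-overlapping tracts per individual with
  expected counts {3, 2, 2, 1, 0.5} in the length classes {[0.3,1), [1,1.5),
  [1.5,5), [5,10), [10,16]} Mb (lengths uniform within class) — a high-ROH
  population, of the order seen in cohorts with substantial recent parental
  relatedness, chosen so that per-individual comparisons have signal at n =
  20. Inside a tract both haplotypes carry one drawn allele, so the truth
  layer is strictly homozygous there; every observed het inside a tract is
  attributable to the recorded channel-error list.
* **Channel noise.** True hets flip to a random homozygote at 0.3% (WGS) and
  0.1% (array); any call drops out at 0.2%; and homozygous calls flip to
  spurious hets at a total rate of 2.4/Mb (WGS; presets 0.3 and 4.5/Mb
  bracket the published population range) and 0/Mb (array). Crucially, the
  false hets are a mixture: half arrive as scattered singletons, half in
  clusters of 2–3 *adjacent* sites. This reflects how low-coverage miscalls
  actually occur — concentrated around alignment-problem and paralogous
  regions rather than uniformly — and it is what gives the window tolerance
  its observable effect: under the scanner's semantics a lone false het never
  breaks a segment at any `h >= 1`, so a purely uniform error process of this
  marginal rate would leave NROH essentially identical across tolerances,
  contrary to what cross-platform comparisons report. With clusters capped at
  size 3, tolerance h = 1 is broken by any cluster, h = 2 by triples, and
  h = 3 absorbs everything — reproducing "3 hets per window" as the
  equivalence point.

All randomness flows from one seed; identical seed and configuration
reproduce every output byte for byte. What the simulator does *not* emulate:
LD and haplotype structure, ascertainment bias of array content, coverage
heterogeneity along the genome, population structure between individuals, and
rate differences between populations beyond the preset error levels. Passing
tests on this generator therefore demonstrate the *mechanics* of the
comparison — recovery of planted autozygosity, the fragmentation-vs-tolerance
trade-off, and the equalisation of channels at h = 3 — not calibrated
agreement with any particular cohort.

`truth_overlap()` scores a callset against the planted truth: base-pair
sensitivity and precision per length class, the fraction of tracts recovered
at >= 50% reciprocal overlap, and fragmentation (calls per detected tract).

## Numerical and engineering choices

* Coordinates are 1-based and inclusive at both ends;
  `length_bp = end - start + 1`, matching `.hom`-style reporting.
* Heterozygosity is genotype-level; phase is ignored; half-missing genotype
  strings are missing; "chr" contig prefixes are stripped; only autosomes
  1–22 are retained.
* The exact-HWE tie comparison uses a 1e-7 relative tolerance so that
  mathematically equal probabilities computed by different routes land on the
  same side.
* PED/MAP input without explicit reference alleles uses the major allele
  (alphabetic tie-break) as reference, for determinism.
* MWW exactness switches at n = 12 per sample; integer ROH counts routinely
  tie, so the tie-corrected normal approximation is the common path at the
  default scale.
* The per-Mb error rates interpret "per Mb" against homozygous background:
  the per-site flip probability is `rate * spacing / 1e6` applied to
  homozygous calls, so the realised rate inside autozygous tracts — the
  quantity that governs ROH breaking — matches the configured value (the
  test suite checks 2.4/Mb recovery inside tracts); genome-wide the realised
  rate is proportionally lower by the het fraction of the background.
* Problem sizes: unit tests run on constructed sequences of tens to hundreds
  of sites and simulations of 8 individuals x 2 x 12 Mb; the end-to-end
  checks use the default 20 x 4 x 50 Mb conditions, which complete in well
  under a minute.

## Known limitations

* The scanner reproduces documented PLINK `--homozyg` semantics as specified
  above; undocumented corner-case behaviours of particular PLINK builds
  (exact boundary extension at chromosome ends, for example) may differ at
  single-SNP scale.
* A clean (error-free) channel can still absorb one or two *true* background
  hets at a segment end lying just outside a planted tract — the window
  threshold keeps such sites in state — so measured leakage is a hair above
  zero even without channel errors. This is a property of the algorithm, not
  a bug, and disappears inside the tract body.
* With 20 individuals per channel, the unpaired rank test on NROH has limited
  power against the fragmentation shift at h = 1: the direction is stable
  across seeds, but single-replicate significance at the 0.05 level is not
  guaranteed. Cohorts of ~100, as in published comparisons, put the same
  effect far beyond doubt.
* The ep statistic is undefined (returned as `NA`) when no segment reaches
  1 Mb, and mean ROH size is undefined for individuals without qualifying
  segments; downstream comparisons drop such values rather than imputing.

## A minimal session

```{r example, eval = FALSE}
library(rohcompare)

run <- run_dual_platform_analysis(config = sim_config(), h_values = 1:3,
                                  seed = 11)
run                      # headline: NROH equivalence at h = 3
run$comparison           # MWW p and Pearson r per statistic and tolerance
ep_sweep(run$truth$truth_matrix, h_values = 1:3)   # leakage on clean truth
write_run_report(run, "run_out")                   # TSVs + provenance
```
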