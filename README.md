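# rohcompare

Comparing runs of homozygosity (ROH) called from SNP array genotypes with
ROH called from low-coverage whole-genome sequencing (WGS) of the same
individuals.

## The problem

ROH — contiguous stretches where an individual is homozygous at every
assayed site — are a workhorse summary in population and medical genetics:
per-individual NROH (count of ROH > 1 Mb), mean ROH size and SROH (total
summed length > 1 Mb) track demographic history and inbreeding. Arrays call
genotypes almost without error but assay only ~2.5 M sites; low-coverage
(~4x) sequencing assays everything but wrongly calls a fraction of
homozygous sites heterozygous (~2.4 per Mb on average, ~0.3–4.5 per Mb
across populations). Each false heterozygote cluster can break a long ROH,
so ROH statistics from the two technologies are not directly comparable
unless the scanner's per-window heterozygote tolerance *h* is tuned for the
sequencing channel.

`rohcompare` provides the full analysis as a tested R package, for anyone
combining array-era and sequencing-era datasets in a joint ROH study:

* `call_roh()` — a PLINK-style sliding-window ROH scanner (50-SNP windows,
  *h* tolerated hets and 5 missing calls per window, 5% window threshold;
  final segments >= 50 SNPs, >= 300 kb, >= 1 SNP / 50 kb, 1 Mb gap split),
  deterministic and verified against an exhaustive brute-force oracle.
* `apply_qc()` — per-population site filtering: MAF < 0.05 removed, exact
  Hardy–Weinberg test (`hwe_exact_p()`) p < 0.001 removed.
* `concordance_table()` / `roh_error_rate()` — cross-channel genotype
  concordance decomposed into het-array/hom-WGS and hom-array/het-WGS
  components; the latter is the ROH-breaking error.
* `ep_statistic()` / `ep_sweep()` — the heterozygote-leakage statistic
  ep(P, h): the segment-count-weighted mean, over length bins
  {[1,1.5), [1.5,5), [5,10), [10,∞)} Mb, of the mean per-segment fraction of
  SNPs observed heterozygous, as a percentage. A 368-SNP ROH with one
  observed het contributes 1/368 = 0.27%.
* `compare_channels()` — per-individual NROH / mean size / SROH compared
  between array (h = 1) and WGS (h = 1..5) by two-sided
  Mann–Whitney–Wilcoxon tests and Pearson correlations.
* `simulate_genotypes()` — a seeded dual-channel simulator: jittered site
  maps (~1.1 kb WGS, ~7.1 kb array), HWE background genotypes, planted
  autozygous tracts, and channel noise including clustered false
  heterozygotes; `truth_overlap()` scores recovery against the planted
  truth.
* `run_dual_platform_analysis()` — the end-to-end workflow;
  `inst/scripts/rohcompare.R` wraps it for the shell.

Standard formats are supported: VCF in (`read_vcf()`, via vcfR) and out,
PLINK text PED/MAP in, PLINK `.hom`-style segment tables in and out, truth
tracts as BED.

## Worked example

Twenty individuals, four 50 Mb chromosomes, planted autozygous tracts, WGS
channel with 2.4 clustered false hets per Mb — then QC, ROH calling at
h = 1..3 on WGS vs h = 1 on the array, and the channel comparison:

```r
library(rohcompare)
run <- run_dual_platform_analysis(config = sim_config(), h_values = 1:3,
                                  seed = 11)
run
#> roh_comparison_run [SIM]
#>   array segments: 184
#>   wgs h=1 segments: 378
#>   wgs h=2 segments: 266
#>   wgs h=3 segments: 190
#>   NROH MWW p: h=1 0.000173, h=3 0.878
#>   headline (significant at h=1, equivalent at h=3): PASS

run$comparison[, c("statistic", "h", "mww_p", "pearson_r")]
#>   statistic h    mww_p pearson_r
#> 1      nroh 1 1.73e-04     0.642
#> 2      nroh 2 2.88e-02     0.817
#> 3      nroh 3 8.78e-01     0.983
#> 4 mean_size 1 4.54e-06     0.512
#> 5 mean_size 2 4.32e-03     0.781
#> 6 mean_size 3 9.46e-01     0.991
#> 7      sroh 1 1.90e-01     0.993
#> 8      sroh 2 5.61e-01     0.998
#> 9      sroh 3 9.25e-01     1.000
```

Reading the output: at h = 1 the WGS channel calls twice as many segments as
the array (378 vs 184) because clustered miscalls fragment long ROH — the
per-individual NROH distributions differ significantly (MWW p = 1.7e-4) and
correlate only moderately (r = 0.64). Allowing 3 heterozygous SNPs per
window absorbs the miscalls: segment counts converge (190 vs 184), the
distributions become statistically indistinguishable (p = 0.88) and the
per-individual correlation reaches r = 0.98. That is the package's headline
guidance: compare array ROH at h = 1 with low-coverage WGS ROH at h = 3.

The shipped 20-population concordance table reproduces the published
summary arithmetic:

```r
tbl <- read_concordance_table(system.file("extdata",
        "platform_concordance_20pop.tsv", package = "rohcompare"))
str(summarize_concordance(tbl))
#> List of 8
#>  $ mean_concordant    : num 99.6
#>  $ mean_discordant    : num 0.421
#>  $ mean_hetA_homW     : num 0.0844
#>  $ mean_homA_hetW     : num 0.337
#>  $ het_ratio_wgs_array: num 6.32
#>  $ mean_het_wgs       : num 2558284
#>  $ mean_het_array     : num 404753
#>  $ n_populations      : int 20
```

i.e. 99.6% mean concordance, discordance components of 0.1% and 0.3%, and
6.3x more heterozygote calls in the sequencing channel.

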