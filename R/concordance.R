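#' @keywords internal
# indices of sites shared by chromosome+position between two matrices
.shared_sites <- function(a, b) {
  ka <- a$sites$chrom * 2^32 + a$sites$pos
  kb <- b$sites$chrom * 2^32 + b$sites$pos
  m <- match(ka, kb)
  ia <- which(!is.na(m))
  list(a = ia, b = m[ia])
}

#' Cross-channel genotype concordance for one individual
#'
#' Classifies every site present (by chromosome and position) and
#' non-missing in both channels into exactly one of: concordant (same
#' four-state call), het-array/hom-WGS, hom-array/het-WGS, or a
#' hom-ref/hom-alt mismatch (allele-swap discordance, reported separately
#' and excluded from the two named het components).
#'
#' @param array,wgs [genotype_matrix()] objects for the two channels.
#' @param individual Individual ID present in both matrices.
#' @return A list of counts (`n_shared`, `concordant`, `hetA_homW`,
#'   `homA_hetW`, `homhom_mismatch`) and the corresponding percentages of
#'   `n_shared`.
#' @export
concordance_by_individual <- function(array, wgs, individual) {
  if (!individual %in% array$individuals)
    stop("individual ", individual, " missing from the array channel")
  if (!individual %in% wgs$individuals)
    stop("individual ", individual, " missing from the wgs channel")
  sh <- .shared_sites(array, wgs)
  ga <- array$geno[sh$a, match(individual, array$individuals)]
  gw <- wgs$geno[sh$b, match(individual, wgs$individuals)]
  ok <- !is.na(ga) & !is.na(gw)
  ga <- ga[ok]; gw <- gw[ok]
  n <- length(ga)
  conc <- sum(ga == gw)
  hetA_homW <- sum(ga == 1L & gw != 1L)
  homA_hetW <- sum(ga != 1L & gw == 1L)
  homhom <- n - conc - hetA_homW - homA_hetW
  pct <- function(x) if (n > 0) 100 * x / n else NA_real_
  list(n_shared = n, concordant = conc, hetA_homW = hetA_homW,
       homA_hetW = homA_hetW, homhom_mismatch = homhom,
       concordant_pct = pct(conc), discordant_pct = pct(n - conc),
       hetA_homW_pct = pct(hetA_homW), homA_hetW_pct = pct(homA_hetW),
       homhom_mismatch_pct = pct(homhom))
}

#' Population-level concordance decomposition table
#'
#' Averages per-individual concordance percentages over the individuals
#' common to both channels and reports the mean per-individual heterozygote
#' call counts of each channel (over all sites of that channel, not only
#' shared ones). One row per population, mirroring the structure of the
#' reference concordance table shipped in `inst/extdata`.
#'
#' @inheritParams concordance_by_individual
#' @param population Population label for the output row.
#' @return One-row data frame with columns `population`, `mean_het_wgs`,
#'   `mean_het_array`, `concordant`, `discordant`, `hetA_homW`, `homA_hetW`,
#'   `homhom_mismatch`.
#' @export
concordance_table <- function(array, wgs, population = "ALL") {
  ids <- intersect(array$individuals, wgs$individuals)
  if (!length(ids)) stop("no individuals shared between channels")
  per <- lapply(ids, function(i) concordance_by_individual(array, wgs, i))
  m <- function(field) mean(vapply(per, `[[`, numeric(1), field))
  data.frame(population = population,
             mean_het_wgs = mean(colSums(wgs$geno[, ids, drop = FALSE] == 1L,
                                         na.rm = TRUE)),
             mean_het_array = mean(colSums(array$geno[, ids, drop = FALSE] == 1L,
                                           na.rm = TRUE)),
             concordant = m("concordant_pct"), discordant = m("discordant_pct"),
             hetA_homW = m("hetA_homW_pct"), homA_hetW = m("homA_hetW_pct"),
             homhom_mismatch = m("homhom_mismatch_pct"),
             stringsAsFactors = FALSE)
}

#' ROH-breaking error rate of the sequencing channel
#'
#' Rate of sites called homozygous by the array but heterozygous by WGS --
#' the miscalls that can break a run of homozygosity. Computed over sites
#' shared and non-missing in both (post-QC) matrices, taking the array as
#' gold standard: reported as a percentage of shared sites and as a
#' per-megabase rate (mean per-individual count divided by the autosomal
#' span).
#'
#' @inheritParams concordance_by_individual
#' @param span_mb Autosomal span in Mb used for the per-Mb rate. `NULL`
#'   (default) derives it from the WGS matrix's site range; use 2800 for
#'   genome-wide human data.
#' @return A list: `pct` (percent of shared sites), `per_mb`, `mean_count`
#'   (mean per-individual count) and `span_mb`.
#' @export
roh_error_rate <- function(array, wgs, span_mb = NULL) {
  ids <- intersect(array$individuals, wgs$individuals)
  if (!length(ids)) stop("no individuals shared between channels")
  if (is.null(span_mb)) span_mb <- genome_span_bp(wgs) / 1e6
  per <- lapply(ids, function(i) concordance_by_individual(array, wgs, i))
  counts <- vapply(per, `[[`, numeric(1), "homA_hetW")
  pcts <- vapply(per, `[[`, numeric(1), "homA_hetW_pct")
  list(pct = mean(pcts), per_mb = mean(counts) / span_mb,
       mean_count = mean(counts), span_mb = span_mb)
}

#' Autosomal span covered by a genotype matrix
#'
#' Sum over chromosomes of `max(pos) - min(pos) + 1`.
#'
#' @param gm A [genotype_matrix()].
#' @return Span in bp.
#' @export
genome_span_bp <- function(gm) {
  s <- split(gm$sites$pos, gm$sites$chrom)
  sum(vapply(s, function(p) max(p) - min(p) + 1, numeric(1)))
}

#' Mean spacing between heterozygous calls
#'
#' Autosomal span divided by the mean per-individual heterozygote call
#' count, in kb. With genome-wide human data and ~2.6 M hets this is the
#' familiar "1 het per 1.1 kb" figure for low-coverage sequencing (vs ~7 kb
#' for a 2.5 M-site array).
#'
#' @param gm A [genotype_matrix()].
#' @param span_bp Autosomal span in bp; default derives it from the matrix.
#' @return Mean kb between het calls, or `NA` if there are no het calls.
#' @export
het_density <- function(gm, span_bp = NULL) {
  if (is.null(span_bp)) span_bp <- genome_span_bp(gm)
  mean_het <- mean(colSums(gm$geno == 1L, na.rm = TRUE))
  if (mean_het == 0) return(NA_real_)
  (span_bp / mean_het) / 1000
}

#' Read a concordance decomposition table
#'
#' Reads a tab-separated table with the columns produced by
#' [concordance_table()] (`population`, `mean_het_wgs`, `mean_het_array`,
#' `concordant`, `discordant`, `hetA_homW`, `homA_hetW`, ...). The package
#' ships such a table for 20 world populations genotyped on both an Omni
#' 2.5-8 array and ~4x whole-genome sequencing (1000 Genomes Phase 3 and
#' African Genome Variation Project cohorts) at
#' `system.file("extdata", "platform_concordance_20pop.tsv", package = "rohcompare")`.
#'
#' @param path Path to the TSV.
#' @return A data frame.
#' @export
read_concordance_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("population", "mean_het_wgs", "mean_het_array", "concordant",
            "discordant", "hetA_homW", "homA_hetW")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df
}

#' Summary arithmetic over a concordance table
#'
#' Column means of the concordance decomposition plus the WGS/array mean
#' heterozygote-count ratio, i.e. the headline numbers of a cross-platform
#' variant-calling comparison.
#'
#' @param tbl A data frame from [read_concordance_table()] or rows from
#'   [concordance_table()].
#' @return A list: `mean_concordant`, `mean_discordant`, `mean_hetA_homW`,
#'   `mean_homA_hetW`, `het_ratio_wgs_array`, `mean_het_wgs`,
#'   `mean_het_array`, `n_populations`.
#' @export
summarize_concordance <- function(tbl) {
  list(mean_concordant = mean(tbl$concordant),
       mean_discordant = mean(tbl$discordant),
       mean_hetA_homW = mean(tbl$hetA_homW),
       mean_homA_hetW = mean(tbl$homA_hetW),
       het_ratio_wgs_array = mean(tbl$mean_het_wgs) / mean(tbl$mean_het_array),
       mean_het_wgs = mean(tbl$mean_het_wgs),
       mean_het_array = mean(tbl$mean_het_array),
       n_populations = nrow(tbl))
}
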