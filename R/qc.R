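#' Per-site quality-control statistics
#'
#' Computes, for every site of a genotype matrix, the genotype counts over
#' called (non-missing) individuals, the minor allele frequency and the
#' exact Hardy-Weinberg p-value. MAF is computed from allele counts over
#' called individuals only: `maf = min(c_alt, c_ref) / (2 * n_called)` with
#' `c_alt = 2 * n_hom_alt + n_het`.
#'
#' @param gm A [genotype_matrix()].
#' @return A data frame with one row per site: `id`, `n_called`, `n_het`,
#'   `n_hom_ref`, `n_hom_alt`, `maf`, `hwe_p`. Sites with zero called
#'   individuals get `NA` statistics.
#' @export
site_qc_stats <- function(gm) {
  g <- gm$geno
  n_het <- rowSums(g == 1L, na.rm = TRUE)
  n_hom_ref <- rowSums(g == 0L, na.rm = TRUE)
  n_hom_alt <- rowSums(g == 2L, na.rm = TRUE)
  n_called <- n_het + n_hom_ref + n_hom_alt
  c_alt <- 2 * n_hom_alt + n_het
  maf <- ifelse(n_called > 0, pmin(c_alt, 2 * n_called - c_alt) / (2 * n_called), NA_real_)
  # the p-value depends only on (n_het, minor hom, major hom): dedupe for speed
  key <- paste(n_het, pmin(n_hom_ref, n_hom_alt), pmax(n_hom_ref, n_hom_alt))
  uk <- !duplicated(key)
  pu <- hwe_exact_p(n_het[uk], pmin(n_hom_ref, n_hom_alt)[uk],
                    pmax(n_hom_ref, n_hom_alt)[uk])
  hwe_p <- pu[match(key, key[uk])]
  hwe_p[n_called == 0] <- NA_real_
  data.frame(id = gm$sites$id, n_called = n_called, n_het = n_het,
             n_hom_ref = n_hom_ref, n_hom_alt = n_hom_alt,
             maf = maf, hwe_p = hwe_p, stringsAsFactors = FALSE)
}

# core of the exact test for one genotype configuration.
# Conditional on the observed allele counts, the probability of k heterozygotes
# is proportional to n! / (n_mm! k! n_MM!) * 2^k; the two-sided p-value sums the
# probabilities of all het counts (same parity as the minor allele count) whose
# probability does not exceed that of the observed count. Computed through the
# ratio recurrence P(k-2)/P(k) = k(k-1) / (4 (n_mm+1)(n_MM+1)) in log space.
.hwe_p1 <- function(nhet, nhom1, nhom2) {
  n <- nhet + nhom1 + nhom2
  if (n == 0L) return(NA_real_)
  m <- 2L * min(nhom1, nhom2) + nhet     # minor allele count
  if (m == 0L) return(1)                 # monomorphic
  ks <- seq.int(m %% 2L, m, by = 2L)
  nk <- length(ks)
  logu <- numeric(nk)
  if (nk > 1L) {
    # walk downward from k = m
    k <- ks[nk:2L]
    hom_minor_next <- (m - k) / 2 + 1     # minor homs after removing one het pair
    hom_major_next <- ((2 * n - m) - k) / 2 + 1
    steps <- log(k) + log(k - 1) - log(4) - log(hom_minor_next) - log(hom_major_next)
    logu[(nk - 1L):1L] <- cumsum(steps)
  }
  u <- exp(logu - max(logu))
  u <- u / sum(u)
  p_obs <- u[match(nhet, ks)]
  min(1, sum(u[u <= p_obs * (1 + 1e-7)]))
}

#' Exact Hardy-Weinberg test p-value
#'
#' Two-sided exact test of Hardy-Weinberg proportions conditional on the
#' observed allele counts (no mid-p correction): the p-value is the sum of
#' the probabilities of all heterozygote counts, compatible with the same
#' allele counts and sample size, whose conditional probability does not
#' exceed that of the observed count. Monomorphic sites return 1. The test is
#' invariant under swapping the two homozygote counts. Vectorised over its
#' arguments.
#'
#' @param n_het,n_hom_ref,n_hom_alt Non-negative genotype counts
#'   (`sum >= 1`).
#' @param method `"exact"` (default) or `"chisq"` for the 1-df chi-square
#'   goodness-of-fit variant (no continuity correction), provided for
#'   comparison.
#' @return Numeric vector of p-values in (0, 1].
#' @export
hwe_exact_p <- function(n_het, n_hom_ref, n_hom_alt, method = c("exact", "chisq")) {
  method <- match.arg(method)
  stopifnot(length(n_het) == length(n_hom_ref),
            length(n_het) == length(n_hom_alt))
  if (any(n_het < 0 | n_hom_ref < 0 | n_hom_alt < 0, na.rm = TRUE))
    stop("genotype counts must be non-negative")
  if (method == "chisq") {
    return(mapply(function(h, r, a) {
      n <- h + r + a
      if (n == 0L) return(NA_real_)
      p <- (2 * r + h) / (2 * n)
      if (p == 0 || p == 1) return(1)
      e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
      stat <- sum((c(r, h, a) - e)^2 / e)
      stats::pchisq(stat, df = 1, lower.tail = FALSE)
    }, n_het, n_hom_ref, n_hom_alt))
  }
  mapply(.hwe_p1, as.integer(n_het), as.integer(n_hom_ref), as.integer(n_hom_alt))
}

#' Filter sites by minor allele frequency and Hardy-Weinberg equilibrium
#'
#' Removes sites with `maf < maf_min` (strictly lower; a site at exactly the
#' threshold is retained) or exact HWE p-value `< hwe_alpha`, plus sites with
#' zero called individuals. Intended to be applied per population and per
#' channel independently. Idempotent: filtering twice equals filtering once.
#'
#' @param gm A [genotype_matrix()].
#' @param maf_min Minimum minor allele frequency retained (default 0.05).
#' @param hwe_alpha HWE removal threshold on the exact p-value (default 0.001).
#' @return A list with components `matrix` (the filtered
#'   [genotype_matrix()]), `report` (data frame `site_id`, `reason` in
#'   {"maf", "hwe", "maf+hwe", "no_calls"}, `value` of the offending
#'   statistic) and `stats` (full [site_qc_stats()] of the input).
#' @export
apply_qc <- function(gm, maf_min = 0.05, hwe_alpha = 0.001) {
  st <- site_qc_stats(gm)
  no_calls <- st$n_called == 0
  fail_maf <- !no_calls & st$maf < maf_min
  fail_hwe <- !no_calls & st$hwe_p < hwe_alpha
  drop <- no_calls | fail_maf | fail_hwe
  reason <- character(sum(drop))
  idx <- which(drop)
  reason[no_calls[idx]] <- "no_calls"
  reason[fail_maf[idx] & !fail_hwe[idx]] <- "maf"
  reason[!fail_maf[idx] & fail_hwe[idx]] <- "hwe"
  reason[fail_maf[idx] & fail_hwe[idx]] <- "maf+hwe"
  report <- data.frame(site_id = st$id[idx], reason = reason,
                       value = ifelse(fail_maf[idx], st$maf[idx], st$hwe_p[idx]),
                       stringsAsFactors = FALSE)
  attr(report, "n_removed_maf") <- sum(fail_maf)
  attr(report, "n_removed_hwe") <- sum(fail_hwe)
  attr(report, "n_removed_no_calls") <- sum(no_calls)
  if (all(drop))
    stop("QC removed every site (maf: ", sum(fail_maf), ", hwe: ",
         sum(fail_hwe), ", no calls: ", sum(no_calls), ")")
  list(matrix = subset_sites(gm, !drop), report = report, stats = st)
}
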