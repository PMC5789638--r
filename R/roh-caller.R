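#' Parameters of the sliding-window ROH scanner
#'
#' Defaults reproduce the standard PLINK `--homozyg` parameterisation for
#' joint array/WGS analyses: windows of 50 SNPs scanned along each
#' chromosome, up to `window_het` heterozygous and 5 missing calls tolerated
#' per window, a SNP considered inside a homozygous segment when at least 5%
#' of the windows covering it are fully "homozygous", and final segments
#' required to have at least 50 SNPs, span at least 300 kb, and carry at
#' least 1 SNP per 50 kb. Consecutive sites further apart than `max_gap_kb`
#' split a segment.
#'
#' @param window_het Heterozygous calls tolerated per window (`h`, 1-5 in
#'   typical sweeps).
#' @param window_snp Number of SNPs per scanning window.
#' @param window_missing Missing calls tolerated per window.
#' @param window_threshold Minimum proportion of covering windows that must
#'   be homozygous for a SNP to be in a segment.
#' @param min_snp Minimum SNP count of a final segment.
#' @param min_kb Minimum length (kb) of a final segment.
#' @param density_kb_per_snp Maximum kb per SNP in a final segment (density
#'   filter: at least 1 SNP per this many kb).
#' @param max_gap_kb Maximum gap (kb) between consecutive SNPs within one
#'   segment.
#' @return An object of class `roh_params`.
#' @export
roh_params <- function(window_het = 1L, window_snp = 50L, window_missing = 5L,
                       window_threshold = 0.05, min_snp = 50L, min_kb = 300,
                       density_kb_per_snp = 50, max_gap_kb = 1000) {
  p <- list(window_het = as.integer(window_het),
            window_snp = as.integer(window_snp),
            window_missing = as.integer(window_missing),
            window_threshold = window_threshold,
            min_snp = as.integer(min_snp), min_kb = min_kb,
            density_kb_per_snp = density_kb_per_snp, max_gap_kb = max_gap_kb)
  stopifnot(p$window_snp >= 1L, p$window_het >= 0L, p$window_missing >= 0L,
            p$window_threshold > 0, p$window_threshold <= 1,
            p$min_snp >= 1L, p$min_kb > 0, p$density_kb_per_snp > 0,
            p$max_gap_kb > 0)
  structure(p, class = "roh_params")
}

#' Per-window homozygosity flags for one chromosome
#'
#' Slides a `window_snp`-SNP window one site at a time along an ordered
#' per-chromosome call sequence; window `i` (sites `i .. i+window_snp-1`) is
#' flagged homozygous iff it contains at most `window_het` heterozygous and
#' at most `window_missing` missing calls.
#'
#' @param calls Integer genotype codes (0/1/2/NA) for one individual on one
#'   chromosome, in position order.
#' @param params An [roh_params()].
#' @return Logical vector of length `max(0, n - window_snp + 1)`; a
#'   chromosome with fewer sites than the window yields zero windows.
#' @export
window_flags <- function(calls, params = roh_params()) {
  n <- length(calls)
  W <- params$window_snp
  if (n < W) return(logical(0))
  het <- !is.na(calls) & calls == 1L
  mis <- is.na(calls)
  ch <- c(0L, cumsum(het))
  cm <- c(0L, cumsum(mis))
  i <- seq_len(n - W + 1L)
  (ch[i + W] - ch[i]) <= params$window_het &
    (cm[i + W] - cm[i]) <= params$window_missing
}

#' Per-site homozygous-segment state from window flags
#'
#' A site is "in state" iff the proportion of homozygous windows among the
#' windows containing it is at least `window_threshold`. Sites near the
#' chromosome ends are covered by fewer than `window_snp` windows; the actual
#' count of covering windows is used as the denominator. Sites covered by no
#' window (chromosome shorter than the window) are never in state.
#'
#' @param flags Logical window flags from [window_flags()].
#' @param n_sites Number of sites on the chromosome.
#' @param params An [roh_params()].
#' @return Logical vector of length `n_sites`.
#' @export
snp_roh_state <- function(flags, n_sites, params = roh_params()) {
  W <- params$window_snp
  nw <- length(flags)
  if (nw == 0L) return(rep(FALSE, n_sites))
  s <- seq_len(n_sites)
  lo <- pmax(1L, s - W + 1L)
  hi <- pmin(s, nw)
  covered <- hi - lo + 1L
  cf <- c(0L, cumsum(flags))
  nflag <- cf[hi + 1L] - cf[lo]
  nflag / covered >= params$window_threshold
}

# candidate run -> retained segments for one individual-chromosome.
# pos/calls are the full per-chromosome vectors; runs is a 2-column matrix of
# candidate [start,end] site indices.
.finalize_runs <- function(runs, pos, calls, params) {
  out <- vector("list", nrow(runs))
  het <- !is.na(calls) & calls == 1L
  ok <- !is.na(calls) & calls != 1L   # non-het, non-missing
  gap_bp <- params$max_gap_kb * 1000
  k <- 0L
  for (r in seq_len(nrow(runs))) {
    a <- runs[r, 1L]; b <- runs[r, 2L]
    idx <- a:b
    # split between consecutive sites whose gap exceeds the maximum
    cut <- which(diff(pos[idx]) > gap_bp)
    starts <- c(a, idx[cut + 1L])
    ends <- c(idx[cut], b)
    for (p in seq_along(starts)) {
      i0 <- starts[p]; i1 <- ends[p]
      # trim so the first and last site are non-het, non-missing
      good <- which(ok[i0:i1])
      if (!length(good)) next
      i0t <- i0 + good[1L] - 1L
      i1t <- i0 + good[length(good)] - 1L
      nsnp <- i1t - i0t + 1L
      len <- pos[i1t] - pos[i0t] + 1L
      if (nsnp < params$min_snp) next
      if (len < params$min_kb * 1000) next
      if (nsnp / (len / 1000) < 1 / params$density_kb_per_snp) next
      k <- k + 1L
      out[[k]] <- c(i0t, i1t, nsnp, sum(het[i0t:i1t]))
    }
  }
  if (k == 0L) return(NULL)
  do.call(rbind, out[seq_len(k)])
}

#' Call runs of homozygosity from a genotype matrix
#'
#' The full observational scanner: per individual and chromosome, window
#' flags are computed ([window_flags()]), per-site states derived
#' ([snp_roh_state()]), maximal runs of in-state sites form candidate
#' segments, runs are split at inter-SNP gaps larger than `max_gap_kb`,
#' segment boundaries are trimmed so the first and last site are non-het and
#' non-missing, and segments are retained iff they satisfy the final SNP
#' count, length and density filters. The observed heterozygote count inside
#' each retained segment is recorded. Deterministic: identical input and
#' parameters give identical output.
#'
#' @param gm A (QC-filtered) [genotype_matrix()].
#' @param params An [roh_params()].
#' @param population Population label carried into the callset.
#' @return An [roh_callset()] (possibly with zero segments).
#' @export
call_roh <- function(gm, params = roh_params(), population = NA_character_) {
  segs <- list()
  chroms <- unique(gm$sites$chrom)
  for (chrom in chroms) {
    cidx <- which(gm$sites$chrom == chrom)
    pos <- gm$sites$pos[cidx]
    for (j in seq_along(gm$individuals)) {
      calls <- gm$geno[cidx, j]
      flags <- window_flags(calls, params)
      state <- snp_roh_state(flags, length(calls), params)
      if (!any(state)) next
      rl <- rle(state)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      runs <- cbind(starts[rl$values], ends[rl$values])
      fin <- .finalize_runs(runs, pos, calls, params)
      if (is.null(fin)) next
      segs[[length(segs) + 1L]] <- data.frame(
        iid = gm$individuals[j], chrom = chrom,
        start = pos[fin[, 1L]], end = pos[fin[, 2L]],
        nsnp = fin[, 3L], nhet = fin[, 4L], stringsAsFactors = FALSE)
    }
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(iid = character(0), chrom = integer(0), start = integer(0),
               end = integer(0), nsnp = integer(0), nhet = integer(0),
               stringsAsFactors = FALSE)
  roh_callset(segments, params = params, channel = gm$channel,
              individuals = gm$individuals, population = population)
}
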