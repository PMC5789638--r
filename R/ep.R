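#' Default ROH length bins (Mb) for the heterozygote-leakage statistic
#'
#' Half-open intervals `[1,1.5), [1.5,5), [5,10), [10,Inf)` Mb, covering all
#' segments of at least 1 Mb.
#'
#' @return A list of `c(lower, upper)` pairs in Mb.
#' @export
default_length_bins <- function() {
  list(c(1, 1.5), c(1.5, 5), c(5, 10), c(10, Inf))
}

#' Per-bin heterozygote leakage inside called ROH
#'
#' For each length bin `[x, y)` (Mb), the number of segments falling in the
#' bin and the arithmetic mean over those segments of the observed
#' heterozygote content. By default the content of a segment is the
#' *fraction* of its SNPs observed heterozygous (`nhet / nsnp`); set
#' `use_count = TRUE` for the raw per-segment het count instead. An empty
#' bin contributes 0 with weight 0.
#'
#' @param callset An [roh_callset()] computed at some tolerance `h`.
#' @param bins List of `c(lower, upper)` length bins in Mb (see
#'   [default_length_bins()]).
#' @param use_count Use raw het counts instead of per-segment fractions.
#' @return Data frame with one row per bin: `bin`, `lower_mb`, `upper_mb`,
#'   `n_segments`, `ep_bin`.
#' @export
ep_bin_values <- function(callset, bins = default_length_bins(),
                          use_count = FALSE) {
  s <- callset$segments
  len_mb <- s$length_bp / 1e6
  val <- if (use_count) s$nhet else s$nhet / s$nsnp
  rows <- lapply(bins, function(b) {
    inb <- len_mb >= b[1] & len_mb < b[2]
    data.frame(bin = sprintf("[%g,%g)", b[1], b[2]),
               lower_mb = b[1], upper_mb = b[2], n_segments = sum(inb),
               ep_bin = if (any(inb)) mean(val[inb]) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Observed heterozygote leakage statistic ep(P, h)
#'
#' Summarises how many heterozygous calls actually sit inside the ROH called
#' for a population at window tolerance `h`: the segment-count-weighted mean
#' over length bins of the per-bin mean heterozygote content, expressed as a
#' percentage. With the default per-segment fraction definition this equals
#' `100 * mean(nhet / nsnp)` over all segments of at least 1 Mb,
#' independently of the binning. A single 368-SNP segment carrying one het
#' gives 0.27%.
#'
#' @inheritParams ep_bin_values
#' @return The statistic as a percentage, or `NA` if no segment reaches the
#'   smallest bin.
#' @export
ep_statistic <- function(callset, bins = default_length_bins(),
                         use_count = FALSE) {
  bv <- ep_bin_values(callset, bins, use_count)
  w <- bv$n_segments
  if (sum(w) == 0) return(NA_real_)
  100 * sum(w * bv$ep_bin) / sum(w)
}

#' Heterozygote-leakage sweep over window tolerances
#'
#' Calls ROH at each tolerance `h` and evaluates [ep_statistic()], the usual
#' way to locate the WGS tolerance whose leakage matches the array channel
#' at `h = 1`.
#'
#' @param gm A QC-filtered [genotype_matrix()].
#' @param params Base [roh_params()]; `window_het` is overridden by each `h`.
#' @param h_values Tolerances to sweep (subset of 1..5 typically).
#' @param population Population label.
#' @inheritParams ep_bin_values
#' @return Data frame `population`, `channel`, `h`, `n_segments`, `ep`; the
#'   per-bin tables are attached as the `"bins"` attribute (a list indexed
#'   by `h`), the callsets as `"callsets"`.
#' @export
ep_sweep <- function(gm, params = roh_params(), h_values = 1:5,
                     population = NA_character_,
                     bins = default_length_bins(), use_count = FALSE) {
  out <- vector("list", length(h_values))
  bintabs <- list()
  callsets <- list()
  for (k in seq_along(h_values)) {
    h <- h_values[k]
    p <- params
    p$window_het <- as.integer(h)
    cs <- call_roh(gm, p, population = population)
    bintabs[[as.character(h)]] <- ep_bin_values(cs, bins, use_count)
    callsets[[as.character(h)]] <- cs
    out[[k]] <- data.frame(population = population, channel = gm$channel,
                           h = h,
                           n_segments = sum(bintabs[[as.character(h)]]$n_segments),
                           ep = ep_statistic(cs, bins, use_count),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "bins") <- bintabs
  attr(res, "callsets") <- callsets
  res
}
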