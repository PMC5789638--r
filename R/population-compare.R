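#' Per-individual ROH summaries
#'
#' For every individual scanned by the callset (including those with zero
#' qualifying segments): NROH, the count of segments longer than `min_mb`;
#' the mean size (Mb) of those segments; and SROH, their total summed length
#' (Mb). The 1 Mb default keeps only ROH plausibly arising from identity by
#' descent and removes LD effects. Individuals with no qualifying segment
#' report `nroh = 0`, `sroh_mb = 0` and `mean_size_mb = NA`.
#'
#' @param callset An [roh_callset()].
#' @param min_mb Minimum segment length retained, in Mb (strictly greater
#'   than).
#' @return Data frame `iid`, `nroh`, `mean_size_mb`, `sroh_mb`.
#' @export
summarize_roh_individuals <- function(callset, min_mb = 1) {
  s <- callset$segments
  len_mb <- s$length_bp / 1e6
  keep <- len_mb > min_mb
  ids <- callset$individuals
  nroh <- integer(length(ids))
  sroh <- numeric(length(ids))
  msz <- rep(NA_real_, length(ids))
  if (any(keep)) {
    t1 <- tapply(len_mb[keep], factor(s$iid[keep], levels = ids), length)
    t2 <- tapply(len_mb[keep], factor(s$iid[keep], levels = ids), sum)
    hit <- !is.na(t1)
    nroh[hit] <- t1[hit]
    sroh[hit] <- t2[hit]
    msz[hit] <- sroh[hit] / nroh[hit]
  }
  data.frame(iid = ids, nroh = nroh, mean_size_mb = msz, sroh_mb = sroh,
             stringsAsFactors = FALSE)
}

#' Two-sided Mann-Whitney-Wilcoxon rank-sum test
#'
#' Thin wrapper over [stats::wilcox.test()]: exact enumeration when both
#' samples have at most 12 observations and there are no ties, otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param a,b Non-empty numeric samples.
#' @return Two-sided p-value.
#' @export
mww_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 12 && length(b) <= 12 && !ties
  suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                      correct = TRUE))$p.value
}

#' Pearson product-moment correlation with p-value
#'
#' Paired per-individual values from the two channels; the p-value comes
#' from the t-distribution with `n - 2` degrees of freedom. Pairs with a
#' missing value are dropped.
#'
#' @param a,b Paired numeric vectors (same individuals, same order).
#' @return List `r`, `p`, `n`; `r` is `NA` when either vector has zero
#'   variance or fewer than 3 complete pairs remain.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must be paired (equal length)")
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3 || stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Array-vs-WGS comparison of per-individual ROH statistics
#'
#' For each summary statistic (NROH, mean size, SROH) and each WGS window
#' tolerance `h`: the two-sided MWW p-value between the array (h = 1) and
#' WGS per-individual distributions, and the Pearson correlation of the
#' paired per-individual values. This is the numerical content of the usual
#' correlation / significance heat-maps.
#'
#' @param array_callset [roh_callset()] from the array channel (h = 1).
#' @param wgs_callsets Named list of WGS [roh_callset()]s; names are the
#'   tolerances `h` (defaults to each callset's own tolerance).
#' @param min_mb Minimum segment length (Mb) for the summaries.
#' @return Data frame `statistic`, `h`, `mww_p`, `pearson_r`, `pearson_p`.
#'   Matrices (statistic x h) for heat-map rendering are attached as
#'   attributes `"mww_matrix"` and `"cor_matrix"`; per-individual summaries
#'   as `"summaries"`.
#' @export
compare_channels <- function(array_callset, wgs_callsets, min_mb = 1) {
  if (inherits(wgs_callsets, "roh_callset")) wgs_callsets <- list(wgs_callsets)
  if (is.null(names(wgs_callsets)) || any(names(wgs_callsets) == ""))
    names(wgs_callsets) <- vapply(wgs_callsets, function(cs)
      as.character(cs$het_tolerance), character(1))
  ids <- array_callset$individuals
  for (cs in wgs_callsets) {
    extra <- c(setdiff(ids, cs$individuals), setdiff(cs$individuals, ids))
    if (length(extra))
      stop("individual sets differ between channels: ",
           paste(extra, collapse = ", "))
  }
  sa <- summarize_roh_individuals(array_callset, min_mb)
  sw <- lapply(wgs_callsets, summarize_roh_individuals, min_mb = min_mb)
  stats_cols <- c(nroh = "nroh", mean_size = "mean_size_mb", sroh = "sroh_mb")
  rows <- list()
  for (st in names(stats_cols)) {
    col <- stats_cols[[st]]
    for (h in names(sw)) {
      w <- sw[[h]][match(ids, sw[[h]]$iid), col]
      a <- sa[[col]]
      pr <- pearson_r(a, w)
      rows[[length(rows) + 1L]] <- data.frame(
        statistic = st, h = as.integer(h),
        mww_p = mww_test(a, w), pearson_r = pr$r, pearson_p = pr$p,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  hs <- sort(unique(res$h))
  mk <- function(col) {
    m <- matrix(NA_real_, nrow = length(stats_cols), ncol = length(hs),
                dimnames = list(names(stats_cols), hs))
    for (i in seq_len(nrow(res)))
      m[res$statistic[i], as.character(res$h[i])] <- res[[col]][i]
    m
  }
  attr(res, "mww_matrix") <- mk("mww_p")
  attr(res, "cor_matrix") <- mk("pearson_r")
  attr(res, "summaries") <- c(list(array = sa), stats::setNames(sw, paste0("wgs_h", names(sw))))
  res
}

#' Mean summed ROH length by length class
#'
#' Per-individual summed segment lengths in the short (0.3-1 Mb), medium
#' (1-8 Mb) and long (> 8 Mb) classes, averaged over the population. The
#' three class sums partition each individual's total ROH length at or above
#' the lowest break.
#'
#' @param callset An [roh_callset()].
#' @param breaks_mb Class boundaries in Mb (lower edges plus `Inf`).
#' @return A list: `per_individual` (data frame, one row per individual and
#'   class) and `population_mean` (named vector of mean summed Mb per
#'   class).
#' @export
length_class_sums <- function(callset, breaks_mb = c(0.3, 1, 8, Inf)) {
  stopifnot(length(breaks_mb) >= 2, !is.unsorted(breaks_mb))
  labs <- paste0("[", breaks_mb[-length(breaks_mb)], ",",
                 breaks_mb[-1L], ")")
  s <- callset$segments
  len_mb <- s$length_bp / 1e6
  ids <- callset$individuals
  per <- expand.grid(iid = ids, class = labs, stringsAsFactors = FALSE)
  per$sum_mb <- 0
  if (nrow(s)) {
    cls <- cut(len_mb, breaks = breaks_mb, labels = labs, right = FALSE)
    keep <- !is.na(cls)
    if (any(keep)) {
      agg <- stats::aggregate(len_mb[keep],
                              by = list(iid = s$iid[keep], class = as.character(cls[keep])),
                              FUN = sum)
      idx <- match(paste(agg$iid, agg$class), paste(per$iid, per$class))
      per$sum_mb[idx] <- agg$x
    }
  }
  pop <- c(tapply(per$sum_mb, per$class, mean))[labs]
  list(per_individual = per, population_mean = pop)
}
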