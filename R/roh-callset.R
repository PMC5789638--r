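#' Set of called runs of homozygosity
#'
#' A data frame of called ROH segments plus the calling context: the
#' parameters used, the technology channel, the population label and the
#' per-window heterozygote tolerance. Segment coordinates are 1-based and
#' inclusive at both ends; `length_bp = end - start + 1`.
#'
#' @param segments Data frame with columns `iid`, `chrom`, `start`, `end`,
#'   `nsnp` (sites in segment), `nhet` (observed het calls inside the
#'   segment). A `length_bp` column is added if absent.
#' @param params The [roh_params()] used to call the segments.
#' @param channel Channel tag ("array" or "wgs").
#' @param individuals All individuals scanned (so individuals with zero
#'   segments are retained by downstream summaries).
#' @param population Population label.
#'
#' @return An object of class `roh_callset`.
#' @export
roh_callset <- function(segments, params = roh_params(), channel = "array",
                        individuals = unique(segments$iid), population = NA_character_) {
  need <- c("iid", "chrom", "start", "end", "nsnp", "nhet")
  stopifnot(is.data.frame(segments), all(need %in% names(segments)))
  segments <- segments[need]
  segments$iid <- as.character(segments$iid)
  for (col in c("chrom", "start", "end", "nsnp", "nhet"))
    segments[[col]] <- as.integer(segments[[col]])
  segments$length_bp <- segments$end - segments$start + 1L
  if (nrow(segments)) {
    stopifnot(all(segments$start <= segments$end),
              all(segments$nhet <= segments$nsnp),
              all(segments$nsnp >= 1L))
    o <- order(segments$iid, segments$chrom, segments$start)
    segments <- segments[o, , drop = FALSE]
    rownames(segments) <- NULL
    by <- split(segments, list(segments$iid, segments$chrom), drop = TRUE)
    for (b in by) {
      if (nrow(b) > 1L && any(b$start[-1L] <= b$end[-nrow(b)]))
        stop("overlapping segments for individual ", b$iid[1L],
             " on chromosome ", b$chrom[1L])
    }
  }
  structure(list(segments = segments, params = params, channel = channel,
                 individuals = as.character(individuals),
                 population = population,
                 het_tolerance = params$window_het),
            class = "roh_callset")
}

#' @export
print.roh_callset <- function(x, ...) {
  cat("roh_callset [", x$channel, ", h=", x$het_tolerance, "]: ",
      nrow(x$segments), " segments across ", length(x$individuals),
      " individuals\n", sep = "")
  if (nrow(x$segments))
    cat("  total length: ",
        round(sum(as.numeric(x$segments$length_bp)) / 1e6, 2), " Mb; hets inside: ",
        sum(x$segments$nhet), "\n", sep = "")
  invisible(x)
}

#' Write a callset as a PLINK .hom-style table
#'
#' One row per segment, tab-separated, with columns IID, CHR, POS1, POS2,
#' KB (length in kb, 3 decimals), NSNP and NHET. An empty callset produces a
#' header-only file.
#'
#' @param callset An [roh_callset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hom_table <- function(callset, path) {
  s <- callset$segments
  df <- data.frame(IID = s$iid, CHR = s$chrom, POS1 = s$start, POS2 = s$end,
                   KB = sprintf("%.3f", (s$end - s$start + 1) / 1000),
                   NSNP = s$nsnp, NHET = s$nhet)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PLINK .hom-style table back into a callset
#'
#' Inverse of [write_hom_table()]; the calling context (params, channel,
#' individual universe) is not stored in the table and must be re-supplied.
#'
#' @param path Path to a table written by [write_hom_table()].
#' @inheritParams roh_callset
#' @return An [roh_callset()].
#' @export
read_hom_table <- function(path, params = roh_params(), channel = "array",
                           individuals = NULL, population = NA_character_) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(IID = "character"))
  segments <- data.frame(iid = df$IID, chrom = df$CHR, start = df$POS1,
                         end = df$POS2, nsnp = df$NSNP, nhet = df$NHET,
                         stringsAsFactors = FALSE)
  if (is.null(individuals)) individuals <- unique(segments$iid)
  roh_callset(segments, params = params, channel = channel,
              individuals = individuals, population = population)
}
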