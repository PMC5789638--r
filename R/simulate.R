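#' Configuration of the dual-channel genotype simulator
#'
#' Describes the generative model for paired array/WGS genotype observations
#' over diploid autosomes with planted autozygous tracts. Sites are placed
#' at jittered regular spacing; the array sites are a positional subset of
#' the WGS sites, so the two channels share a comparison universe by
#' construction. Background genotypes are drawn independently per site under
#' Hardy-Weinberg proportions from per-site allele frequencies (uniform on
#' `maf_range`); inside planted tracts both haplotypes carry the same allele
#' (autozygosity), so the truth layer is strictly homozygous there.
#'
#' Observation noise per channel: true heterozygotes flip to a random
#' homozygote at `*_false_hom_rate`; homozygous calls flip to spurious
#' heterozygotes at a total rate of `*_false_het_per_mb` per megabase.
#' False heterozygotes are a mixture of scattered singletons and short
#' clusters at adjacent sites (`het_error_clustered_fraction` of miscalls
#' belong to clusters, with sizes drawn from `cluster_size_probs`),
#' reflecting the locally clustered miscalls of low-coverage sequencing
#' around alignment-problem regions. Any call can drop out at
#' `missing_rate`.
#'
#' @param n_individuals Individuals per population (default 20).
#' @param n_chromosomes Number of autosomes simulated (default 4).
#' @param chrom_length_bp Length of each chromosome (default 50 Mb).
#' @param wgs_spacing_bp Mean spacing of WGS sites (default 1100, i.e. ~1
#'   site per 1.1 kb).
#' @param array_spacing_bp Mean spacing of array sites (default 7100).
#' @param maf_range Range of per-site allele frequencies (default
#'   `c(0.05, 0.5)`).
#' @param tract_rates Named numeric vector: expected planted-tract count per
#'   individual for each length class; names are `"lower-upper"` bounds in
#'   Mb. Lengths are uniform within a class.
#' @param wgs_false_het_per_mb,array_false_het_per_mb Spurious-heterozygote
#'   rate per Mb per individual (defaults 2.4 and 0; population presets of
#'   interest are ~0.3 for the cleanest and ~4.5 for the noisiest cohorts).
#' @param het_error_clustered_fraction Fraction of false-het calls belonging
#'   to multi-site clusters.
#' @param cluster_size_probs Named probabilities of cluster sizes (adjacent
#'   sites), default `c("2" = 0.6, "3" = 0.4)`.
#' @param wgs_false_hom_rate,array_false_hom_rate Probability that a true
#'   heterozygote is observed homozygous.
#' @param missing_rate Per-call dropout probability per channel.
#' @param population Population label.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 20L, n_chromosomes = 4L,
                       chrom_length_bp = 50e6,
                       wgs_spacing_bp = 1100, array_spacing_bp = 7100,
                       maf_range = c(0.05, 0.5),
                       tract_rates = c("0.3-1" = 3, "1-1.5" = 2, "1.5-5" = 2,
                                       "5-10" = 1, "10-16" = 0.5),
                       wgs_false_het_per_mb = 2.4,
                       array_false_het_per_mb = 0,
                       het_error_clustered_fraction = 0.5,
                       cluster_size_probs = c("2" = 0.6, "3" = 0.4),
                       wgs_false_hom_rate = 0.003,
                       array_false_hom_rate = 0.001,
                       missing_rate = 0.002,
                       population = "SIM") {
  cfg <- as.list(environment())
  stopifnot(cfg$n_individuals >= 1, cfg$n_chromosomes >= 1,
            cfg$n_chromosomes <= 22,
            cfg$wgs_spacing_bp >= 1, cfg$array_spacing_bp >= cfg$wgs_spacing_bp,
            cfg$wgs_false_het_per_mb >= 0, cfg$array_false_het_per_mb >= 0,
            cfg$het_error_clustered_fraction >= 0,
            cfg$het_error_clustered_fraction <= 1,
            abs(sum(cfg$cluster_size_probs) - 1) < 1e-9,
            cfg$missing_rate >= 0, cfg$missing_rate < 1)
  bounds <- .parse_tract_classes(cfg$tract_rates)
  if (any(bounds$upper_mb * 1e6 > cfg$chrom_length_bp))
    stop("tract class upper bound exceeds chromosome length")
  expected_mb <- sum(cfg$tract_rates * (bounds$lower_mb + bounds$upper_mb) / 2)
  genome_mb <- cfg$n_chromosomes * cfg$chrom_length_bp / 1e6
  if (expected_mb > 0.5 * genome_mb)
    stop("tract demands exceed chromosome capacity: expected ",
         round(expected_mb, 1), " Mb of tracts per individual vs ",
         genome_mb, " Mb of genome (limit 50%)")
  structure(cfg, class = "sim_config")
}

.parse_tract_classes <- function(rates) {
  parts <- strsplit(names(rates), "-", fixed = TRUE)
  data.frame(class = names(rates),
             lower_mb = vapply(parts, function(p) as.numeric(p[1]), numeric(1)),
             upper_mb = vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
             rate = unname(rates), stringsAsFactors = FALSE)
}

# jittered regular site positions on one chromosome
.sim_positions <- function(length_bp, spacing) {
  n_draw <- ceiling(length_bp / spacing * 2.2) + 10L
  steps <- spacing * stats::runif(n_draw, 0.5, 1.5)
  pos <- round(cumsum(steps))
  as.integer(pos[pos <= length_bp - spacing / 2])
}

# non-overlapping tract placement for one individual
.sim_tracts_one <- function(cfg, classes) {
  placed <- data.frame(chrom = integer(0), start = numeric(0), end = numeric(0),
                       class = character(0), stringsAsFactors = FALSE)
  for (ci in seq_len(nrow(classes))) {
    count <- stats::rpois(1L, classes$rate[ci])
    for (k in seq_len(count)) {
      len <- round(stats::runif(1, classes$lower_mb[ci], classes$upper_mb[ci]) * 1e6)
      for (try in 1:100) {
        chrom <- sample.int(cfg$n_chromosomes, 1L)
        start <- floor(stats::runif(1, 1, cfg$chrom_length_bp - len))
        end <- start + len - 1
        prev <- placed[placed$chrom == chrom, , drop = FALSE]
        if (!nrow(prev) || all(end < prev$start | start > prev$end)) {
          placed <- rbind(placed, data.frame(chrom = chrom, start = start,
                                             end = end, class = classes$class[ci],
                                             stringsAsFactors = FALSE))
          break
        }
      }
    }
  }
  placed
}

# apply channel observation noise to a truth genotype block (one chromosome);
# returns the observed block plus realized error records
.observe_channel <- function(truth, pos, false_het_per_mb, clustered_fraction,
                             cluster_size_probs, false_hom_rate, missing_rate) {
  obs <- truth
  n_sites <- nrow(obs)
  n_ind <- ncol(obs)
  err <- list()
  # false homozygotes on true-het sites
  if (false_hom_rate > 0) {
    hets <- which(obs == 1L)
    flip <- hets[stats::runif(length(hets)) < false_hom_rate]
    if (length(flip)) {
      obs[flip] <- 2L * (stats::runif(length(flip)) < 0.5)
      err[[length(err) + 1L]] <- data.frame(
        ind = (flip - 1L) %/% n_sites + 1L, pos = pos[(flip - 1L) %% n_sites + 1L],
        type = "false_hom", stringsAsFactors = FALSE)
    }
  }
  # false heterozygotes: scattered singletons + short adjacent-site clusters
  if (false_het_per_mb > 0) {
    span_mb <- (max(pos) - min(pos) + 1) / 1e6
    mean_spacing_mb <- span_mb / n_sites
    sizes <- as.integer(names(cluster_size_probs))
    mean_size <- sum(sizes * cluster_size_probs)
    singleton_per_mb <- false_het_per_mb * (1 - clustered_fraction)
    cluster_per_mb <- false_het_per_mb * clustered_fraction / mean_size
    # singletons: per-site Bernoulli on homozygous calls
    p_single <- singleton_per_mb * mean_spacing_mb
    hom <- !is.na(obs) & obs != 1L
    hit <- hom & matrix(stats::runif(n_sites * n_ind) < p_single, n_sites, n_ind)
    flip <- which(hit)
    # clusters: Poisson number per individual, consecutive sites
    cl_flip <- integer(0)
    for (j in seq_len(n_ind)) {
      ncl <- stats::rpois(1L, cluster_per_mb * span_mb)
      if (ncl == 0L) next
      starts <- sample.int(n_sites, ncl, replace = TRUE)
      sz <- sample(sizes, ncl, replace = TRUE, prob = cluster_size_probs)
      for (c in seq_len(ncl)) {
        s_idx <- starts[c]:min(n_sites, starts[c] + sz[c] - 1L)
        lin <- (j - 1L) * n_sites + s_idx
        cl_flip <- c(cl_flip, lin[hom[lin]])
      }
    }
    flip <- unique(c(flip, cl_flip))
    if (length(flip)) {
      obs[flip] <- 1L
      err[[length(err) + 1L]] <- data.frame(
        ind = (flip - 1L) %/% n_sites + 1L, pos = pos[(flip - 1L) %% n_sites + 1L],
        type = "false_het", stringsAsFactors = FALSE)
    }
  }
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(n_sites * n_ind) < missing_rate, n_sites, n_ind)
    obs[drop] <- NA_integer_
  }
  list(obs = obs, errors = if (length(err)) do.call(rbind, err) else
    data.frame(ind = integer(0), pos = integer(0), type = character(0),
               stringsAsFactors = FALSE))
}

#' Simulate paired array/WGS genotype observations
#'
#' Draws site maps, truth genotypes with planted autozygous tracts, and
#' channel-specific noisy observations under a [sim_config()]. All
#' randomness is driven by the single `seed`; identical seed and
#' configuration reproduce the result exactly.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list of class `roh_simulation`: `array` and `wgs`
#'   ([genotype_matrix()] observations), and `truth` (class `sim_truth`)
#'   holding the planted tracts, the realized per-channel error-site lists,
#'   the noise-free truth layer as a `genotype_matrix`, the config and the
#'   seed.
#' @export
simulate_genotypes <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  classes <- .parse_tract_classes(config$tract_rates)
  n_ind <- config$n_individuals
  ids <- sprintf("sim%03d", seq_len(n_ind))

  # site maps and allele frequencies per chromosome
  pos_list <- lapply(seq_len(config$n_chromosomes), function(chrom)
    .sim_positions(config$chrom_length_bp, config$wgs_spacing_bp))
  p_list <- lapply(pos_list, function(p)
    stats::runif(length(p), config$maf_range[1], config$maf_range[2]))
  array_keep <- lapply(pos_list, function(p)
    stats::runif(length(p)) < config$wgs_spacing_bp / config$array_spacing_bp)

  # planted autozygous tracts
  tracts <- do.call(rbind, lapply(seq_len(n_ind), function(j) {
    tr <- .sim_tracts_one(config, classes)
    if (nrow(tr)) cbind(iid = ids[j], tr, stringsAsFactors = FALSE) else NULL
  }))
  if (is.null(tracts))
    tracts <- data.frame(iid = character(0), chrom = integer(0),
                         start = numeric(0), end = numeric(0),
                         class = character(0), stringsAsFactors = FALSE)

  truth_blocks <- list(); wgs_blocks <- list(); arr_blocks <- list()
  err_all <- list()
  for (chrom in seq_len(config$n_chromosomes)) {
    pos <- pos_list[[chrom]]
    p <- p_list[[chrom]]
    ns <- length(pos)
    # background genotypes under HWE
    g <- matrix((stats::runif(ns * n_ind) < p) + (stats::runif(ns * n_ind) < p),
                nrow = ns, ncol = n_ind)
    storage.mode(g) <- "integer"
    # force autozygosity inside planted tracts: one allele drawn, doubled
    for (j in seq_len(n_ind)) {
      tr <- tracts[tracts$iid == ids[j] & tracts$chrom == chrom, , drop = FALSE]
      for (t in seq_len(nrow(tr))) {
        idx <- which(pos >= tr$start[t] & pos <= tr$end[t])
        if (length(idx))
          g[idx, j] <- 2L * (stats::runif(length(idx)) < p[idx])
      }
    }
    truth_blocks[[chrom]] <- g
    ow <- .observe_channel(g, pos, config$wgs_false_het_per_mb,
                           config$het_error_clustered_fraction,
                           config$cluster_size_probs,
                           config$wgs_false_hom_rate, config$missing_rate)
    wgs_blocks[[chrom]] <- ow$obs
    keep <- array_keep[[chrom]]
    oa <- .observe_channel(g[keep, , drop = FALSE], pos[keep],
                           config$array_false_het_per_mb,
                           config$het_error_clustered_fraction,
                           config$cluster_size_probs,
                           config$array_false_hom_rate, config$missing_rate)
    arr_blocks[[chrom]] <- oa$obs
    if (nrow(ow$errors))
      err_all[[length(err_all) + 1L]] <- data.frame(
        channel = "wgs", iid = ids[ow$errors$ind], chrom = chrom,
        pos = ow$errors$pos, type = ow$errors$type, stringsAsFactors = FALSE)
    if (nrow(oa$errors))
      err_all[[length(err_all) + 1L]] <- data.frame(
        channel = "array", iid = ids[oa$errors$ind], chrom = chrom,
        pos = oa$errors$pos, type = oa$errors$type, stringsAsFactors = FALSE)
  }

  mk_sites <- function(chroms, poss) {
    data.frame(chrom = chroms, pos = poss,
               id = sprintf("%d_%d", chroms, poss),
               ref = "A", alt = "G", stringsAsFactors = FALSE)
  }
  all_chrom <- rep(seq_len(config$n_chromosomes), lengths(pos_list))
  all_pos <- unlist(pos_list)
  wgs_sites <- mk_sites(all_chrom, all_pos)
  keep_vec <- unlist(array_keep)
  wgs_gm <- genotype_matrix(do.call(rbind, wgs_blocks), wgs_sites, ids, "wgs")
  arr_gm <- genotype_matrix(do.call(rbind, arr_blocks),
                            wgs_sites[keep_vec, , drop = FALSE], ids, "array")
  truth_gm <- genotype_matrix(do.call(rbind, truth_blocks), wgs_sites, ids, "wgs")
  errors <- if (length(err_all)) do.call(rbind, err_all) else
    data.frame(channel = character(0), iid = character(0), chrom = integer(0),
               pos = integer(0), type = character(0), stringsAsFactors = FALSE)
  tracts$length_bp <- tracts$end - tracts$start + 1
  truth <- structure(list(tracts = tracts, errors = errors,
                          truth_matrix = truth_gm, config = config,
                          seed = seed),
                     class = "sim_truth")
  structure(list(array = arr_gm, wgs = wgs_gm, truth = truth),
            class = "roh_simulation")
}

#' @export
print.roh_simulation <- function(x, ...) {
  cfg <- x$truth$config
  cat("roh_simulation: ", cfg$n_individuals, " individuals, ",
      cfg$n_chromosomes, " x ", cfg$chrom_length_bp / 1e6, " Mb\n", sep = "")
  cat("  wgs sites: ", nrow(x$wgs$sites), "; array sites: ",
      nrow(x$array$sites), "\n", sep = "")
  cat("  planted tracts: ", nrow(x$truth$tracts), "; recorded errors: ",
      nrow(x$truth$errors), "\n", sep = "")
  invisible(x)
}

#' Write a simulation to disk
#'
#' Two channel-tagged VCFs, a truth BED of planted tracts (0-based,
#' half-open, with individual and class columns) and a JSON echo of the
#' configuration and seed.
#'
#' @param sim A `roh_simulation` from [simulate_genotypes()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(array = file.path(dir, "array.vcf"),
             wgs = file.path(dir, "wgs.vcf"),
             truth = file.path(dir, "truth_tracts.bed"),
             config = file.path(dir, "sim_config.json"))
  write_vcf(sim$array, paths[["array"]])
  write_vcf(sim$wgs, paths[["wgs"]])
  tr <- sim$truth$tracts
  bed <- data.frame(chrom = tr$chrom, start = tr$start - 1, end = tr$end,
                    name = paste(tr$iid, tr$class, sep = "|"))
  utils::write.table(bed, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  cfg <- sim$truth$config
  class(cfg) <- NULL
  jsonlite::write_json(list(config = cfg, seed = sim$truth$seed),
                       paths[["config"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Sensitivity and precision of a callset against planted truth
#'
#' Base-pair-level recovery of the planted autozygous tracts by a callset:
#' per tract length class, the fraction of planted bp covered by same-
#' individual called segments (sensitivity), the fraction of tracts
#' recovered at >= `min_reciprocal` reciprocal overlap by a single call, and
#' the mean number of calls overlapping each detected tract
#' (fragmentation). Precision is the fraction of called bp lying inside any
#' planted tract, per called-segment length class. An `all` row aggregates
#' across classes.
#'
#' @param callset An [roh_callset()].
#' @param truth A `sim_truth` from [simulate_genotypes()].
#' @param breaks_mb Length-class boundaries in Mb.
#' @param min_reciprocal Reciprocal-overlap threshold for "recovered".
#' @return A data frame keyed by `class` with tract-side columns
#'   (`n_tracts`, `tract_bp`, `covered_bp`, `sensitivity`, `recovered`,
#'   `fragmentation`) and call-side columns (`n_segments`, `segment_bp`,
#'   `segment_in_tract_bp`, `precision`). Precision is `NA` where there are
#'   no segments; sensitivity is 0 where tracts exist but nothing was
#'   called.
#' @export
truth_overlap <- function(callset, truth, breaks_mb = c(0.3, 1, 8, Inf),
                          min_reciprocal = 0.5) {
  tr <- truth$tracts
  sg <- callset$segments
  labs <- paste0("[", breaks_mb[-length(breaks_mb)], ",", breaks_mb[-1L], ")")
  cls_of <- function(len_bp) as.character(cut(len_bp / 1e6, breaks = breaks_mb,
                                              labels = labs, right = FALSE))
  # tract side
  n_tr <- nrow(tr)
  covered <- numeric(n_tr); best_recip <- numeric(n_tr); n_calls <- integer(n_tr)
  for (t in seq_len(n_tr)) {
    s <- sg[sg$iid == tr$iid[t] & sg$chrom == tr$chrom[t], , drop = FALSE]
    if (!nrow(s)) next
    ov <- pmin(s$end, tr$end[t]) - pmax(s$start, tr$start[t]) + 1
    hit <- ov > 0
    covered[t] <- sum(ov[hit])
    n_calls[t] <- sum(hit)
    if (any(hit))
      best_recip[t] <- max(pmin(ov[hit] / tr$length_bp[t],
                                ov[hit] / s$length_bp[hit]))
  }
  tcls <- cls_of(tr$length_bp)
  # call side
  n_sg <- nrow(sg)
  inside <- numeric(n_sg)
  for (s in seq_len(n_sg)) {
    t <- tr[tr$iid == sg$iid[s] & tr$chrom == sg$chrom[s], , drop = FALSE]
    if (!nrow(t)) next
    ov <- pmin(t$end, sg$end[s]) - pmax(t$start, sg$start[s]) + 1
    inside[s] <- sum(ov[ov > 0])
  }
  scls <- cls_of(sg$length_bp)
  row_for <- function(lab) {
    ti <- if (lab == "all") rep(TRUE, n_tr) else !is.na(tcls) & tcls == lab
    si <- if (lab == "all") rep(TRUE, n_sg) else !is.na(scls) & scls == lab
    tract_bp <- sum(tr$length_bp[ti])
    seg_bp <- sum(as.numeric(sg$length_bp[si]))
    detected <- ti & n_calls > 0
    data.frame(class = lab, n_tracts = sum(ti), tract_bp = tract_bp,
               covered_bp = sum(covered[ti]),
               sensitivity = if (tract_bp > 0) sum(covered[ti]) / tract_bp else NA_real_,
               recovered = if (any(ti)) mean(best_recip[ti] >= min_reciprocal) else NA_real_,
               fragmentation = if (any(detected)) mean(n_calls[detected]) else NA_real_,
               n_segments = sum(si), segment_bp = seg_bp,
               segment_in_tract_bp = sum(inside[si]),
               precision = if (seg_bp > 0) sum(inside[si]) / seg_bp else NA_real_,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(c(labs, "all"), row_for))
}
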