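test_that("identical seed and config reproduce byte-identical outputs", {
  cfg <- small_sim_config()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(simulate_genotypes(cfg, seed = 31), d1)
  write_simulation(simulate_genotypes(cfg, seed = 31), d2)
  for (f in c("array.vcf", "wgs.vcf", "truth_tracts.bed", "sim_config.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # and a different seed changes the data
  d3 <- withr::local_tempdir()
  write_simulation(simulate_genotypes(cfg, seed = 32), d3)
  expect_false(identical(readLines(file.path(d1, "wgs.vcf")),
                         readLines(file.path(d3, "wgs.vcf"))))
})

test_that("written VCFs round-trip through the reader", {
  sim <- simulate_genotypes(small_sim_config(), seed = 77)
  d <- withr::local_tempdir()
  write_simulation(sim, d)
  back <- read_vcf(file.path(d, "wgs.vcf"), "wgs", verbose = FALSE)
  expect_identical(back$geno, sim$wgs$geno)
  expect_identical(back$sites$pos, sim$wgs$sites$pos)
})

test_that("the truth layer is strictly homozygous inside planted tracts and every observed het there is a recorded error", {
  sim <- simulate_genotypes(small_sim_config(), seed = 41)
  tr <- sim$truth$tracts
  err <- sim$truth$errors
  truth <- sim$truth$truth_matrix
  for (r in seq_len(nrow(tr))) {
    j <- match(tr$iid[r], truth$individuals)
    idx <- which(truth$sites$chrom == tr$chrom[r] &
                 truth$sites$pos >= tr$start[r] & truth$sites$pos <= tr$end[r])
    expect_equal(sum(truth$geno[idx, j] == 1L, na.rm = TRUE), 0L)
    # observed hets inside the tract are exactly the recorded false hets
    obs_het <- sim$wgs$sites$pos[idx][which(sim$wgs$geno[idx, j] == 1L)]
    rec <- err$pos[err$channel == "wgs" & err$iid == tr$iid[r] &
                   err$chrom == tr$chrom[r] & err$type == "false_het"]
    expect_true(all(obs_het %in% rec))
  }
  # tracts never overlap within an individual-chromosome
  by <- split(tr, list(tr$iid, tr$chrom), drop = TRUE)
  for (b in by) {
    b <- b[order(b$start), ]
    if (nrow(b) > 1) expect_true(all(b$start[-1] > b$end[-nrow(b)]))
  }
})

test_that("site densities approach the configured spacings", {
  cfg <- small_sim_config()
  sim <- simulate_genotypes(cfg, seed = 13)
  span <- genome_span_bp(sim$wgs)
  expect_equal(span / nrow(sim$wgs$sites), cfg$wgs_spacing_bp, tolerance = 0.05)
  expect_equal(genome_span_bp(sim$array) / nrow(sim$array$sites),
               cfg$array_spacing_bp, tolerance = 0.1)
  # array sites are a positional subset of WGS sites
  expect_true(all(sim$array$sites$id %in% sim$wgs$sites$id))
})

test_that("the realized false-het rate inside tracts matches the configured rate", {
  cfg <- sim_config()   # default study conditions, 2.4/Mb
  sim <- simulate_genotypes(cfg, seed = 99)
  tr <- sim$truth$tracts
  err <- sim$truth$errors
  n_in <- 0L
  for (r in seq_len(nrow(tr))) {
    rec <- err[err$channel == "wgs" & err$iid == tr$iid[r] &
               err$chrom == tr$chrom[r] & err$type == "false_het", ]
    n_in <- n_in + sum(rec$pos >= tr$start[r] & rec$pos <= tr$end[r])
  }
  tract_mb <- sum(tr$length_bp) / 1e6
  expected <- cfg$wgs_false_het_per_mb * tract_mb
  # clustering overdisperses the count, but 3 sqrt(lambda) on ~1200 events
  # is still a generous +-9% band
  expect_lt(abs(n_in - expected), 3 * sqrt(expected) * 1.5)
})

test_that("a single planted tract with a clean channel is recovered almost exactly", {
  cfg <- sim_config(n_individuals = 2L, n_chromosomes = 1L,
                    chrom_length_bp = 12e6,
                    tract_rates = c("4.9-5.1" = 1e-9),
                    wgs_false_het_per_mb = 0, wgs_false_hom_rate = 0,
                    array_false_hom_rate = 0, missing_rate = 0)
  sim <- simulate_genotypes(cfg, seed = 5)
  # plant one 5-Mb tract manually for determinism of the scenario
  sim$truth$tracts <- data.frame(iid = "sim001", chrom = 1L,
                                 start = 3e6, end = 8e6 - 1,
                                 class = "4.9-5.1", length_bp = 5e6,
                                 stringsAsFactors = FALSE)
  j <- 1L
  idx <- which(sim$wgs$sites$pos >= 3e6 & sim$wgs$sites$pos < 8e6)
  p <- 0.3
  set.seed(6)
  auto <- 2L * (runif(length(idx)) < p)
  sim$wgs$geno[idx, j] <- auto
  keep <- match(sim$array$sites$id, sim$wgs$sites$id)
  sim$array$geno[, j] <- sim$wgs$geno[keep, j]
  for (channel in c("array", "wgs")) {
    cs <- call_roh(sim[[channel]], roh_params(window_het = 1L))
    ov <- truth_overlap(cs, sim$truth)
    all_row <- ov[ov$class == "all", ]
    expect_equal(all_row$recovered, 1)
    # reciprocal overlap at least 95%
    s <- cs$segments[cs$segments$iid == "sim001", ]
    s <- s[which.max(s$length_bp), ]
    inter <- min(s$end, 8e6 - 1) - max(s$start, 3e6) + 1
    expect_gte(inter / 5e6, 0.95)
    expect_gte(inter / s$length_bp, 0.95)
  }
})

test_that("recovery metrics behave on perfect and empty callsets", {
  sim <- simulate_genotypes(small_sim_config(), seed = 21)
  tr <- sim$truth$tracts
  perfect <- roh_callset(
    data.frame(iid = tr$iid, chrom = tr$chrom, start = tr$start, end = tr$end,
               nsnp = 100L, nhet = 0L),
    roh_params(), individuals = sim$wgs$individuals)
  ov <- truth_overlap(perfect, sim$truth)
  all_row <- ov[ov$class == "all", ]
  expect_equal(all_row$sensitivity, 1)
  expect_equal(all_row$precision, 1)
  expect_equal(all_row$recovered, 1)
  empty <- roh_callset(perfect$segments[0, ], roh_params(),
                       individuals = sim$wgs$individuals)
  ov0 <- truth_overlap(empty, sim$truth)
  all0 <- ov0[ov0$class == "all", ]
  expect_equal(all0$sensitivity, 0)
  expect_true(is.na(all0$precision))
})

test_that("impossible tract demands fail with a capacity report", {
  expect_error(sim_config(n_chromosomes = 1L, chrom_length_bp = 10e6,
                          tract_rates = c("1-3" = 5)),
               "capacity")
  expect_error(sim_config(n_chromosomes = 1L, chrom_length_bp = 10e6,
                          tract_rates = c("11-12" = 0.1)),
               "exceeds chromosome length")
})
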