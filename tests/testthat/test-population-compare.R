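test_that("per-individual summaries apply the length threshold", {
  segs <- data.frame(iid = "a", chrom = 1L,
                     start = c(1e6, 5e6, 9e6),
                     end = c(1e6 + 1.2e6 - 1, 5e6 + 2e6 - 1, 9e6 + 0.8e6 - 1),
                     nsnp = c(100L, 100L, 100L), nhet = 0L)
  cs <- roh_callset(segs, roh_params(), individuals = c("a", "b"))
  s <- summarize_roh_individuals(cs, min_mb = 1)
  expect_equal(s$nroh, c(2L, 0L))
  expect_equal(s$mean_size_mb[1], 1.6)
  expect_equal(s$sroh_mb[1], 3.2)
  expect_true(is.na(s$mean_size_mb[2]))
  expect_equal(s$sroh_mb[2], 0)
})

test_that("summaries match a brute-force filter-and-aggregate oracle", {
  set.seed(3)
  for (i in 1:15) {
    ids <- paste0("i", 1:6)
    n <- sample(0:40, 1)
    if (n == 0) {
      segs <- data.frame(iid = character(0), chrom = integer(0),
                         start = integer(0), end = integer(0),
                         nsnp = integer(0), nhet = integer(0))
    } else {
      len <- round(runif(n, 2e5, 9e6))
      start <- round(seq(1e6, by = 2e7, length.out = n))
      segs <- data.frame(iid = sample(ids, n, replace = TRUE),
                         chrom = sample(1:2, n, replace = TRUE),
                         start = start, end = start + len - 1,
                         nsnp = 100L, nhet = 0L)
    }
    cs <- roh_callset(segs, roh_params(), individuals = ids)
    s <- summarize_roh_individuals(cs, min_mb = 1)
    for (id in ids) {
      lens <- (segs$end - segs$start + 1)[segs$iid == id] / 1e6
      lens <- lens[lens > 1]
      row <- s[s$iid == id, ]
      expect_equal(row$nroh, length(lens))
      expect_equal(row$sroh_mb, sum(lens))
      if (length(lens)) expect_equal(row$mean_size_mb, mean(lens))
      else expect_true(is.na(row$mean_size_mb))
      if (row$nroh > 0)
        expect_equal(row$sroh_mb, row$nroh * row$mean_size_mb, tolerance = 1e-9)
    }
  }
})

test_that("rank-sum p-values match exact enumeration for small samples", {
  # separated samples: U = 0, p = 2/20
  expect_equal(mww_test(c(1, 2, 3), c(10, 20, 30)), 0.1)
  expect_equal(oracle_mww(c(1, 2, 3), c(10, 20, 30)), 0.1)
  # identical tie-free shifts of each other enumerate symmetrically
  set.seed(9)
  for (i in 1:25) {
    a <- round(rnorm(sample(3:6, 1)), 6)
    b <- round(rnorm(sample(3:6, 1), mean = runif(1, -1, 1)), 6)
    expect_equal(mww_test(a, b), oracle_mww(a, b), tolerance = 1e-12)
    # symmetry under swapping samples
    expect_equal(mww_test(a, b), mww_test(b, a), tolerance = 1e-12)
  }
  # the large-sample approximation tracks enumeration for n = 10 vs 10
  a <- rnorm(10); b <- rnorm(10, 0.5)
  p_exact <- oracle_mww(a, b)
  p_approx <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                                  correct = TRUE))$p.value
  expect_lt(abs(p_exact - p_approx), 0.01)
  expect_error(mww_test(numeric(0), 1), "non-empty")
})

test_that("Pearson correlation matches direct summation and handles degeneracy", {
  expect_equal(pearson_r(1:10, 1:10)$r, 1)
  expect_equal(pearson_r(1:10, -(1:10))$r, -1)
  set.seed(12)
  for (i in 1:10) {
    a <- rnorm(15); b <- rnorm(15)
    pr <- pearson_r(a, b)
    # textbook formula by direct summation
    r <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(pr$r, r, tolerance = 1e-12)
    tstat <- r * sqrt(13 / (1 - r^2))
    expect_equal(pr$p, 2 * stats::pt(-abs(tstat), df = 13), tolerance = 1e-12)
  }
  expect_true(is.na(pearson_r(rep(1, 5), rnorm(5))$r))
  expect_true(is.na(pearson_r(1:2, 2:1)$r))
})

test_that("length-class sums partition the total ROH length", {
  segs <- data.frame(iid = "a", chrom = 1L,
                     start = c(1e6, 5e6, 2e7),
                     end = c(1e6 + 5e5 - 1, 5e6 + 3e6 - 1, 2e7 + 9e6 - 1),
                     nsnp = 100L, nhet = 0L)
  cs <- roh_callset(segs, roh_params(), individuals = "a")
  lc <- length_class_sums(cs)
  expect_equal(unname(lc$population_mean), c(0.5, 3, 9))
  expect_equal(sum(lc$population_mean), sum(segs$end - segs$start + 1) / 1e6)
  # empty callset -> all zeros
  cs0 <- roh_callset(segs[0, ], roh_params(), individuals = c("a", "b"))
  expect_true(all(length_class_sums(cs0)$population_mean == 0))
  # partition identity on random callsets
  set.seed(8)
  for (i in 1:10) {
    n <- sample(1:30, 1)
    len <- round(runif(n, 3.1e5, 2e7))
    start <- round(seq(1e6, by = 3e7, length.out = n))
    segs <- data.frame(iid = sample(c("a", "b"), n, replace = TRUE), chrom = 1L,
                       start = start, end = start + len - 1, nsnp = 10L, nhet = 0L)
    cs <- roh_callset(segs, roh_params(), individuals = c("a", "b"))
    lc <- length_class_sums(cs)
    per <- lc$per_individual
    for (id in c("a", "b"))
      expect_equal(sum(per$sum_mb[per$iid == id]),
                   sum((segs$end - segs$start + 1)[segs$iid == id]) / 1e6,
                   tolerance = 1e-9)
  }
})

test_that("channel comparison rejects asymmetric individual sets", {
  segs <- data.frame(iid = "a", chrom = 1L, start = 1e6, end = 3e6,
                     nsnp = 100L, nhet = 0L)
  csa <- roh_callset(segs, roh_params(), individuals = c("a", "b"))
  csw <- roh_callset(segs, roh_params(window_het = 2L), channel = "wgs",
                     individuals = c("a", "c"))
  expect_error(compare_channels(csa, list(csw)), "differ.*b.*c|differ.*c.*b")
})

test_that("channels sharing truth and error-free observation are statistically equivalent", {
  cfg <- small_sim_config(wgs_false_het_per_mb = 0, wgs_false_hom_rate = 0,
                          array_false_hom_rate = 0, missing_rate = 0)
  sim <- simulate_genotypes(cfg, seed = 2024)
  csa <- call_roh(sim$array, roh_params(window_het = 1L))
  csw <- lapply(1:3, function(h) call_roh(sim$wgs, roh_params(window_het = h)))
  names(csw) <- 1:3
  cmp <- compare_channels(csa, csw)
  expect_true(all(cmp$mww_p[cmp$statistic == "nroh"] > 0.05))
})
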