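# fixtures built in code: genotype matrices, random caller instances, small sims

make_gm <- function(calls, pos = NULL, chrom = 1L, channel = "array",
                    ids = NULL) {
  # calls: integer vector (one individual) or matrix (sites x individuals)
  if (is.null(dim(calls))) calls <- matrix(calls, ncol = 1L)
  n <- nrow(calls)
  if (is.null(pos)) pos <- seq(10000L, by = 10000L, length.out = n)
  if (is.null(ids)) ids <- paste0("ind", seq_len(ncol(calls)))
  sites <- data.frame(chrom = chrom, pos = as.integer(pos),
                      id = paste0("s", chrom, "_", seq_len(n)),
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(calls, sites, ids, channel)
}

# random single-individual caller instance over one chromosome
random_roh_instance <- function(n_max = 500, max_spacing = 60000) {
  n <- sample(60:n_max, 1L)
  # mostly sub-gap spacings with occasional jumps to exercise the gap rule
  gaps <- ifelse(runif(n) < 0.01, round(runif(n, 1.1e6, 2e6)),
                 round(runif(n, 500, max_spacing)))
  pos <- cumsum(gaps)
  p_het <- runif(1, 0.01, 0.35)
  calls <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE,
                  prob = c((1 - p_het) * 0.6, p_het, (1 - p_het) * 0.38, 0.02))
  params <- roh_params(
    window_het = sample(0:3, 1L),
    window_snp = sample(c(10L, 20L, 50L), 1L),
    window_missing = sample(0:5, 1L),
    window_threshold = 0.05,
    min_snp = sample(c(10L, 25L, 50L), 1L),
    min_kb = sample(c(50, 100, 300), 1L),
    density_kb_per_snp = 50,
    max_gap_kb = 1000)
  list(calls = calls, pos = pos, params = params)
}

# small, fast simulation shared by several tests
small_sim_config <- function(...) {
  sim_config(n_individuals = 8L, n_chromosomes = 2L, chrom_length_bp = 12e6,
             tract_rates = c("0.5-1" = 1, "1-3" = 1.5, "3-5" = 0.5), ...)
}

# default-scale simulation computed once per test run (lazy, memoised)
.default_run_cache <- new.env(parent = emptyenv())
default_scale_run <- function() {
  if (is.null(.default_run_cache$run)) {
    .default_run_cache$run <- run_dual_platform_analysis(
      config = sim_config(), h_values = 1:3, seed = 20260925L)
  }
  .default_run_cache$run
}
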