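# independent brute-force oracles, deliberately naive and separate from the
# package implementation paths

# exact HWE p-value by direct log-multinomial enumeration over all het counts
# compatible with the observed allele counts
oracle_hwe <- function(n_het, n_hom_ref, n_hom_alt) {
  n <- n_het + n_hom_ref + n_hom_alt
  if (n == 0L) return(NA_real_)
  nA <- 2L * n_hom_ref + n_het
  m <- min(nA, 2L * n - nA)
  if (m == 0L) return(1)
  ks <- seq.int(m %% 2L, m, by = 2L)
  logp <- vapply(ks, function(k) {
    hom_minor <- (m - k) / 2
    hom_major <- (2 * n - m - k) / 2
    lfactorial(n) - lfactorial(hom_minor) - lfactorial(k) -
      lfactorial(hom_major) + k * log(2)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_het, ks)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# vectorised over all valid het counts for one (n, minor-allele-count) pair;
# returns data.frame(nhet, p)
oracle_hwe_all <- function(n, m) {
  ks <- seq.int(m %% 2L, m, by = 2L)
  logp <- lfactorial(n) - lfactorial((m - ks) / 2) - lfactorial(ks) -
    lfactorial((2 * n - m - ks) / 2) + ks * log(2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p <- vapply(seq_along(ks), function(i)
    min(1, sum(pr[pr <= pr[i] * (1 + 1e-7)])), numeric(1))
  data.frame(nhet = ks, p = p)
}

# two-sided MWW p-value by full enumeration of all group assignments
oracle_mww <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(na + nb, na)
  us <- apply(combs, 2L, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# naive ROH caller: materialises every window and every per-site proportion
oracle_roh <- function(calls, pos, params) {
  n <- length(calls)
  W <- params$window_snp
  flags <- logical(0)
  if (n >= W) {
    flags <- vapply(seq_len(n - W + 1L), function(i) {
      w <- calls[i:(i + W - 1L)]
      sum(!is.na(w) & w == 1L) <= params$window_het &&
        sum(is.na(w)) <= params$window_missing
    }, logical(1))
  }
  state <- vapply(seq_len(n), function(s) {
    cover <- which(vapply(seq_along(flags), function(i)
      s >= i && s <= i + W - 1L, logical(1)))
    if (!length(cover)) return(FALSE)
    sum(flags[cover]) / length(cover) >= params$window_threshold
  }, logical(1))
  # runs of in-state sites
  segs <- list()
  s0 <- NULL
  for (i in seq_len(n + 1L)) {
    if (i <= n && state[i]) {
      if (is.null(s0)) s0 <- i
    } else if (!is.null(s0)) {
      segs[[length(segs) + 1L]] <- c(s0, i - 1L)
      s0 <- NULL
    }
  }
  out <- list()
  for (seg in segs) {
    # gap splitting
    idx <- seg[1]:seg[2]
    pieces <- list()
    p0 <- idx[1]
    for (k in seq_along(idx)[-1]) {
      if (pos[idx[k]] - pos[idx[k - 1]] > params$max_gap_kb * 1000) {
        pieces[[length(pieces) + 1L]] <- c(p0, idx[k - 1])
        p0 <- idx[k]
      }
    }
    pieces[[length(pieces) + 1L]] <- c(p0, idx[length(idx)])
    for (pc in pieces) {
      i0 <- pc[1]; i1 <- pc[2]
      while (i0 <= i1 && (is.na(calls[i0]) || calls[i0] == 1L)) i0 <- i0 + 1L
      while (i1 >= i0 && (is.na(calls[i1]) || calls[i1] == 1L)) i1 <- i1 - 1L
      if (i0 > i1) next
      nsnp <- i1 - i0 + 1L
      len <- pos[i1] - pos[i0] + 1L
      if (nsnp < params$min_snp) next
      if (len < params$min_kb * 1000) next
      if (nsnp / (len / 1000) < 1 / params$density_kb_per_snp) next
      out[[length(out) + 1L]] <- data.frame(
        start = pos[i0], end = pos[i1], nsnp = nsnp,
        nhet = sum(!is.na(calls[i0:i1]) & calls[i0:i1] == 1L))
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      nsnp = integer(0), nhet = integer(0)))
  do.call(rbind, out)
}

# segment table of one individual from the package caller, comparable shape
caller_segments_one <- function(calls, pos, params) {
  gm <- make_gm(calls, pos = pos)
  s <- call_roh(gm, params)$segments
  data.frame(start = s$start, end = s$end, nsnp = s$nsnp, nhet = s$nhet)
}
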