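# Brute-force oracles and small fixture builders, independent of the package
# implementations they check.

# Enumerate every step-1 window of `window` flags; flag windows with strictly
# more than min_frac TRUE; merge overlapping/abutting flagged windows by
# explicit per-SNP coverage marking. Returns tibble(from, to) of merged spans.
brute_force_windows <- function(flags, window, min_frac) {
  n <- length(flags)
  covered <- rep(FALSE, n)
  if (n >= window) {
    for (s in seq_len(n - window + 1)) {
      idx <- s:(s + window - 1)
      if (mean(flags[idx]) > min_frac) covered[idx] <- TRUE
    }
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(
    from = starts[r$values],
    to = ends[r$values]
  )
}

# Random informative-SNP table (read counts) on one chromosome with a mix of
# balanced and imbalanced stretches; used for oracle-equivalence checks.
random_imbalance_snps <- function(n, seed) {
  set.seed(seed)
  n_reg <- sample(0:2, 1)
  simulate_informative_snps(
    n_snps = n, n_regions = n_reg,
    region_size = sample(40:90, 1), depth = 40,
    tumor_minor_frac = runif(1, 0.2, 0.6), seed = seed
  )
}

# Random informative-probe BAF table on one chromosome with implanted
# low-MAF stretches.
random_loh_probes <- function(n, seed) {
  set.seed(seed)
  baf <- rbinom(n, 50, 0.5) / 50
  n_reg <- sample(0:2, 1)
  if (n_reg > 0) {
    for (k in seq_len(n_reg)) {
      len <- sample(80:180, 1)
      if (len >= n) len <- n - 1
      st <- sample.int(n - len, 1)
      side <- sample(c(0.15, 0.85), 1)
      baf[st:(st + len - 1)] <- rbinom(len, 50, side) / 50
    }
  }
  tibble::tibble(chrom = "1", pos = 3000L * seq_len(n), baf = baf)
}

# Piecewise-constant series with k true breakpoints and Gaussian noise.
# Breakpoints are constructed directly with all segments >= min_seg probes
# (no rejection sampling, so generation always terminates).
stepped_series <- function(n, k, gap = 1, sd = 0.2, seed = 1, min_seg = 60) {
  set.seed(seed)
  stopifnot(n >= (k + 1) * min_seg)
  bp <- if (k > 0) {
    slack <- n - (k + 1) * min_seg
    extras <- sort(sample.int(slack + 1, k, replace = TRUE) - 1L)
    min_seg * seq_len(k) + extras
  } else {
    integer(0)
  }
  levels <- cumsum(c(0, sample(c(-gap, gap), k, replace = TRUE)))
  from <- c(1, bp + 1)
  to <- c(bp, n)
  mu <- numeric(n)
  for (i in seq_along(from)) mu[from[i]:to[i]] <- levels[i]
  list(x = mu + rnorm(n, 0, sd), breakpoints = bp, mu = mu)
}

# Tiny cohort config used across tests (fast; noiseless variants derive from
# it by overriding purity/noise).
tiny_config <- function(...) {
  sim_config(
    n_samples = 4, n_chroms = 2, probes_per_chrom = 600,
    recurrent_lesions = tibble::tibble(
      chrom = "2", start_probe = 201L, n_probes = 80L,
      direction = "del", frequency = 0.5
    ),
    instability_mixture = tibble::tibble(
      weight = c(0.5, 0.5), target = c(0.3, 0.6)
    ),
    ...
  )
}

# Majority coarse state called over each implanted truth segment.
segment_recovery <- function(cohort, stated_segments) {
  ts <- cohort$truth$segments
  ok <- logical(nrow(ts))
  for (i in seq_len(nrow(ts))) {
    seg <- stated_segments[
      stated_segments$sample_id == ts$sample_id[i] &
        stated_segments$chrom == ts$chrom[i] &
        stated_segments$end > ts$start[i] &
        stated_segments$start < ts$end[i],
    ]
    if (nrow(seg) == 0) {
      ok[i] <- FALSE
      next
    }
    ov <- pmin(seg$end, ts$end[i]) - pmax(seg$start, ts$start[i])
    called <- tapply(ov, coarse_state(seg$state), sum)
    ok[i] <- names(which.max(called)) == coarse_state(ts$state[i])
  }
  ok
}
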