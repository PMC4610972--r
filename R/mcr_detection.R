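#' Build the samples-by-markers amplitude matrix
#'
#' Broadcasts segment mean LRR back onto every member probe so that focal
#' and broad events compete on a common per-marker scale. Markers are probes,
#' in genomic order.
#'
#' @param segments Segment tibble with `sample_id`, `chrom`, `start`, `end`,
#'   `mean_lrr` (0-based half-open intervals).
#' @param probes Probe tibble with `chrom`, `pos` (one sample's grid or a
#'   cohort tibble; the unique `(chrom, pos)` grid is used).
#' @param exclude Optional tibble of intervals (`chrom`, `start`, `end`) to
#'   mask, e.g. a hyper-polymorphic region; overlapping markers are dropped.
#' @return A list with `amplitude` (numeric matrix samples x markers) and
#'   `markers` (tibble: chrom, pos in genomic order).
#' @export
build_amplitude_matrix <- function(segments, probes, exclude = NULL) {
  markers <- probes |>
    distinct(.data$chrom, .data$pos) |>
    sort_genomic()
  if (!is.null(exclude) && nrow(exclude) > 0) {
    drop <- rep(FALSE, nrow(markers))
    for (i in seq_len(nrow(exclude))) {
      drop <- drop | (markers$chrom == exclude$chrom[i] &
        markers$pos > exclude$start[i] & markers$pos <= exclude$end[i])
    }
    markers <- markers[!drop, , drop = FALSE]
  }
  samples <- unique(segments$sample_id)
  A <- matrix(0, nrow = length(samples), ncol = nrow(markers),
    dimnames = list(samples, NULL)
  )
  key <- paste(markers$chrom, markers$pos)
  idx_by_chrom <- split(seq_len(nrow(markers)), markers$chrom)
  for (s in seq_along(samples)) {
    seg <- segments[segments$sample_id == samples[s], ]
    for (i in seq_len(nrow(seg))) {
      idx <- idx_by_chrom[[seg$chrom[i]]]
      if (is.null(idx)) next
      hit <- idx[markers$pos[idx] > seg$start[i] & markers$pos[idx] <= seg$end[i]]
      A[s, hit] <- seg$mean_lrr[i]
    }
  }
  if (any(!is.finite(A))) abort("non-finite amplitudes in matrix")
  list(amplitude = A, markers = markers)
}

#' Per-marker G-scores
#'
#' The recurrence score of marker `i` in a given direction is frequency
#' times average exceeding amplitude:
#' amplification `G(i) = (1/N) * sum_s a_si * 1[a_si >= theta]`,
#' deletion `G(i) = (1/N) * sum_s (-a_si) * 1[a_si <= -theta]`.
#'
#' @param amplitude Samples-by-markers numeric matrix.
#' @param direction `"amp"` or `"del"`.
#' @param theta Amplitude threshold (default 0.15; the deletion threshold is
#'   `-theta`).
#' @return Numeric vector of per-marker G-scores (all `>= 0`).
#' @export
g_scores <- function(amplitude, direction = c("amp", "del"), theta = 0.15) {
  direction <- match.arg(direction)
  if (length(amplitude) == 0 || nrow(amplitude) == 0) {
    abort("empty amplitude matrix")
  }
  if (theta <= 0) abort("theta must be positive")
  if (direction == "amp") {
    colSums(amplitude * (amplitude >= theta)) / nrow(amplitude)
  } else {
    colSums(-amplitude * (amplitude <= -theta)) / nrow(amplitude)
  }
}

#' Permutation null p-values for per-marker G-scores
#'
#' Breaks locus alignment while preserving each sample's alteration burden:
#' within every sample independently, marker amplitudes are permuted; the
#' G-scores of all markers from all permutations form a pooled null. The
#' p-value of marker `i` is
#' `p(i) = (1 + N_ge(i)/M) / (1 + n_perm)` where `N_ge(i)` is the number of
#' pooled null scores at or above `G(i)` and `M` the number of markers —
#' i.e. one plus the average per-permutation exceedance count over one plus
#' the number of permutations, so the smallest achievable p-value is
#' `1/(1 + n_perm)`.
#'
#' @inheritParams g_scores
#' @param n_perm Number of permutations (at least 100; default 10000).
#' @param seed Integer seed (the permutation stream is seeded locally and
#'   does not disturb the caller's RNG).
#' @return Numeric vector of per-marker p-values.
#' @export
permutation_null <- function(amplitude, direction = c("amp", "del"),
                             theta = 0.15, n_perm = 10000, seed = 1) {
  direction <- match.arg(direction)
  perm_null_both(amplitude, theta, n_perm, seed)[[direction]]
}

# Shared permutation engine: one permutation stream scores both directions.
# The per-permutation shuffling and scoring loop is compiled (see
# src/perm_null.cpp); it draws from R's RNG, so results are reproducible
# given the seed and do not disturb the caller's RNG stream.
perm_null_both <- function(amplitude, theta, n_perm, seed) {
  if (n_perm < 100) abort("n_perm must be at least 100")
  if (length(amplitude) == 0 || nrow(amplitude) == 0) {
    abort("empty amplitude matrix")
  }
  M <- ncol(amplitude)
  G <- list(
    amp = g_scores(amplitude, "amp", theta),
    del = g_scores(amplitude, "del", theta)
  )
  ord <- lapply(G, order)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  counts <- perm_null_counts(
    amplitude, theta, as.integer(n_perm),
    G$amp[ord$amp], G$del[ord$del]
  )
  out <- list()
  for (dir in c("amp", "del")) {
    p_sorted <- (1 + counts[[dir]] / M) / (1 + n_perm)
    p <- numeric(M)
    p[ord[[dir]]] <- p_sorted
    out[[dir]] <- pmin(p, 1)
  }
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values in `[0, 1]`, same order as `p`.
#' @export
bh_qvalues <- function(p) {
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Extract minimal common regions from marker-level scores
#'
#' Maximal runs of contiguous markers (within a chromosome) with `q < alpha`
#' form candidate regions; each region's peak is the sub-run attaining the
#' maximal G-score. Carriers are the samples whose amplitude exceeds the
#' threshold anywhere in the peak. The reported peak is widened by a
#' deterministic leave-one-out robustness approximation: the G-score over the
#' region is recomputed with each carrier left out in turn and the peak is
#' the smallest interval containing the core peak and the `confidence`
#' fraction of leave-one-out peak locations.
#'
#' @param G Per-marker G-scores (one direction).
#' @param q Per-marker q-values aligned with `G`.
#' @param amplitude Samples-by-markers matrix used for the scores.
#' @param markers Marker tibble (`chrom`, `pos`) aligned with columns.
#' @param direction `"amp"` or `"del"`.
#' @param alpha Significance cutoff on q (default 0.05, strict).
#' @param confidence Fraction of leave-one-out peaks the widened peak must
#'   contain (default 0.99).
#' @param theta Amplitude threshold used for carrier status (default 0.15).
#' @return Tibble of MCRs: `chrom`, `start`, `end`, `direction`, `g_score`,
#'   `q_value`, `n_carriers`, `peak_start`, `peak_end`. Empty when no marker
#'   is significant.
#' @export
extract_mcrs <- function(G, q, amplitude, markers,
                         direction = c("amp", "del"),
                         alpha = 0.05, confidence = 0.99, theta = 0.15) {
  direction <- match.arg(direction)
  M <- length(G)
  stopifnot(length(q) == M, ncol(amplitude) == M, nrow(markers) == M)
  sig <- q < alpha
  if (!any(sig)) {
    return(tibble(
      chrom = character(0), start = integer(0), end = integer(0),
      direction = character(0), g_score = numeric(0), q_value = numeric(0),
      n_carriers = integer(0), peak_start = integer(0), peak_end = integer(0)
    ))
  }
  exceed <- if (direction == "amp") amplitude >= theta else amplitude <= -theta
  runs <- tibble(idx = which(sig), chrom = markers$chrom[sig]) |>
    mutate(run = cumsum(c(
      TRUE,
      diff(.data$idx) != 1 | .data$chrom[-1] != .data$chrom[-n()]
    )))
  out <- list()
  for (r in split(runs$idx, runs$run)) {
    Gr <- G[r]
    peak_core <- r[which(Gr == max(Gr))]
    peak_core <- peak_core[cumsum(c(TRUE, diff(peak_core) != 1)) == 1] # first tied run
    carriers <- which(rowSums(exceed[, peak_core, drop = FALSE]) > 0)
    # leave-one-out peak locations over the run
    lo <- hi <- integer(0)
    for (s in carriers) {
      Gs <- if (direction == "amp") {
        colSums(amplitude[-s, r, drop = FALSE] *
          (amplitude[-s, r, drop = FALSE] >= theta))
      } else {
        colSums(-amplitude[-s, r, drop = FALSE] *
          (amplitude[-s, r, drop = FALSE] <= -theta))
      }
      pk <- r[which(Gs == max(Gs))]
      lo <- c(lo, min(pk))
      hi <- c(hi, max(pk))
    }
    if (length(lo) > 0) {
      k <- ceiling(confidence * length(lo))
      # smallest interval containing the core and k of the LOO peaks: trim
      # the most outlying (1 - confidence) fraction symmetrically
      lo_keep <- sort(lo)[max(1L, length(lo) - k + 1L)]
      hi_keep <- sort(hi)[min(length(hi), k)]
      peak_from <- min(min(peak_core), lo_keep)
      peak_to <- max(max(peak_core), hi_keep)
    } else {
      peak_from <- min(peak_core)
      peak_to <- max(peak_core)
    }
    ch <- markers$chrom[r[1]]
    out[[length(out) + 1]] <- tibble(
      chrom = ch,
      start = markers$pos[min(r)] - 1L,
      end = markers$pos[max(r)],
      direction = direction,
      g_score = max(Gr),
      q_value = min(q[r]),
      n_carriers = length(carriers),
      peak_start = markers$pos[peak_from] - 1L,
      peak_end = markers$pos[peak_to]
    )
  }
  bind_rows(out)
}

#' Scan a segmented cohort for recurrent minimal common regions
#'
#' End-to-end GISTIC-style scan: broadcasts segment means to markers,
#' computes amplification and deletion G-scores, permutation-null p-values,
#' Benjamini-Hochberg q-values and extracts significant MCRs in both
#' directions.
#'
#' @param segments Stated segment tibble for the whole cohort.
#' @param probes Probe tibble defining the marker grid.
#' @param theta Amplitude threshold (default 0.15).
#' @param n_perm Permutations per direction (default 10000).
#' @param alpha q-value cutoff (default 0.05).
#' @param confidence Peak-widening confidence (default 0.99).
#' @param exclude Optional mask intervals (see [build_amplitude_matrix()]).
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `mcr_scan`: list with `mcrs` (both
#'   directions), `scores` (per-marker tibble: chrom, pos, g_amp, q_amp,
#'   g_del, q_del) and the call parameters.
#' @export
detect_mcrs <- function(segments, probes, theta = 0.15, n_perm = 10000,
                        alpha = 0.05, confidence = 0.99, exclude = NULL,
                        seed = 1) {
  am <- build_amplitude_matrix(segments, probes, exclude = exclude)
  res <- list()
  scores <- am$markers
  pboth <- perm_null_both(am$amplitude, theta, n_perm, seed)
  for (dir in c("amp", "del")) {
    G <- g_scores(am$amplitude, dir, theta)
    qv <- bh_qvalues(pboth[[dir]])
    res[[dir]] <- extract_mcrs(G, qv, am$amplitude, am$markers, dir,
      alpha = alpha, confidence = confidence, theta = theta
    )
    scores[[paste0("g_", dir)]] <- G
    scores[[paste0("q_", dir)]] <- qv
  }
  structure(
    list(
      mcrs = bind_rows(res), scores = scores,
      theta = theta, n_perm = n_perm, alpha = alpha,
      confidence = confidence, seed = seed,
      n_samples = nrow(am$amplitude)
    ),
    class = "mcr_scan"
  )
}

#' @export
print.mcr_scan <- function(x, ...) {
  cat(
    "<mcr_scan>", x$n_samples, "samples,", nrow(x$scores), "markers,",
    x$n_perm, "permutations per direction\n"
  )
  cat(" significant MCRs (q <", x$alpha, "):", nrow(x$mcrs), "\n")
  if (nrow(x$mcrs) > 0) print(x$mcrs)
  invisible(x)
}
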