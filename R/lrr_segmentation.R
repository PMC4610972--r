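# Prefix-sum helpers for O(1) segment mean / within-segment variance.
seg_stats <- function(S1, S2, a, b) {
  n <- b - a + 1
  s1 <- S1[b + 1] - S1[a]
  s2 <- S2[b + 1] - S2[a]
  m <- s1 / n
  v <- if (n > 1) max((s2 - s1^2 / n) / (n - 1), 0) else 0
  list(n = n, mean = m, var = v)
}

# Welch-style t score between two flanking segments, with a variance floor so
# noiseless (zero-variance) flanks still give finite, very large scores.
t_between <- function(S1, S2, a, m, b, var_floor = 1e-12) {
  l <- seg_stats(S1, S2, a, m)
  r <- seg_stats(S1, S2, m + 1, b)
  se <- sqrt(max(l$var, var_floor) / l$n + max(r$var, var_floor) / r$n)
  abs(l$mean - r$mean) / se
}

# Best split of [a, b]: maximises the two-sample t score over cut points
# leaving at least min_piece probes on each side. Returns c(cut, t) or NULL.
best_split <- function(S1, S2, a, b, min_piece) {
  if (b - a + 1 < 2 * min_piece) {
    return(NULL)
  }
  cuts <- (a + min_piece - 1):(b - min_piece)
  n1 <- cuts - a + 1
  n2 <- b - cuts
  s1l <- S1[cuts + 1] - S1[a]
  s2l <- S2[cuts + 1] - S2[a]
  s1r <- S1[b + 1] - S1[cuts + 1]
  s2r <- S2[b + 1] - S2[cuts + 1]
  m1 <- s1l / n1
  m2 <- s1r / n2
  v1 <- ifelse(n1 > 1, pmax((s2l - s1l^2 / n1) / (n1 - 1), 0), 0)
  v2 <- ifelse(n2 > 1, pmax((s2r - s1r^2 / n2) / (n2 - 1), 0), 0)
  tt <- abs(m1 - m2) / sqrt(pmax(v1, 1e-12) / n1 + pmax(v2, 1e-12) / n2)
  i <- which.max(tt)
  c(cuts[i], tt[i])
}

#' Segment an LRR track by change-point fitting with backward elimination
#'
#' Two-phase procedure for one chromosome of ordered LRR values:
#' over-segmentation by recursive binary splitting on the maximal two-sample
#' t statistic, followed by backward elimination that repeatedly removes the
#' weakest surviving breakpoint (Welch-type t score between its flanking
#' segments) until every surviving breakpoint scores above `T`; finally the
#' weakest breakpoints of any segment shorter than `min_probes` are removed
#' so every reported segment carries at least `min_probes` probes (a
#' chromosome shorter than `min_probes` is returned as a single segment).
#'
#' @param lrr Numeric vector of LRR values in genomic order (one chromosome).
#' @param T Sensitivity threshold: a breakpoint survives only with t score
#'   strictly greater than `T` (default 10).
#' @param min_probes Minimum probes per reported segment (default 50).
#' @param split_t Liberal threshold used during over-segmentation (default 3).
#' @param min_piece Smallest piece considered while splitting (default 5).
#' @return Tibble with columns `probe_from`, `probe_to`, `n_probes`,
#'   `mean_lrr`; attribute `breakpoints` holds a tibble of retained
#'   breakpoints (`probe_index` = last probe of the left segment,
#'   `t_score`).
#' @export
segment_lrr <- function(lrr, T = 10, min_probes = 50, split_t = 3,
                        min_piece = 5) {
  if (any(!is.finite(lrr))) abort("non-finite LRR values; pre-clean the input")
  n <- length(lrr)
  if (n == 0) abort("empty LRR vector")
  S1 <- c(0, cumsum(lrr))
  S2 <- c(0, cumsum(lrr^2))

  finish <- function(bp) {
    from <- c(1L, bp + 1L)
    to <- c(bp, n)
    t_scores <- if (length(bp)) {
      vapply(seq_along(bp), function(i) {
        a <- if (i == 1) 1L else bp[i - 1] + 1L
        b <- if (i == length(bp)) n else bp[i + 1]
        t_between(S1, S2, a, bp[i], b)
      }, numeric(1))
    } else {
      numeric(0)
    }
    seg <- tibble(
      probe_from = as.integer(from), probe_to = as.integer(to),
      n_probes = as.integer(to - from + 1),
      mean_lrr = (S1[to + 1] - S1[from]) / (to - from + 1)
    )
    attr(seg, "breakpoints") <- tibble(
      probe_index = as.integer(bp), t_score = t_scores
    )
    seg
  }

  if (n < 2 * min_piece) {
    return(finish(integer(0)))
  }

  # phase 1: liberal recursive binary splitting
  bp <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack) > 0) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    sp <- best_split(S1, S2, iv[1], iv[2], min_piece)
    if (is.null(sp) || sp[2] <= split_t) next
    cut <- as.integer(sp[1])
    bp <- c(bp, cut)
    stack <- c(stack, list(c(iv[1], cut)), list(c(cut + 1L, iv[2])))
  }
  bp <- sort(bp)

  # current t score of breakpoint i given its neighbours
  bp_t <- function(bp, i) {
    a <- if (i == 1) 1L else bp[i - 1] + 1L
    b <- if (i == length(bp)) n else bp[i + 1]
    t_between(S1, S2, a, bp[i], b)
  }

  # phase 2: backward elimination to T
  while (length(bp) > 0) {
    ts <- vapply(seq_along(bp), function(i) bp_t(bp, i), numeric(1))
    weakest <- which.min(ts)
    if (ts[weakest] > T) break
    bp <- bp[-weakest]
  }

  # phase 3: enforce the minimum segment length
  repeat {
    if (length(bp) == 0) break
    from <- c(1L, bp + 1L)
    to <- c(bp, n)
    len <- to - from + 1
    short <- which(len < min_probes)
    if (length(short) == 0) break
    s <- short[which.min(len[short])]
    cand <- unique(c(
      if (s > 1) s - 1L else integer(0),
      if (s <= length(bp)) s else integer(0)
    ))
    ts <- vapply(cand, function(i) bp_t(bp, i), numeric(1))
    bp <- bp[-cand[which.min(ts)]]
  }

  # phase 4: local refinement — greedy splitting can land a cut a probe or
  # two off the least-squares optimum; re-optimise each breakpoint position
  # between its fixed neighbours until stable
  sse_ab <- function(a, b) {
    nn <- b - a + 1
    s1 <- S1[b + 1] - S1[a]
    (S2[b + 1] - S2[a]) - s1^2 / nn
  }
  if (length(bp) > 0) {
    for (pass in 1:20) {
      moved <- FALSE
      for (i in seq_along(bp)) {
        a <- if (i == 1) 1L else bp[i - 1] + 1L
        b <- if (i == length(bp)) n else bp[i + 1]
        lo <- a + min_probes - 1L
        hi <- b - min_probes
        if (lo > hi) next
        cuts <- lo:hi
        cost <- vapply(cuts, function(cut) {
          sse_ab(a, cut) + sse_ab(cut + 1L, b)
        }, numeric(1))
        best <- cuts[which.min(cost)]
        if (best != bp[i]) {
          bp[i] <- best
          moved <- TRUE
        }
      }
      if (!moved) break
    }
  }

  finish(bp)
}

#' Exact least-squares segmentation oracle (dynamic programming)
#'
#' Finds the globally optimal partition of a numeric series into `k + 1`
#' segments (exactly `k` breakpoints) minimising the residual sum of squares.
#' Exhaustive dynamic programming; intended as an independent reference for
#' validating [segment_lrr()] on small inputs.
#'
#' @param lrr Numeric vector (length at most 2000).
#' @param k Number of breakpoints (at most 5).
#' @return List with `breakpoints` (integer vector, last probe of each left
#'   segment), `sse` (optimal residual sum of squares) and `segments`
#'   (tibble as in [segment_lrr()]).
#' @export
exact_segmentation_oracle <- function(lrr, k) {
  n <- length(lrr)
  if (n > 2000) abort("oracle limited to 2000 probes")
  if (k > 5) abort("oracle limited to k <= 5 breakpoints")
  if (k >= n) abort("k must be smaller than the number of probes")
  S1 <- c(0, cumsum(lrr))
  S2 <- c(0, cumsum(lrr^2))
  sse_ab <- function(a, b) { # segment cost for a..b (1-based, inclusive)
    nn <- b - a + 1
    s1 <- S1[b + 1] - S1[a]
    (S2[b + 1] - S2[a]) - s1^2 / nn
  }
  # D[m+1, j]: best cost of first j points with m breakpoints
  D <- matrix(Inf, k + 1, n)
  B <- matrix(NA_integer_, k + 1, n)
  D[1, ] <- vapply(seq_len(n), function(j) sse_ab(1, j), numeric(1))
  if (k > 0) {
    for (m in seq_len(k)) {
      for (j in (m + 1):n) {
        i <- m:(j - 1) # last point of previous part
        nn <- j - i
        s1 <- S1[j + 1] - S1[i + 1]
        cost <- (S2[j + 1] - S2[i + 1]) - s1^2 / nn
        tot <- D[m, i] + cost
        best <- which.min(tot)
        D[m + 1, j] <- tot[best]
        B[m + 1, j] <- i[best]
      }
    }
  }
  bp <- integer(0)
  j <- n
  m <- k
  while (m > 0) {
    j <- B[m + 1, j]
    bp <- c(j, bp)
    m <- m - 1
  }
  from <- c(1L, bp + 1L)
  to <- c(bp, n)
  list(
    breakpoints = as.integer(bp),
    sse = D[k + 1, n],
    segments = tibble(
      probe_from = as.integer(from), probe_to = as.integer(to),
      n_probes = as.integer(to - from + 1),
      mean_lrr = (S1[to + 1] - S1[from]) / (to - from + 1)
    )
  )
}

#' Segment a cohort probe table
#'
#' Applies [segment_lrr()] per sample and chromosome. The LRR track of each
#' sample is median-centred first by default (standard array practice; the
#' genome-wide median is diploid in tumors whose gain and loss fractions stay
#' below one half).
#'
#' @param probes Probe tibble with columns `chrom`, `pos`, `lrr` and
#'   optionally `sample_id`.
#' @param T,min_probes,split_t Passed to [segment_lrr()].
#' @param center Baseline correction per sample before segmentation:
#'   `"mode"` (default) recentres on the density peak of the LRR
#'   distribution, which stays anchored to the diploid level even when a
#'   large fraction of the genome is altered; `"median"` is the classical
#'   array practice but drifts once gains/losses cover a sizable share of
#'   probes; `"none"` disables correction.
#' @return Tibble of segments with columns `sample_id`, `chrom`, `start`,
#'   `end` (0-based half-open bp), `probe_from`, `probe_to`, `n_probes`,
#'   `mean_lrr`.
#' @export
segment_probes <- function(probes, T = 10, min_probes = 50, split_t = 3,
                           center = c("mode", "median", "none")) {
  center <- match.arg(center)
  check_probe_cols(probes, c("chrom", "pos", "lrr"))
  if (!"sample_id" %in% names(probes)) probes$sample_id <- "sample"
  if (any(!is.finite(probes$lrr))) {
    abort("non-finite LRR values; pre-clean the input (see read_probe_matrix)")
  }
  probes <- sort_genomic(probes)
  out <- probes |>
    group_by(.data$sample_id) |>
    dplyr::group_modify(function(df, key) {
      offset <- lrr_baseline_offset(df$lrr, center)
      df |>
        group_by(.data$chrom) |>
        dplyr::group_modify(function(dc, kc) {
          seg <- segment_lrr(dc$lrr - offset,
            T = T, min_probes = min_probes,
            split_t = split_t
          )
          seg |>
            mutate(
              start = dc$pos[.data$probe_from] - 1L,
              end = dc$pos[.data$probe_to],
              .before = 1
            )
        }) |>
        ungroup()
    }) |>
    ungroup() |>
    select(
      "sample_id", "chrom", "start", "end", "probe_from", "probe_to",
      "n_probes", "mean_lrr"
    )
  out
}

# Baseline offset of an LRR track. "mode" takes the kernel-density peak
# (robust to large altered fractions: the diploid component stays the
# highest peak until it is no longer the largest state); "median" is the
# classical recentring; "none" returns 0.
lrr_baseline_offset <- function(lrr, method = c("mode", "median", "none")) {
  method <- match.arg(method)
  if (method == "none") {
    return(0)
  }
  if (method == "median") {
    return(median(lrr))
  }
  if (length(unique(lrr)) == 1) {
    return(lrr[1])
  }
  d <- stats::density(lrr, n = 512)
  d$x[which.max(d$y)]
}
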