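#' Array MAF from a B allele frequency
#'
#' Maps an array BAF to a minor/major allele ratio on the same scale as the
#' read-count MAF statistic: `min(baf, 1 - baf) / max(baf, 1 - baf)`.
#' Equals 1 for a balanced heterozygote (BAF 0.5) and 0 for a homozygous or
#' fully imbalanced probe (BAF 0 or 1).
#'
#' @param baf BAF values in `[0, 1]` (vectorised).
#' @return Values in `[0, 1]`.
#' @export
array_maf <- function(baf) {
  if (any(baf < 0 | baf > 1)) abort("BAF must lie in [0, 1]")
  lo <- pmin(baf, 1 - baf)
  hi <- pmax(baf, 1 - baf)
  ifelse(hi == 0, 1, lo / hi) # baf exactly 0.5 handled by lo/hi = 1
}

#' Default thresholds for six-state segment classification
#'
#' @param neutral_band Copy-neutral LRR band half-width (default 0.075).
#' @param focal_band Amplification/deletion LRR threshold (default 0.15).
#' @param loh_maf_ceiling Per-SNP array-MAF ceiling counted as LOH evidence
#'   (default 0.9).
#' @param loh_window LOH window size in informative SNPs (default 100).
#' @param loh_min_frac Strict lower bound on the low-MAF fraction in a
#'   flagged LOH window (default 0.8).
#' @param loh_overlap Fraction of a segment's probes that must fall in LOH
#'   regions for a copy-neutral segment to be called CNNLOH (default 0.5,
#'   strict).
#' @return A named list of class `state_thresholds`.
#' @export
state_thresholds <- function(neutral_band = 0.075, focal_band = 0.15,
                             loh_maf_ceiling = 0.9, loh_window = 100,
                             loh_min_frac = 0.8, loh_overlap = 0.5) {
  if (!(neutral_band > 0 && neutral_band < focal_band)) {
    abort("need 0 < neutral_band < focal_band")
  }
  structure(
    list(
      neutral_band = neutral_band, focal_band = focal_band,
      loh_maf_ceiling = loh_maf_ceiling, loh_window = loh_window,
      loh_min_frac = loh_min_frac, loh_overlap = loh_overlap
    ),
    class = "state_thresholds"
  )
}

#' Call LOH regions by sliding windows over informative SNPs
#'
#' Slides a `loh_window`-SNP window (step 1) over the informative
#' (germline-heterozygous) probes of each chromosome and flags windows in
#' which strictly more than `loh_min_frac` of SNPs have array MAF at or below
#' `loh_maf_ceiling`; flagged windows are merged into maximal regions.
#'
#' Because a window is flagged well before it lies fully inside an LOH
#' region, raw merged spans systematically overshoot the true edges, and two
#' nearby LOH regions can be bridged across a short retained-heterozygosity
#' gap. With `refine_edges = TRUE` (default) each merged candidate region
#' (plus a one-window context on each side) is re-fitted by least-squares
#' changepoint segmentation of the numeric per-SNP MAF series; sub-intervals
#' whose mean MAF exceeds `split_maf` (inconsistent with allelic loss at any
#' usable purity) are removed, which localises boundaries to a few SNPs and
#' splits bridged regions. `refine_edges = FALSE` reports the raw
#' merged-window spans (the exact window-enumeration semantics, used for
#' oracle comparisons).
#'
#' @param snps Tibble of informative SNPs with columns `chrom`, `pos`, `baf`,
#'   sorted within chromosome (sorted on entry if not).
#' @param thresholds A [state_thresholds()] object.
#' @param refine_edges Refine merged-region boundaries on the MAF series
#'   (default `TRUE`).
#' @param split_maf Mean-MAF ceiling for a refined sub-interval to be kept
#'   as LOH (default 0.6; a balanced heterozygote has expected MAF near 1,
#'   copy-neutral LOH at purity 0.3 or more gives MAF at or below ~0.55).
#' @return Tibble of LOH regions: `chrom`, `start`, `end` (0-based half-open
#'   bp), `from_snp`, `to_snp`, `n_informative`, `fraction_low_maf`.
#'   Chromosomes with fewer than `loh_window` informative SNPs yield no
#'   calls.
#' @export
call_loh <- function(snps, thresholds = state_thresholds(),
                     refine_edges = TRUE, split_maf = 0.6) {
  check_probe_cols(snps, c("chrom", "pos", "baf"))
  w <- thresholds$loh_window
  snps <- sort_genomic(snps) |>
    mutate(
      maf_value = array_maf(.data$baf),
      low_maf = .data$maf_value <= thresholds$loh_maf_ceiling
    )
  snps |>
    group_by(.data$chrom) |>
    dplyr::group_modify(function(df, key) {
      reg <- scan_windows(df$low_maf, w, thresholds$loh_min_frac)
      empty <- tibble(
        start = integer(0), end = integer(0), from_snp = integer(0),
        to_snp = integer(0), n_informative = integer(0),
        fraction_low_maf = numeric(0)
      )
      if (nrow(reg) == 0) {
        return(empty)
      }
      n <- nrow(df)
      if (refine_edges) {
        # re-fit every candidate (with one window of context) on the MAF
        # series and keep only low-MAF sub-intervals
        kept_from <- integer(0)
        kept_to <- integer(0)
        for (i in seq_len(nrow(reg))) {
          lo <- max(1L, reg$from[i] - w)
          hi <- min(n, reg$to[i] + w)
          fit <- segment_lrr(df$maf_value[lo:hi],
            T = 5, min_probes = 8, split_t = 2
          )
          low <- fit[fit$mean_lrr <= split_maf, , drop = FALSE]
          if (nrow(low) == 0) next
          kept_from <- c(kept_from, lo + low$probe_from - 1L)
          kept_to <- c(kept_to, lo + low$probe_to - 1L)
        }
        if (length(kept_from) == 0) {
          return(empty)
        }
        ord <- order(kept_from)
        kept_from <- kept_from[ord]
        kept_to <- kept_to[ord]
        # union of overlapping/abutting kept intervals
        fu <- kept_from[1]
        tu <- kept_to[1]
        out_f <- integer(0)
        out_t <- integer(0)
        for (i in seq_along(kept_from)[-1]) {
          if (kept_from[i] <= tu + 1L) {
            tu <- max(tu, kept_to[i])
          } else {
            out_f <- c(out_f, fu)
            out_t <- c(out_t, tu)
            fu <- kept_from[i]
            tu <- kept_to[i]
          }
        }
        reg <- tibble(from = c(out_f, fu), to = c(out_t, tu))
      }
      reg |>
        mutate(
          start = df$pos[.data$from] - 1L,
          end = df$pos[.data$to],
          from_snp = .data$from, to_snp = .data$to,
          n_informative = .data$to - .data$from + 1L,
          fraction_low_maf = map2_dbl_local(
            .data$from, .data$to,
            function(a, b) mean(df$low_maf[a:b])
          )
        ) |>
        select(
          "start", "end", "from_snp", "to_snp", "n_informative",
          "fraction_low_maf"
        )
    }) |>
    ungroup()
}

#' Select informative (germline-heterozygous) probes
#'
#' In simulated cohorts the truth genotype column is used directly; on real
#' data with a paired blood array, heterozygosity is inferred from the blood
#' BAF lying in `[0.25, 0.75]`. Without either source the caller must supply
#' their own heterozygosity flags — the function refuses to guess.
#'
#' @param probes Probe tibble; either a `genotype` column (`"het"` values are
#'   informative) or a `blood_baf` column must be present.
#' @param blood_range Blood-BAF heterozygosity band (default `c(0.25, 0.75)`).
#' @return The informative subset of `probes`.
#' @export
informative_probes <- function(probes, blood_range = c(0.25, 0.75)) {
  if ("genotype" %in% names(probes)) {
    return(probes |> filter(.data$genotype == "het"))
  }
  if ("blood_baf" %in% names(probes)) {
    return(probes |> filter(
      .data$blood_baf >= blood_range[1], .data$blood_baf <= blood_range[2]
    ))
  }
  abort(paste0(
    "cannot determine heterozygosity: supply a 'genotype' or 'blood_baf' ",
    "column (no silent guessing from tumor BAF)"
  ))
}

#' Classify one segment into the six-state scheme
#'
#' Applies the printed LRR thresholds with inclusive boundaries:
#' amplification if mean LRR >= `focal_band`; else gain if >= `neutral_band`;
#' deletion if <= `-focal_band`; else loss if <= `-neutral_band`; otherwise
#' (|LRR| < `neutral_band`, copy-neutral) CNNLOH when the segment's overlap
#' with LOH regions exceeds `loh_overlap` of its genomic extent, else normal.
#'
#' @param mean_lrr Segment mean LRR (scalar).
#' @param loh_overlap_frac Fraction of the segment covered by LOH regions.
#' @param thresholds A [state_thresholds()] object.
#' @return One of `"normal"`, `"gain"`, `"loss"`, `"CNNLOH"`,
#'   `"amplification"`, `"deletion"`.
#' @export
classify_segment <- function(mean_lrr, loh_overlap_frac = 0,
                             thresholds = state_thresholds()) {
  stopifnot(is.finite(mean_lrr))
  th <- thresholds
  if (mean_lrr >= th$focal_band) {
    "amplification"
  } else if (mean_lrr >= th$neutral_band) {
    "gain"
  } else if (mean_lrr <= -th$focal_band) {
    "deletion"
  } else if (mean_lrr <= -th$neutral_band) {
    "loss"
  } else if (loh_overlap_frac > th$loh_overlap) {
    "CNNLOH"
  } else {
    "normal"
  }
}

#' Coarse (four-state) view of a six-state label
#'
#' Amplification is a focal subtype of gain, deletion of loss; this accessor
#' collapses the focal states onto their broad parents.
#'
#' @param state Character vector of six-state labels.
#' @return Character vector over `normal`, `gain`, `loss`, `CNNLOH`.
#' @export
coarse_state <- function(state) {
  dplyr::case_match(
    state,
    "amplification" ~ "gain",
    "deletion" ~ "loss",
    .default = state
  )
}

# bp overlap of [s1,e1) with the union of intervals in `iv` (tibble start/end)
interval_overlap_bp <- function(s1, e1, iv) {
  if (nrow(iv) == 0) {
    return(0)
  }
  sum(pmax(0, pmin(e1, iv$end) - pmax(s1, iv$start)))
}

#' Assign six-state labels to segmented cohort data
#'
#' Combines LRR segments with LOH regions. LRR carries no signal across a
#' copy-neutral LOH boundary, so each copy-neutral candidate segment is first
#' split at the LOH-region edges that fall inside it (each resulting piece is
#' wholly inside or outside LOH); every piece's mean LRR is recomputed from
#' the member probes and the six-state rule of [classify_segment()] is
#' applied.
#'
#' @param segments Segment tibble from [segment_probes()] (columns
#'   `sample_id`, `chrom`, `start`, `end`, `probe_from`, `probe_to`,
#'   `n_probes`, `mean_lrr`).
#' @param probes Probe tibble with `sample_id`, `chrom`, `pos`, `lrr` (used
#'   to recompute means of split pieces).
#' @param loh LOH regions per sample: tibble with `sample_id`, `chrom`,
#'   `start`, `end` (e.g. [call_loh()] run per sample).
#' @param thresholds A [state_thresholds()] object.
#' @param split_at_loh Split copy-neutral segments at LOH edges before
#'   classification (default `TRUE`).
#' @param center Baseline correction applied when recomputing piece means;
#'   must match the `center` choice used in [segment_probes()] (default
#'   `"mode"`).
#' @return Segment tibble with recomputed pieces and a `state` column.
#' @export
call_states <- function(segments, probes, loh, thresholds = state_thresholds(),
                        split_at_loh = TRUE,
                        center = c("mode", "median", "none")) {
  center <- match.arg(center)
  if (!"sample_id" %in% names(probes)) probes$sample_id <- "sample"
  if (!"sample_id" %in% names(segments)) segments$sample_id <- "sample"
  if (!"sample_id" %in% names(loh)) loh$sample_id <- "sample"
  probes <- sort_genomic(probes)
  if (center != "none") {
    probes <- probes |>
      group_by(.data$sample_id) |>
      mutate(lrr = .data$lrr - lrr_baseline_offset(.data$lrr, center)) |>
      ungroup()
  }
  pieces <- segments |>
    group_by(.data$sample_id, .data$chrom) |>
    dplyr::group_modify(function(df, key) {
      pp <- probes |>
        filter(
          .data$sample_id == key$sample_id[1], .data$chrom == key$chrom[1]
        )
      lr <- loh |>
        filter(
          .data$sample_id == key$sample_id[1], .data$chrom == key$chrom[1]
        )
      out <- list()
      for (i in seq_len(nrow(df))) {
        s <- df$start[i]
        e <- df$end[i]
        cuts <- numeric(0)
        if (split_at_loh && nrow(lr) > 0) {
          cuts <- sort(unique(c(
            lr$start[lr$start > s & lr$start < e],
            lr$end[lr$end > s & lr$end < e]
          )))
        }
        bounds <- c(s, cuts, e)
        for (j in seq_len(length(bounds) - 1)) {
          ps <- bounds[j]
          pe <- bounds[j + 1]
          idx <- which(pp$pos > ps & pp$pos <= pe)
          if (length(idx) == 0) next
          m <- mean(pp$lrr[idx])
          ov <- interval_overlap_bp(ps, pe, lr) / (pe - ps)
          out[[length(out) + 1]] <- tibble(
            start = ps, end = pe,
            probe_from = min(idx), probe_to = max(idx),
            n_probes = length(idx), mean_lrr = m,
            state = classify_segment(m, ov, thresholds)
          )
        }
      }
      bind_rows(out)
    }) |>
    ungroup()
  pieces
}
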