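#' Minor allele fraction from read counts
#'
#' The allelic-imbalance statistic for an informative SNP: the number of
#' reads carrying the minor allele divided by the number carrying the major
#' allele. 1 means perfect allelic balance; 0 means complete loss of one
#' allele.
#'
#' @param minor,major Nonnegative read counts with `minor <= major` and
#'   `major > 0` (vectorised).
#' @return `minor / major`, in `[0, 1]`.
#' @examples
#' maf(3, 7)
#' @export
maf <- function(minor, major) {
  if (any(minor < 0)) abort("minor counts must be nonnegative")
  if (any(major <= 0)) abort("major counts must be positive (depth rule excludes major = 0)")
  if (any(minor > major)) abort("minor count cannot exceed major count")
  minor / major
}

#' Is a SNP's tumor/blood MAF difference significant?
#'
#' One-sided rule: the SNP shows significant allelic imbalance when the blood
#' MAF exceeds the tumor MAF by at least `delta` (`MAF_B - MAF_T >= delta`);
#' a tumor more balanced than blood is never flagged.
#'
#' @param maf_b,maf_t Blood and tumor MAF, each in `[0, 1]` (vectorised).
#' @param delta Significance margin (default 0.1).
#' @return Logical vector.
#' @export
is_significant <- function(maf_b, maf_t, delta = 0.1) {
  if (any(maf_b < 0 | maf_b > 1 | maf_t < 0 | maf_t > 1)) {
    abort("MAF values must lie in [0, 1]")
  }
  # epsilon guard so the decimal threshold closes as printed (0.6 - 0.5 is
  # fractionally below 0.1 in binary floating point)
  (maf_b - maf_t) >= delta - 1e-9
}

# Shared window scan: returns merged regions for per-SNP logical flags within
# one chromosome, using strict "> min_frac" window flagging.
scan_windows <- function(flag, window, min_frac) {
  counts <- window_counts(flag, window)
  starts <- which(counts / window > min_frac)
  merge_flagged_windows(starts, window)
}

#' Call allelically imbalanced regions by sliding SNP windows
#'
#' Computes per-SNP blood and tumor MAF, flags SNPs whose blood-minus-tumor
#' MAF difference is at least `delta`, slides a `window`-SNP window (step 1
#' SNP, never spanning chromosomes) and flags windows in which strictly more
#' than `min_frac` of SNPs are significant. Overlapping or abutting flagged
#' windows are merged into maximal regions spanning their outermost SNPs.
#'
#' @param snps Tibble of informative SNPs with columns `chrom`, `pos`,
#'   `blood_minor`, `blood_major`, `tumor_minor`, `tumor_major`, sorted by
#'   position within chromosome (sorted on entry if not).
#' @param window Window size in SNPs (default 50).
#' @param min_frac Strict lower bound on the significant fraction (default
#'   0.7).
#' @param delta MAF difference margin (default 0.1).
#' @param step Window step in SNPs (only step 1 is supported; the argument
#'   records the convention).
#' @return A list with `regions` (tibble: chrom, start, end (0-based
#'   half-open bp), from_snp, to_snp, n_snps, fraction_significant) and
#'   `snps` (the input with `maf_b`, `maf_t`, `significant` appended).
#'   Chromosomes with fewer than `window` SNPs yield no calls.
#' @export
call_imbalanced_regions <- function(snps, window = 50, min_frac = 0.7,
                                    delta = 0.1, step = 1) {
  if (step != 1) abort("only step = 1 window sliding is implemented")
  needed <- c(
    "chrom", "pos", "blood_minor", "blood_major",
    "tumor_minor", "tumor_major"
  )
  missing <- setdiff(needed, names(snps))
  if (length(missing) > 0) {
    abort(paste0("snps are missing column(s): ", paste(missing, collapse = ", ")))
  }
  snps <- sort_genomic(snps) |>
    mutate(
      maf_b = maf(.data$blood_minor, .data$blood_major),
      maf_t = maf(.data$tumor_minor, .data$tumor_major),
      significant = is_significant(.data$maf_b, .data$maf_t, delta)
    )
  regions <- snps |>
    group_by(.data$chrom) |>
    dplyr::group_modify(function(df, key) {
      reg <- scan_windows(df$significant, window, min_frac)
      if (nrow(reg) == 0) {
        return(tibble(
          start = integer(0), end = integer(0), from_snp = integer(0),
          to_snp = integer(0), n_snps = integer(0),
          fraction_significant = numeric(0)
        ))
      }
      reg |>
        mutate(
          start = df$pos[.data$from] - 1L,
          end = df$pos[.data$to],
          from_snp = .data$from, to_snp = .data$to,
          n_snps = .data$to - .data$from + 1L,
          fraction_significant = map2_dbl_local(
            .data$from, .data$to,
            function(a, b) mean(df$significant[a:b])
          )
        ) |>
        select(
          "start", "end", "from_snp", "to_snp", "n_snps",
          "fraction_significant"
        )
    }) |>
    ungroup()
  list(regions = regions, snps = snps)
}

map2_dbl_local <- function(x, y, f) {
  vapply(seq_along(x), function(i) f(x[i], y[i]), numeric(1))
}
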