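#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   across bind_rows left_join n row_number lag lead distinct pull rename
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map2 pmap map_dbl map_int map_lgl map_chr list_rbind
#' @importFrom stats rnorm rbinom runif rexp median sd setNames p.adjust
#'   wilcox.test chisq.test fisher.test pchisq ks.test quantile
#' @importFrom Rcpp evalCpp
#' @useDynLib tumorcna, .registration = TRUE
NULL

# Sliding-window flag counts: number of TRUE in each window of `window`
# consecutive elements, step 1. Returns numeric vector of length
# length(flags) - window + 1 (or length 0 if too short).
window_counts <- function(flags, window) {
  n <- length(flags)
  if (n < window) return(numeric(0))
  cs <- cumsum(as.numeric(flags))
  cs[window:n] - c(0, cs[seq_len(n - window)])
}

# Merge flagged window start indices (step-1 windows of width `window`) into
# maximal runs: windows are merged when overlapping or abutting, i.e. when the
# next flagged start is <= current start + window. Returns a tibble with the
# SNP-index span of each merged region (first SNP of first window to last SNP
# of last window, 1-based inclusive).
merge_flagged_windows <- function(starts, window) {
  if (length(starts) == 0) {
    return(tibble(from = integer(0), to = integer(0)))
  }
  starts <- sort(starts)
  new_run <- c(TRUE, diff(starts) > window)
  run_id <- cumsum(new_run)
  tibble(
    from = as.integer(tapply(starts, run_id, min)),
    to = as.integer(tapply(starts, run_id, max)) + window - 1L
  )
}

# Validate a probe tibble has the expected columns and types.
check_probe_cols <- function(probes, cols = c("chrom", "pos", "baf", "lrr")) {
  missing <- setdiff(cols, names(probes))
  if (length(missing) > 0) {
    abort(paste0(
      "probe table is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  invisible(probes)
}

# Order chromosomes naturally: numeric names numerically, the rest after.
chrom_order <- function(chrom) {
  u <- unique(as.character(chrom))
  num <- suppressWarnings(as.numeric(sub("^chr", "", u)))
  u[order(is.na(num), num, u)]
}

sort_genomic <- function(df) {
  df |>
    mutate(chrom = factor(.data$chrom, levels = chrom_order(.data$chrom))) |>
    arrange(.data$chrom, .data$pos) |>
    mutate(chrom = as.character(.data$chrom))
}
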