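#' Read a SNP-array probe matrix
#'
#' Reads a tab-separated probe table with header columns `probe_id`, `chrom`,
#' `pos`, `baf` and `lrr` (one row per probe; positions are 1-based, as in
#' array manifests). Rows with non-finite BAF or LRR are dropped and counted;
#' the input is sorted by `(chrom, pos)` if it is not already. BAF values must
#' lie in `[0, 1]` after cleaning.
#'
#' @param path Path to a tab-separated file.
#' @param max_drop_frac Maximum tolerated fraction of rows dropped for
#'   malformed numeric cells before the read is treated as an error.
#' @param quiet Suppress the dropped-row message.
#' @return A tibble with columns `probe_id`, `chrom`, `pos`, `baf`, `lrr`
#'   (plus any extra columns present in the file), sorted by genome position,
#'   with attribute `n_dropped` recording the number of removed rows.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' readr::write_tsv(tibble::tibble(
#'   probe_id = c("p1", "p2"), chrom = "1", pos = c(100L, 200L),
#'   baf = c(0.5, 0.1), lrr = c(0, -0.6)
#' ), tf)
#' read_probe_matrix(tf)
#' @export
read_probe_matrix <- function(path, max_drop_frac = 0.05, quiet = FALSE) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_probe_cols(raw, c("probe_id", "chrom", "pos", "baf", "lrr"))
  raw <- raw |>
    mutate(
      chrom = as.character(.data$chrom),
      pos = suppressWarnings(as.integer(.data$pos)),
      baf = suppressWarnings(as.numeric(.data$baf)),
      lrr = suppressWarnings(as.numeric(.data$lrr))
    )
  keep <- is.finite(raw$pos) & is.finite(raw$baf) & is.finite(raw$lrr)
  n_dropped <- sum(!keep)
  if (nrow(raw) > 0 && n_dropped / nrow(raw) > max_drop_frac) {
    abort(sprintf(
      "%d of %d probe rows (%.1f%%) are malformed, above the %.1f%% tolerance",
      n_dropped, nrow(raw), 100 * n_dropped / nrow(raw), 100 * max_drop_frac
    ))
  }
  out <- raw[keep, , drop = FALSE]
  if (any(out$baf < 0 | out$baf > 1)) {
    abort("BAF values outside [0, 1] in probe table")
  }
  if (anyDuplicated(out$probe_id)) {
    abort("duplicate probe_id values in probe table")
  }
  out <- sort_genomic(out)
  if (n_dropped > 0 && !quiet) {
    inform(sprintf("dropped %d probe row(s) with non-finite values", n_dropped))
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a probe matrix to a tab-separated file
#'
#' @param probes Probe tibble as returned by [read_probe_matrix()] or
#'   [simulate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_matrix <- function(probes, path) {
  check_probe_cols(probes, c("probe_id", "chrom", "pos", "baf", "lrr"))
  readr::write_tsv(probes, path, progress = FALSE)
  invisible(path)
}

#' Write segments as BED6
#'
#' Writes one BED6 line per segment: `chrom`, 0-based `start`, half-open
#' `end`, `name` = state label, `score` = `round(1000 * min(1, |mean LRR|))`,
#' `strand` = ".". Segment tables carry 0-based half-open coordinates
#' internally, so `start`/`end` are written as-is. Segments from a single
#' sample must not overlap (a segmentation is a partition).
#'
#' @param segments Tibble with columns `chrom`, `start`, `end`, `state`,
#'   `mean_lrr` (and optionally `sample_id`; overlap is checked per sample).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  needed <- c("chrom", "start", "end", "state", "mean_lrr")
  missing <- setdiff(needed, names(segments))
  if (length(missing) > 0) {
    abort(paste0("segments are missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(segments) > 0) {
    if (any(segments$start >= segments$end)) {
      abort("segment intervals must satisfy start < end")
    }
    grp <- if ("sample_id" %in% names(segments)) segments$sample_id else ""
    by_grp <- split(segments, list(grp, segments$chrom), drop = TRUE)
    for (g in by_grp) {
      g <- g[order(g$start), , drop = FALSE]
      if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)])) {
        abort("overlapping segments within one sample; segmentation must partition")
      }
    }
  }
  bed <- tibble(
    chrom = as.character(segments$chrom),
    start = as.integer(segments$start),
    end = as.integer(segments$end),
    name = as.character(segments$state),
    score = as.integer(round(1000 * pmin(1, abs(segments$mean_lrr)))),
    strand = "."
  )
  header <- "# BED6: chrom start end state score(1000*min(1,|meanLRR|)) strand"
  writeLines(header, path)
  readr::write_tsv(bed, path, col_names = FALSE, append = TRUE, progress = FALSE)
  invisible(path)
}

#' Read a BED6 segment file written by [write_segments_bed()]
#'
#' @param path Path to a BED6 file; lines starting with `#` are skipped.
#' @return Tibble with columns `chrom`, `start`, `end`, `state`, `score`,
#'   `strand` (0-based half-open intervals).
#' @export
read_segments_bed <- function(path) {
  bed <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "state", "score", "strand"),
    col_types = "ciicic", comment = "#", progress = FALSE
  )
  as_tibble(bed)
}

#' Read a clinical covariate table
#'
#' Reads a CSV with one row per patient. Recognised columns are `sample_id`,
#' `tp53_mutated`, `ln_metastasis`, `survival_days` and `event`; any other
#' columns (gender, age, stage, ...) are preserved as additional covariates.
#' Empty survival cells become missing values; an `event` value is required
#' whenever `survival_days` is present.
#'
#' @param path Path to a CSV file with a header.
#' @return A tibble, one row per sample.
#' @export
read_clinical <- function(path) {
  cl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(cl)) {
    abort("clinical table is missing column: sample_id")
  }
  cl$sample_id <- as.character(cl$sample_id)
  if (anyDuplicated(cl$sample_id)) {
    abort("duplicate sample_id in clinical table")
  }
  for (col in c("tp53_mutated", "ln_metastasis", "event")) {
    if (col %in% names(cl)) cl[[col]] <- as.logical(cl[[col]])
  }
  if ("survival_days" %in% names(cl)) {
    cl$survival_days <- suppressWarnings(as.numeric(cl$survival_days))
    if (any(!is.na(cl$survival_days) & cl$survival_days < 0)) {
      abort("survival_days must be nonnegative")
    }
    if ("event" %in% names(cl)) {
      bad <- !is.na(cl$survival_days) & is.na(cl$event)
      if (any(bad)) {
        abort("event flag missing for samples with survival_days present")
      }
    } else {
      abort("survival_days present but event column missing")
    }
  }
  as_tibble(cl)
}
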