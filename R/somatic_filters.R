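#' Quality-trim a sequencing tag
#'
#' Scans the tag left to right; at the first position where two adjacent
#' bases both have Phred quality below `qual_floor`, those two bases and
#' everything after them are trimmed. Tags shorter than `min_len` after
#' trimming are rejected. A single isolated low-quality base never triggers
#' trimming.
#'
#' @param bases Character scalar of bases over `{A, C, G, T, N}`.
#' @param quals Integer vector of Phred scores, one per base.
#' @param qual_floor Phred threshold (default 20).
#' @param min_len Minimum kept length (default 35 nt).
#' @return A list with elements `bases`, `quals`, `kept` (logical) and
#'   `trimmed` (logical). Rejected tags have `kept = FALSE` and empty
#'   `bases`/`quals`.
#' @examples
#' trim_tag(strrep("A", 40), c(rep(30, 10), 15, 15, rep(30, 28)))$kept
#' @export
trim_tag <- function(bases, quals, qual_floor = 20, min_len = 35) {
  n <- nchar(bases)
  if (length(quals) != n) {
    abort("bases and quals must have the same length")
  }
  if (any(quals < 0)) abort("Phred qualities must be nonnegative")
  if (n == 0) {
    return(list(bases = "", quals = integer(0), kept = FALSE, trimmed = FALSE))
  }
  low <- quals < qual_floor
  pair <- which(low[-n] & low[-1])
  trimmed <- length(pair) > 0
  keep_len <- if (trimmed) pair[1] - 1L else n
  if (keep_len < min_len) {
    return(list(bases = "", quals = integer(0), kept = FALSE, trimmed = trimmed))
  }
  list(
    bases = substr(bases, 1, keep_len),
    quals = quals[seq_len(keep_len)],
    kept = TRUE,
    trimmed = trimmed
  )
}

#' Filter candidate somatic sites by tumor/blood read support
#'
#' Applies the three tumor/normal post-processing filters to a site table:
#' (1) coverage at least `min_cov` in both tumor and blood; (2) quality-passing
#' mutant reads make up at least `min_alt_frac` of the tumor reads; (3) no
#' mutant reads in the blood sample. Each failing site is annotated with the
#' first violated rule.
#'
#' Rule (2) is applied, by default, as `tumor_alt_q20 / tumor_depth >=
#' min_alt_frac` (quality-passing alt reads over total tumor depth, the
#' conventional alt-allele-fraction filter). The literal alternative reading
#' — at least 20% of the mutant-supporting reads are themselves Q >= 20 —
#' is available with `denominator = "alt_reads"`.
#'
#' @param sites Tibble with columns `tumor_depth`, `tumor_alt_q20`,
#'   `tumor_alt_total`, `blood_depth`, `blood_alt_total` (one row per site).
#' @param min_cov Minimum coverage in each tissue (default 10).
#' @param min_alt_frac Minimum quality-passing alt fraction (default 0.20).
#' @param denominator `"depth"` (default) or `"alt_reads"` (see Details).
#' @return The input tibble with logical `pass` and character `reason`
#'   columns appended (`reason` is `NA` for passing sites; otherwise one of
#'   `"coverage"`, `"alt_quality_fraction"`, `"blood_contains_mutant"`).
#' @export
filter_somatic <- function(sites, min_cov = 10, min_alt_frac = 0.20,
                           denominator = c("depth", "alt_reads")) {
  denominator <- match.arg(denominator)
  needed <- c(
    "tumor_depth", "tumor_alt_q20", "tumor_alt_total",
    "blood_depth", "blood_alt_total"
  )
  missing <- setdiff(needed, names(sites))
  if (length(missing) > 0) {
    abort(paste0("sites are missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(sites$tumor_alt_q20 > sites$tumor_alt_total) ||
    any(sites$tumor_alt_total > sites$tumor_depth) ||
    any(sites$blood_alt_total > sites$blood_depth)) {
    abort("read-count invariants violated (alt_q20 <= alt_total <= depth)")
  }
  denom <- if (denominator == "depth") {
    sites$tumor_depth
  } else {
    sites$tumor_alt_total
  }
  frac_ok <- denom > 0 & sites$tumor_alt_q20 >= min_alt_frac * denom
  cov_ok <- sites$tumor_depth >= min_cov & sites$blood_depth >= min_cov
  blood_ok <- sites$blood_alt_total == 0
  reason <- dplyr::case_when(
    !cov_ok ~ "coverage",
    !frac_ok ~ "alt_quality_fraction",
    !blood_ok ~ "blood_contains_mutant",
    TRUE ~ NA_character_
  )
  sites |>
    mutate(pass = cov_ok & frac_ok & blood_ok, reason = reason)
}

#' Summarise a mutation consequence spectrum
#'
#' Counts verified mutations by consequence class and reports raw-rounded
#' percentages (two decimals; no largest-remainder reconciliation, so the
#' printed percentages may not sum to exactly 100).
#'
#' @param mutations Tibble with columns `sample_id` and `class`
#'   (`missense`, `nonsense`, `indel`, `splice-site`, `read-through`,
#'   `synonymous` or `other`).
#' @return A list with `spectrum` (tibble: class, n, percent) and
#'   `per_sample` (tibble: sample_id, n_mutations). Empty input yields empty
#'   tables.
#' @examples
#' mut <- tibble::tibble(
#'   sample_id = c("a", "a", "b"),
#'   class = c("missense", "missense", "nonsense")
#' )
#' summarize_mutation_spectrum(mut)$spectrum
#' @export
summarize_mutation_spectrum <- function(mutations) {
  classes <- c(
    "missense", "nonsense", "indel", "splice-site",
    "read-through", "synonymous", "other"
  )
  if (nrow(mutations) == 0) {
    return(list(
      spectrum = tibble(class = character(0), n = integer(0), percent = numeric(0)),
      per_sample = tibble(sample_id = character(0), n_mutations = integer(0))
    ))
  }
  if (!all(mutations$class %in% classes)) {
    abort(paste0(
      "unknown consequence class; expected one of: ",
      paste(classes, collapse = ", ")
    ))
  }
  spectrum <- mutations |>
    dplyr::count(.data$class, name = "n") |>
    mutate(percent = round(100 * .data$n / sum(.data$n), 2)) |>
    arrange(dplyr::desc(.data$n))
  per_sample <- mutations |>
    dplyr::count(.data$sample_id, name = "n_mutations")
  list(spectrum = spectrum, per_sample = per_sample)
}

#' Pooled mutation rate across screening panels
#'
#' Pools mutated/screened counts from one or more sample panels and reports
#' the percentage `100 * sum(mutated) / sum(total)`.
#'
#' @param counts Tibble (or data frame) with columns `mutated` and `total`,
#'   one row per panel.
#' @param digits Decimal places for the returned percentage (default 2;
#'   `NULL` returns the unrounded value).
#' @return A single percentage.
#' @examples
#' pooled_mutation_rate(tibble::tibble(mutated = c(5, 23), total = c(9, 46)))
#' @export
pooled_mutation_rate <- function(counts, digits = 2) {
  if (!all(c("mutated", "total") %in% names(counts))) {
    abort("counts must have columns mutated and total")
  }
  if (any(counts$mutated > counts$total) || any(counts$mutated < 0)) {
    abort("each mutated count must lie in [0, total]")
  }
  tot <- sum(counts$total)
  if (tot == 0) abort("total screened count is zero")
  pct <- 100 * sum(counts$mutated) / tot
  if (is.null(digits)) pct else round(pct, digits)
}
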