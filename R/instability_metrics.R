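#' Per-sample genomic-instability fractions
#'
#' Divides the number of probes undergoing each alteration type by the total
#' probe count, per sample and per chromosome. Gain counts gain plus
#' amplification probes, loss counts loss plus deletion probes, CNNLOH counts
#' CNNLOH probes; the three classes are mutually exclusive, so the overall
#' fraction is their sum. A sample is flagged `severe` when its overall
#' fraction reaches 0.5.
#'
#' @param segments Stated segment tibble (from [call_states()]) with columns
#'   `sample_id`, `chrom`, `n_probes`, `state`.
#' @param severe_cut Overall-fraction threshold for the severe flag
#'   (inclusive; default 0.5).
#' @return A list with `profile` (tibble: sample_id, frac_gain, frac_loss,
#'   frac_cnnloh, frac_overall, severe) and `by_chrom` (tibble: sample_id,
#'   chrom, frac_gain, frac_loss, frac_cnnloh).
#' @export
instability_fractions <- function(segments, severe_cut = 0.5) {
  needed <- c("sample_id", "chrom", "n_probes", "state")
  missing <- setdiff(needed, names(segments))
  if (length(missing) > 0) {
    abort(paste0("segments are missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(segments) == 0 || sum(segments$n_probes) == 0) {
    abort("no probes in segment table")
  }
  buckets <- segments |>
    mutate(bucket = dplyr::case_when(
      .data$state %in% c("gain", "amplification") ~ "gain",
      .data$state %in% c("loss", "deletion") ~ "loss",
      .data$state == "CNNLOH" ~ "cnnloh",
      TRUE ~ "normal"
    ))
  tally <- function(df, ...) {
    df |>
      group_by(...) |>
      summarise(
        total = sum(.data$n_probes),
        gain = sum(.data$n_probes[.data$bucket == "gain"]),
        loss = sum(.data$n_probes[.data$bucket == "loss"]),
        cnnloh = sum(.data$n_probes[.data$bucket == "cnnloh"]),
        .groups = "drop"
      ) |>
      mutate(
        frac_gain = .data$gain / .data$total,
        frac_loss = .data$loss / .data$total,
        frac_cnnloh = .data$cnnloh / .data$total
      )
  }
  profile <- tally(buckets, .data$sample_id) |>
    mutate(
      frac_overall = .data$frac_gain + .data$frac_loss + .data$frac_cnnloh,
      severe = .data$frac_overall >= severe_cut
    ) |>
    select(
      "sample_id", "frac_gain", "frac_loss", "frac_cnnloh",
      "frac_overall", "severe"
    )
  by_chrom <- tally(buckets, .data$sample_id, .data$chrom) |>
    select("sample_id", "chrom", "frac_gain", "frac_loss", "frac_cnnloh")
  list(profile = profile, by_chrom = by_chrom)
}

#' Count segment breakpoints per chromosome arm
#'
#' Counts internal segment boundaries (the junction between two consecutive
#' segments of one chromosome) falling on each arm, given a centromere
#' table. A junction at genomic position `x` belongs to the p arm when
#' `x < centromere_pos`, else to the q arm. Sample-arms whose count reaches
#' `flag_threshold` are flagged as chromothripsis candidates (the threshold
#' is a screening parameter, not a full chromothripsis test).
#'
#' @param segments Segment tibble with `sample_id`, `chrom`, `start`, `end`
#'   (0-based half-open), sorted or not.
#' @param arms Tibble with columns `chrom`, `centromere_pos` (bp); see
#'   [sim_arm_table()] for simulated cohorts.
#' @param flag_threshold Breakpoint count flagging a candidate arm
#'   (default 20).
#' @return Tibble: `sample_id`, `chrom`, `arm`, `n_breakpoints`,
#'   `candidate` (logical).
#' @export
breakpoints_per_arm <- function(segments, arms, flag_threshold = 20) {
  if (!all(c("chrom", "centromere_pos") %in% names(arms))) {
    abort("arms must have columns chrom and centromere_pos")
  }
  if (!"sample_id" %in% names(segments)) segments$sample_id <- "sample"
  junctions <- segments |>
    group_by(.data$sample_id, .data$chrom) |>
    arrange(.data$start, .by_group = TRUE) |>
    filter(row_number() < n()) |> # junction after each non-final segment
    ungroup() |>
    dplyr::transmute(
      .data$sample_id, .data$chrom,
      junction_pos = as.numeric(.data$end)
    )
  grid <- tidyr::expand_grid(
    distinct(segments, .data$sample_id),
    arms |> select("chrom", "centromere_pos"),
    arm_side = c("p", "q")
  )
  counts <- junctions |>
    left_join(arms, by = "chrom") |>
    mutate(arm_side = as.character(
      ifelse(.data$junction_pos < .data$centromere_pos, "p", "q")
    )) |>
    dplyr::count(.data$sample_id, .data$chrom, .data$arm_side, name = "n_breakpoints")
  grid |>
    left_join(counts, by = c("sample_id", "chrom", "arm_side")) |>
    mutate(
      n_breakpoints = as.integer(tidyr::replace_na(.data$n_breakpoints, 0L)),
      arm = paste0(.data$chrom, .data$arm_side),
      candidate = .data$n_breakpoints >= flag_threshold
    ) |>
    select("sample_id", "chrom", "arm", "n_breakpoints", "candidate") |>
    arrange(.data$sample_id, .data$chrom, .data$arm)
}
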