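#' Run the full array pipeline on a cohort probe table
#'
#' Convenience wrapper chaining the array stages: per-sample LRR
#' segmentation, LOH window calling on informative probes, six-state
#' classification and instability profiling.
#'
#' @param probes Cohort probe tibble (`sample_id`, `chrom`, `pos`, `baf`,
#'   `lrr`, plus a `genotype` or `blood_baf` column for informativeness).
#' @param thresholds A [state_thresholds()] object.
#' @param T,min_probes Segmentation parameters (see [segment_lrr()]).
#' @param center LRR baseline correction (see [segment_probes()]).
#' @param refine_loh_edges Refine LOH region edges (default `TRUE`).
#' @return A list with `segments` (stated segments), `loh` (per-sample LOH
#'   regions), `profile` and `by_chrom` (from [instability_fractions()]).
#' @export
profile_cohort <- function(probes, thresholds = state_thresholds(),
                           T = 10, min_probes = 50,
                           center = c("mode", "median", "none"),
                           refine_loh_edges = TRUE) {
  center <- match.arg(center)
  if (!"sample_id" %in% names(probes)) probes$sample_id <- "sample"
  segments <- segment_probes(probes,
    T = T, min_probes = min_probes,
    center = center
  )
  loh <- probes |>
    group_by(.data$sample_id) |>
    dplyr::group_modify(function(df, key) {
      inf <- informative_probes(df)
      call_loh(inf, thresholds, refine_edges = refine_loh_edges)
    }) |>
    ungroup()
  stated <- call_states(segments, probes, loh,
    thresholds = thresholds,
    center = center
  )
  fr <- instability_fractions(stated)
  list(
    segments = stated, loh = loh,
    profile = fr$profile, by_chrom = fr$by_chrom
  )
}
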