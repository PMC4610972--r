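#' @importFrom ggplot2 ggplot aes geom_line geom_step geom_col geom_hline
#'   geom_point geom_violin geom_jitter facet_grid facet_wrap labs
#'   scale_y_log10 theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot per-sample instability fractions
#'
#' Stacked per-sample bar chart of the gain / loss / CNNLOH fractions,
#' ordered by overall instability, with the severe cut marked.
#'
#' @param profile Tibble from [instability_fractions()] (`$profile`).
#' @param severe_cut Severity threshold line (default 0.5).
#' @return A ggplot object.
#' @export
plot_instability <- function(profile, severe_cut = 0.5) {
  long <- profile |>
    arrange(.data$frac_overall) |>
    mutate(sample_id = factor(.data$sample_id, levels = .data$sample_id)) |>
    tidyr::pivot_longer(
      c("frac_gain", "frac_loss", "frac_cnnloh"),
      names_to = "type", values_to = "fraction"
    ) |>
    mutate(type = sub("frac_", "", .data$type))
  ggplot(long, aes(x = .data$sample_id, y = .data$fraction, fill = .data$type)) +
    geom_col() +
    geom_hline(yintercept = severe_cut, linetype = "dashed") +
    labs(
      x = NULL, y = "fraction of probes altered", fill = NULL,
      title = "Genomic instability per sample"
    ) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot instability fractions split by a clinical group
#'
#' Violin-with-points comparison of an instability fraction between two
#' groups (e.g. TP53 mutated vs wild type).
#'
#' @param profile Tibble from [instability_fractions()] (`$profile`).
#' @param clinical Clinical tibble with `sample_id` and the grouping column.
#' @param group Name of the logical grouping column (default
#'   `"tp53_mutated"`).
#' @param fraction Which fraction column to plot (default `"frac_overall"`).
#' @return A ggplot object.
#' @export
plot_fractions_by_group <- function(profile, clinical,
                                    group = "tp53_mutated",
                                    fraction = "frac_overall") {
  dat <- profile |> dplyr::inner_join(clinical, by = "sample_id")
  ggplot(dat, aes(
    x = factor(.data[[group]], c(FALSE, TRUE), c("wild type", "mutated")),
    y = .data[[fraction]]
  )) +
    geom_violin(fill = "grey85") +
    geom_jitter(width = 0.08, height = 0, size = 1) +
    labs(x = group, y = fraction) +
    theme_minimal()
}

#' G-score and q-value track of an MCR scan
#'
#' @param object An `mcr_scan` object.
#' @param ... Unused.
#' @return A ggplot object: per-marker G-scores (amplification up, deletion
#'   down) facetted by chromosome, with significant MCRs marked.
#' @method autoplot mcr_scan
#' @export
autoplot.mcr_scan <- function(object, ...) {
  sc <- object$scores |>
    tidyr::pivot_longer(c("g_amp", "g_del"),
      names_to = "direction",
      values_to = "g", names_prefix = "g_"
    ) |>
    mutate(g = ifelse(.data$direction == "del", -.data$g, .data$g))
  p <- ggplot(sc, aes(
    x = .data$pos / 1e6, y = .data$g, colour = .data$direction
  )) +
    geom_line(linewidth = 0.3) +
    facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x", space = "free_x") +
    labs(
      x = "position (Mb)", y = "G-score (del down)",
      title = sprintf(
        "Recurrent alteration scan (%d samples, %d permutations)",
        object$n_samples, object$n_perm
      )
    ) +
    theme_minimal()
  if (nrow(object$mcrs) > 0) {
    marks <- object$mcrs |>
      mutate(y = ifelse(.data$direction == "del", -.data$g_score, .data$g_score))
    p <- p + geom_point(
      data = marks,
      aes(x = (.data$start + .data$end) / 2e6, y = .data$y),
      colour = "black", shape = 17, size = 2
    )
  }
  p
}

#' Kaplan-Meier curve plot
#'
#' @param object A `km_logrank` object.
#' @param ... Unused.
#' @return A ggplot step plot of the two survival curves with the log-rank p
#'   in the title.
#' @method autoplot km_logrank
#' @export
autoplot.km_logrank <- function(object, ...) {
  curves <- object$curves |>
    group_by(.data$group) |>
    dplyr::group_modify(~ bind_rows(
      tibble(time = 0, n_risk = max(.x$n_risk), n_event = 0L, surv = 1),
      .x |> select("time", "n_risk", "n_event", "surv")
    )) |>
    ungroup()
  ggplot(curves, aes(x = .data$time, y = .data$surv, colour = .data$group)) +
    geom_step() +
    labs(
      x = "time (days)", y = "survival probability",
      title = sprintf("Log-rank p = %.3g", object$p_value)
    ) +
    ggplot2::ylim(0, 1) +
    theme_minimal()
}
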