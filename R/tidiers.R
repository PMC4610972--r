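#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an MCR scan
#'
#' @param x An `mcr_scan` object.
#' @param ... Unused.
#' @return The MCR tibble (one row per significant region, both directions).
#' @method tidy mcr_scan
#' @export
tidy.mcr_scan <- function(x, ...) x$mcrs

#' One-row summary of an MCR scan
#'
#' @inheritParams tidy.mcr_scan
#' @return Tibble with marker/permutation counts and per-direction MCR
#'   totals.
#' @method glance mcr_scan
#' @export
glance.mcr_scan <- function(x, ...) {
  tibble(
    n_samples = x$n_samples, n_markers = nrow(x$scores),
    n_perm = x$n_perm, alpha = x$alpha,
    n_mcr_amp = sum(x$mcrs$direction == "amp"),
    n_mcr_del = sum(x$mcrs$direction == "del")
  )
}

#' Tidy a rank-sum test
#'
#' @param x A `rank_sum_test` object.
#' @param ... Unused.
#' @return One-row tibble with the U statistic, p-value and group medians.
#' @method tidy rank_sum_test
#' @export
tidy.rank_sum_test <- function(x, ...) {
  tibble(
    statistic = x$statistic, p_value = x$p_value,
    median_x = unname(x$medians["x"]), median_y = unname(x$medians["y"]),
    n_x = unname(x$n["x"]), n_y = unname(x$n["y"]), method = x$method
  )
}

#' @rdname tidy.rank_sum_test
#' @method glance rank_sum_test
#' @export
glance.rank_sum_test <- function(x, ...) tidy(x)

#' Tidy a contingency test result
#'
#' @param x A `contingency_result` object.
#' @param ... Unused.
#' @return One-row tibble with p-value, odds ratio and method.
#' @method tidy contingency_result
#' @export
tidy.contingency_result <- function(x, ...) {
  tibble(
    p_value = x$p_value, odds_ratio = x$odds_ratio,
    or_haldane = x$or_haldane, method = x$method,
    degenerate = x$degenerate
  )
}

#' Tidy Kaplan-Meier curves
#'
#' @param x A `km_logrank` object.
#' @param ... Unused.
#' @return Step-function tibble (`group`, `time`, `n_risk`, `n_event`,
#'   `surv`).
#' @method tidy km_logrank
#' @export
tidy.km_logrank <- function(x, ...) x$curves

#' One-row summary of a log-rank comparison
#'
#' @inheritParams tidy.km_logrank
#' @return Tibble with the chi-square statistic and p-value.
#' @method glance km_logrank
#' @export
glance.km_logrank <- function(x, ...) {
  tibble(chisq = x$chisq, p_value = x$p_value)
}
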