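#' Mann-Whitney U (Wilcoxon rank-sum) comparison of two groups
#'
#' Computes the U statistic and a two-sided p-value. For small samples
#' (`length(x) + length(y) <= max_exact`) an exact p-value is computed by
#' complete enumeration of all group labelings (handles ties); otherwise the
#' tie-corrected normal approximation with continuity correction is used
#' (the correction keeps the approximation within ~0.01 of the exact
#' enumeration at moderate sample sizes).
#'
#' @param x,y Numeric vectors (both nonempty).
#' @param max_exact Largest combined sample size for the exact path
#'   (default 12).
#' @return An object of class `rank_sum_test`: list with `statistic` (U for
#'   the first group), `p_value`, `method`, `medians` (named length-2) and
#'   the group sizes.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value # exact, 0.1
#' @export
mann_whitney <- function(x, y, max_exact = 12) {
  if (length(x) == 0 || length(y) == 0) abort("both groups must be nonempty")
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (max(c(x, y)) == min(c(x, y))) {
    p <- 1
    method <- "degenerate (all values identical)"
  } else if (nx + ny <= max_exact) {
    p <- mw_exact_p(x, y)
    method <- "exact enumeration"
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    p <- wt$p.value
    if (!is.finite(p)) p <- 1
    method <- "normal approximation, tie- and continuity-corrected"
  }
  structure(
    list(
      statistic = U, p_value = p, method = method,
      medians = c(x = median(x), y = median(y)),
      n = c(x = nx, y = ny)
    ),
    class = "rank_sum_test"
  )
}

# Exact two-sided rank-sum p by complete enumeration of all C(nx+ny, nx)
# assignments of the pooled values to the first group. Two-sided p doubles
# the smaller tail (capped at 1), measured on U.
mw_exact_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(length(pooled), nx)
  U_all <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
  lo <- mean(U_all <= U_obs)
  hi <- mean(U_all >= U_obs)
  min(1, 2 * min(lo, hi))
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat("Mann-Whitney U =", x$statistic, " p =", signif(x$p_value, 4), "\n")
  cat(
    " medians:", signif(x$medians[1], 4), "vs", signif(x$medians[2], 4),
    " (n =", x$n[1], "vs", x$n[2], ";", x$method, ")\n"
  )
  invisible(x)
}

#' 2x2 contingency test with automatic method choice
#'
#' Tests independence in a 2x2 table. `method = "auto"` (default) uses
#' Fisher's exact test when any expected cell count is below 5 or any
#' observed cell is zero, and the chi-square test without continuity
#' correction otherwise. The odds ratio is
#' the cross-product `ad/bc`, with a Haldane correction (+0.5 to every cell)
#' when any cell is zero.
#'
#' @param a,b,c,d Nonnegative integer cell counts (rows = group, columns =
#'   outcome), or `a` may be a 2x2 matrix.
#' @param method `"auto"`, `"chi2"` or `"fisher"`.
#' @return An object of class `contingency_result`: list with `p_value`,
#'   `odds_ratio`, `or_haldane` (logical), `method`, `table` and
#'   `degenerate` (logical; degenerate margins give p = 1 and an undefined
#'   odds ratio).
#' @export
contingency_test <- function(a, b = NULL, c = NULL, d = NULL,
                             method = c("auto", "chi2", "fisher")) {
  method <- match.arg(method)
  tab <- if (is.matrix(a)) a else matrix(c(a, c, b, d), 2, 2)
  if (any(tab < 0) || sum(tab) == 0) abort("need nonnegative counts, total > 0")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(structure(
      list(
        p_value = 1, odds_ratio = NA_real_, or_haldane = FALSE,
        method = "degenerate margin", table = tab, degenerate = TRUE
      ),
      class = "contingency_result"
    ))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (method == "auto") {
    method <- if (any(expected < 5) || any(tab == 0)) "fisher" else "chi2"
  }
  p <- if (method == "fisher") {
    fisher.test(tab)$p.value
  } else {
    suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  }
  haldane <- any(tab == 0)
  tt <- if (haldane) tab + 0.5 else tab
  or <- (tt[1, 1] * tt[2, 2]) / (tt[1, 2] * tt[2, 1])
  structure(
    list(
      p_value = p, odds_ratio = or, or_haldane = haldane,
      method = method, table = tab, degenerate = FALSE
    ),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(
    "2x2 test (", x$method, "): p =", signif(x$p_value, 4),
    " OR =", signif(x$odds_ratio, 4),
    if (x$or_haldane) "(Haldane-corrected)" else "", "\n"
  )
  invisible(x)
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per group and the log-rank chi-square
#' test (1 df) for a two-group comparison.
#'
#' @param times Nonnegative follow-up times.
#' @param events Logical (or 0/1) event indicators.
#' @param groups Two-level grouping vector.
#' @return An object of class `km_logrank`: list with `curves` (tibble:
#'   group, time, n_risk, n_event, surv), `p_value`, `chisq` and `fit` (the
#'   underlying [survival::survfit] object). All-censored input gives
#'   p = 1 with a warning.
#' @export
km_logrank <- function(times, events, groups) {
  if (any(times < 0, na.rm = TRUE)) abort("times must be nonnegative")
  events <- as.logical(events)
  keep <- !is.na(times) & !is.na(events) & !is.na(groups)
  times <- times[keep]
  events <- events[keep]
  groups <- as.factor(droplevels(as.factor(groups[keep])))
  if (nlevels(groups) != 2) abort("groups must have exactly two levels")
  df <- data.frame(time = times, event = as.integer(events), group = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  if (sum(df$event) == 0) {
    warn("no events observed; log-rank p set to 1")
    p <- 1
    chisq <- 0
  } else {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    chisq <- sd$chisq
    p <- 1 - pchisq(chisq, df = 1)
  }
  strata <- rep(names(fit$strata), fit$strata)
  curves <- tibble(
    group = sub("^group=", "", strata),
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    surv = fit$surv
  )
  structure(
    list(curves = curves, p_value = p, chisq = chisq, fit = fit),
    class = "km_logrank"
  )
}

#' @export
print.km_logrank <- function(x, ...) {
  cat("log-rank chi-square =", signif(x$chisq, 4), " p =", signif(x$p_value, 4), "\n")
  invisible(x)
}

#' Cohort-level clinical association report
#'
#' Reproduces the study-style association battery from a per-sample
#' instability profile and a clinical table: rank-sum comparisons of the
#' gain/loss/CNNLOH/overall fractions by TP53 mutation status, a severity
#' (overall fraction >= 0.5) by lymph-node-metastasis contingency test
#' (both margin conditionings reported), a severity by TP53 contingency
#' test, and a Kaplan-Meier/log-rank comparison of survival by severity.
#'
#' @param profile Tibble from [instability_fractions()] (`$profile`).
#' @param clinical Clinical tibble (see [read_clinical()]).
#' @return An object of class `clinical_assoc`: list with `fraction_tests`
#'   (tidy tibble of the four rank-sum tests), `severity_ln` and
#'   `severity_tp53` (`contingency_result`s), `ln_percentages` (both
#'   conditionings of the severity/metastasis 2x2), and `survival`
#'   (`km_logrank`, `NULL` when survival columns are absent).
#' @export
associate_clinical <- function(profile, clinical) {
  dat <- profile |> dplyr::inner_join(clinical, by = "sample_id")
  if (nrow(dat) == 0) abort("no overlapping sample_ids")
  fraction_tests <- purrr::map(
    c("frac_gain", "frac_loss", "frac_cnnloh", "frac_overall"),
    function(v) {
      mt <- mann_whitney(
        dat[[v]][dat$tp53_mutated],
        dat[[v]][!dat$tp53_mutated]
      )
      tibble(
        fraction = sub("frac_", "", v),
        median_mutated = unname(mt$medians["x"]),
        median_wildtype = unname(mt$medians["y"]),
        statistic = mt$statistic, p_value = mt$p_value
      )
    }
  ) |> list_rbind()
  tab_ln <- table(
    severe = factor(dat$severe, c(TRUE, FALSE)),
    ln = factor(dat$ln_metastasis, c(TRUE, FALSE))
  )
  severity_ln <- contingency_test(unclass(tab_ln))
  # both conditionings of the printed percentages
  ln_percentages <- tibble(
    conditioning = c("ln_met_given_severity", "severity_given_ln_met"),
    pct_severe = c(
      100 * tab_ln[1, 1] / sum(tab_ln[1, ]),
      100 * tab_ln[1, 1] / sum(tab_ln[, 1])
    ),
    pct_low = c(
      100 * tab_ln[2, 1] / sum(tab_ln[2, ]),
      100 * tab_ln[1, 2] / sum(tab_ln[, 2])
    )
  )
  tab_tp53 <- table(
    severe = factor(dat$severe, c(TRUE, FALSE)),
    tp53 = factor(dat$tp53_mutated, c(TRUE, FALSE))
  )
  severity_tp53 <- contingency_test(unclass(tab_tp53))
  surv <- NULL
  if (all(c("survival_days", "event") %in% names(dat)) &&
    any(!is.na(dat$survival_days))) {
    surv <- km_logrank(dat$survival_days, dat$event, dat$severe)
  }
  structure(
    list(
      fraction_tests = fraction_tests,
      severity_ln = severity_ln, severity_tp53 = severity_tp53,
      ln_percentages = ln_percentages,
      survival = surv
    ),
    class = "clinical_assoc"
  )
}

#' @export
print.clinical_assoc <- function(x, ...) {
  cat("Instability fractions by TP53 status (rank-sum):\n")
  print(x$fraction_tests)
  cat("\nSeverity x LN metastasis: ")
  print(x$severity_ln)
  cat("Severity x TP53: ")
  print(x$severity_tp53)
  if (!is.null(x$survival)) {
    cat("Survival by severity: ")
    print(x$survival)
  }
  invisible(x)
}
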