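test_that("rank-sum exact path matches complete enumeration", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1) # 2 * 1/20 labelings
  expect_match(r$method, "exact")

  # identical multisets: perfect symmetry
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # all values identical across groups
  expect_equal(mann_whitney(rep(2, 4), rep(2, 5))$p_value, 1)

  # cross-check the exact path against wilcox.test's exact p (no ties)
  set.seed(10)
  for (i in 1:20) {
    x <- rnorm(sample(3:6, 1))
    y <- rnorm(sample(3:6, 1))
    ours <- mann_whitney(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic))
  }
})

test_that("normal approximation stays close to exact enumeration from n = 10", {
  set.seed(22)
  for (i in 1:5) {
    x <- rnorm(10)
    y <- rnorm(10, 0.5)
    exact <- mann_whitney(x, y, max_exact = 20)$p_value
    approx <- mann_whitney(x, y, max_exact = 0)$p_value
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("rank-sum type-I error is calibrated at the nominal level", {
  set.seed(77)
  rej <- vapply(1:800, function(i) {
    mann_whitney(rnorm(28), rnorm(27))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("contingency tests pick the method from expected counts", {
  # (10,0,0,10): small expected cells -> Fisher, matched against the exact
  # hypergeometric tail computed directly
  r <- contingency_test(10, 0, 0, 10)
  expect_equal(r$method, "fisher")
  expect_equal(r$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(r$or_haldane)
  expect_equal(r$odds_ratio, 10.5 * 10.5 / (0.5 * 0.5))

  # perfect independence
  r2 <- contingency_test(5, 5, 5, 5)
  expect_equal(r2$p_value, 1)
  expect_equal(r2$odds_ratio, 1)

  # large table: chi-square without continuity correction; frozen hand value
  r3 <- contingency_test(21, 7, 9, 18)
  expect_equal(r3$method, "chi2")
  expect_lt(abs(r3$p_value - 0.0019), 1e-4)
  # agreement with Fisher within the usual approximation slack
  r3f <- contingency_test(21, 7, 9, 18, method = "fisher")
  expect_lt(abs(r3$p_value - r3f$p_value), 0.005)

  # invariance under simultaneous row and column swaps
  r4 <- contingency_test(18, 9, 7, 21)
  expect_equal(r4$p_value, r3$p_value)
  expect_equal(r4$odds_ratio, r3$odds_ratio)

  # degenerate margin
  r5 <- contingency_test(0, 0, 3, 4)
  expect_true(r5$degenerate)
  expect_equal(r5$p_value, 1)
  expect_true(is.na(r5$odds_ratio))
})

test_that("Kaplan-Meier curves and the log-rank test behave as estimators", {
  # identical event patterns in both groups: p = 1
  t1 <- c(1, 2, 3, 4, 5)
  same <- km_logrank(c(t1, t1), rep(TRUE, 10), rep(c("a", "b"), each = 5))
  expect_equal(same$p_value, 1, tolerance = 1e-9)

  # complete separation: group a dies at 1, group b at 2
  sep <- km_logrank(
    rep(c(1, 2), each = 10), rep(TRUE, 20),
    rep(c("a", "b"), each = 10)
  )
  expect_lt(sep$p_value, 0.01)

  # curves are non-increasing step functions starting at 1 after time zero
  set.seed(9)
  km <- km_logrank(rexp(40), runif(40) < 0.7, rep(c("a", "b"), 20))
  curves <- tidy(km)
  for (g in unique(curves$group)) {
    s <- curves$surv[curves$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_lte(max(s), 1)
  }

  # all-censored input warns and returns p = 1
  expect_warning(
    allc <- km_logrank(c(1, 2, 3, 4), rep(FALSE, 4), c("a", "a", "b", "b")),
    "no events"
  )
  expect_equal(allc$p_value, 1)
  expect_error(km_logrank(c(-1, 2), c(TRUE, TRUE), c("a", "b")), "nonnegative")
})

test_that("the cohort association battery couples to the generator design", {
  co <- simulate_cohort(sim_config(), seed = 31)
  # truth fractions stand in for the profile: association logic is the target
  assoc <- associate_clinical(co$truth$fractions, co$clinical)
  ft <- assoc$fraction_tests
  expect_equal(ft$fraction, c("gain", "loss", "cnnloh", "overall"))
  # TP53-mutated group is enriched for unstable genomes by construction
  expect_true(all(ft$median_mutated >= ft$median_wildtype))
  expect_lt(ft$p_value[ft$fraction == "overall"], 0.05)
  expect_s3_class(assoc$severity_ln, "contingency_result")
  expect_equal(nrow(assoc$ln_percentages), 2)
  expect_s3_class(assoc$survival, "km_logrank")
  expect_error(
    associate_clinical(
      co$truth$fractions,
      dplyr::mutate(co$clinical, sample_id = paste0("x", sample_id))
    ),
    "overlapping"
  )
})

test_that("severity-metastasis association rejects in most replicate cohorts", {
  hits <- vapply(1:10, function(s) {
    co <- simulate_cohort(
      sim_config(
        n_chroms = 2, probes_per_chrom = 300, min_cnnloh_probes = 150,
        recurrent_lesions = tibble::tibble(
          chrom = "2", start_probe = 101L, n_probes = 60L,
          direction = "del", frequency = 17 / 55
        )
      ),
      seed = 1000 + s
    )
    assoc <- associate_clinical(co$truth$fractions, co$clinical)
    assoc$severity_ln$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
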