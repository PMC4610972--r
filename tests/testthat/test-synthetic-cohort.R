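test_that("expected BAF and LRR follow the purity mixture model", {
  expect_equal(expected_baf("het", 1, 1, 1), 0.5)
  expect_equal(expected_baf("het", 2, 0, 1), 0)
  expect_equal(expected_baf("het", 2, 0, 0.7), 0.15) # (0 + 0.3) / (1.4 + 0.6)
  expect_equal(expected_baf("homA", 3, 0, 0.4), 0)
  expect_equal(expected_baf("homB", 0, 3, 0.4), 1)
  expect_true(is.na(expected_baf("het", 0, 0, 1))) # zero total dose
  expect_error(expected_baf("het", -1, 1, 1), "nonnegative")
  expect_error(expected_baf("het", 1, 1, 0), "purity")

  expect_equal(expected_lrr(1, 1, 0.3), 0)
  expect_equal(expected_lrr(2, 1, 1), log2(1.5))
  expect_equal(expected_lrr(2, 2, 0.5), log2(1.5))
  expect_equal(expected_lrr(0, 0, 0.5), -1) # only the normal moiety remains
})

test_that("sim_config validates mixtures, frequencies and feasibility", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(
    sim_config(instability_mixture = tibble::tibble(weight = c(0.5, 0.4), target = c(0.1, 0.2))),
    "sum to 1"
  )
  expect_error(
    sim_config(instability_mixture = tibble::tibble(weight = 1, target = 0.99)),
    "nfeasible"
  )
  expect_error(
    sim_config(recurrent_lesions = tibble::tibble(
      chrom = "1", start_probe = 1L, n_probes = 10L, direction = "amp",
      frequency = 1.2
    )),
    "frequencies"
  )
  expect_error(sim_config(probes_per_chrom = 50), "at least 100")
})

test_that("simulation is deterministic given the seed", {
  cfg <- tiny_config()
  a <- simulate_cohort(cfg, seed = 42)
  b <- simulate_cohort(cfg, seed = 42)
  expect_identical(a$probes, b$probes)
  expect_identical(a$truth, b$truth)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$somatic_sites, b$somatic_sites)
  c <- simulate_cohort(cfg, seed = 43)
  expect_false(identical(a$probes$baf, c$probes$baf))
})

test_that("truth bookkeeping is exact and carrier counts are exact", {
  cfg <- sim_config(
    n_samples = 55, n_chroms = 2, probes_per_chrom = 300,
    min_cnnloh_probes = 150,
    recurrent_lesions = tibble::tibble(
      chrom = "2", start_probe = 101L, n_probes = 60L,
      direction = "del", frequency = 17 / 55
    )
  )
  co <- simulate_cohort(cfg, seed = 9)
  # exact carrier count: round(17/55 * 55) = 17
  carriers <- co$truth$segments |>
    dplyr::filter(state == "deletion", chrom == "2") |>
    dplyr::distinct(sample_id)
  expect_equal(nrow(carriers), 17)
  # fractions recomputed from the segment table match the bookkeeping exactly
  N <- cfg$n_chroms * cfg$probes_per_chrom
  recomputed <- co$truth$segments |>
    dplyr::mutate(len = probe_to - probe_from + 1) |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(frac = sum(len) / N)
  merged <- dplyr::left_join(co$truth$fractions, recomputed, by = "sample_id") |>
    dplyr::mutate(frac = dplyr::coalesce(frac, 0))
  expect_equal(merged$frac_overall, merged$frac, tolerance = 1e-12)
})

test_that("a zero-fraction mixture yields an unaltered cohort", {
  cfg <- sim_config(
    n_samples = 3, n_chroms = 2, probes_per_chrom = 300,
    instability_mixture = tibble::tibble(weight = 1, target = 0),
    recurrent_lesions = tibble::tibble(
      chrom = character(0), start_probe = integer(0), n_probes = integer(0),
      direction = character(0), frequency = numeric(0)
    )
  )
  co <- simulate_cohort(cfg, seed = 2)
  expect_equal(co$truth$fractions$frac_overall, rep(0, 3))
  expect_equal(nrow(co$truth$segments), 0)
})

test_that("mean BAF at het CNNLOH markers converges to the expectation with depth", {
  # binomial noise: empirical mean within 3 binomial SEs of the model value
  for (depth in c(50, 500)) {
    cfg <- tiny_config(baf_read_depth = depth, purity = 0.7)
    co <- simulate_cohort(cfg, seed = 21)
    tr <- truth_probe_states(co)
    het_cnnloh <- co$probes |>
      dplyr::mutate(true_state = tr$true_state) |>
      dplyr::filter(genotype == "het", true_state == "CNNLOH")
    expect_gt(nrow(het_cnnloh), 100)
    # haplotype orientation is random: fold BAF about 0.5
    folded <- pmin(het_cnnloh$baf, 1 - het_cnnloh$baf)
    mu <- expected_baf("het", 2, 0, 0.7)
    se <- sqrt(mu * (1 - mu) / depth / nrow(het_cnnloh))
    expect_lt(abs(mean(folded) - mu), 3 * se + 1e-9)
  }
})

test_that("somatic site tables encode the intended artifact structure", {
  co <- simulate_cohort(tiny_config(), seed = 3)
  sites <- co$somatic_sites
  expect_true(all(sites$tumor_alt_q20 <= sites$tumor_alt_total))
  expect_true(all(sites$tumor_alt_total <= sites$tumor_depth))
  expect_true(all(sites$blood_alt_total <= sites$blood_depth))
  expect_true(all(sites$blood_alt_total[sites$truth == "somatic"] == 0))
  expect_true(all(sites$tumor_depth[sites$truth == "low_coverage"] < 10))
  expect_true(all(sites$blood_alt_total[sites$truth == "germline"] >= 1))
})
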