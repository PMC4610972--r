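test_that("tag trimming follows the adjacent-low-quality rule", {
  # no adjacent low-quality pair: unchanged
  t1 <- trim_tag(strrep("A", 75), rep(30, 75))
  expect_true(t1$kept && !t1$trimmed)
  expect_equal(nchar(t1$bases), 75)

  # a single isolated low base never triggers trimming
  q <- rep(30, 75)
  q[6] <- 15
  t2 <- trim_tag(strrep("C", 75), q)
  expect_true(t2$kept && !t2$trimmed)
  expect_equal(t2$quals, q)

  # adjacent pair at 0-based 10,11: keep 10 bases -> below 35 -> rejected
  q <- rep(30, 40)
  q[11:12] <- 15
  t3 <- trim_tag(strrep("G", 40), q)
  expect_false(t3$kept)
  expect_true(t3$trimmed)

  # pair late in a long tag: trimmed but kept
  q <- rep(30, 75)
  q[51:52] <- 10
  t4 <- trim_tag(strrep("T", 75), q)
  expect_true(t4$kept && t4$trimmed)
  expect_equal(nchar(t4$bases), 50)

  # empty tag rejected; mismatched lengths error
  expect_false(trim_tag("", integer(0))$kept)
  expect_error(trim_tag("ACGT", c(30, 30)), "same length")
})

test_that("trimming is idempotent", {
  set.seed(5)
  n_kept <- 0
  for (i in 1:50) {
    n <- sample(40:80, 1)
    # mostly good bases with sporadic low-quality ones, so a fair share of
    # tags survive trimming
    q <- sample(c(15L, 30L), n, replace = TRUE, prob = c(0.15, 0.85))
    t1 <- trim_tag(strrep("A", n), q)
    if (!t1$kept) next
    n_kept <- n_kept + 1
    t2 <- trim_tag(t1$bases, t1$quals)
    expect_identical(t2$bases, t1$bases)
    expect_identical(t2$quals, t1$quals)
  }
  expect_gt(n_kept, 10)
})

test_that("somatic filter applies the three rules in order", {
  site <- function(td, q20, at, bd, ba) {
    tibble::tibble(
      tumor_depth = td, tumor_alt_q20 = q20, tumor_alt_total = at,
      blood_depth = bd, blood_alt_total = ba
    )
  }
  # coverage rule first (tumor side)
  r <- filter_somatic(site(9, 5, 5, 30, 0))
  expect_false(r$pass)
  expect_equal(r$reason, "coverage")
  # coverage rule (blood side)
  expect_equal(filter_somatic(site(30, 10, 10, 9, 0))$reason, "coverage")
  # 12/50 = 0.24 >= 0.20 and clean blood -> pass
  r2 <- filter_somatic(site(50, 12, 12, 40, 0))
  expect_true(r2$pass)
  expect_true(is.na(r2$reason))
  # mutant allele in blood -> fail with the blood rule
  expect_equal(filter_somatic(site(50, 30, 30, 40, 1))$reason, "blood_contains_mutant")
  # zero depth: coverage failure, no division error
  expect_equal(filter_somatic(site(0, 0, 0, 30, 0))$reason, "coverage")
  # alternative denominator: 20% of alt reads being Q>=20 passes a site the
  # depth-denominated filter rejects
  weak <- site(50, 4, 16, 40, 0)
  expect_false(filter_somatic(weak)$pass)
  expect_true(filter_somatic(weak, denominator = "alt_reads")$pass)
})

test_that("the filter pass-set shrinks as thresholds tighten", {
  co <- simulate_cohort(tiny_config(), seed = 8)
  sites <- co$somatic_sites
  base_pass <- sum(filter_somatic(sites)$pass)
  for (mc in c(12, 15, 20)) {
    expect_lte(sum(filter_somatic(sites, min_cov = mc)$pass), base_pass)
  }
  for (fr in c(0.25, 0.3, 0.4)) {
    expect_lte(sum(filter_somatic(sites, min_alt_frac = fr)$pass), base_pass)
  }
  # nested thresholds are monotone against each other too
  expect_lte(
    sum(filter_somatic(sites, min_cov = 20, min_alt_frac = 0.4)$pass),
    sum(filter_somatic(sites, min_cov = 15, min_alt_frac = 0.3)$pass)
  )
})

test_that("all true somatic sites with adequate support are recovered", {
  co <- simulate_cohort(tiny_config(), seed = 13)
  flagged <- filter_somatic(co$somatic_sites)
  eligible <- flagged$truth == "somatic" & flagged$tumor_depth >= 10 &
    flagged$tumor_alt_q20 / flagged$tumor_depth >= 0.25
  expect_true(all(flagged$pass[eligible])) # 100% recall on eligible truth
  # artifacts are rejected
  expect_false(any(flagged$pass[flagged$truth != "somatic"]))
})

test_that("mutation spectrum percentages use raw rounding", {
  mut <- tibble::tibble(
    sample_id = rep("s", 108),
    class = rep(
      c("missense", "nonsense", "indel", "splice-site", "read-through"),
      c(80, 12, 14, 1, 1)
    )
  )
  sp <- summarize_mutation_spectrum(mut)$spectrum
  expect_equal(sp$percent[sp$class == "missense"], 74.07)
  expect_equal(sp$percent[sp$class == "nonsense"], 11.11)
  expect_equal(sp$percent[sp$class == "indel"], 12.96)
  expect_equal(sp$percent[sp$class == "splice-site"], 0.93)

  one <- summarize_mutation_spectrum(
    tibble::tibble(sample_id = "a", class = "missense")
  )
  expect_equal(one$spectrum$percent, 100)
  two <- summarize_mutation_spectrum(
    tibble::tibble(sample_id = c("a", "b"), class = c("missense", "indel"))
  )
  expect_equal(two$spectrum$percent, c(50, 50))
  empty <- summarize_mutation_spectrum(tibble::tibble(
    sample_id = character(0), class = character(0)
  ))
  expect_equal(nrow(empty$spectrum), 0)
  expect_error(
    summarize_mutation_spectrum(tibble::tibble(sample_id = "a", class = "weird")),
    "unknown consequence class"
  )
})

test_that("pooled mutation rates pool numerators and denominators", {
  expect_equal(
    pooled_mutation_rate(tibble::tibble(mutated = c(5, 23), total = c(9, 46))),
    round(100 * 28 / 55, 2)
  )
  expect_equal(
    pooled_mutation_rate(
      tibble::tibble(mutated = c(2, 2), total = c(9, 120)),
      digits = 1
    ),
    3.1
  )
  expect_equal(pooled_mutation_rate(tibble::tibble(mutated = 0, total = 100)), 0)
  expect_error(pooled_mutation_rate(tibble::tibble(mutated = 1, total = 0)))
  expect_error(
    pooled_mutation_rate(tibble::tibble(mutated = 5, total = 4)),
    "\\[0, total\\]"
  )
})
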