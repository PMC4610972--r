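test_that("array MAF maps BAF onto the minor/major ratio scale", {
  expect_equal(array_maf(0.5), 1)
  expect_equal(array_maf(0), 0)
  expect_equal(array_maf(1), 0)
  expect_equal(array_maf(0.3), 0.3 / 0.7)
  expect_equal(array_maf(0.7), 0.3 / 0.7) # symmetric about 0.5
  expect_error(array_maf(1.2), "\\[0, 1\\]")
})

make_loh_probes <- function(low, chrom = "1") {
  # low: logical, TRUE -> baf far from 0.5 (maf ~ 0.11), FALSE -> balanced
  n <- length(low)
  tibble::tibble(
    chrom = chrom, pos = 3000L * seq_len(n),
    baf = ifelse(low, 0.1, 0.5)
  )
}

test_that("LOH windows use the strict more-than-80% rule", {
  # 81/100 low-MAF SNPs -> flagged; raw mode keeps window semantics
  r81 <- call_loh(make_loh_probes(c(rep(TRUE, 81), rep(FALSE, 19))),
    refine_edges = FALSE
  )
  expect_equal(nrow(r81), 1)
  r80 <- call_loh(make_loh_probes(c(rep(TRUE, 80), rep(FALSE, 20))),
    refine_edges = FALSE
  )
  expect_equal(nrow(r80), 0)
  # all balanced: no LOH anywhere
  expect_equal(nrow(call_loh(make_loh_probes(rep(FALSE, 300)))), 0)
  # below one window of informative SNPs: no calls
  expect_equal(nrow(call_loh(make_loh_probes(rep(TRUE, 99)))), 0)
})

test_that("LOH calling matches the brute-force window oracle in raw mode", {
  th <- state_thresholds()
  for (seed in 1:60) {
    probes <- random_loh_probes(n = sample(120:500, 1), seed = seed)
    got <- call_loh(probes, refine_edges = FALSE)
    flags <- array_maf(probes$baf) <= th$loh_maf_ceiling
    oracle <- brute_force_windows(flags, 100, 0.8)
    expect_equal(got$from_snp, oracle$from, info = paste("seed", seed))
    expect_equal(got$to_snp, oracle$to, info = paste("seed", seed))
  }
})

test_that("refined LOH regions localise edges and split bridged gaps", {
  # noiseless: refined edges are exact
  lowv <- c(rep(FALSE, 60), rep(TRUE, 150), rep(FALSE, 90))
  r <- call_loh(make_loh_probes(lowv))
  expect_equal(r$from_snp, 61)
  expect_equal(r$to_snp, 210)
  # two regions bridged across a 25-SNP balanced gap are separated
  lowv2 <- c(rep(TRUE, 120), rep(FALSE, 25), rep(TRUE, 120), rep(FALSE, 50))
  r2 <- call_loh(make_loh_probes(lowv2))
  expect_equal(nrow(r2), 2)
  expect_equal(r2$from_snp, c(1, 146))
  expect_equal(r2$to_snp, c(120, 265))
  # raw mode reports them as one merged span
  expect_equal(nrow(call_loh(make_loh_probes(lowv2), refine_edges = FALSE)), 1)
})

test_that("informative probe selection needs genotypes or blood BAF", {
  pr <- tibble::tibble(chrom = "1", pos = 1:4 * 1000L, baf = c(0.5, 0, 1, 0.5))
  expect_error(informative_probes(pr), "genotype")
  pr$genotype <- c("het", "homA", "homB", "het")
  expect_equal(nrow(informative_probes(pr)), 2)
  pr$genotype <- NULL
  pr$blood_baf <- c(0.5, 0.02, 0.98, 0.6)
  expect_equal(nrow(informative_probes(pr)), 2)
})

test_that("six-state classification closes every printed boundary", {
  th <- state_thresholds()
  # LRR thresholds, inclusive as printed
  expect_equal(classify_segment(0.074, 0, th), "normal")
  expect_equal(classify_segment(0.075, 0, th), "gain")
  expect_equal(classify_segment(0.10, 0, th), "gain")
  expect_equal(classify_segment(0.149, 0, th), "gain")
  expect_equal(classify_segment(0.15, 0, th), "amplification")
  expect_equal(classify_segment(-0.074, 0, th), "normal")
  expect_equal(classify_segment(-0.075, 0, th), "loss")
  expect_equal(classify_segment(-0.149, 0, th), "loss")
  expect_equal(classify_segment(-0.15, 0, th), "deletion")
  expect_equal(classify_segment(-0.20, 0, th), "deletion")
  # copy-neutral band: CNNLOH needs majority LOH overlap
  expect_equal(classify_segment(0.0, 1, th), "CNNLOH")
  expect_equal(classify_segment(0.0, 0.51, th), "CNNLOH")
  expect_equal(classify_segment(0.0, 0.5, th), "normal") # strict majority
  expect_equal(classify_segment(0.0, 0, th), "normal")
})

test_that("the six states are exhaustive and mutually exclusive", {
  th <- state_thresholds()
  set.seed(1)
  for (i in 1:200) {
    st <- classify_segment(runif(1, -2, 2), runif(1), th)
    expect_true(st %in% c(
      "normal", "gain", "loss", "CNNLOH", "amplification", "deletion"
    ))
  }
  expect_equal(coarse_state(c("amplification", "deletion", "gain", "CNNLOH")),
    c("gain", "loss", "gain", "CNNLOH"))
})

test_that("call_states splits copy-neutral segments at LOH edges", {
  # one chromosome, flat LRR, CNNLOH in the middle third
  n <- 600
  probes <- tibble::tibble(
    sample_id = "s", chrom = "1", pos = 3000L * seq_len(n),
    baf = 0.5, lrr = 0
  )
  loh <- tibble::tibble(
    sample_id = "s", chrom = "1",
    start = probes$pos[201] - 1L, end = probes$pos[400]
  )
  seg <- segment_probes(probes, center = "none")
  stated <- call_states(seg, probes, loh, center = "none")
  expect_equal(stated$state, c("normal", "CNNLOH", "normal"))
  expect_equal(stated$n_probes, c(200L, 200L, 200L))
  # without splitting, the overlap rule alone decides the whole segment
  whole <- call_states(seg, probes, loh, split_at_loh = FALSE, center = "none")
  expect_equal(nrow(whole), 1)
  expect_equal(whole$state, "normal") # 1/3 overlap is not a majority
})
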