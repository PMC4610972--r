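test_that("G-scores are frequency times exceeding amplitude", {
  # marker with amplitude 0.5 in 2 of 3 samples: G = (0.5 + 0.5)/3
  A <- matrix(c(0.5, 0.5, 0, 0, 0, 0), nrow = 3)
  expect_equal(g_scores(A, "amp")[1], 1 / 3)
  expect_equal(g_scores(A, "amp")[2], 0)
  # all-zero matrix scores zero everywhere
  expect_equal(g_scores(matrix(0, 4, 5), "amp"), rep(0, 5))
  # amplitudes below theta are gated out
  expect_equal(g_scores(matrix(0.1, 4, 5), "amp", theta = 0.15), rep(0, 5))
  # deletion direction uses the negated amplitude
  D <- matrix(c(-0.6, 0, -0.2, 0.4), nrow = 2)
  expect_equal(g_scores(D, "del"), c(0.3, 0.1))
  expect_error(g_scores(matrix(numeric(0), 0, 0), "amp"), "empty")
  expect_error(g_scores(matrix(1, 2, 2), "amp", theta = 0), "positive")
})

test_that("G-scores are invariant to sample order and monotone in carriers", {
  set.seed(7)
  A <- matrix(rnorm(20 * 50, 0, 0.3), 20, 50)
  expect_equal(g_scores(A, "amp"), g_scores(A[sample(20), ], "amp"))
  expect_equal(g_scores(A, "del"), g_scores(A[sample(20), ], "del"))
  # adding a carrier row never decreases any amp G-score
  extra <- rbind(A, rep(0.5, 50))
  expect_true(all(g_scores(extra, "amp") * 21 >= g_scores(A, "amp") * 20 - 1e-12))
})

test_that("permutation p-values are seed-deterministic with an attainable floor", {
  set.seed(11)
  A <- matrix(rnorm(15 * 120, 0, 0.2), 15, 120)
  A[, 60] <- 2 # one extreme recurrent marker
  p1 <- permutation_null(A, "amp", n_perm = 400, seed = 3)
  p2 <- permutation_null(A, "amp", n_perm = 400, seed = 3)
  expect_identical(p1, p2)
  expect_false(identical(p1, permutation_null(A, "amp", n_perm = 400, seed = 4)))
  # the extreme marker attains the minimal achievable p = 1/(1 + n_perm)
  expect_equal(p1[60], 1 / 401)
  expect_true(all(p1 >= 1 / 401 & p1 <= 1))
  expect_error(permutation_null(A, "amp", n_perm = 50), "at least 100")
})

test_that("permutation p-values are approximately uniform on an iid-noise matrix", {
  set.seed(3)
  A <- matrix(rnorm(20 * 300, 0, 0.2), 20, 300)
  p <- permutation_null(A, "amp", n_perm = 1000, seed = 4)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH q-values follow the step-up rule with monotonicity", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_qvalues(0.2), 0.2)
  expect_equal(bh_qvalues(rep(1, 5)), rep(1, 5))
  # hand case with distinct values: q_i = min over j>=i of p_j * m / j
  p <- c(0.001, 0.01, 0.03, 0.04)
  expect_equal(bh_qvalues(p), c(0.004, 0.02, 0.04, 0.04))
  expect_error(bh_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("MCR extraction finds implanted lesions and nothing on null scores", {
  set.seed(2)
  S <- 30
  M <- 200
  A <- matrix(rnorm(S * M, 0, 0.05), S, M)
  carriers <- 1:9
  A[carriers, 81:100] <- 0.8 # implanted amplification, 9/30 carriers
  markers <- tibble::tibble(chrom = "1", pos = 1000L * seq_len(M))
  G <- g_scores(A, "amp")
  p <- permutation_null(A, "amp", n_perm = 500, seed = 8)
  q <- bh_qvalues(p)
  mcrs <- extract_mcrs(G, q, A, markers, "amp")
  expect_equal(nrow(mcrs), 1)
  expect_equal(mcrs$n_carriers, 9L)
  expect_lte(mcrs$start, markers$pos[81] - 1L)
  expect_gte(mcrs$end, markers$pos[100])
  # peak within region
  expect_gte(mcrs$peak_start, mcrs$start)
  expect_lte(mcrs$peak_end, mcrs$end)
  # no significant markers -> empty result, not an error
  none <- extract_mcrs(G, rep(1, M), A, markers, "amp")
  expect_equal(nrow(none), 0)
})

test_that("two disjoint implanted lesions give two disjoint MCRs", {
  set.seed(4)
  S <- 30
  M <- 300
  A <- matrix(rnorm(S * M, 0, 0.05), S, M)
  A[1:9, 41:60] <- -0.9
  A[10:18, 201:220] <- -0.9
  markers <- tibble::tibble(chrom = "1", pos = 1000L * seq_len(M))
  G <- g_scores(A, "del")
  q <- bh_qvalues(permutation_null(A, "del", n_perm = 500, seed = 9))
  mcrs <- extract_mcrs(G, q, A, markers, "del")
  expect_equal(nrow(mcrs), 2)
  expect_true(mcrs$end[1] <= mcrs$start[2])
})

test_that("detect_mcrs masks excluded intervals", {
  set.seed(6)
  seg <- tibble::tibble(
    sample_id = rep(sprintf("s%02d", 1:20), each = 1),
    chrom = "1", start = 0L, end = 100000L,
    n_probes = 100L, state = "normal",
    mean_lrr = rep(0, 20)
  )
  probes <- tibble::tibble(chrom = "1", pos = 1000L * 1:100)
  am <- build_amplitude_matrix(seg, probes)
  expect_equal(dim(am$amplitude), c(20L, 100L))
  am2 <- build_amplitude_matrix(
    seg, probes,
    exclude = tibble::tibble(chrom = "1", start = 0L, end = 50000L)
  )
  expect_equal(ncol(am2$amplitude), 50L)
  expect_true(all(am2$markers$pos > 50000))
})
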