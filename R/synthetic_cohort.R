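#' Expected B allele frequency under an allele-specific copy-number mixture
#'
#' For a site with germline genotype `het`, `homA` or `homB`, tumor
#' allele-specific copy number `(cA, cB)` and tumor purity `rho`, the expected
#' array BAF of the tumor specimen is the B-allele dose over the total dose of
#' the tumor/normal cell mixture. Heterozygous normal cells contribute one
#' copy of each allele:
#' \deqn{BAF = \frac{\rho c_B + (1-\rho)}{\rho (c_A + c_B) + 2 (1-\rho)}.}
#' Homozygous genotypes return 0 (`homA`) or 1 (`homB`) exactly.
#'
#' @param genotype One of `"het"`, `"homA"`, `"homB"` (vectorised).
#' @param cA,cB Nonnegative integer copy numbers of the two parental alleles.
#' @param purity Tumor cell fraction in `(0, 1]`.
#' @return Expected BAF in `[0, 1]`; `NA` where the total dose is zero
#'   (homozygous-deletion marker at purity 1).
#' @examples
#' expected_baf("het", 2, 0, purity = 0.7) # 0.15
#' @export
expected_baf <- function(genotype, cA, cB, purity = 1) {
  if (any(cA < 0 | cB < 0)) abort("copy numbers must be nonnegative")
  if (any(purity <= 0 | purity > 1)) abort("purity must be in (0, 1]")
  n <- max(length(genotype), length(cA), length(cB), length(purity))
  genotype <- rep_len(genotype, n)
  cA <- rep_len(cA, n)
  cB <- rep_len(cB, n)
  purity <- rep_len(purity, n)
  denom <- purity * (cA + cB) + (1 - purity) * 2
  het <- (purity * cB + (1 - purity)) / ifelse(denom == 0, NA_real_, denom)
  out <- ifelse(genotype == "homA", 0,
    ifelse(genotype == "homB", 1, het)
  )
  out
}

#' Expected Log R ratio for a total copy number under purity dilution
#'
#' \deqn{LRR = \log_2\frac{\rho (c_A + c_B) + 2 (1-\rho)}{2}.}
#' A diploid locus gives 0 at any purity.
#'
#' @inheritParams expected_baf
#' @return Expected LRR (real; `-Inf` for homozygous deletion at purity 1).
#' @examples
#' expected_lrr(2, 1, purity = 1) # log2(1.5)
#' @export
expected_lrr <- function(cA, cB, purity = 1) {
  if (any(cA < 0 | cB < 0)) abort("copy numbers must be nonnegative")
  if (any(purity <= 0 | purity > 1)) abort("purity must be in (0, 1]")
  log2((purity * (cA + cB) + (1 - purity) * 2) / 2)
}

#' Configuration for the synthetic tumor-cohort generator
#'
#' Builds a validated configuration describing the cohort the generator
#' emulates: a ~55-sample tumor series with a bimodal-to-spread genomic
#' instability distribution, recurrent focal lesions carried by an exact
#' number of samples, purity-diluted BAF/LRR signal, and clinical covariates
#' statistically coupled to instability.
#'
#' The default instability mixture (8 samples near 0.02, 17 at 0.25, 20 at
#' 0.557 and 10 at 0.90 overall altered fraction) reproduces a cohort median
#' overall fraction of ~0.56 with 30/55 samples at or above the 0.5 "severe"
#' cut; the default composition splits alterations into gain/loss/CNNLOH at
#' 0.20/0.12/0.68, and recurrent focal lesions are carried by 17/55 samples.
#'
#' @param n_samples Number of tumor samples.
#' @param n_chroms Number of (autosome-like) chromosomes simulated.
#' @param probes_per_chrom Probes per chromosome (>= 100).
#' @param probe_spacing_bp Genomic spacing between adjacent probes.
#' @param purity Tumor cell fraction in `(0, 1]`.
#' @param lrr_noise_sd Gaussian noise SD added to expected LRR (0 = noiseless).
#' @param baf_read_depth Binomial depth for BAF noise (`Inf` = noiseless BAF).
#' @param het_prob Probability a probe is heterozygous in the germline.
#' @param instability_mixture Data frame with columns `weight` (summing to 1)
#'   and `target` (overall altered fraction per mixture class, all <= 0.98).
#' @param composition Named numeric `(gain, loss, cnnloh)` sharing out each
#'   sample's altered-fraction target; must sum to 1.
#' @param composition_jitter Dirichlet concentration for per-sample jitter of
#'   `composition` (0 disables jitter).
#' @param recurrent_lesions Data frame with columns `chrom`, `start_probe`,
#'   `n_probes`, `direction` (`"amp"`/`"del"`), `frequency`; each lesion is
#'   implanted in exactly `round(frequency * n_samples)` samples.
#' @param min_seg_probes Minimum implanted gain/loss segment length (probes).
#' @param min_cnnloh_probes Minimum implanted CNNLOH segment length (probes);
#'   kept large enough that a 100-informative-SNP LOH window fits inside.
#' @param tp53_prob Named numeric `(severe, low)`: probability of TP53
#'   mutation given severe / non-severe instability class (allocated as exact
#'   rounded counts per group).
#' @param ln_metastasis_prob Named numeric `(severe, low)`: probability of
#'   lymph-node metastasis by severity.
#' @param survival_median_days Named numeric `(severe, low)`: median survival
#'   used for the exponential event-time draw.
#' @param censor_range_days Length-2 numeric range of the uniform
#'   administrative censoring time.
#' @param n_somatic_sites,n_artifact_sites True-somatic and artifact site
#'   counts per sample in the read-count table.
#' @param shatter Optional list `(sample, chrom, arm, n_breakpoints,
#'   seg_probes)` implanting a many-breakpoint ("shattered") chromosome arm.
#' @param seed Default seed used by [simulate_cohort()].
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 55,
                       n_chroms = 8,
                       probes_per_chrom = 600,
                       probe_spacing_bp = 3000,
                       purity = 0.7,
                       lrr_noise_sd = 0.15,
                       baf_read_depth = 50,
                       het_prob = 0.3,
                       instability_mixture = tibble(
                         weight = c(8, 17, 20, 10) / 55,
                         target = c(0.02, 0.25, 0.557, 0.90)
                       ),
                       composition = c(gain = 0.20, loss = 0.12, cnnloh = 0.68),
                       composition_jitter = 30,
                       recurrent_lesions = tibble(
                         chrom = c("2", "5"),
                         start_probe = c(201L, 301L),
                         n_probes = c(80L, 80L),
                         direction = c("amp", "del"),
                         frequency = c(17 / 55, 17 / 55)
                       ),
                       min_seg_probes = 60,
                       min_cnnloh_probes = 400,
                       tp53_prob = c(severe = 0.70, low = 0.28),
                       ln_metastasis_prob = c(severe = 0.65, low = 0.25),
                       survival_median_days = c(severe = 500, low = 1100),
                       censor_range_days = c(300, 1800),
                       n_somatic_sites = 60,
                       n_artifact_sites = 45,
                       shatter = NULL,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_chroms = as.integer(n_chroms),
    probes_per_chrom = as.integer(probes_per_chrom),
    probe_spacing_bp = as.integer(probe_spacing_bp),
    purity = purity, lrr_noise_sd = lrr_noise_sd,
    baf_read_depth = baf_read_depth, het_prob = het_prob,
    instability_mixture = as_tibble(instability_mixture),
    composition = composition, composition_jitter = composition_jitter,
    recurrent_lesions = as_tibble(recurrent_lesions),
    min_seg_probes = as.integer(min_seg_probes),
    min_cnnloh_probes = as.integer(min_cnnloh_probes),
    tp53_prob = tp53_prob, ln_metastasis_prob = ln_metastasis_prob,
    survival_median_days = survival_median_days,
    censor_range_days = censor_range_days,
    n_somatic_sites = as.integer(n_somatic_sites),
    n_artifact_sites = as.integer(n_artifact_sites),
    shatter = shatter, seed = as.integer(seed)
  )
  if (abs(sum(cfg$instability_mixture$weight) - 1) > 1e-8) {
    abort("instability_mixture weights must sum to 1")
  }
  if (any(cfg$instability_mixture$target > 0.98)) {
    abort("infeasible altered-fraction target (> 0.98)")
  }
  if (any(cfg$instability_mixture$target < 0)) {
    abort("altered-fraction targets must be nonnegative")
  }
  if (cfg$probes_per_chrom < 100) {
    abort("probes_per_chrom must be at least 100")
  }
  if (nrow(cfg$recurrent_lesions) > 0) {
    if (any(cfg$recurrent_lesions$frequency < 0 |
      cfg$recurrent_lesions$frequency > 1)) {
      abort("recurrent lesion frequencies must lie in [0, 1]")
    }
    if (!all(cfg$recurrent_lesions$direction %in% c("amp", "del"))) {
      abort("recurrent lesion direction must be 'amp' or 'del'")
    }
    if (!all(cfg$recurrent_lesions$chrom %in% as.character(seq_len(cfg$n_chroms)))) {
      abort("recurrent lesion chrom outside the simulated genome")
    }
    if (any(cfg$recurrent_lesions$start_probe < 1 |
      cfg$recurrent_lesions$start_probe + cfg$recurrent_lesions$n_probes - 1 >
        cfg$probes_per_chrom)) {
      abort("recurrent lesion probe range outside the chromosome")
    }
  }
  if (abs(sum(cfg$composition) - 1) > 1e-8 ||
    !all(c("gain", "loss", "cnnloh") %in% names(cfg$composition))) {
    abort("composition must be named (gain, loss, cnnloh) and sum to 1")
  }
  structure(cfg, class = "sim_config")
}

state_copies <- function(state) {
  switch(state,
    normal = c(1L, 1L), gain = c(2L, 1L), loss = c(1L, 0L),
    CNNLOH = c(2L, 0L), amplification = c(2L, 2L), deletion = c(0L, 0L)
  )
}

# Place a segment of `len` probes into the free runs of `occupied` (logical).
# Leftover free space on either side of the placed segment is kept at 0 or at
# least `min_gap` probes, so implanted truth never forces the segmentation
# floor to merge a short spacer away; a placement may therefore expand to
# fill its gap. Returns c(from, to) probe indices or NULL if no gap fits.
place_in_gaps <- function(occupied, len, min_gap = 0L) {
  r <- rle(occupied)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(!r$values & r$lengths >= len)
  if (length(ok) == 0) {
    return(NULL)
  }
  pick <- ok[sample.int(length(ok), 1)]
  L <- r$lengths[pick]
  if (L - len < min_gap) len <- L # fill the whole gap
  slack <- L - len
  interior <- if (slack >= 2 * min_gap) (slack - 2 * min_gap + 1L) else 0L
  choices <- c(0L, slack)
  if (interior > 0) {
    choices <- c(choices, min_gap + sample.int(interior, 1) - 1L)
  }
  off <- choices[sample.int(length(choices), 1)]
  from <- starts[pick] + off
  c(from, from + len - 1L)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- alpha
  g / sum(g)
}

#' Simulate a synthetic tumor cohort with ground truth
#'
#' Generates per-sample SNP-array probe tracks (BAF/LRR), a truth set of
#' implanted allele-specific copy-number segments, a clinical table coupled to
#' genomic instability, and tumor/blood site read-count tables for somatic
#' filtering. Deterministic given `seed`.
#'
#' Per sample: an instability class is drawn by exact allocation from the
#' configured mixture; recurrent focal lesions are implanted in an exact
#' rounded number of carrier samples; non-overlapping gain/loss/CNNLOH
#' segments (log-uniform lengths) are implanted until the class target
#' altered fraction is met; BAF is emitted as `Binomial(depth, expected
#' BAF)/depth` and LRR as `Normal(expected LRR, sd)`.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return An object of class `cna_cohort`: a list with elements
#'   `probes` (tibble: sample_id, probe_id, chrom, pos, genotype, baf, lrr),
#'   `truth` (list with `segments` — implanted altered segments with
#'   allele-specific copies, 0-based half-open genomic intervals and probe
#'   index spans — and `fractions` — exact per-sample altered fractions),
#'   `clinical` (tibble) and `somatic_sites` (tibble with truth labels), plus
#'   the `config`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_samples
  P <- config$probes_per_chrom
  nc <- config$n_chroms
  spacing <- config$probe_spacing_bp
  chroms <- as.character(seq_len(nc))
  N <- P * nc
  sample_ids <- sprintf("S%02d", seq_len(n))

  # --- instability classes: exact allocation -------------------------------
  mix <- config$instability_mixture
  counts <- floor(mix$weight * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(mix$weight * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  targets <- sample(rep(mix$target, counts))
  severe_class <- targets >= 0.5

  # --- recurrent lesion carriers: exact rounded counts ---------------------
  rec <- config$recurrent_lesions
  carriers <- vector("list", nrow(rec))
  if (nrow(rec) > 0) {
    for (j in seq_len(nrow(rec))) {
      k <- round(rec$frequency[j] * n)
      carriers[[j]] <- sample.int(n, k)
    }
  }

  # --- implant segments per sample -----------------------------------------
  truth_segments <- vector("list", n)
  comp <- config$composition[c("gain", "loss", "cnnloh")]
  for (s in seq_len(n)) {
    occ <- lapply(chroms, function(ch) rep(FALSE, P))
    names(occ) <- chroms
    segs <- list()
    add_seg <- function(ch, from, to, state) {
      cc <- state_copies(state)
      segs[[length(segs) + 1]] <<- tibble(
        chrom = ch, probe_from = from, probe_to = to,
        start = (from - 1L) * spacing, end = to * spacing,
        cA = cc[1], cB = cc[2], state = state
      )
      occ[[ch]][from:to] <<- TRUE
    }
    # recurrent focal lesions first, at fixed loci
    if (nrow(rec) > 0) {
      for (j in seq_len(nrow(rec))) {
        if (s %in% carriers[[j]]) {
          st <- if (rec$direction[j] == "amp") "amplification" else "deletion"
          from <- rec$start_probe[j]
          to <- from + rec$n_probes[j] - 1L
          add_seg(rec$chrom[j], from, to, st)
        }
      }
    }
    # shattered arm (many-breakpoint option)
    sh <- config$shatter
    if (!is.null(sh) && s == sh$sample) {
      arm_from <- if (identical(sh$arm, "p")) 1L else P %/% 2L + 1L
      arm_to <- if (identical(sh$arm, "p")) P %/% 2L else P
      n_seg <- sh$n_breakpoints + 1L
      arm_len <- arm_to - arm_from + 1L
      base <- sh$seg_probes %||% 50L
      if (n_seg * base > arm_len) {
        abort("shattered arm too short for requested breakpoints")
      }
      lens <- rep(base, n_seg)
      slack <- arm_len - sum(lens)
      if (slack > 0) {
        idx <- sample.int(n_seg, slack, replace = TRUE)
        for (i in idx) lens[i] <- lens[i] + 1L
      }
      from <- arm_from
      for (i in seq_len(n_seg)) {
        to <- from + lens[i] - 1L
        if (i %% 2 == 1) add_seg(sh$chrom, from, to, "gain")
        else occ[[sh$chrom]][from:to] <- TRUE # explicit normal spacer
        from <- to + 1L
      }
    }
    # fill to the class target altered fraction
    implanted <- if (length(segs)) {
      sum(map_int(segs, ~ .x$probe_to - .x$probe_from + 1L))
    } else 0L
    budget_total <- max(0, round(targets[s] * N) - implanted)
    shares <- if (config$composition_jitter > 0) {
      rdirichlet1(config$composition_jitter * comp)
    } else {
      comp
    }
    budgets <- setNames(round(budget_total * shares), names(comp))
    min_len <- c(
      gain = config$min_seg_probes, loss = config$min_seg_probes,
      cnnloh = config$min_cnnloh_probes
    )
    # a CNNLOH budget too small for one detectable region is re-spent on
    # gain/loss so low-instability samples still meet their class target
    if (budgets["cnnloh"] < min_len["cnnloh"]) {
      gl <- comp[c("gain", "loss")] / sum(comp[c("gain", "loss")])
      budgets["gain"] <- budgets["gain"] + round(budgets["cnnloh"] * gl["gain"])
      budgets["loss"] <- budgets["loss"] + round(budgets["cnnloh"] * gl["loss"])
      budgets["cnnloh"] <- 0
    }
    gap <- config$min_seg_probes
    for (type in c("cnnloh", "gain", "loss")) {
      attempts <- 0L
      while (budgets[type] >= min_len[type] && attempts < 300L) {
        attempts <- attempts + 1L
        len <- round(exp(runif(1, log(min_len[type]), log(P))))
        len <- min(len, budgets[type], P)
        if (len < min_len[type]) len <- min_len[type]
        if (budgets[type] - len < min_len[type]) len <- min(budgets[type], P)
        ch <- chroms[sample.int(length(chroms), 1)]
        hit <- place_in_gaps(occ[[ch]], len, min_gap = gap)
        if (is.null(hit)) next
        add_seg(ch, hit[1], hit[2], if (type == "cnnloh") "CNNLOH" else type)
        budgets[type] <- budgets[type] - (hit[2] - hit[1] + 1L)
      }
    }
    truth_segments[[s]] <- if (length(segs)) {
      bind_rows(segs) |> mutate(sample_id = sample_ids[s], .before = 1)
    } else {
      tibble(
        sample_id = character(0), chrom = character(0),
        probe_from = integer(0), probe_to = integer(0),
        start = integer(0), end = integer(0),
        cA = integer(0), cB = integer(0), state = character(0)
      )
    }
  }
  truth_segments <- bind_rows(truth_segments) |>
    arrange(.data$sample_id, .data$chrom, .data$probe_from)

  # --- exact truth fractions ------------------------------------------------
  seg_len <- truth_segments |>
    mutate(len = .data$probe_to - .data$probe_from + 1L) |>
    mutate(bucket = dplyr::case_when(
      .data$state %in% c("gain", "amplification") ~ "gain",
      .data$state %in% c("loss", "deletion") ~ "loss",
      TRUE ~ "cnnloh"
    ))
  fractions <- tibble(sample_id = sample_ids) |>
    left_join(
      seg_len |>
        group_by(.data$sample_id, .data$bucket) |>
        summarise(p = sum(.data$len) / N, .groups = "drop") |>
        tidyr::pivot_wider(
          names_from = "bucket", values_from = "p",
          names_prefix = "frac_"
        ),
      by = "sample_id"
    ) |>
    mutate(across(dplyr::starts_with("frac_"), ~ tidyr::replace_na(.x, 0)))
  for (col in c("frac_gain", "frac_loss", "frac_cnnloh")) {
    if (!col %in% names(fractions)) fractions[[col]] <- 0
  }
  fractions <- fractions |>
    mutate(
      frac_overall = .data$frac_gain + .data$frac_loss + .data$frac_cnnloh,
      severe = .data$frac_overall >= 0.5
    ) |>
    select(
      "sample_id", "frac_gain", "frac_loss", "frac_cnnloh",
      "frac_overall", "severe"
    )

  # --- probe signal ---------------------------------------------------------
  grid <- tibble(
    chrom = rep(chroms, each = P),
    probe_idx = rep(seq_len(P), nc),
    pos = rep(spacing * seq_len(P), nc),
    probe_id = sprintf("p_%s_%04d", rep(chroms, each = P), rep(seq_len(P), nc))
  )
  probes <- vector("list", n)
  for (s in seq_len(n)) {
    cA <- rep(1L, N)
    cB <- rep(1L, N)
    ts <- truth_segments[truth_segments$sample_id == sample_ids[s], ]
    if (nrow(ts) > 0) {
      for (i in seq_len(nrow(ts))) {
        off <- (match(ts$chrom[i], chroms) - 1L) * P
        idx <- (off + ts$probe_from[i]):(off + ts$probe_to[i])
        cA[idx] <- ts$cA[i]
        cB[idx] <- ts$cB[i]
      }
    }
    geno <- sample(c("het", "homA", "homB"), N,
      replace = TRUE,
      prob = c(config$het_prob, (1 - config$het_prob) / 2, (1 - config$het_prob) / 2)
    )
    # random parental-haplotype orientation for het sites
    flip <- runif(N) < 0.5
    eA <- ifelse(flip, cB, cA)
    eB <- ifelse(flip, cA, cB)
    p_baf <- expected_baf(geno, eA, eB, config$purity)
    p_baf[is.na(p_baf)] <- 0.5 # zero-dose marker: intensity is pure noise
    baf <- if (is.finite(config$baf_read_depth)) {
      rbinom(N, config$baf_read_depth, p_baf) / config$baf_read_depth
    } else {
      p_baf
    }
    mu_lrr <- expected_lrr(cA, cB, config$purity)
    mu_lrr[!is.finite(mu_lrr)] <- -5 # array saturation floor
    lrr <- if (config$lrr_noise_sd > 0) {
      rnorm(N, mu_lrr, config$lrr_noise_sd)
    } else {
      mu_lrr
    }
    probes[[s]] <- grid |>
      mutate(
        sample_id = sample_ids[s], .before = 1
      ) |>
      mutate(genotype = geno, baf = baf, lrr = lrr)
  }
  probes <- bind_rows(probes)

  # --- clinical table coupled to instability --------------------------------
  severe_real <- fractions$severe
  tp53 <- rep(FALSE, n)
  for (grp in c(TRUE, FALSE)) {
    idx <- which(severe_class == grp)
    p <- if (grp) config$tp53_prob[["severe"]] else config$tp53_prob[["low"]]
    k <- round(p * length(idx))
    if (k > 0) tp53[idx[sample.int(length(idx), k)]] <- TRUE
  }
  p_ln <- ifelse(severe_real, config$ln_metastasis_prob[["severe"]],
    config$ln_metastasis_prob[["low"]]
  )
  ln <- runif(n) < p_ln
  med <- ifelse(severe_real, config$survival_median_days[["severe"]],
    config$survival_median_days[["low"]]
  )
  t_event <- rexp(n, rate = log(2) / med)
  t_cens <- runif(n, config$censor_range_days[1], config$censor_range_days[2])
  clinical <- tibble(
    sample_id = sample_ids,
    tp53_mutated = tp53,
    ln_metastasis = ln,
    survival_days = round(pmin(t_event, t_cens), 1),
    event = t_event <= t_cens,
    age = round(rnorm(n, 60, 8)),
    gender = sample(c("M", "F"), n, replace = TRUE, prob = c(0.7, 0.3)),
    stage = sample(c("I", "II", "III"), n, replace = TRUE)
  )

  somatic_sites <- simulate_somatic_sites(
    sample_ids,
    n_true = config$n_somatic_sites, n_artifact = config$n_artifact_sites
  )

  structure(
    list(
      probes = probes,
      truth = list(segments = truth_segments, fractions = fractions),
      clinical = clinical,
      somatic_sites = somatic_sites,
      config = config,
      seed = seed
    ),
    class = "cna_cohort"
  )
}

#' @export
print.cna_cohort <- function(x, ...) {
  cat(
    "<cna_cohort>", x$config$n_samples, "samples,",
    x$config$n_chroms, "chromosomes x", x$config$probes_per_chrom, "probes\n"
  )
  cat(
    " implanted segments:", nrow(x$truth$segments),
    "| median truth overall fraction:",
    signif(median(x$truth$fractions$frac_overall), 3), "\n"
  )
  invisible(x)
}

# Tumor/blood site read counts: true somatic sites satisfy all three
# post-processing filters with margin; artifact sites violate exactly one
# (low coverage, low base-quality alt support, or mutant reads in blood).
simulate_somatic_sites <- function(sample_ids, n_true = 60, n_artifact = 45) {
  bases <- c("A", "C", "G", "T")
  one_sample <- function(sid) {
    n_all <- n_true + n_artifact
    kind <- c(
      rep("somatic", n_true),
      rep(c("low_coverage", "low_quality", "germline"),
        length.out = n_artifact
      )
    )
    tumor_depth <- 10L + stats::rpois(n_all, 40)
    tumor_depth[kind == "low_coverage"] <-
      sample(3:9, sum(kind == "low_coverage"), replace = TRUE)
    frac <- runif(n_all, 0.25, 0.6)
    alt_q20 <- pmin(tumor_depth, as.integer(ceiling(frac * tumor_depth)))
    lowq <- kind == "low_quality"
    alt_q20[lowq] <- as.integer(floor(runif(sum(lowq), 0, 0.15) * tumor_depth[lowq]))
    alt_total <- pmin(
      tumor_depth,
      alt_q20 + rbinom(n_all, 3, 0.3) + ifelse(lowq, 5L, 0L)
    )
    blood_depth <- 10L + stats::rpois(n_all, 30)
    blood_alt <- integer(n_all)
    germ <- kind == "germline"
    blood_alt[germ] <- pmax(1L, rbinom(sum(germ), blood_depth[germ], 0.45))
    ref <- sample(bases, n_all, replace = TRUE)
    alt <- map_chr(ref, ~ sample(setdiff(bases, .x), 1))
    tibble(
      sample_id = sid,
      chrom = as.character(sample.int(8, n_all, replace = TRUE)),
      pos = sample.int(3e6, n_all),
      ref = ref, alt = alt,
      tumor_depth = tumor_depth,
      tumor_alt_q20 = alt_q20,
      tumor_alt_total = alt_total,
      blood_depth = blood_depth,
      blood_alt_total = blood_alt,
      truth = kind
    )
  }
  bind_rows(lapply(sample_ids, one_sample))
}

#' Simulate informative-SNP read-count tables with imbalanced regions
#'
#' Generates one chromosome of informative SNPs (heterozygous in blood, >= 10
#' reads in both tissues) with a configurable number of implanted allelic
#' imbalance regions in which the tumor minor-allele fraction is suppressed.
#' Used to exercise the sliding-window imbalance caller against ground truth
#' and brute-force oracles.
#'
#' @param n_snps Number of informative SNPs.
#' @param n_regions Number of implanted imbalanced regions.
#' @param region_size SNP length of each implanted region.
#' @param depth Mean read depth per tissue.
#' @param tumor_minor_frac Expected tumor minor/major ratio inside implanted
#'   regions (well below the blood's balanced expectation).
#' @param seed Integer seed.
#' @return Tibble with columns `chrom`, `pos`, `blood_minor`, `blood_major`,
#'   `tumor_minor`, `tumor_major`, `in_region` (truth flag).
#' @export
simulate_informative_snps <- function(n_snps = 300, n_regions = 1,
                                      region_size = 80, depth = 40,
                                      tumor_minor_frac = 0.3, seed = 1) {
  set.seed(seed)
  in_region <- rep(FALSE, n_snps)
  region_size <- min(region_size, n_snps)
  if (n_regions > 0 && region_size > 0) {
    starts <- sort(sample.int(
      max(1, n_snps - region_size + 1), n_regions,
      replace = TRUE # overlapping draws simply merge
    ))
    for (st in starts) in_region[st:(st + region_size - 1)] <- TRUE
  }
  draw_pair <- function(p) {
    tot <- 10L + stats::rpois(n_snps, depth - 10)
    b <- rbinom(n_snps, tot, p)
    cbind(pmin(b, tot - b), pmax(b, tot - b))
  }
  blood <- draw_pair(rep(0.5, n_snps))
  p_t <- ifelse(in_region, tumor_minor_frac / (1 + tumor_minor_frac), 0.5)
  tumor <- draw_pair(p_t)
  tibble(
    chrom = "1", pos = 3000L * seq_len(n_snps),
    blood_minor = blood[, 1], blood_major = blood[, 2],
    tumor_minor = tumor[, 1], tumor_major = tumor[, 2],
    in_region = in_region
  )
}

#' Chromosome-arm table for a simulated cohort
#'
#' Returns the arm boundaries used by [breakpoints_per_arm()] for a simulated
#' cohort: each chromosome's centromere is placed at its probe-grid midpoint.
#'
#' @param config A [sim_config()] object.
#' @return Tibble with columns `chrom` and `centromere_pos` (bp).
#' @export
sim_arm_table <- function(config) {
  P <- config$probes_per_chrom
  sp <- config$probe_spacing_bp
  tibble(
    chrom = as.character(seq_len(config$n_chroms)),
    centromere_pos = sp * (P %/% 2) + sp %/% 2
  )
}

#' Per-probe truth states for a simulated cohort
#'
#' Expands the truth segment table to one state label per probe per sample
#' (probes outside any implanted segment are `normal`).
#'
#' @param cohort A `cna_cohort` object.
#' @return Tibble `sample_id`, `chrom`, `pos`, `true_state`.
#' @export
truth_probe_states <- function(cohort) {
  stopifnot(inherits(cohort, "cna_cohort"))
  P <- cohort$config$probes_per_chrom
  sp <- cohort$config$probe_spacing_bp
  grid <- cohort$probes |>
    select("sample_id", "chrom", "pos")
  ts <- cohort$truth$segments
  grid$true_state <- "normal"
  if (nrow(ts) > 0) {
    key <- paste(grid$sample_id, grid$chrom)
    pos_idx <- grid$pos %/% sp # probe index within chromosome
    for (i in seq_len(nrow(ts))) {
      sel <- key == paste(ts$sample_id[i], ts$chrom[i]) &
        pos_idx >= ts$probe_from[i] & pos_idx <= ts$probe_to[i]
      grid$true_state[sel] <- ts$state[i]
    }
  }
  grid
}
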