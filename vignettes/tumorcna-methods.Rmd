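---
title: "Models and methods behind tumorcna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tumorcna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorcna)
library(dplyr)
```

tumorcna characterises structural genomic alterations in tumor cohorts
profiled with SNP genotyping arrays, together with the tumor/blood
sequencing filters and clinical statistics that surround such a study. This
vignette explains the models the package implements, the parameters that
matter, the numerical choices we made where the design was genuinely open,
and what the synthetic-cohort tests do and do not establish about real
data.

## The observables

A SNP array reports two quantities per probe. The **Log R ratio (LRR)** is
the log2 ratio of observed to expected total intensity, a proxy for total
copy number with 0 at diploid. The **B allele frequency (BAF)** is the
normalised fraction of signal from the "B" allele: ~0.5 at a balanced
heterozygote, 0 or 1 at homozygotes. For a tumor of purity $\rho$ with
allele-specific copy number $(c_A, c_B)$ at a germline-heterozygous site,

$$\mathrm{BAF} = \frac{\rho\,c_B + (1-\rho)}{\rho\,(c_A+c_B) + 2(1-\rho)},
\qquad
\mathrm{LRR} = \log_2 \frac{\rho\,(c_A+c_B) + 2(1-\rho)}{2}.$$

`expected_baf()` and `expected_lrr()` implement exactly these mixtures; the
generator emits `Binomial(depth, BAF)/depth` and
`Normal(LRR, sd)` draws around them.

On sequencing data the analogous allelic statistic is the **minor allele
fraction (MAF)**: the minor-allele read count divided by the major-allele
read count at an informative (germline-heterozygous, $\geq 10$ reads in
both tissues) SNP — 1 at perfect balance, 0 at complete allelic loss. On
arrays, where only BAF is observable, `array_maf()` maps BAF onto the same
scale as $\min(b, 1-b)/\max(b, 1-b)$.

## Somatic-site filtering

Sequencing tags are quality-trimmed with a two-adjacent-bases rule: at the
first position where two consecutive bases fall below Phred 20, those bases
and everything after them are removed; tags shorter than 35 nt are
discarded. A single isolated low-quality base never triggers trimming, and
the rule is idempotent.

Candidate somatic sites then pass three filters: coverage of at least 10x
in both tumor and blood; quality-passing mutant reads making up at least
20% of tumor reads; and zero mutant reads in blood. The 20% rule is
ambiguous in its usual phrasing — "at least 20% of mutant alleles had
quality >= 20" can denominate by total depth or by mutant reads. We
default to total depth (the conventional alt-allele-fraction filter, and
the reading consistent with a specificity-increasing step); the literal
alternative is available via `filter_somatic(denominator = "alt_reads")`.

## Allelic imbalance and LOH by window sliding

Both scans use the same machinery (step-1 sliding windows, strict
thresholds, merging of overlapping flagged windows):

* **Allelic imbalance** (sequencing): a SNP is significant when
  $\mathrm{MAF}_B - \mathrm{MAF}_T \geq 0.1$ (one-sided — a tumor *more*
  balanced than blood is never evidence of alteration). A 50-SNP window is
  flagged when strictly more than 70% of its SNPs are significant.
* **LOH** (arrays): a 100-informative-SNP window is flagged when strictly
  more than 80% of SNPs have array MAF $\leq 0.9$.

Windows never span chromosomes; a chromosome with fewer informative SNPs
than one window yields no calls. Region boundaries are the outermost SNPs
of the merged flagged windows. A decimal-threshold epsilon (`1e-9`) keeps
boundaries closing exactly as printed (`0.6 - 0.5` is fractionally below
`0.1` in binary floating point).

**Edge refinement.** A window is flagged well before it lies fully inside
an LOH region, so raw merged spans overshoot the true edges — and with
noisy BAF the per-SNP low-MAF indicator has a high background rate (~0.70
at binomial depth 50), so two nearby regions can be bridged across a short
retained-heterozygosity gap. `call_loh(refine_edges = TRUE)` (the default)
therefore re-fits each merged candidate, plus one window of context, by
least-squares changepoint segmentation of the numeric per-SNP MAF series
and keeps only sub-intervals whose mean MAF is at most 0.6 — a level that
any copy-neutral LOH at purity $\gtrsim 0.3$ stays below, while a balanced
heterozygous stretch sits near 1. The window rule remains the detector;
refinement only relocates boundaries and removes bridged gaps.
`refine_edges = FALSE` preserves the exact window-enumeration semantics
(this is what the brute-force oracle tests compare against). Refined
regions can be slightly shorter than one window after edge trimming.

Informative SNPs are chosen from a truth `genotype` column in simulation,
or from a paired blood array (blood BAF in $[0.25, 0.75]$) on real data;
with neither available, `informative_probes()` refuses to guess
heterozygosity from tumor BAF alone.

## LRR segmentation

`segment_lrr()` partitions each chromosome's LRR track into
piecewise-constant segments with a sensitivity parameter `T = 10` and a
floor of 50 probes per segment:

1. **Over-segmentation** by recursive binary splitting on the maximal
   two-sample t statistic (liberal threshold `split_t = 3`, minimum piece 5
   probes).
2. **Backward elimination**: repeatedly remove the weakest surviving
   breakpoint — Welch-type t score between its two flanking segments,
   $|\Delta \bar{x}| / \sqrt{s_1^2/n_1 + s_2^2/n_2}$ with a $10^{-12}$
   variance floor so noiseless flanks give finite, very large scores —
   until every survivor scores strictly above `T`.
3. **Minimum-length enforcement**: the weakest breakpoints of any segment
   shorter than 50 probes are removed (a chromosome shorter than the floor
   is one segment).
4. **Local refinement**: greedy splitting can land a cut a probe or two
   off the least-squares optimum, so each breakpoint is re-optimised
   between its fixed neighbours until stable. On strong signals this
   reaches the exact dynamic-programming optimum
   (`exact_segmentation_oracle()`, the test reference).

The `T` scale is a t-like score on segment means; the elimination
reproduces the operative filtering semantics of sensitivity-`T`
segmentation, and `T` should be treated as a calibration knob when porting
thresholds from other segmentation engines.

**Baseline correction.** Classical practice recentres each sample's LRR on
its median. That fails for heavily altered tumor genomes: a sample with
~30% of probes gained shifts its LRR median by about +0.08, past the
$\pm 0.075$ copy-neutral band, which relabels every copy-neutral segment.
The default is therefore `center = "mode"` — the kernel-density peak of
the LRR distribution, which stays anchored to the diploid level until the
diploid component is no longer the largest — with `"median"` and `"none"`
available.

## Six-state classification

Segments are classified with inclusive thresholds exactly as printed:
amplification at mean LRR $\geq 0.15$; gain at $\geq 0.075$; deletion at
$\leq -0.15$; loss at $\leq -0.075$; otherwise ($|LRR| < 0.075$,
copy-neutral) CNNLOH when the segment's overlap with LOH regions exceeds
50%, else normal. The overlap majority rule is our determination — the
printed scheme states only "retaining heterozygosity" for normal — and the
threshold is configurable (`state_thresholds()`).

Two structural consequences are worth understanding:

* **LRR is blind to CNNLOH boundaries** (total copy number does not
  change), so `call_states()` first splits copy-neutral candidate segments
  at the LOH-region edges that fall inside them, recomputes each piece's
  mean from its member probes, and classifies the pieces. Without this
  split, a CNNLOH region covering 40% of an LRR-flat chromosome would be
  invisible. Split pieces may be shorter than the 50-probe segmentation
  floor; the floor applies to the LRR partition, not to LOH-derived
  refinements.
* **Broad single-copy events exceed the focal bands at realistic purity**:
  a one-copy gain has expected LRR $\log_2 1.5 \approx 0.585$ at purity 1
  and $0.433$ at purity 0.7, both above the 0.15 amplification threshold;
  similarly one-copy losses fall below $-0.15$. The six-state rule
  therefore labels such events with the focal states. The focal labels are
  amplitude refinements of the broad ones — `coarse_state()` collapses
  amplification into gain and deletion into loss, and instability
  fractions and recovery tests operate on these buckets.

## Instability metrics

`instability_fractions()` divides the number of probes in each bucket
(gain + amplification, loss + deletion, CNNLOH) by the total probe count,
per sample and per chromosome; the three buckets are mutually exclusive so
the overall fraction is their sum. `severe` is inclusive at 0.5.
`breakpoints_per_arm()` counts internal segment junctions per chromosome
arm against a centromere table; an arm with at least 20 breakpoints
(configurable) is flagged as a chromothripsis *candidate* — a screening
count, not the field's full chromothripsis criteria, and the 20 is a
package parameter, not a literature constant.

## Recurrent minimal common regions

Segment means are broadcast back onto probes (markers), so focal and broad
events compete on one scale. Per marker and direction,

$$G_{\mathrm{amp}}(i) = \tfrac{1}{N}\sum_s a_{si}\,[a_{si} \geq \theta],
\qquad
G_{\mathrm{del}}(i) = \tfrac{1}{N}\sum_s (-a_{si})\,[a_{si} \leq -\theta],$$

with $\theta = 0.15$ — frequency times average exceeding amplitude. The
null preserves each sample's alteration burden (the key confounder) while
breaking locus alignment: marker amplitudes are permuted within every
sample independently. All marker scores from all permutations form a
pooled null, and $p(i) = (1 + N_{\geq}(i)/M)\,/\,(1 + n_\mathrm{perm})$
where $N_{\geq}(i)$ is the pooled exceedance count and $M$ the number of
markers, so the smallest achievable p-value is $1/(1+n_\mathrm{perm})$ and
null p-values are uniform. Benjamini–Hochberg q-values
(`stats::p.adjust`) are thresholded at $q < 0.05$; maximal significant
marker runs become regions, the sub-run of maximal G is the peak, carriers
are samples exceeding $\theta$ anywhere in the peak, and the reported peak
is widened by a deterministic leave-one-out approximation (the union of
argmax sub-runs with each carrier left out, at the 0.99 confidence
fraction) — a stand-in for full region-bound resampling, and labelled as
such. A mask of hyper-polymorphic intervals can be supplied via
`exclude`. The permutation loop is compiled (Rcpp) and draws from R's RNG,
so results are reproducible under `set.seed`.

Because the null is marginal-preserving but ignores the long-range
correlation of broad segments, clustered exceedances appear as *one*
region rather than many; with BH control the mean false-region count on
null cohorts stays well below one (measured in the acceptance suite).

## Clinical association statistics

`mann_whitney()` reports the U statistic with an exact
complete-enumeration p-value for small samples (combined n of at most 12
by default; ties handled by enumeration on ranks) and the tie-corrected
normal approximation with continuity correction otherwise — the correction
keeps the approximation within ~0.01 of exact enumeration at n = 10 per
group, where the uncorrected version deviates by up to ~0.034.
`contingency_test()` auto-selects Fisher's exact test when any expected
cell is below 5 *or any observed cell is zero* (a zero cell makes the
chi-square unreliable regardless of expectations), otherwise chi-square
without continuity correction; odds ratios use the Haldane +0.5 correction
at zero cells. `km_logrank()` wraps `survival::survfit`/`survdiff` for
product-limit curves and the two-group log-rank test.
`associate_clinical()` bundles the study-style battery: rank-sum
comparisons of the four instability fractions by TP53 status, severity by
lymph-node-metastasis and severity by TP53 contingency tests (both margin
conditionings of the percentages are reported, since "63% vs 37%" style
summaries are ambiguous about the conditioning), and survival by severity.

## The synthetic cohort: what it emulates

`simulate_cohort()` generates the study conditions the analysis assumes —
and is the ground for every end-to-end test:

* **Cohort**: 55 samples, 8 chromosomes x 600 probes at 3 kb spacing
  (~one probe per 3 kb, the scanning scale of a modern genotyping array;
  the genome is scaled down from 22 autosomes for desk-scale runtimes, and
  all fractions are probe-normalised so results are size-free).
* **Instability mixture**: exact allocation of 8 samples near 0.02, 17 at
  0.25, 20 at 0.557 and 10 at 0.90 overall altered fraction — chosen once
  to reproduce a cohort median overall fraction of ~0.56, 30/55 severe
  samples, and a low-instability tail of 8 samples, the distribution shape
  the analysis is meant to face.
* **Composition**: gain/loss/CNNLOH shares 0.20/0.12/0.68 with Dirichlet
  jitter (concentration 30), giving cohort-median per-type fractions of
  roughly 0.09-0.11 / 0.05-0.07 / 0.25-0.38 — CNNLOH-dominated, as in
  heavily rearranged squamous tumors.
* **Recurrent lesions**: one focal amplification (copies (2,2)) and one
  focal homozygous deletion (copies (0,0)) at fixed loci, each carried by
  an exact `round(17/55 * n)` samples — exact counts, not per-sample
  Bernoulli, so detection tests are non-flaky.
* **Signal**: purity 0.7, LRR noise sd 0.15, BAF binomial depth 50,
  heterozygosity 0.3. The purity and noise levels are package assumptions
  (stated here, not literature facts). Implanted segments are log-uniform
  in length from 60 probes (400 for CNNLOH, so a 100-informative-SNP
  window fits inside at heterozygosity 0.3) to a whole chromosome, placed
  so that flanking free runs are either zero or at least 60 probes —
  sub-floor spacers would be invisible to a 50-probe segmentation by
  construction.
* **Clinical coupling**: TP53 mutation assigned per instability class
  (70% of severe-class, 28% of low-class samples; 28/55 overall);
  lymph-node metastasis at probability 0.65 given severe vs 0.25
  otherwise (chosen a priori to give ~85% power for the severity
  association at n = 55); exponential survival with medians 500 vs 1100
  days and uniform censoring.
* **Sequencing sites**: per sample, 60 true somatic sites engineered to
  clear all three filters with margin and 45 artifact sites violating
  exactly one each (low coverage, low base-quality support, mutant reads
  in blood).

**What passing tests do not show.** The generator's noise is
homoscedastic and probe-independent; real arrays have GC waves,
probe-specific biases, and BAF bands distorted by subclonality. There are
no subclonal mixtures, no chromothripsis rearrangement graphs (only the
many-breakpoint arm option for breakpoint counting), and genotypes are
independent across probes (no LD). Recovery under these conditions
demonstrates the pipeline's correctness and calibration, not its
robustness to platform artefacts.

## Numerical choices and degenerate inputs

* Internal intervals are 0-based half-open; probe positions on disk are
  1-based; BED output follows the BED convention.
* Malformed numeric probe rows are dropped with a count; above 5% dropped
  (configurable) the read errors out.
* `segment_lrr` rejects non-finite LRR (pre-clean with
  `read_probe_matrix`); zero-variance flanks use a $10^{-12}$ variance
  floor; degenerate rank-sum inputs (all values identical) give p = 1;
  all-censored survival input warns and gives p = 1; degenerate
  contingency margins give p = 1 with an undefined odds ratio.
* Chromosome 600-probe test sizes and the 2000-permutation acceptance
  scans are the package's desk-scale choices; `n_perm = 10000` is the
  default for real analyses.

## Worked sizes in the acceptance suite

The acceptance checks run: 200 random window-oracle instances (up to 500
SNPs); 25 segmentation instances (n up to 500, k up to 3) against the
dynamic-programming optimum; a 55-sample noisy cohort (mean
|overall-fraction error| <= 0.02), its noiseless twin (every implanted
segment recovered at the coarse state), and a 4400-probe shattered-arm
case (42/42 breakpoints); 20 implant and 20 null MCR replicates at
n_perm = 2000 (detection in >= 19/20, mean false regions < 0.5); 2000
null rank-sum replicates (type-I error in [0.04, 0.06]) and a
Kolmogorov–Smirnov uniformity check of permutation p-values; and the
boundary-fidelity battery for every printed threshold.
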