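Package: tumorcna
Title: Tumor Copy-Number Alteration, LOH and Genomic-Instability Profiling from SNP Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for characterising structural genomic alterations
    in tumor cohorts profiled with SNP genotyping arrays and paired
    tumor/blood sequencing. Implements quality trimming of sequencing tags and
    tumor/normal somatic-site filters; minor-allele-fraction based allelic
    imbalance scanning with sliding SNP windows; Log R ratio change-point
    segmentation with t-score backward elimination; copy-neutral LOH detection
    and six-state segment classification (normal, gain, loss, CNNLOH,
    amplification, deletion); per-sample genomic-instability fractions and
    per-arm breakpoint counts; GISTIC-style G-score permutation scanning for
    recurrent minimal common regions; and clinical association statistics
    (rank-sum comparisons, contingency tests, Kaplan-Meier/log-rank survival).
    A synthetic tumor-cohort generator with full ground truth makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    survival,
    stats
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
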