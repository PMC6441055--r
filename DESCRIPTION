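Package: haplochip
Title: Allele-Specific ChIP-Seq Imbalance and Backcross Linkage Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for localizing cis-regulatory variants that act in an
    allele-specific manner in F1-hybrid mouse tumour models. Implements
    haplotype assignment of ChIP-seq reads at strain-informative SNPs,
    sliding-window allelic counting with an aneuploidy-aware per-chromosome
    median baseline, an exact conditional (binomial) test of allelic
    imbalance per window and clone, Fisher's combined probability across
    clones, Benjamini-Hochberg FDR control and merging of significant
    windows into candidate enhancer regions. Companion tools cover
    backcross linkage mapping over a microsatellite marker panel
    (marker-by-marker Fisher exact association, penetrance with exact
    confidence intervals, recombinant-based candidate intervals) and
    allele-specific expression calling from diagnostic-SNP counts. A
    seed-controlled synthetic-data generator emulates trisomic allelic
    baselines, implanted allele-biased enhancers, replicate clones and
    backcross cohorts, with ground-truth sidecars for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
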