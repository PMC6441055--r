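# haplochip

Allele-specific ChIP-seq imbalance analysis and backcross linkage
statistics for F1-hybrid mouse tumour models.

## The problem

When a tumour arises in a hybrid between two inbred mouse strains (here
129P2 and FVB/N), a cis-acting regulatory variant shows up as an *allelic
imbalance*: reads from an active-chromatin ChIP (H3K27-Ac) pile up
preferentially on the haplotype carrying the activating variant. Finding
such a variant means (i) assigning reads to haplotypes at strain-informative
SNPs, (ii) scanning the genome for windows whose 129P2 read fraction
deviates from the chromosome's expected ratio, and (iii) tying the
candidate region to the phenotype with classical mouse genetics —
backcross linkage over a microsatellite panel, penetrance, and
allele-specific expression of nearby genes.

A crucial subtlety is aneuploidy: tumour clones often gain chromosomes, so
the expected 129P2 fraction is not 1/2. A chromosome with one 129P2 and
two FVB/N copies has an expected allelic balance of 1/3, and `haplochip`
estimates this baseline per chromosome (and per clone) as the **median
window allelic ratio** rather than assuming diploidy.

## The statistics

For a window with allele counts (c₁, c₂) and baseline ratio ρ, the two
allele counts are modelled as Poisson; conditioning on the total reduces
the rate comparison to an **exact binomial test** of c₁ successes in
n = c₁+c₂ trials with success probability ρ, two-sided by the
minimum-likelihood rule. Per-clone p-values are combined with **Fisher's
method**, χ² = −2 Σ ln pᵢ ~ χ²(2k), and **Benjamini–Hochberg** adjustment
across all windows controls the FDR. Windows with q below threshold and a
consistent direction are merged into regions that report their minimum q
and width-weighted mean fold-change (pooled fraction / ρ).

The cross-genetics side uses a Fisher exact test per microsatellite marker
(Bonferroni-flagged), recombinant-intersection candidate intervals, and
exact Clopper–Pearson penetrance intervals. A seed-controlled simulator
generates reads with configurable haplotype copy numbers, implanted
allele-biased enhancers, replicate clones and backcross cohorts, with
ground-truth sidecars.

## Worked example

Simulate three tumour clones on a 500 kb trisomic (1×129P2 : 2×FVB/N)
chromosome with one implanted 5 kb enhancer whose 129P2 fraction is twice
the 1/3 baseline, then run the scan:

```r
library(haplochip)

sim <- simulate_chip_reads(
  chrom_spec("chr15", 5e5, copies_a1 = 1, copies_a2 = 2),
  enhancers = enhancer_spec("chr15", 2e5, 2.05e5,
                            coverage_mult = 5, a1_fraction = 2/3),
  sim = read_sim(background_rate = 0.3, n_clones = 3, seed = 42)
)
fit <- run_imbalance(sim$reads, sim$snps, observations = sim$observations,
                     chrom_lengths = c(chr15 = 5e5))
fit
#> Allele-specific imbalance scan
#>   reads: 468846 (188605 informative, 0 conflict, 280241 non-informative)
#>   windows tested: 5833 of 6997 tiled (min_total = 10 per clone)
#>   significant windows (q < 0.05): 64; regions (A1_up): 1
fit$regions
#> # A tibble: 1 × 7
#>   chrom  start    end         q  fold direction n_windows
#>   <chr>  <int>  <int>     <dbl> <dbl> <chr>         <int>
#> 1 chr15 199500 205500 4.27e-266  1.98 A1_up            63
```

The single called region overlaps the implanted enhancer, its fold-change
(pooled 129P2 fraction over the median baseline) recovers the simulated
2-fold effect, and its q-value is far below the 1% FDR used for headline
regions. `tidy(fit)` returns the per-window table, `glance(fit)` a one-row
summary, and `autoplot(fit)` the allelic-fraction track.

The genetics arithmetic works on printed counts directly:

```r
penetrance(70, 91)       # carrier penetrance
#> # A tibble: 1 × 5
#>   affected total penetrance_pct ci_lo_pct ci_hi_pct
#>      <int> <int>          <dbl>     <dbl>     <dbl>
#> 1       70    91           76.9      66.9      85.1
contingency_exact(19, 72, 1, 94)  # metaplasia-by-genotype 2x2 table
#> [1] 5.601421e-06
```

A thin command-line wrapper over the same functions ships at
`inst/cli/haplochip.R` with subcommands `simulate-chip`, `simulate-cross`,
`assign`, `imbalance`, `call-regions`, `linkage`, `penetrance` and `ase`.

## Package layout

- `R/` — simulators (`simulate_chip_reads`, `simulate_cross`), assignment
  (`assign_reads`), scan (`make_windows`, `count_windows`,
  `chromosome_baseline`, `exact_allelic_test`, `fisher_combine`, `bh_fdr`,
  `run_imbalance`, `call_regions`), genetics (`marker_scan`,
  `candidate_interval`, `penetrance`, `contingency_exact`), ASE
  (`ase_call`), IO (minimal VCF, reads TSV, BED6, cohort TSV, SAM text).
- `vignettes/allelic-imbalance-methods.Rmd` — the model, its assumptions,
  parameter defaults and design choices.
- `tests/testthat/` — unit, property and end-to-end suites, all on
  seeded in-code fixtures.
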