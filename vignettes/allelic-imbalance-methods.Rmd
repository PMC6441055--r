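---
title: "Methods: allele-specific ChIP-seq imbalance and backcross linkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific ChIP-seq imbalance and backcross linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplochip)
library(dplyr)
```

## The problem

In an F1 hybrid between two inbred mouse strains (here 129P2 and FVB/N),
every autosomal locus carries one haplotype from each parent, and the
thousands of SNPs that distinguish the strains make sequencing reads
*allele-informative*: a read overlapping such a SNP reveals which haplotype
it came from. If a cis-regulatory variant activates an enhancer on one
haplotype only, the active-chromatin mark H3K27-Ac accumulates
preferentially on that haplotype, and the fraction of ChIP-seq reads
supporting that allele rises locally above the genome's baseline.

`haplochip` implements that analysis end to end — haplotype assignment of
reads at strain SNPs, sliding-window allelic counting, an exact per-window
test against an aneuploidy-aware baseline, combination of replicate clones,
FDR control, and region calling — together with the companion genetics:
backcross linkage mapping over a microsatellite panel, penetrance
estimation, and allele-specific expression (ASE) calling. A seed-controlled
simulator generates every input with known ground truth.

Throughout, haplotype **A1 = 129P2** and **A2 = FVB/N**; intervals are
0-based half-open (BED convention); VCF positions are converted on load.

## Read assignment

Each read votes once per overlapping strain SNP: the A1 base is an A1 vote,
the A2 base an A2 vote, and any other base is a *silent non-vote*, treated
as sequencing error rather than evidence. Unanimous votes assign the read;
mixed votes make it a `CONFLICT`; no votes make it `NONINFORMATIVE`. Only
A1/A2 reads enter any downstream count.

Two choices here were genuinely open and are worth stating:

* **Conflicted reads are dropped by default.** A read carrying discordant
  SNP bases cannot be said to "support either" haplotype; discarding it is
  conservative. `conflict_policy = "majority"` awards the read to the
  majority vote instead (ties remain conflicts) for users who prefer power
  over caution.
* **Duplicate reads are not collapsed**, and no mapping-bias correction
  (e.g. N-masked remapping) or base-quality weighting is applied. These are
  deliberate non-goals; on real data a mapping-bias-aware upstream pipeline
  is advisable.

## The window scan and its baseline

Windows of several sizes (default 250, 500 and 1000 bp — a multi-scale
rendering of a "variable size" scan) tile each chromosome, stepping by half
a window so that features falling across a window boundary at one scale are
captured by the overlapping phase or by another scale. Partial windows at
the chromosome end are dropped. A read is counted into a window iff its
*start* lies inside; within one size tier this counts every read exactly
once per overlapping phase and avoids double counting by read extent.

The expected allelic ratio is **not** assumed to be 1/2. Tumour genomes are
frequently aneuploid, and a chromosome present as one 129P2 plus two FVB/N
copies pushes the expected 129P2 fraction of every window on it to 1/3. The
baseline is therefore the **median allelic ratio per chromosome** over
windows with at least `min_total` informative reads, computed per clone
(clones can differ in karyotype; `pool_baseline = TRUE` pools them). The
median, unlike the mean, moves by at most one order statistic when a few
windows contain genuinely imbalanced enhancers, so the signal being hunted
does not contaminate its own null. The baseline is clamped to
`[1e-6, 1 - 1e-6]` so it is always a usable binomial success probability.

## The exact test, combination, and FDR

Per window and clone, the A1/A2 counts `(c1, c2)` are compared with the
baseline ratio `rho`. Modelling the two allele counts as Poisson and
conditioning on their total reduces the comparison of their rates to an
exact binomial test of `c1` successes in `c1 + c2` trials with success
probability `rho` — the classical exact construction, and the only one
computable from the counts and baseline alone. Two-sidedness is by the
minimum-likelihood rule (sum all outcomes no more likely than observed,
with the customary `1 + 1e-7` tie tolerance), so the modal outcome yields
p = 1. The implementation enumerates the full pmf, shared across windows
with the same `(n, rho)`; tests verify equality with brute-force
enumeration for every total up to 200 and with `stats::binom.test`.

The test is two-sided even though the biological question ("more H3K27-Ac
on the 129P2 allele") is directional: deviation in either direction is
evidence against the baseline, and direction is applied afterwards as a
filter at region-calling time. This keeps the p-values interpretable and
the FDR calculation honest for both tails.

Per window, the clone p-values are combined with Fisher's method
(`-2 * sum(log p) ~ chi-square` with `2k` df). A window is combined only if
*every* clone reaches `min_total` informative reads in it; windows failing
this anywhere are dropped before combination (never imputed) and counted in
the run report. Combined p-values that underflow the chi-square tail are
floored at `1e-300`. Benjamini–Hochberg adjustment is applied once across
all windows of all chromosomes and size tiers (per the default; a
per-chromosome variant can be had by running chromosomes separately), and
windows with `q` below the threshold (default 0.05) in the requested
direction are merged — overlapping or book-ended, across size tiers — into
regions reporting their minimum q and width-weighted mean fold-change
`pooled_fraction / rho`.

Numerical conventions collected in one place: `min_total` defaults to 10
informative reads (the paper-scale datasets easily clear it; it is a
config value, not a constant); step fraction 1/2; q-threshold 0.05;
baseline clamp `1e-6`; p-value floor `1e-300`; Fisher tie tolerance
`1 + 1e-7`.

## What the simulator emulates — and what it does not

`simulate_chip_reads()` generates the data structure the statistics consume,
not raw sequencing: fixed-length single-end reads with uniform start
positions, each carrying observed bases only at the SNPs it overlaps.

* Haplotype copy number per chromosome (`copies_a1`, `copies_a2`) sets the
  background probability that a read originates from A1 — `1:2` gives the
  trisomic 1/3 baseline.
* Implanted enhancers multiply the local read rate (`coverage_mult`) and
  override the local A1 probability (`a1_fraction`); setting
  `a1_fraction = 2 * baseline` emulates a variant that doubles the 129P2
  fraction.
* Replicate clones are independent draws; sequencing error flips a SNP base
  to the *other* haplotype's base with probability `error_rate` — the worst
  case for assignment, chosen to stress the conflict rule.
* Strain SNPs arrive as a Poisson process at `snp_density` per kb (default
  5/kb, the right order for 129P2 vs FVB/N).

Not emulated: fragment-length and GC effects, mapping bias, PCR
duplicates, overdispersion beyond Poisson/binomial, indels. Passing tests
on this simulator therefore validate the *statistics* — calibration of the
exact test, FDR control, baseline estimation, recovery of implanted effect
sizes — not robustness to alignment artefacts of real data.

Default depths were chosen once, as round numbers giving comfortable
window-level counts: the baseline-verification simulations use ~220
informative reads per 500 bp window, the enhancer-recovery simulations
~120 per window per clone, on 10 Mb chromosomes in the acceptance script
and 1.5-3 Mb equivalents in the test suite (identical per-window depth,
smaller genome).

`simulate_cross()` draws backcross genotypes marker-by-marker along each
chromosome with recombination probability `recomb_per_mb * distance`
between neighbours (default 0.005/Mb ~ 0.5 cM/Mb) and a phenotype from the
penetrance of the genotype at one linked marker. It emulates segregation
and incomplete penetrance, not interference or genotyping error.

## Cross genetics

The linkage readout is deliberately simple: per marker, a two-sided Fisher
exact test on the 2x2 genotype-by-phenotype table, ranked, with a
Bonferroni flag at `alpha / n_markers`. (The original genome scans of this
kind report "strong linkage" without naming a statistic; Fisher exact is
the package's choice and is labelled as such.) `candidate_interval()`
reproduces recombinant fine-mapping logic: the interval is the largest
marker run at which *every affected carrier* retains the 129P2 allele,
expanded to the flanking markers where the first breakpoints fall. Only
affected animals are used — under incomplete penetrance, an unaffected
carrier excludes nothing. Mice with ambiguous crossover placement between
markers are implicitly uninformative, since only typed marker positions
bound the interval. `penetrance()` is plain arithmetic with an exact
Clopper–Pearson interval, valid at 0/n and n/n.

## ASE calling

`ase_call()` abstracts diagnostic-SNP scoring of transcripts to allele
counts and reuses the same exact binomial machinery against a configurable
`null_fraction` (0.5 for a diploid locus; copy-number-adjusted otherwise).
Defaults: `min_depth = 20` observations before any verdict, `alpha = 0.05`.
There is no field-standard numeric threshold for "primarily expressed from
one allele"; significance-based calling at `alpha` is this package's
convention.

## Known limitations

* Sliding windows overlap, so neighbouring tests are correlated; BH still
  controls FDR under this positive dependence, but the effective number of
  independent tests is roughly halved per tier.
* With ~100 truly imbalanced windows rejected genome-wide, BH at 5% admits
  a handful of false windows by design; isolated one-window regions far
  from any candidate should be read accordingly (or called at a stricter
  threshold, as the 1% used for the headline enhancer region).
* The exact test is discrete: at low counts it is conservative, which is
  visible as super-uniform null p-values in the calibration tests.
* Baselines need at least one qualifying window per chromosome per clone;
  sparse chromosomes are skipped with a logged reason rather than guessed.

## Problem sizes used in validation

The shipped test suite and acceptance script run entirely on simulated
data: a 1 Mb / 10 Mb trisomic chromosome for baseline verification
(~1.1M / 11M reads), a 2 Mb / 10 Mb three-clone enhancer recovery (~3.7M /
18M reads), twenty 150 kb null replicates for FDR calibration, and twenty
200-mouse cohorts for linkage recovery. These sizes were chosen so that
every generative parameter is recovered within tight binomial error while
the whole suite stays fast on a laptop.
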