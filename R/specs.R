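#' Describe a simulated chromosome
#'
#' A chromosome is described by its length, the number of copies of each
#' parental haplotype it carries, and the density of strain-informative SNPs.
#' The copy numbers set the expected allelic fraction of background reads:
#' a cell with one 129P2 (A1) and two FVB/N (A2) copies — the trisomy seen in
#' the tumour-derived clones that motivates the aneuploidy-aware baseline —
#' yields an expected A1 fraction of 1/3 rather than 1/2.
#'
#' @param name Chromosome label, e.g. `"chr15"`.
#' @param length Chromosome length in bp (positive integer).
#' @param copies_a1,copies_a2 Copies of the A1 (129P2) and A2 (FVB/N)
#'   haplotype carried by the simulated cells. Non-negative integers with
#'   `copies_a1 + copies_a2 >= 1`.
#' @param snp_density Expected strain-informative SNPs per kb (> 0). Inbred
#'   mouse strains such as 129P2 and FVB/N differ at roughly one SNP per
#'   150-200 bp, hence the default of 5 per kb.
#'
#' @return A one-row tibble; rows from repeated calls can be combined with
#'   [dplyr::bind_rows()] to describe several chromosomes.
#' @seealso [simulate_chip_reads()]
#' @export
#' @examples
#' chrom_spec("chr15", 1e6, copies_a1 = 1, copies_a2 = 2)
chrom_spec <- function(name, length, copies_a1 = 1, copies_a2 = 1,
                       snp_density = 5) {
  stopifnot(is.character(name), length(name) == 1L)
  length <- .check_count(length, "length", min = 1)
  copies_a1 <- .check_count(copies_a1, "copies_a1", min = 0)
  copies_a2 <- .check_count(copies_a2, "copies_a2", min = 0)
  if (copies_a1 + copies_a2 < 1) {
    abort("`copies_a1 + copies_a2` must be at least 1.")
  }
  if (!is.numeric(snp_density) || snp_density <= 0) {
    abort("`snp_density` must be a positive number of SNPs per kb.")
  }
  tibble(
    name = name, length = length,
    copies_a1 = copies_a1, copies_a2 = copies_a2,
    snp_density = as.numeric(snp_density)
  )
}

#' Describe an implanted allele-biased enhancer
#'
#' An enhancer is a window of the simulated chromosome in which reads are
#' emitted at `coverage_mult` times the background rate and drawn from the
#' A1 (129P2) haplotype with probability `a1_fraction` instead of the
#' copy-number baseline. Setting `a1_fraction` to twice the chromosome
#' baseline reproduces the regime of a cis-activating variant that doubles
#' the allelic fraction of the activating haplotype.
#'
#' @param chrom Chromosome label (must match a [chrom_spec()] name).
#' @param start,end 0-based half-open interval in bp.
#' @param coverage_mult Fold increase of the total read rate inside the
#'   region (>= 1).
#' @param a1_fraction True A1 fraction inside the region, in (0, 1).
#'
#' @return A one-row tibble.
#' @export
#' @examples
#' enhancer_spec("chr15", 5e5, 5.05e5, coverage_mult = 5, a1_fraction = 2 / 3)
enhancer_spec <- function(chrom, start, end, coverage_mult = 1, a1_fraction) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- .check_count(start, "start", min = 0)
  end <- .check_count(end, "end", min = 1)
  if (end <= start) abort("`end` must be greater than `start`.")
  if (!is.numeric(coverage_mult) || coverage_mult < 1) {
    abort("`coverage_mult` must be >= 1.")
  }
  if (!is.numeric(a1_fraction) || a1_fraction <= 0 || a1_fraction >= 1) {
    abort("`a1_fraction` must lie strictly between 0 and 1.")
  }
  tibble(
    chrom = chrom, start = start, end = end,
    coverage_mult = as.numeric(coverage_mult),
    a1_fraction = as.numeric(a1_fraction)
  )
}

#' Read-simulation settings
#'
#' Controls the read model of [simulate_chip_reads()]: single-end reads of
#' fixed length with uniform start positions, carrying observed bases only at
#' the strain-informative SNPs they overlap. A sequencing error flips a SNP
#' base to the *other* haplotype's base — the worst case for haplotype
#' assignment, chosen to stress the conflict-handling rule rather than to be
#' a realistic substitution model.
#'
#' @param read_length Read length in bp.
#' @param background_rate Expected reads per bp per clone outside enhancers.
#'   At the default read length this corresponds to a raw coverage of
#'   `read_length * background_rate` fold.
#' @param error_rate Per-SNP-base probability of misreading towards the other
#'   haplotype, in [0, 0.5).
#' @param n_clones Number of replicate tumour-derived clones (>= 1), each
#'   sampled independently.
#' @param seed Integer seed; mandatory so that every simulation is
#'   reproducible by construction.
#'
#' @return An object of class `read_sim` (a validated list).
#' @export
#' @examples
#' read_sim(background_rate = 0.05, n_clones = 3, seed = 1)
read_sim <- function(read_length = 100, background_rate = 0.2,
                     error_rate = 0, n_clones = 3, seed) {
  read_length <- .check_count(read_length, "read_length", min = 1)
  if (!is.numeric(background_rate) || background_rate <= 0) {
    abort("`background_rate` must be > 0 reads per bp per clone.")
  }
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 0.5) {
    abort("`error_rate` must lie in [0, 0.5).")
  }
  n_clones <- .check_count(n_clones, "n_clones", min = 1)
  if (missing(seed)) abort("`seed` is mandatory for read simulation.")
  seed <- .check_count(seed, "seed", min = -.Machine$integer.max)
  structure(
    list(
      read_length = read_length,
      background_rate = as.numeric(background_rate),
      error_rate = as.numeric(error_rate),
      n_clones = n_clones,
      seed = seed
    ),
    class = "read_sim"
  )
}

#' Backcross cohort settings
#'
#' Describes a backcross of an F1 (129P2 x FVB/N) hybrid to the FVB/N parent:
#' every mouse is either heterozygous (`HET_129`) or homozygous FVB/N
#' (`HOM_FVB`) at each microsatellite marker. Genotypes are co-inherited
#' along a chromosome except for recombination between adjacent markers, and
#' a binary phenotype is drawn from the penetrance of the mouse's genotype at
#' one designated linked marker.
#'
#' @param n_mice Cohort size (>= 1).
#' @param markers Tibble with columns `marker`, `chrom`, `pos` (bp), sorted
#'   by `(chrom, pos)`; mimics a genome-wide microsatellite panel typed at
#'   ~20 Mb (~10 cM) spacing.
#' @param linked_marker Name or index of the marker truly linked to the
#'   phenotype.
#' @param penetrance_carrier Probability that a heterozygous (129P2 carrier)
#'   mouse is affected.
#' @param penetrance_noncarrier Probability that a homozygous FVB/N mouse is
#'   affected; must not exceed `penetrance_carrier`.
#' @param recomb_per_mb Recombination probability per Mb between adjacent
#'   markers (capped at 0.5); the default 0.005/Mb corresponds to the usual
#'   mouse-autosome average of ~0.5 cM per Mb.
#' @param seed Integer seed (mandatory).
#'
#' @return An object of class `cross_spec` (a validated list).
#' @seealso [simulate_cross()]
#' @export
cross_spec <- function(n_mice, markers, linked_marker,
                       penetrance_carrier, penetrance_noncarrier = 0,
                       recomb_per_mb = 0.005, seed) {
  n_mice <- .check_count(n_mice, "n_mice", min = 1)
  markers <- as_tibble(markers)
  if (nrow(markers) == 0L) abort("`markers` must contain at least one marker.")
  if (!all(c("marker", "chrom", "pos") %in% names(markers))) {
    abort("`markers` needs columns `marker`, `chrom` and `pos`.")
  }
  if (anyDuplicated(markers$marker)) abort("marker names must be unique.")
  ord <- order(markers$chrom, markers$pos)
  if (!identical(ord, seq_len(nrow(markers)))) {
    abort("`markers` must be sorted by (chrom, pos).")
  }
  if (is.character(linked_marker)) {
    linked_marker <- match(linked_marker, markers$marker)
    if (is.na(linked_marker)) abort("`linked_marker` not found in `markers`.")
  }
  linked_marker <- .check_count(linked_marker, "linked_marker", min = 1)
  if (linked_marker > nrow(markers)) abort("`linked_marker` out of range.")
  for (p in c(penetrance_carrier, penetrance_noncarrier)) {
    if (!is.numeric(p) || p < 0 || p > 1) abort("penetrances must lie in [0, 1].")
  }
  if (penetrance_carrier < penetrance_noncarrier) {
    abort("`penetrance_carrier` must be >= `penetrance_noncarrier`.")
  }
  if (!is.numeric(recomb_per_mb) || recomb_per_mb < 0) {
    abort("`recomb_per_mb` must be >= 0.")
  }
  if (missing(seed)) abort("`seed` is mandatory for cohort simulation.")
  seed <- .check_count(seed, "seed", min = -.Machine$integer.max)
  structure(
    list(
      n_mice = n_mice, markers = markers, linked_marker = linked_marker,
      penetrance_carrier = as.numeric(penetrance_carrier),
      penetrance_noncarrier = as.numeric(penetrance_noncarrier),
      recomb_per_mb = as.numeric(recomb_per_mb), seed = seed
    ),
    class = "cross_spec"
  )
}

.check_count <- function(x, what, min) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %s.", what, format(min)))
  }
  as.integer(x)
}
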