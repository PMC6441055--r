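#' Simulate allele-informative ChIP-seq reads
#'
#' Generates everything the imbalance pipeline consumes: a strain-SNP table,
#' fixed-length single-end reads for each replicate clone with observed bases
#' at the SNPs they overlap, and a ground-truth table of implanted enhancer
#' regions. Outside enhancers a read's haplotype of origin is drawn in
#' proportion to the chromosome's haplotype copy numbers (one 129P2 copy plus
#' two FVB/N copies gives P(A1) = 1/3); inside an enhancer the haplotype is
#' drawn with probability `a1_fraction` and the total read rate is
#' `coverage_mult` times background. Each observed SNP base is flipped to the
#' other haplotype's base with probability `error_rate`.
#'
#' Reads are intervals plus per-SNP observations — no full sequences — since
#' the downstream statistics consume only allele-informative evidence. Read
#' starts are uniform over positions that keep the read inside the
#' chromosome, so no partial reads are emitted.
#'
#' @param chroms Tibble of chromosome descriptions from [chrom_spec()].
#' @param enhancers Optional tibble from [enhancer_spec()]; regions must lie
#'   within their chromosome and must not overlap one another.
#' @param sim A [read_sim()] settings object (carries the seed).
#'
#' @return An object of class `chip_sim`: a list with
#' \describe{
#'   \item{reads}{tibble of `read_id`, `chrom`, `start`, `end` (0-based
#'     half-open), `clone`, and `hap` — the true haplotype of origin, kept
#'     for validation only.}
#'   \item{observations}{tibble of `read_id`, `chrom`, `pos` (0-based),
#'     `base`: the base each read reports at each SNP it overlaps.}
#'   \item{snps}{SNP table as used by [assign_reads()]: `chrom`, `pos`
#'     (0-based), `a1_base`, `a2_base`.}
#'   \item{truth}{tibble of implanted regions with their true `a1_fraction`,
#'     plus the per-chromosome baseline fraction implied by copy number.}
#'   \item{config}{all specs and the seed, suitable for JSON serialisation.}
#' }
#' @export
#' @examples
#' sim <- simulate_chip_reads(
#'   chrom_spec("chr15", 2e5, copies_a1 = 1, copies_a2 = 2),
#'   sim = read_sim(background_rate = 0.05, n_clones = 1, seed = 7)
#' )
#' dplyr::count(sim$reads, hap)
simulate_chip_reads <- function(chroms, enhancers = NULL, sim) {
  chroms <- as_tibble(chroms)
  stopifnot(inherits(sim, "read_sim"))
  if (anyDuplicated(chroms$name)) abort("chromosome names must be unique.")
  enhancers <- if (is.null(enhancers) || nrow(as_tibble(enhancers)) == 0L) {
    tibble(chrom = character(), start = integer(), end = integer(),
           coverage_mult = numeric(), a1_fraction = numeric())
  } else {
    as_tibble(enhancers)
  }
  .validate_enhancers(enhancers, chroms)

  withr::with_seed(sim$seed, {
    snps <- .sim_snps(chroms)
    out <- vector("list", nrow(chroms) * sim$n_clones)
    k <- 0L
    for (ci in seq_len(nrow(chroms))) {
      cr <- chroms[ci, ]
      enh <- enhancers[enhancers$chrom == cr$name, , drop = FALSE]
      for (clone in seq_len(sim$n_clones)) {
        k <- k + 1L
        out[[k]] <- .sim_clone_reads(cr, enh, sim)
      }
    }
    reads <- bind_rows(out)
    n_per <- vapply(out, nrow, integer(1))
    reads$clone <- rep(rep(seq_len(sim$n_clones), times = nrow(chroms)), n_per)
    reads$read_id <- seq_len(nrow(reads))
    reads <- reads[, c("read_id", "chrom", "start", "end", "clone", "hap")]
    obs <- .observe_snps(reads, snps, sim$error_rate)
    baseline <- chroms$copies_a1 / (chroms$copies_a1 + chroms$copies_a2)
    truth <- enhancers
    truth$baseline_fraction <- baseline[match(truth$chrom, chroms$name)]
    structure(
      list(
        reads = reads, observations = obs, snps = snps, truth = truth,
        config = list(
          chroms = chroms, enhancers = enhancers,
          read_length = sim$read_length,
          background_rate = sim$background_rate,
          error_rate = sim$error_rate, n_clones = sim$n_clones,
          seed = sim$seed
        )
      ),
      class = "chip_sim"
    )
  })
}

.validate_enhancers <- function(enhancers, chroms) {
  if (nrow(enhancers) == 0L) return(invisible())
  i <- match(enhancers$chrom, chroms$name)
  if (anyNA(i)) abort("enhancer on unknown chromosome.")
  if (any(enhancers$start < 0 | enhancers$end > chroms$length[i])) {
    abort("enhancer regions must lie within their chromosome.")
  }
  by_chrom <- split(enhancers, enhancers$chrom)
  for (e in by_chrom) {
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1L && any(e$start[-1] < e$end[-nrow(e)])) {
      abort("enhancer regions on one chromosome must not overlap.")
    }
  }
  invisible()
}

.sim_snps <- function(chroms) {
  per <- lapply(seq_len(nrow(chroms)), function(i) {
    cr <- chroms[i, ]
    n <- rpois(1L, cr$length * cr$snp_density / 1000)
    n <- min(n, cr$length)
    if (n == 0L) {
      warn(sprintf("chromosome %s received zero informative SNPs.", cr$name))
      return(tibble(chrom = character(), pos = integer(),
                    a1_base = character(), a2_base = character()))
    }
    pos <- sort(sample.int(cr$length, n)) - 1L
    a1 <- sample.int(4L, n, replace = TRUE)
    shift <- sample.int(3L, n, replace = TRUE)
    a2 <- ((a1 - 1L + shift) %% 4L) + 1L
    tibble(chrom = cr$name, pos = pos,
           a1_base = .bases[a1], a2_base = .bases[a2])
  })
  bind_rows(per)
}

# Reads for one clone on one chromosome. Haplotype probability is decided by
# the read's start position (consistent with the start-point window rule).
.sim_clone_reads <- function(cr, enh, sim) {
  L <- sim$read_length
  max_start <- cr$length - L
  if (max_start < 0L) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), hap = character()))
  }
  n_bg <- rpois(1L, cr$length * sim$background_rate)
  starts <- floor(runif(n_bg, 0, max_start + 1L))
  if (nrow(enh) > 0L) {
    extra <- lapply(seq_len(nrow(enh)), function(j) {
      lo <- enh$start[j]
      hi <- min(enh$end[j] - 1L, max_start)
      if (hi < lo) return(numeric())
      n_e <- rpois(1L, (hi - lo + 1L) * sim$background_rate *
                     (enh$coverage_mult[j] - 1))
      floor(runif(n_e, lo, hi + 1L))
    })
    starts <- c(starts, unlist(extra))
  }
  starts <- as.integer(starts)
  p_a1 <- rep(cr$copies_a1 / (cr$copies_a1 + cr$copies_a2), length(starts))
  if (nrow(enh) > 0L) {
    for (j in seq_len(nrow(enh))) {
      inside <- starts >= enh$start[j] & starts < enh$end[j]
      p_a1[inside] <- enh$a1_fraction[j]
    }
  }
  hap <- ifelse(runif(length(starts)) < p_a1, "A1", "A2")
  tibble(chrom = cr$name, start = starts, end = starts + L, hap = hap)
}

# Per-read SNP observations: the read reports its haplotype's base at every
# SNP it overlaps, flipped to the other haplotype's base with prob error_rate.
.observe_snps <- function(reads, snps, error_rate) {
  if (nrow(reads) == 0L || nrow(snps) == 0L) {
    return(tibble(read_id = integer(), chrom = character(),
                  pos = integer(), base = character()))
  }
  hits <- .overlap_points(reads, snps$chrom, snps$pos)
  if (length(hits$read) == 0L) {
    return(tibble(read_id = integer(), chrom = character(),
                  pos = integer(), base = character()))
  }
  is_a1 <- reads$hap[hits$read] == "A1"
  flip <- if (error_rate > 0) runif(length(is_a1)) < error_rate else
    rep(FALSE, length(is_a1))
  use_a1 <- xor(is_a1, flip)
  base <- ifelse(use_a1, snps$a1_base[hits$point], snps$a2_base[hits$point])
  tibble(
    read_id = reads$read_id[hits$read],
    chrom = snps$chrom[hits$point],
    pos = snps$pos[hits$point],
    base = base
  )
}

# Overlap read intervals [start, end) with 0-based point positions,
# chromosome-aware. Returns parallel index vectors.
.overlap_points <- function(reads, point_chrom, point_pos) {
  rd <- GenomicRanges::GRanges(
    reads$chrom, IRanges::IRanges(reads$start + 1L, reads$end)
  )
  pt <- GenomicRanges::GRanges(
    point_chrom, IRanges::IRanges(point_pos + 1L, point_pos + 1L)
  )
  ov <- GenomicRanges::findOverlaps(rd, pt)
  list(read = S4Vectors::queryHits(ov), point = S4Vectors::subjectHits(ov))
}

#' Simulate a backcross cohort
#'
#' Draws genotypes for `n_mice` backcross mice over a microsatellite panel
#' and a binary phenotype controlled by one linked marker. Each mouse's
#' genotype at the first marker of a chromosome is `HET_129` or `HOM_FVB`
#' with equal probability (Mendelian backcross segregation); moving along
#' the chromosome, the genotype switches between adjacent markers with
#' probability `recomb_per_mb` times the inter-marker distance (capped at
#' 0.5). The phenotype of each mouse is Bernoulli with the penetrance of its
#' genotype at the linked marker; affected mice additionally receive a
#' positive tumour count.
#'
#' @param spec A [cross_spec()] object.
#'
#' @return An object of class `cross_cohort`: a list with `genotypes` (wide
#'   tibble, `mouse_id` plus one column per marker), `phenotypes`
#'   (`mouse_id`, `affected`, `tumour_count`), `markers` (the marker map) and
#'   `truth` (name of the linked marker and the penetrances used).
#' @export
#' @examples
#' mk <- tibble::tibble(
#'   marker = paste0("M", 1:5), chrom = "chr15", pos = seq(5e6, 85e6, 2e7)
#' )
#' simulate_cross(cross_spec(50, mk, "M5", 70 / 91, seed = 11))
simulate_cross <- function(spec) {
  stopifnot(inherits(spec, "cross_spec"))
  mk <- spec$markers
  withr::with_seed(spec$seed, {
    geno <- matrix(NA_integer_, nrow = spec$n_mice, ncol = nrow(mk))
    for (ch in unique(mk$chrom)) {
      idx <- which(mk$chrom == ch)
      g <- rbinom(spec$n_mice, 1L, 0.5)
      geno[, idx[1L]] <- g
      if (length(idx) > 1L) {
        for (j in seq_along(idx)[-1L]) {
          d_mb <- (mk$pos[idx[j]] - mk$pos[idx[j - 1L]]) / 1e6
          r <- min(0.5, spec$recomb_per_mb * d_mb)
          flip <- rbinom(spec$n_mice, 1L, r)
          g <- as.integer(xor(g, flip))
          geno[, idx[j]] <- g
        }
      }
    }
    carrier <- geno[, spec$linked_marker] == 1L
    p <- ifelse(carrier, spec$penetrance_carrier, spec$penetrance_noncarrier)
    affected <- rbinom(spec$n_mice, 1L, p) == 1L
    tumours <- integer(spec$n_mice)
    tumours[affected] <- 1L + rpois(sum(affected), 4)

    gt <- matrix(c("HOM_FVB", "HET_129")[geno + 1L], nrow = spec$n_mice)
    colnames(gt) <- mk$marker
    genotypes <- bind_cols(
      tibble(mouse_id = sprintf("m%03d", seq_len(spec$n_mice))),
      as_tibble(gt)
    )
    structure(
      list(
        genotypes = genotypes,
        phenotypes = tibble(
          mouse_id = genotypes$mouse_id,
          affected = affected, tumour_count = tumours
        ),
        markers = mk,
        truth = list(
          linked_marker = mk$marker[spec$linked_marker],
          penetrance_carrier = spec$penetrance_carrier,
          penetrance_noncarrier = spec$penetrance_noncarrier,
          seed = spec$seed
        )
      ),
      class = "cross_cohort"
    )
  })
}
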