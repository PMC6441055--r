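#' Marker-by-marker genotype-phenotype association scan
#'
#' For every microsatellite marker of a backcross cohort, builds the 2x2
#' table of genotype (`HET_129` carrier vs `HOM_FVB`) against the binary
#' phenotype and computes a two-sided Fisher exact p-value. The genome-wide
#' scan reports the markers ranked by p, flagging those below
#' the Bonferroni threshold `alpha / n_markers`. The association statistic
#' (Fisher exact plus Bonferroni flag) is this package's choice of linkage
#' readout and is labelled as such in the output.
#'
#' @param cohort A `cross_cohort` (from [simulate_cross()] or
#'   [read_cohort_tsv()]).
#' @param alpha Genome-wide significance level for the Bonferroni flag
#'   (default 0.05).
#' @return A tibble of class `linkage_scan`, ranked by p-value: `marker`,
#'   `chrom`, `pos`, the 2x2 cell counts (`aff_het`, `aff_hom`, `unaff_het`,
#'   `unaff_hom`), `p`, `or_direction` (`"HET_129"` when carriers are
#'   enriched among affected), `monomorphic`, `bonferroni_sig`.
#' @export
marker_scan <- function(cohort, alpha = 0.05) {
  ck <- .as_cohort(cohort)
  geno <- ck$genotypes
  aff <- ck$phenotypes$affected[match(geno$mouse_id, ck$phenotypes$mouse_id)]
  if (anyNA(aff)) abort("every mouse needs a phenotype.")
  markers <- ck$markers
  if (nrow(geno) < 2L) abort("need at least 2 mice.")
  rows <- lapply(seq_len(nrow(markers)), function(i) {
    m <- markers$marker[i]
    het <- geno[[m]] == "HET_129"
    tab <- c(
      aff_het = sum(aff & het), aff_hom = sum(aff & !het),
      unaff_het = sum(!aff & het), unaff_hom = sum(!aff & !het)
    )
    mono <- sum(het) == 0L || sum(!het) == 0L
    p <- if (mono || all(aff) || all(!aff)) {
      1
    } else {
      fisher.test(matrix(tab, nrow = 2, byrow = TRUE))$p.value
    }
    # carrier enrichment among affected, on margin-normalised rates
    rate_het <- if (sum(het) > 0) sum(aff & het) / sum(het) else NA_real_
    rate_hom <- if (sum(!het) > 0) sum(aff & !het) / sum(!het) else NA_real_
    dir <- if (mono || is.na(rate_het) || is.na(rate_hom)) NA_character_
      else if (rate_het >= rate_hom) "HET_129" else "HOM_FVB"
    tibble(
      marker = m, chrom = markers$chrom[i], pos = markers$pos[i],
      aff_het = tab[["aff_het"]], aff_hom = tab[["aff_hom"]],
      unaff_het = tab[["unaff_het"]], unaff_hom = tab[["unaff_hom"]],
      p = p, or_direction = dir, monomorphic = mono
    )
  })
  out <- bind_rows(rows)
  out$bonferroni_sig <- out$p < alpha / nrow(out)
  out <- arrange(out, .data$p, .data$pos)
  class(out) <- c("linkage_scan", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "n_mice") <- nrow(geno)
  out
}

#' One-row summary of a linkage scan
#'
#' @param x A `linkage_scan` tibble from [marker_scan()].
#' @param ... Unused.
#' @return One-row tibble with the top marker, its p-value, the Bonferroni
#'   threshold and the number of genome-wide-significant markers.
#' @export
glance.linkage_scan <- function(x, ...) {
  tibble(
    n_markers = nrow(x),
    n_mice = attr(x, "n_mice"),
    top_marker = x$marker[1],
    top_p = x$p[1],
    bonferroni_threshold = attr(x, "alpha") / nrow(x),
    n_significant = sum(x$bonferroni_sig)
  )
}

#' Candidate interval from affected recombinants
#'
#' Delineates the candidate region on one chromosome as the largest run of
#' markers at which *every* affected carrier mouse retains the 129P2 allele
#' (the intersection of their heterozygous segments), expanded to the
#' flanking markers where the first recombinant breakpoints fall. Only
#' affected animals are used: unaffected carriers cannot exclude regions
#' under incomplete penetrance. A carrier is a mouse heterozygous somewhere
#' on the target chromosome. When the intersection is empty the top
#' association marker plus/minus one marker is returned, flagged by
#' `method = "fallback"`.
#'
#' @param cohort A `cross_cohort`.
#' @param target_chrom Chromosome to fine-map.
#' @return One-row tibble `chrom`, `start`, `end` (bp, marker-bounded),
#'   `n_markers` (markers in the shared segment), `method`
#'   (`"intersection"` or `"fallback"`).
#' @export
candidate_interval <- function(cohort, target_chrom) {
  ck <- .as_cohort(cohort)
  mk <- ck$markers[ck$markers$chrom == target_chrom, , drop = FALSE]
  if (nrow(mk) < 2L) abort("need at least 2 markers on the target chromosome.")
  aff_ids <- ck$phenotypes$mouse_id[ck$phenotypes$affected]
  if (length(aff_ids) == 0L) abort("no affected mice in the cohort.")
  geno <- ck$genotypes[ck$genotypes$mouse_id %in% aff_ids, , drop = FALSE]
  gm <- as.matrix(geno[, mk$marker, drop = FALSE]) == "HET_129"
  carriers <- rowSums(gm) > 0L
  gm <- gm[carriers, , drop = FALSE]
  shared <- if (nrow(gm) > 0L) unname(colSums(gm) == nrow(gm)) else
    rep(FALSE, nrow(mk))
  if (!any(shared)) {
    scan <- marker_scan(ck)
    scan <- scan[scan$chrom == target_chrom, , drop = FALSE]
    top <- match(scan$marker[1], mk$marker)
    lo <- max(1L, top - 1L)
    hi <- min(nrow(mk), top + 1L)
    return(tibble(chrom = target_chrom, start = mk$pos[lo], end = mk$pos[hi],
                  n_markers = hi - lo + 1L, method = "fallback"))
  }
  runs <- rle(shared)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  i0 <- starts[best]
  i1 <- ends[best]
  lo <- max(1L, i0 - 1L)
  hi <- min(nrow(mk), i1 + 1L)
  tibble(chrom = target_chrom, start = mk$pos[lo], end = mk$pos[hi],
         n_markers = i1 - i0 + 1L, method = "intersection")
}

#' Penetrance with an exact confidence interval
#'
#' Fraction of genotype carriers displaying the phenotype, as a percentage,
#' with an exact (Clopper-Pearson) binomial confidence interval. The
#' degenerate 0/n and n/n cases yield valid one-sided intervals.
#'
#' @param affected_carriers Number of affected carriers (vectorised).
#' @param total_carriers Total carriers (> 0).
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble `affected`, `total`, `penetrance_pct`, `ci_lo_pct`,
#'   `ci_hi_pct`.
#' @export
#' @examples
#' penetrance(70, 91) # 76.9%, the "over 75%" carrier penetrance regime
penetrance <- function(affected_carriers, total_carriers, conf_level = 0.95) {
  m <- max(length(affected_carriers), length(total_carriers))
  a <- rep_len(affected_carriers, m)
  t <- rep_len(total_carriers, m)
  if (any(t <= 0)) abort("`total_carriers` must be positive.")
  if (any(a < 0 | a > t)) abort("`affected_carriers` must lie in [0, total].")
  ci <- vapply(seq_len(m), function(i) {
    binom.test(a[i], t[i], conf.level = conf_level)$conf.int
  }, numeric(2))
  tibble(
    affected = as.integer(a), total = as.integer(t),
    penetrance_pct = 100 * a / t,
    ci_lo_pct = 100 * ci[1, ], ci_hi_pct = 100 * ci[2, ]
  )
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric p-value with minimum-likelihood two-siding, for
#' printed contingency tables such as phenotype frequencies by genotype
#' class. The all-zero table yields p = 1 by convention.
#'
#' @param a,b First row of the table (e.g. affected / unaffected carriers).
#' @param c,d Second row (e.g. affected / unaffected non-carriers).
#' @return The two-sided p-value.
#' @export
#' @examples
#' contingency_exact(19, 72, 1, 94) # lung-metaplasia enrichment table
contingency_exact <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(x < 0) || any(x != floor(x))) {
    abort("table entries must be non-negative integers.")
  }
  if (sum(x) == 0) return(1)
  fisher.test(matrix(x, nrow = 2, byrow = TRUE))$p.value
}

.as_cohort <- function(cohort) {
  if (inherits(cohort, "cross_cohort")) return(cohort)
  if (is.list(cohort) &&
        all(c("genotypes", "phenotypes", "markers") %in% names(cohort))) {
    return(structure(cohort, class = "cross_cohort"))
  }
  abort("`cohort` must be a cross_cohort (genotypes + phenotypes + markers).")
}

#' @export
print.cross_cohort <- function(x, ...) {
  cat(sprintf(
    "Backcross cohort: %d mice x %d markers, %d affected\n",
    nrow(x$genotypes), nrow(x$markers), sum(x$phenotypes$affected)
  ))
  invisible(x)
}
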