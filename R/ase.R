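#' Call allele-specific expression from diagnostic-SNP counts
#'
#' Estimates the 129P2 (A1) transcript fraction of each gene from counts of
#' allele-diagnostic observations — the quantitative abstraction of scoring
#' a 3'UTR SNP in sequenced amplicons — and classifies each locus as
#' `A1_biased`, `A2_biased` or `balanced`. The test is the same exact
#' two-sided binomial used by the ChIP-seq imbalance scan, against
#' `null_fraction` (0.5 for a balanced diploid locus; set it to the
#' copy-number-adjusted fraction, e.g. 1/3, on an aneuploid background).
#' Loci below `min_depth` total observations receive verdict `withheld`.
#' Confidence intervals are exact Clopper-Pearson at level `1 - alpha`.
#'
#' @param data Tibble with columns `gene`, `c1` (A1-supporting
#'   observations) and `c2` (A2-supporting observations).
#' @param null_fraction Expected A1 fraction under no allele bias (default
#'   0.5).
#' @param alpha Significance level for the verdict (default 0.05).
#' @param min_depth Minimum `c1 + c2` for a verdict (default 20).
#' @return Tibble `gene`, `c1`, `c2`, `fraction`, `ci_lo`, `ci_hi`, `p`,
#'   `verdict` (factor: `A1_biased`, `A2_biased`, `balanced`, `withheld`).
#' @export
#' @examples
#' ase_call(tibble::tibble(
#'   gene = c("Wnt7b", "Fbln1"), c1 = c(95, 52), c2 = c(5, 48)
#' ))
ase_call <- function(data, null_fraction = 0.5, alpha = 0.05,
                     min_depth = 20) {
  data <- as_tibble(data)
  if (!all(c("gene", "c1", "c2") %in% names(data))) {
    abort("`data` needs columns gene, c1, c2.")
  }
  if (null_fraction <= 0 || null_fraction >= 1) {
    abort("`null_fraction` must lie strictly between 0 and 1.")
  }
  n <- data$c1 + data$c2
  deep <- n >= min_depth
  p <- rep(NA_real_, nrow(data))
  ci_lo <- rep(NA_real_, nrow(data))
  ci_hi <- rep(NA_real_, nrow(data))
  if (any(deep)) {
    p[deep] <- exact_allelic_test(data$c1[deep], data$c2[deep], null_fraction)
    ci <- vapply(which(deep), function(i) {
      binom.test(data$c1[i], n[i], conf.level = 1 - alpha)$conf.int
    }, numeric(2))
    ci_lo[deep] <- ci[1, ]
    ci_hi[deep] <- ci[2, ]
  }
  fraction <- ifelse(n > 0, data$c1 / n, NA_real_)
  verdict <- rep("withheld", nrow(data))
  sig <- deep & p < alpha
  verdict[deep & !sig] <- "balanced"
  verdict[sig & fraction > null_fraction] <- "A1_biased"
  verdict[sig & fraction < null_fraction] <- "A2_biased"
  verdict[sig & fraction == null_fraction] <- "balanced"
  tibble(
    gene = data$gene, c1 = as.integer(data$c1), c2 = as.integer(data$c2),
    fraction = fraction, ci_lo = ci_lo, ci_hi = ci_hi, p = p,
    verdict = factor(verdict,
                     levels = c("A1_biased", "A2_biased", "balanced",
                                "withheld"))
  )
}
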