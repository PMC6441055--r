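#' Exact conditional test of allelic imbalance
#'
#' Tests whether the A1 read count of a window deviates from the expected
#' allelic ratio. The exact comparison of two Poisson-distributed allele
#' counts against a fixed rate ratio, conditioned on their observed total,
#' reduces to an exact binomial test of `c1` successes in `n = c1 + c2`
#' trials with success probability `rho` — the form computable from the
#' counts and the baseline alone. The p-value is two-sided by the
#' minimum-likelihood rule: the sum of the probabilities of all outcomes no
#' more likely than the observed one (with the customary `1 + 1e-7` relative
#' tolerance for ties), so the modal outcome yields p = 1 and p always lies
#' in (0, 1].
#'
#' The implementation enumerates the full binomial pmf, shared across calls
#' with equal `(n, rho)`, so genome scans with a common per-chromosome
#' baseline are vectorised cheaply.
#'
#' @param c1,c2 Non-negative integer A1 and A2 counts (vectorised; recycled).
#'   Every `c1 + c2` must be at least 1.
#' @param rho Expected A1 fraction in (0, 1), e.g. the per-chromosome median
#'   allelic ratio (1/3 for a 1:2 trisomy).
#' @return Numeric vector of two-sided exact p-values.
#' @export
#' @examples
#' exact_allelic_test(5, 5, 0.5)        # modal outcome: p = 1
#' exact_allelic_test(20, 10, 0.5)      # ~0.099
#' exact_allelic_test(0, 30, 1 / 3)
exact_allelic_test <- function(c1, c2, rho) {
  m <- max(length(c1), length(c2), length(rho))
  c1 <- rep_len(as.numeric(c1), m)
  c2 <- rep_len(as.numeric(c2), m)
  rho <- rep_len(as.numeric(rho), m)
  if (any(is.na(c1) | is.na(c2) | c1 < 0 | c2 < 0 |
            c1 != floor(c1) | c2 != floor(c2))) {
    abort("`c1` and `c2` must be non-negative integers.")
  }
  n <- c1 + c2
  if (any(n < 1)) abort("each window must have `c1 + c2 >= 1`.")
  if (any(is.na(rho) | rho <= 0 | rho >= 1)) {
    abort("`rho` must lie strictly between 0 and 1.")
  }
  p <- numeric(m)
  grp <- paste(n, rho)
  for (g in split(seq_len(m), grp)) {
    ni <- n[g[1]]
    ri <- rho[g[1]]
    d <- dbinom(0:ni, ni, ri)
    ord <- order(d)
    cum <- cumsum(d[ord])
    thr <- d[c1[g] + 1] * (1 + 1e-7)
    k <- findInterval(thr, d[ord])
    p[g] <- pmin(1, cum[pmax(k, 1L)])
  }
  p
}

#' Fisher's combined probability test
#'
#' Combines independent p-values — here, the per-clone window p-values of
#' the allelic imbalance test — into one statistic:
#' `chi2 = -2 * sum(log(p))`, which under the joint null follows a
#' chi-square distribution with `2k` degrees of freedom for `k` p-values.
#' Zero p-values are floored at 1e-300 with a warning so the statistic stays
#' finite, and a combined p-value that underflows the chi-square tail is
#' likewise floored at 1e-300 so it remains in (0, 1].
#'
#' @param p Numeric vector of p-values in (0, 1] (one set to combine), or a
#'   matrix/data frame with one row per window and one column per clone.
#' @return A tibble with columns `chi2`, `df` and `p_combined`, one row per
#'   combined set.
#' @export
#' @examples
#' fisher_combine(c(0.05, 0.05, 0.05))
fisher_combine <- function(p) {
  pm <- if (is.matrix(p) || is.data.frame(p)) as.matrix(p) else
    matrix(as.numeric(p), nrow = 1L)
  if (ncol(pm) < 1L || nrow(pm) < 1L) abort("`p` must contain p-values.")
  if (any(is.na(pm)) || any(pm < 0) || any(pm > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  if (any(pm == 0)) {
    warn("zero p-value(s) floored at 1e-300 before combination.")
    pm[pm == 0] <- 1e-300
  }
  chi2 <- -2 * rowSums(log(pm))
  df <- 2L * ncol(pm)
  tibble(
    chi2 = chi2, df = df,
    # the upper tail can underflow to 0 for extreme statistics; keep the
    # combined p in (0, 1] as the downstream BH step requires
    p_combined = pmax(pchisq(chi2, df = df, lower.tail = FALSE), 1e-300)
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR-adjusted q-values (via [stats::p.adjust()]), applied once
#' across all tested windows of a run so the selection `q < threshold`
#' controls the expected false-discovery proportion genome-wide.
#'
#' @param p Numeric vector of p-values in (0, 1]; may be empty.
#' @return Numeric vector of q-values of the same length.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  p.adjust(p, method = "BH")
}
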