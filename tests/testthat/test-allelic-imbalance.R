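# Brute-force oracle for the two-sided minimum-likelihood binomial p-value:
# enumerate the full pmf and sum every outcome no more likely than observed.
oracle_two_sided <- function(x, n, rho) {
  d <- dbinom(0:n, n, rho)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

test_that("window tiling follows the stated start/step/clipping convention", {
  w <- make_windows(1000, sizes = 250, step_fraction = 0.5)
  expect_equal(nrow(w), 7L)
  expect_equal(w$start, seq(0L, 750L, by = 125L))
  expect_equal(w$end - w$start, rep(250L, 7))

  expect_warning(w0 <- make_windows(100, sizes = 250), "shorter")
  expect_equal(nrow(w0), 0L)

  # closed-form count for each size tier on a 10 kb chromosome
  w3 <- make_windows(10000, sizes = c(250, 500, 1000), step_fraction = 0.5)
  counts <- table(w3$size)
  for (s in c(250, 500, 1000)) {
    expect_equal(unname(counts[as.character(s)]),
                 floor((10000 - s) / (s * 0.5)) + 1)
  }
  expect_true(all(w3$end <= 10000))
})

test_that("reads are counted into windows by their start coordinate", {
  snps <- tiny_snps()
  reads <- dplyr::bind_rows(
    tiny_read(1:3, start = 100L, end = 200L, obs = "149:A"),  # 3 x A1 inside
    tiny_read(4L, start = 120L, end = 220L, obs = "149:T"),   # 1 x A2 inside
    tiny_read(5L, start = 99L, end = 199L, obs = "149:A"),    # 1 bp before
    tiny_read(6L, start = 250L, end = 350L, obs = "300:T")    # beyond window
  )
  calls <- assign_reads(reads, snps)
  win <- tibble::tibble(chrom = "chr15", size = 100L, start = 100L,
                        end = 200L)
  wc <- count_windows(calls, win)
  expect_equal(wc$c1, 3L)
  expect_equal(wc$c2, 1L)
  # empty window
  wc0 <- count_windows(calls, tibble::tibble(chrom = "chr15", size = 100L,
                                             start = 500L, end = 600L))
  expect_equal(wc0$c1 + wc0$c2, 0L)
})

test_that("baseline is the median allelic ratio over qualifying windows", {
  wc <- tibble::tibble(
    chrom = "chr15", size = 500L, start = c(0L, 500L, 1000L),
    end = c(500L, 1000L, 1500L), clone = 1L,
    c1 = c(30L, 33L, 36L), c2 = c(70L, 67L, 64L)
  )
  b <- chromosome_baseline(wc, min_total = 10)
  expect_equal(b$rho, 0.33)

  # all windows below min_total: skipped with a message
  expect_message(
    b0 <- chromosome_baseline(dplyr::mutate(wc, c1 = 1L, c2 = 1L),
                              min_total = 10),
    "skipped"
  )
  expect_equal(nrow(b0), 0L)

  # robustness: one extreme window moves the median by one order statistic
  wc5 <- tibble::tibble(
    chrom = "chr15", size = 500L, start = seq(0L, 2000L, 500L),
    end = seq(500L, 2500L, 500L), clone = 1L,
    c1 = c(30L, 31L, 33L, 35L, 36L), c2 = c(70L, 69L, 67L, 65L, 64L)
  )
  rho0 <- chromosome_baseline(wc5, min_total = 10)$rho
  wc6 <- dplyr::bind_rows(wc5, tibble::tibble(
    chrom = "chr15", size = 500L, start = 2500L, end = 3000L, clone = 1L,
    c1 = 100L, c2 = 0L
  ))
  rho1 <- chromosome_baseline(wc6, min_total = 10)$rho
  fr <- sort(wc5$c1 / 100)
  expect_lte(abs(rho1 - rho0), max(diff(fr)))
})

test_that("exact allelic test equals brute-force pmf enumeration", {
  expect_equal(exact_allelic_test(5, 5, 0.5), 1)
  expect_equal(exact_allelic_test(20, 10, 0.5), 0.0987371467053889,
               tolerance = 1e-12)
  expect_equal(exact_allelic_test(0, 30, 1 / 3),
               oracle_two_sided(0, 30, 1 / 3), tolerance = 1e-13)
  # sweep small totals against the oracle at the three baseline regimes
  for (rho in c(0.1, 1 / 3, 0.5)) {
    for (n in c(1, 2, 7, 30, 61)) {
      x <- 0:n
      expect_equal(
        exact_allelic_test(x, n - x, rho),
        vapply(x, oracle_two_sided, numeric(1), n = n, rho = rho),
        tolerance = 1e-12
      )
    }
  }
  # agrees with the standard exact binomial test implementation
  expect_equal(exact_allelic_test(17, 40, 1 / 3),
               binom.test(17, 57, 1 / 3)$p.value, tolerance = 1e-12)
  expect_error(exact_allelic_test(0, 0, 0.5), "c1 \\+ c2")
  expect_error(exact_allelic_test(1, 1, 0), "strictly between")
})

test_that("Fisher combination matches the closed-form even-df chi-square tail", {
  # survival function for even df: exp(-x/2) * sum_{j<df/2} (x/2)^j / j!
  chisq_sf_even <- function(x, df) {
    j <- 0:(df / 2 - 1)
    exp(-x / 2) * sum((x / 2)^j / factorial(j))
  }
  out <- fisher_combine(c(0.05, 0.05, 0.05))
  expect_equal(out$chi2, 17.9743936413239, tolerance = 1e-12)
  expect_equal(out$df, 6L)
  expect_equal(out$p_combined, chisq_sf_even(out$chi2, 6),
               tolerance = 1e-10)

  expect_equal(fisher_combine(0.05)$p_combined, 0.05, tolerance = 1e-12)
  expect_equal(fisher_combine(c(1, 1, 1))$chi2, 0)
  expect_equal(fisher_combine(c(1, 1, 1))$p_combined, 1)

  set.seed(1)
  pm <- matrix(runif(60), ncol = 3)
  got <- fisher_combine(pm)
  want <- vapply(seq_len(20), function(i) {
    chisq_sf_even(-2 * sum(log(pm[i, ])), 6)
  }, numeric(1))
  expect_equal(got$p_combined, want, tolerance = 1e-10)

  expect_warning(z <- fisher_combine(c(0, 0.5)), "floored")
  expect_true(is.finite(z$chi2))
})

test_that("BH adjustment matches hand-enumerated step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 4)), rep(0.2, 4))
  expect_equal(bh_fdr(0.123), 0.123)
  expect_equal(bh_fdr(numeric()), numeric())
  # step-up by hand: q_(i) = min_{j >= i} min(1, p_(j) * m / j)
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216,
         0.222, 0.251, 0.269, 0.275, 0.34, 0.341, 0.384, 0.569, 0.594, 0.696)
  m <- length(p)
  hand <- rev(cummin(rev(pmin(1, sort(p) * m / seq_len(m)))))[rank(p)]
  expect_equal(bh_fdr(p), hand)
})

test_that("significant windows merge into direction-consistent regions", {
  base <- tibble::tibble(
    chrom = "chr15", size = 500L,
    start = c(1000L, 1250L, 3000L, 5000L),
    end = c(1500L, 1750L, 3500L, 5500L),
    chi2 = 1, df = 2L, p_combined = 1,
    q = c(0.001, 0.004, 0.2, 0.003),
    pooled_fraction = c(0.66, 0.70, 0.34, 0.10),
    rho = 1 / 3
  )
  base$fold <- base$pooled_fraction / base$rho
  r <- call_regions(base, q_threshold = 0.05, direction = "A1_up")
  expect_equal(nrow(r), 1L) # two overlapping A1-up windows merge
  expect_equal(r$start, 1000L)
  expect_equal(r$end, 1750L)
  expect_equal(r$q, 0.001)
  expect_equal(r$n_windows, 2L)
  # width-weighted mean fold of the two members
  expect_equal(r$fold, mean(c(0.66, 0.70) / (1 / 3)))

  rboth <- call_regions(base, q_threshold = 0.05, direction = "both")
  expect_equal(nrow(rboth), 2L)
  expect_setequal(rboth$direction, c("A1_up", "A2_up"))

  expect_equal(nrow(call_regions(base, q_threshold = 1e-5)), 0L)
  # book-ended windows merge too
  bk <- base[1:2, ]
  bk$start <- c(1000L, 1500L)
  bk$end <- c(1500L, 2000L)
  expect_equal(nrow(call_regions(bk)), 1L)
})
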