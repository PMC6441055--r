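# Full hypergeometric enumeration oracle for the two-sided Fisher exact test
# (minimum-likelihood two-siding), independent of stats::fisher.test.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  x <- max(0, k - n):min(k, m)
  dens <- dhyper(x, m, n, k)
  sum(dens[dens <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

test_that("penetrance arithmetic and exact CIs behave at the boundaries", {
  p <- penetrance(70, 91)
  expect_equal(p$penetrance_pct, 100 * 70 / 91)
  expect_gte(p$penetrance_pct, 75)
  expect_true(p$ci_lo_pct <= p$penetrance_pct &&
                p$penetrance_pct <= p$ci_hi_pct)

  p0 <- penetrance(0, 95)
  expect_equal(p0$penetrance_pct, 0)
  expect_equal(p0$ci_lo_pct, 0)
  expect_gt(p0$ci_hi_pct, 0)

  p1 <- penetrance(91, 91)
  expect_equal(p1$penetrance_pct, 100)
  expect_equal(p1$ci_hi_pct, 100)
  expect_lt(p1$ci_lo_pct, 100)

  expect_error(penetrance(1, 0), "positive")
})

test_that("2x2 exact test matches hypergeometric enumeration", {
  expect_equal(contingency_exact(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
  expect_equal(contingency_exact(0, 10, 0, 10), 1)
  expect_equal(contingency_exact(0, 0, 0, 0), 1)
  cases <- list(c(19, 72, 1, 94), c(3, 7, 5, 5), c(12, 2, 3, 9),
                c(1, 1, 1, 1), c(8, 0, 2, 6))
  for (x in cases) {
    expect_equal(contingency_exact(x[1], x[2], x[3], x[4]),
                 oracle_fisher(x[1], x[2], x[3], x[4]), tolerance = 1e-10)
  }
  # symmetric under simultaneous row and column swaps
  for (x in cases) {
    expect_equal(contingency_exact(x[1], x[2], x[3], x[4]),
                 contingency_exact(x[4], x[3], x[2], x[1]),
                 tolerance = 1e-12)
  }
  expect_error(contingency_exact(-1, 1, 1, 1), "non-negative")
})

test_that("the marker scan finds the linked marker and ranks it first", {
  ck <- simulate_cross(cross_spec(200, marker_panel(), 10, 0.77, 0,
                                  seed = 61))
  scan <- marker_scan(ck)
  expect_identical(scan$marker[1], "M010")
  expect_true(scan$bonferroni_sig[1])
  expect_identical(scan$or_direction[1], "HET_129")
  g <- glance(scan)
  expect_identical(g$top_marker, "M010")
  expect_equal(g$n_markers, 20L)
  expect_s3_class(autoplot(scan), "ggplot")
})

test_that("scan p-values are invariant to mouse ordering", {
  ck <- simulate_cross(cross_spec(100, marker_panel(), 5, 0.8, 0.05,
                                  seed = 62))
  idx <- sample.int(100)
  ck2 <- ck
  ck2$genotypes <- ck$genotypes[idx, ]
  ck2$phenotypes <- ck$phenotypes[idx, ]
  s1 <- marker_scan(ck)
  s2 <- marker_scan(ck2)
  expect_equal(s1$p, s2$p)
  expect_equal(s1$marker, s2$marker)
})

test_that("degenerate scans are handled: all affected, monomorphic marker", {
  ck <- simulate_cross(cross_spec(50, marker_panel(5), 3, 1, 1, seed = 63))
  scan <- marker_scan(ck)
  expect_true(all(scan$p == 1))

  ck2 <- simulate_cross(cross_spec(40, marker_panel(3), 2, 0.8, seed = 64))
  ck2$genotypes$M001 <- "HOM_FVB" # force monomorphic
  scan2 <- marker_scan(ck2)
  expect_true(scan2$monomorphic[scan2$marker == "M001"])
  expect_equal(scan2$p[scan2$marker == "M001"], 1)
})

test_that("candidate interval brackets the linked marker via recombinants", {
  ck <- simulate_cross(cross_spec(200, marker_panel(), 10, 0.9, 0,
                                  recomb_per_mb = 0.01, seed = 65))
  iv <- candidate_interval(ck, "chr15")
  truth_pos <- ck$markers$pos[10]
  expect_identical(iv$method, "intersection")
  expect_true(iv$start <= truth_pos && truth_pos <= iv$end)
  # recombinants exist at this recombination rate, so the interval is a
  # proper sub-segment of the chromosome
  expect_lt(iv$end - iv$start, max(ck$markers$pos) - min(ck$markers$pos))
})

test_that("candidate interval spans all markers when nothing recombines", {
  ck <- simulate_cross(cross_spec(60, marker_panel(), 10, 0.9, 0,
                                  recomb_per_mb = 0, seed = 66))
  iv <- candidate_interval(ck, "chr15")
  expect_equal(iv$start, min(ck$markers$pos))
  expect_equal(iv$end, max(ck$markers$pos))
  expect_equal(iv$n_markers, 20L)
})

test_that("a single affected mouse defines its own carrier segment", {
  mk <- marker_panel(6)
  geno <- tibble::tibble(
    mouse_id = "m001",
    M001 = "HOM_FVB", M002 = "HET_129", M003 = "HET_129",
    M004 = "HET_129", M005 = "HOM_FVB", M006 = "HOM_FVB"
  )
  ck <- structure(
    list(
      genotypes = geno,
      phenotypes = tibble::tibble(mouse_id = "m001", affected = TRUE,
                                  tumour_count = 3L),
      markers = mk, truth = NULL
    ),
    class = "cross_cohort"
  )
  iv <- candidate_interval(ck, "chr15")
  # the HET run is markers 2-4, expanded to the flanking markers 1 and 5
  expect_equal(iv$start, mk$pos[1])
  expect_equal(iv$end, mk$pos[5])
  expect_equal(iv$n_markers, 3L)
})
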