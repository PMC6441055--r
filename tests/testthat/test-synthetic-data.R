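test_that("simulation is byte-identical under a fixed seed", {
  s1 <- small_sim(seed = 11)
  s2 <- small_sim(seed = 11)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$observations, s2$observations)
  expect_identical(s1$snps, s2$snps)
  s3 <- small_sim(seed = 12)
  expect_false(identical(s1$reads, s3$reads))
})

test_that("total read count is Poisson-consistent with length x rate", {
  len <- 2e5
  rate <- 0.2
  sim <- small_sim(seed = 3, length = len, rate = rate, n_clones = 2)
  for (cl in 1:2) {
    n <- sum(sim$reads$clone == cl)
    lambda <- len * rate
    expect_lt(abs(n - lambda), 4 * sqrt(lambda))
  }
})

test_that("with error_rate = 0 every observed base matches the true haplotype", {
  sim <- small_sim(seed = 5, rate = 0.1)
  obs <- dplyr::left_join(sim$observations,
                          sim$reads[, c("read_id", "hap")], by = "read_id")
  obs <- dplyr::left_join(obs, sim$snps, by = c("chrom", "pos"))
  expected <- ifelse(obs$hap == "A1", obs$a1_base, obs$a2_base)
  expect_identical(obs$base, expected)
})

test_that("background allelic fraction follows haplotype copy number", {
  # 1:2 copies -> expected A1 fraction 1/3; 1:1 -> 1/2
  sim12 <- small_sim(seed = 21, copies_a1 = 1, copies_a2 = 2)
  n1 <- sum(sim12$reads$hap == "A1")
  expect_within_binom_ci(n1, nrow(sim12$reads), 1 / 3)

  sim11 <- small_sim(seed = 22, copies_a1 = 1, copies_a2 = 1)
  expect_within_binom_ci(sum(sim11$reads$hap == "A1"),
                         nrow(sim11$reads), 0.5)
})

test_that("empirical A1 fraction tightens around 1/3 as coverage grows", {
  # mean absolute error over replicates at a 40x coverage ratio; the
  # high-coverage error must be decisively smaller
  mean_err <- vapply(c(0.02, 0.8), function(rate) {
    errs <- vapply(1:5, function(r) {
      sim <- small_sim(seed = 310 + r, length = 1e5, rate = rate)
      abs(mean(sim$reads$hap == "A1") - 1 / 3)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_lt(mean_err[2], mean_err[1])
})

test_that("implanted enhancer shifts the local A1 fraction and coverage", {
  enh <- enhancer_spec("chr15", 8e4, 9e4, coverage_mult = 5,
                       a1_fraction = 2 / 3)
  sim <- small_sim(seed = 41, rate = 0.3, enhancers = enh)
  inside <- sim$reads$start >= 8e4 & sim$reads$start < 9e4
  expect_within_binom_ci(sum(sim$reads$hap[inside] == "A1"), sum(inside),
                         2 / 3)
  expect_within_binom_ci(sum(sim$reads$hap[!inside] == "A1"), sum(!inside),
                         1 / 3)
  # truth sidecar carries the generative values
  expect_equal(sim$truth$a1_fraction, 2 / 3)
  expect_equal(sim$truth$baseline_fraction, 1 / 3)
})

test_that("invalid enhancer layouts are rejected", {
  enh <- dplyr::bind_rows(
    enhancer_spec("chr15", 1e4, 2e4, 2, 0.5),
    enhancer_spec("chr15", 1.5e4, 2.5e4, 2, 0.5)
  )
  expect_error(small_sim(enhancers = enh), "must not overlap")
  expect_error(
    small_sim(enhancers = enhancer_spec("chr15", 1.9e5, 2.1e5, 2, 0.5)),
    "within their chromosome"
  )
  expect_error(enhancer_spec("chr15", 100, 100, 1, 0.5), "greater than")
})

test_that("a chromosome can end up with zero SNPs, with a warning", {
  expect_warning(
    sim <- simulate_chip_reads(
      chrom_spec("chrU", 1000, snp_density = 1e-9),
      sim = read_sim(background_rate = 0.1, n_clones = 1, seed = 1)
    ),
    "zero informative SNPs"
  )
  expect_gt(nrow(sim$reads), 0)
  expect_equal(nrow(sim$observations), 0)
})

test_that("backcross cohort reproduces penetrance and recombination settings", {
  mk <- marker_panel()
  ck <- simulate_cross(cross_spec(400, mk, 10, 70 / 91, 0, seed = 19))
  carrier <- ck$genotypes[["M010"]] == "HET_129"
  aff <- ck$phenotypes$affected
  expect_within_binom_ci(sum(aff[carrier]), sum(carrier), 70 / 91)
  expect_equal(sum(aff[!carrier]), 0)
  expect_identical(ck$truth$linked_marker, "M010")

  # zero recombination: genotype constant along the chromosome
  ck0 <- simulate_cross(cross_spec(50, mk, 10, 0.5, 0.5,
                                   recomb_per_mb = 0, seed = 23))
  gm <- as.matrix(ck0$genotypes[, mk$marker])
  expect_true(all(apply(gm, 1, function(r) length(unique(r)) == 1L)))

  expect_error(cross_spec(10, mk[0, ], 1, 0.5, seed = 1), "at least one")
  expect_identical(simulate_cross(cross_spec(60, mk, 5, 0.8, seed = 2)),
                   simulate_cross(cross_spec(60, mk, 5, 0.8, seed = 2)))
})
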