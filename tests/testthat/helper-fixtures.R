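# Shared in-code fixtures: tiny SNP tables, reads and simulations used
# across the unit tests. Everything is built programmatically and seeded.

tiny_snps <- function() {
  tibble::tibble(
    chrom = "chr15",
    pos = c(99L, 149L, 300L),
    a1_base = c("G", "A", "T"),
    a2_base = c("C", "T", "G")
  )
}

tiny_read <- function(read_id = 1L, start = 50L, end = 150L, obs = "",
                      clone = 1L, chrom = "chr15") {
  tibble::tibble(read_id = read_id, chrom = chrom, start = start,
                 end = end, clone = clone, obs = obs)
}

# small seeded chip simulation reused by several files
small_sim <- function(seed = 7, length = 2e5, copies_a1 = 1, copies_a2 = 2,
                      rate = 0.2, n_clones = 1, error_rate = 0,
                      enhancers = NULL) {
  simulate_chip_reads(
    chrom_spec("chr15", length, copies_a1, copies_a2),
    enhancers = enhancers,
    sim = read_sim(background_rate = rate, n_clones = n_clones,
                   error_rate = error_rate, seed = seed)
  )
}

marker_panel <- function(n = 20, chrom = "chr15", spacing = 2e7) {
  tibble::tibble(
    marker = sprintf("M%03d", seq_len(n)),
    chrom = chrom,
    pos = seq(5e6, by = spacing, length.out = n)
  )
}

# two-sided binomial-CI check that an empirical proportion is consistent
# with a generative value (independent of the package code under test)
expect_within_binom_ci <- function(successes, n, p_true, conf = 0.999) {
  ci <- stats::binom.test(successes, n, conf.level = conf)$conf.int
  expect_true(
    p_true >= ci[1] && p_true <= ci[2],
    label = sprintf("generative p = %.4f inside %.1f%% CI [%.4f, %.4f] (x = %d, n = %d)",
                    p_true, 100 * conf, ci[1], ci[2], successes, n)
  )
}
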