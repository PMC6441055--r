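#' Run the allele-specific imbalance pipeline
#'
#' End-to-end orchestration of the genome scan: assign reads to haplotypes,
#' tile every chromosome with multi-scale sliding windows, sum allele counts
#' per window and clone, set the expected ratio to the per-chromosome median
#' allelic ratio, test every qualifying window in every clone with the exact
#' conditional test, combine the clone p-values with Fisher's method, adjust
#' with Benjamini-Hochberg across all windows of the run, and merge
#' significant windows of consistent direction into candidate regions.
#'
#' Windows qualify for testing only when *every* clone has at least
#' `min_total` informative reads in them; windows failing this in any clone
#' are dropped before combination (never imputed) and the attrition is
#' recorded in the run report. The test is two-sided; directionality is a
#' post-hoc filter at region-calling time, so a scan for 129P2-up regions
#' does not change any p-value.
#'
#' @param reads Reads tibble (see [assign_reads()]).
#' @param snps SNP table (see [load_snps()]).
#' @param observations Optional long observation tibble (fast path for
#'   simulated data).
#' @param chrom_lengths Named vector of chromosome lengths in bp; when
#'   `NULL`, inferred as the maximum read end per chromosome.
#' @param sizes,step_fraction Window scheme (see [make_windows()]).
#' @param min_total Minimum informative reads per window per clone
#'   (default 10).
#' @param q_threshold FDR threshold for region calling (default 0.05).
#' @param direction `"A1_up"` (default), `"A2_up"`, or `"both"`.
#' @param conflict_policy Passed to [assign_reads()].
#' @param pool_baseline Pool clones for the median baseline?
#' @param n_clones Expected clone count; if supplied and not matching the
#'   clones present in `reads`, the run is rejected.
#'
#' @return An object of class `imbalance_fit` with components
#'   `windows` (per-window test tibble: counts, per-clone p-values packed as
#'   `p_clone<k>` columns, `chi2`, `df`, `p_combined`, `q`,
#'   `pooled_fraction`, `rho` and `fold`), `regions` (see [call_regions()]),
#'   `baselines`, `assignment` (per-chromosome call tallies), `params` and
#'   `report` (per-stage attrition counts). Methods: [tidy()], [glance()],
#'   [autoplot()], `print()`.
#' @export
run_imbalance <- function(reads, snps, observations = NULL,
                          chrom_lengths = NULL,
                          sizes = c(250, 500, 1000), step_fraction = 0.5,
                          min_total = 10, q_threshold = 0.05,
                          direction = c("A1_up", "A2_up", "both"),
                          conflict_policy = c("drop", "majority"),
                          pool_baseline = FALSE, n_clones = NULL) {
  direction <- match.arg(direction)
  conflict_policy <- match.arg(conflict_policy)
  reads <- as_tibble(reads)
  if (nrow(reads) == 0L) abort("`reads` is empty.")
  clones <- sort(unique(reads$clone))
  if (!is.null(n_clones) && length(clones) != n_clones) {
    abort(sprintf("expected %d clone(s) but reads contain %d.",
                  n_clones, length(clones)))
  }
  snps <- validate_snps(snps)
  if (!all(unique(snps$chrom) %in% unique(reads$chrom))) {
    warn("SNP table contains chromosomes absent from the reads.")
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(reads$end, reads$chrom, max)
    chrom_lengths <- setNames(as.integer(chrom_lengths), names(chrom_lengths))
  }

  calls <- assign_reads(reads, snps, observations = observations,
                        conflict_policy = conflict_policy)
  assignment <- assignment_summary(calls)

  windows <- bind_rows(lapply(names(chrom_lengths), function(ch) {
    w <- make_windows(chrom_lengths[[ch]], sizes = sizes,
                      step_fraction = step_fraction)
    if (nrow(w) > 0L) w$chrom <- ch
    w
  }))
  if (nrow(windows) == 0L) abort("no windows could be tiled on any chromosome.")
  counts <- count_windows(calls, windows, clones = clones)
  baselines <- chromosome_baseline(counts, min_total = min_total,
                                   pool_clones = pool_baseline)

  tests <- .test_windows(counts, baselines, clones, min_total, pool_baseline)
  regions <- call_regions(tests, q_threshold = q_threshold,
                          direction = direction)

  n_win <- nrow(windows)
  report <- list(
    n_reads = nrow(reads),
    n_informative = sum(assignment$n_a1 + assignment$n_a2),
    n_conflict = sum(assignment$n_conflict),
    n_noninformative = sum(assignment$n_noninformative),
    n_windows_tiled = n_win,
    n_windows_tested = nrow(tests),
    n_windows_dropped_min_total = n_win - nrow(tests),
    n_windows_significant = sum(tests$q < q_threshold),
    n_regions = nrow(regions)
  )
  structure(
    list(
      windows = tests, regions = regions, baselines = baselines,
      assignment = assignment,
      params = list(
        sizes = sizes, step_fraction = step_fraction, min_total = min_total,
        q_threshold = q_threshold, direction = direction,
        conflict_policy = conflict_policy, pool_baseline = pool_baseline,
        clones = clones, chrom_lengths = as.list(chrom_lengths)
      ),
      report = report
    ),
    class = "imbalance_fit"
  )
}

# Per-window per-clone exact tests + Fisher combination + BH, wide layout.
.test_windows <- function(counts, baselines, clones, min_total,
                          pool_baseline) {
  key <- paste(counts$chrom, counts$size, counts$start)
  ok <- counts$c1 + counts$c2 >= min_total
  qualified <- names(which(tapply(ok, key, all)))
  counts <- counts[key %in% qualified, , drop = FALSE]
  empty <- tibble(
    chrom = character(), size = integer(), start = integer(),
    end = integer(), chi2 = numeric(), df = integer(),
    p_combined = numeric(), q = numeric(), pooled_fraction = numeric(),
    rho = numeric(), fold = numeric()
  )
  if (nrow(counts) == 0L) return(empty)
  if (pool_baseline) {
    counts$rho <- baselines$rho[match(counts$chrom, baselines$chrom)]
  } else {
    bkey <- paste(baselines$chrom, baselines$clone)
    counts$rho <- baselines$rho[match(paste(counts$chrom, counts$clone), bkey)]
  }
  counts <- counts[!is.na(counts$rho), , drop = FALSE]
  # a chromosome lacking a baseline in some clone loses those rows; keep only
  # windows still complete across all clones so the clone matrix stays aligned
  key <- paste(counts$chrom, counts$size, counts$start)
  complete <- names(which(table(key) == length(clones)))
  counts <- counts[key %in% complete, , drop = FALSE]
  if (nrow(counts) == 0L) return(empty)
  counts$p <- exact_allelic_test(counts$c1, counts$c2, counts$rho)

  counts <- arrange(counts, .data$chrom, .data$size, .data$start, .data$clone)
  nc <- length(clones)
  stopifnot(nrow(counts) %% nc == 0L)
  wi <- seq_len(nrow(counts) / nc)
  first <- (wi - 1L) * nc + 1L
  pm <- matrix(counts$p, ncol = nc, byrow = TRUE)
  colnames(pm) <- paste0("p_clone", clones)
  c1m <- matrix(counts$c1, ncol = nc, byrow = TRUE)
  c2m <- matrix(counts$c2, ncol = nc, byrow = TRUE)
  comb <- fisher_combine(pm)
  pooled <- rowSums(c1m) / (rowSums(c1m) + rowSums(c2m))
  rho_bar <- rowMeans(matrix(counts$rho, ncol = nc, byrow = TRUE))
  out <- tibble(
    chrom = counts$chrom[first], size = counts$size[first],
    start = counts$start[first], end = counts$end[first]
  )
  out <- bind_cols(out, as_tibble(c1m, .name_repair = ~ paste0("c1_clone", clones)))
  out <- bind_cols(out, as_tibble(c2m, .name_repair = ~ paste0("c2_clone", clones)))
  out <- bind_cols(out, as_tibble(pm))
  out$chi2 <- comb$chi2
  out$df <- comb$df
  out$p_combined <- comb$p_combined
  out$q <- bh_fdr(out$p_combined)
  out$pooled_fraction <- pooled
  out$rho <- rho_bar
  out$fold <- pooled / rho_bar
  out
}

#' Merge significant windows into candidate regions
#'
#' Selects the windows passing the FDR threshold in the requested direction
#' (for `"A1_up"`, a pooled fraction above the baseline), across all size
#' tiers, and merges overlapping or book-ended windows into regions. Each
#' region reports its best (minimum) q-value and the coverage-weighted mean
#' fold-change of its member windows.
#'
#' @param tests Per-window test tibble (the `windows` component of an
#'   [run_imbalance()] fit).
#' @param q_threshold FDR threshold (default 0.05).
#' @param direction `"A1_up"`, `"A2_up"` or `"both"`.
#' @return Tibble `chrom`, `start`, `end`, `q` (minimum over members),
#'   `fold` (width-weighted mean), `direction`, `n_windows`. Zero rows when
#'   nothing is significant.
#' @export
call_regions <- function(tests, q_threshold = 0.05,
                         direction = c("A1_up", "A2_up", "both")) {
  direction <- match.arg(direction)
  tests <- as_tibble(tests)
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  q = numeric(), fold = numeric(), direction = character(),
                  n_windows = integer())
  if (nrow(tests) == 0L) return(empty)
  keep <- tests$q < q_threshold
  dir_of <- ifelse(tests$pooled_fraction > tests$rho, "A1_up", "A2_up")
  if (direction != "both") keep <- keep & dir_of == direction
  sig <- tests[keep, , drop = FALSE]
  sig_dir <- dir_of[keep]
  if (nrow(sig) == 0L) return(empty)

  out <- lapply(c("A1_up", "A2_up"), function(d) {
    s <- sig[sig_dir == d, , drop = FALSE]
    if (nrow(s) == 0L) return(NULL)
    gr <- GenomicRanges::GRanges(
      s$chrom, IRanges::IRanges(s$start + 1L, s$end)
    )
    # min.gapwidth = 1 merges book-ended (gap 0) windows
    merged <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
    ov <- GenomicRanges::findOverlaps(merged, gr)
    ri <- S4Vectors::queryHits(ov)
    wi <- S4Vectors::subjectHits(ov)
    w <- s$end[wi] - s$start[wi]
    tibble(
      chrom = as.character(GenomicRanges::seqnames(merged)),
      start = GenomicRanges::start(merged) - 1L,
      end = GenomicRanges::end(merged),
      q = as.numeric(tapply(s$q[wi], ri, min)),
      fold = as.numeric(tapply(s$fold[wi] * w, ri, sum) / tapply(w, ri, sum)),
      direction = d,
      n_windows = as.integer(tabulate(ri, nbins = length(merged)))
    )
  })
  arrange(bind_rows(out), .data$chrom, .data$start)
}

#' @export
print.imbalance_fit <- function(x, ...) {
  cat("Allele-specific imbalance scan\n")
  cat(sprintf("  reads: %d (%d informative, %d conflict, %d non-informative)\n",
              x$report$n_reads, x$report$n_informative,
              x$report$n_conflict, x$report$n_noninformative))
  cat(sprintf("  windows tested: %d of %d tiled (min_total = %d per clone)\n",
              x$report$n_windows_tested, x$report$n_windows_tiled,
              x$params$min_total))
  cat(sprintf("  significant windows (q < %g): %d; regions (%s): %d\n",
              x$params$q_threshold, x$report$n_windows_significant,
              x$params$direction, x$report$n_regions))
  invisible(x)
}

#' Tidy the per-window tests of an imbalance fit
#'
#' @param x An `imbalance_fit`.
#' @param ... Unused.
#' @return The per-window test tibble.
#' @export
tidy.imbalance_fit <- function(x, ...) x$windows

#' One-row summary of an imbalance fit
#'
#' @param x An `imbalance_fit`.
#' @param ... Unused.
#' @return A one-row tibble of run-level counts and thresholds.
#' @export
glance.imbalance_fit <- function(x, ...) {
  tibble(
    n_reads = x$report$n_reads,
    n_informative = x$report$n_informative,
    n_windows_tested = x$report$n_windows_tested,
    n_windows_significant = x$report$n_windows_significant,
    n_regions = x$report$n_regions,
    q_threshold = x$params$q_threshold,
    min_total = x$params$min_total,
    n_clones = length(x$params$clones)
  )
}
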