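#' Tile a chromosome with sliding windows of several sizes
#'
#' The genome scan uses a multi-scale sliding window: for each size `s` in
#' `sizes`, windows start at multiples of `s * step_fraction` (default: half
#' a window of overlap) and any window extending past the chromosome end is
#' dropped, so only full-size windows are tested. The union over sizes is
#' returned tagged by size.
#'
#' @param chrom_length Chromosome length in bp.
#' @param sizes Window sizes in bp; the default `c(250, 500, 1000)` spans
#'   the 250-1000 bp range of the scan.
#' @param step_fraction Step between window starts as a fraction of the
#'   size, in (0, 1].
#' @return Tibble with `size`, `start`, `end` (0-based half-open). Empty,
#'   with a warning, when the chromosome is shorter than every size.
#' @export
#' @examples
#' make_windows(1000, sizes = 250, step_fraction = 0.5) # 7 windows
make_windows <- function(chrom_length, sizes = c(250, 500, 1000),
                         step_fraction = 0.5) {
  chrom_length <- .check_count(chrom_length, "chrom_length", min = 1)
  if (!is.numeric(sizes) || length(sizes) == 0L || any(sizes < 1)) {
    abort("`sizes` must be positive window sizes in bp.")
  }
  sizes <- sort(unique(as.integer(sizes)))
  if (!is.numeric(step_fraction) || step_fraction <= 0 || step_fraction > 1) {
    abort("`step_fraction` must lie in (0, 1].")
  }
  if (chrom_length < min(sizes)) {
    warn(sprintf("chromosome of length %d is shorter than every window size.",
                 chrom_length))
    return(tibble(size = integer(), start = integer(), end = integer()))
  }
  per <- lapply(sizes, function(s) {
    if (chrom_length < s) return(NULL)
    step <- max(1L, as.integer(round(s * step_fraction)))
    starts <- seq.int(0L, chrom_length - s, by = step)
    tibble(size = s, start = starts, end = starts + s)
  })
  bind_rows(per)
}

#' Sum allele counts per window and clone
#'
#' A read contributes to a window iff its *start* coordinate lies in
#' `[start, end)` — the start-point rule, which guarantees that within one
#' size tier a read is counted once per overlapping window step but never
#' double-counted by window extent. Only `A1`/`A2` calls contribute;
#' `CONFLICT` and `NONINFORMATIVE` reads are ignored.
#'
#' @param calls Allele-call tibble from [assign_reads()] (one chromosome or
#'   several; windows are per-chromosome).
#' @param windows Window tibble from [make_windows()], or one with an added
#'   `chrom` column. Without a `chrom` column the windows are applied to
#'   every chromosome present in `calls`.
#' @param clones Clone identifiers to tabulate; defaults to those present.
#' @return Tibble `chrom`, `size`, `start`, `end`, `clone`, `c1`, `c2` (the
#'   full windows x clones grid).
#' @export
count_windows <- function(calls, windows, clones = NULL) {
  calls <- as_tibble(calls)
  windows <- as_tibble(windows)
  if (!"chrom" %in% names(windows)) {
    chroms <- unique(calls$chrom)
    windows <- tidyr::crossing(chrom = chroms, windows)
  }
  clones <- clones %||% sort(unique(calls$clone))
  informative <- calls[calls$call %in% c("A1", "A2"), , drop = FALSE]

  win_gr <- GenomicRanges::GRanges(
    windows$chrom, IRanges::IRanges(windows$start + 1L, windows$end)
  )
  nw <- nrow(windows)
  nc <- length(clones)
  c1 <- integer(nw * nc)
  c2 <- integer(nw * nc)
  if (nrow(informative) > 0L) {
    pt <- GenomicRanges::GRanges(
      informative$chrom,
      IRanges::IRanges(informative$start + 1L, informative$start + 1L)
    )
    ov <- GenomicRanges::findOverlaps(win_gr, pt)
    wi <- S4Vectors::queryHits(ov)
    ri <- S4Vectors::subjectHits(ov)
    cl <- match(informative$clone[ri], clones)
    idx <- (cl - 1L) * nw + wi
    isa1 <- informative$call[ri] == "A1"
    c1 <- tabulate(idx[isa1], nbins = nw * nc)
    c2 <- tabulate(idx[!isa1], nbins = nw * nc)
  }
  out <- windows[rep(seq_len(nw), times = nc),
                 c("chrom", "size", "start", "end")]
  out$clone <- rep(clones, each = nw)
  out$c1 <- c1
  out$c2 <- c2
  as_tibble(out)
}

#' Per-chromosome median allelic baseline
#'
#' The expected allelic ratio of each chromosome is set to the median
#' allelic ratio `c1 / (c1 + c2)` over its informative windows — a robust
#' baseline that automatically absorbs aneuploidy (a chromosome present as
#' one 129P2 and two FVB/N copies has a baseline near 1/3) without requiring
#' a copy-number call. Only windows with at least `min_total` informative
#' reads enter the median, and the result is clamped to
#' `[1e-6, 1 - 1e-6]` so it is usable as a binomial success probability.
#' By default the baseline is computed per clone; `pool_clones = TRUE`
#' pools the windows of all clones into a single per-chromosome median.
#'
#' @param window_counts Tibble from [count_windows()].
#' @param min_total Minimum informative reads for a window to qualify
#'   (default 10).
#' @param pool_clones Pool clones before taking the median?
#' @return Tibble `chrom`, `clone` (absent when pooled), `rho`,
#'   `n_windows`. Chromosome/clone combinations with no qualifying window
#'   are skipped with a message.
#' @export
chromosome_baseline <- function(window_counts, min_total = 10,
                                pool_clones = FALSE) {
  wc <- as_tibble(window_counts)
  wc <- wc[wc$c1 + wc$c2 >= min_total, , drop = FALSE]
  keys <- if (pool_clones) "chrom" else c("chrom", "clone")
  full <- distinct(as_tibble(window_counts)[, keys, drop = FALSE])
  out <- wc |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(
      rho = median(.data$c1 / (.data$c1 + .data$c2)),
      n_windows = n(),
      .groups = "drop"
    ) |>
    mutate(rho = pmin(pmax(.data$rho, 1e-6), 1 - 1e-6))
  skipped <- dplyr::anti_join(full, out, by = keys)
  if (nrow(skipped) > 0L) {
    inform(sprintf(
      "chromosome_baseline: skipped %d chromosome/clone set(s) with no window reaching min_total = %d.",
      nrow(skipped), min_total
    ))
  }
  out
}
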