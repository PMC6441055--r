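#' Assign reads to parental haplotypes
#'
#' The counting step of the allele-specific analysis: each read votes once
#' per strain-informative SNP it overlaps — a base equal to the A1 (129P2)
#' base is an A1 vote, the A2 (FVB/N) base an A2 vote, and any other base is
#' a silent non-vote (treated as sequencing error, not as a conflict).
#' Unanimous non-empty votes give the read that haplotype; mixed votes give
#' `CONFLICT`; no votes give `NONINFORMATIVE`.
#'
#' `n_snps_seen` counts the voting SNP observations, so `NONINFORMATIVE`
#' reads have `n_snps_seen == 0` and a `CONFLICT` requires at least two
#' votes. Under the default `conflict_policy = "drop"`, conflicted reads are
#' excluded from all downstream counts — the conservative reading of a read
#' "supporting either" haplotype; `"majority"` instead awards the read to the
#' haplotype with more votes (exact ties remain `CONFLICT`). Duplicate reads
#' are not collapsed. Assignment is per-read and therefore deterministic and
#' independent of read order.
#'
#' @param reads Tibble of reads: `read_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `clone`, and — when `observations` is not supplied — an
#'   `obs` column in the TSV dialect (`"pos:base;pos:base"`, `""`/`NA` for
#'   none).
#' @param snps SNP table as from [load_snps()] (positions 0-based).
#' @param observations Optional long tibble (`read_id`, `chrom`, `pos`,
#'   `base`) as produced by [simulate_chip_reads()]; faster than the string
#'   encoding for large simulations.
#' @param conflict_policy `"drop"` (default) or `"majority"`.
#'
#' @return Tibble of allele calls: `read_id`, `chrom`, `start`, `end`,
#'   `clone`, `call` (factor with levels `A1`, `A2`, `CONFLICT`,
#'   `NONINFORMATIVE`) and `n_snps_seen`, in input read order.
#' @export
#' @examples
#' snps <- tibble::tibble(chrom = "chr15", pos = 99L,
#'                        a1_base = "G", a2_base = "C")
#' reads <- tibble::tibble(read_id = 1L, chrom = "chr15", start = 50L,
#'                         end = 150L, clone = 1L, obs = "99:G")
#' assign_reads(reads, snps)
assign_reads <- function(reads, snps, observations = NULL,
                         conflict_policy = c("drop", "majority")) {
  conflict_policy <- match.arg(conflict_policy)
  reads <- as_tibble(reads)
  snps <- validate_snps(snps)
  if (is.null(observations)) observations <- parse_observations(reads)
  observations <- as_tibble(observations)
  if (nrow(reads) == 0L) {
    return(tibble(read_id = integer(), chrom = character(), start = integer(),
                  end = integer(), clone = integer(),
                  call = factor(character(), levels = .calls),
                  n_snps_seen = integer()))
  }
  .check_obs_covered(reads, observations)

  ridx <- match(observations$read_id, reads$read_id)
  sidx <- .match_snp(observations, snps)
  known <- !is.na(sidx)
  vote_a1 <- known & observations$base == snps$a1_base[pmax(sidx, 1L)]
  vote_a2 <- known & observations$base == snps$a2_base[pmax(sidx, 1L)]

  n <- nrow(reads)
  n_a1 <- tabulate(ridx[vote_a1], nbins = n)
  n_a2 <- tabulate(ridx[vote_a2], nbins = n)
  call <- rep("NONINFORMATIVE", n)
  call[n_a1 > 0L & n_a2 == 0L] <- "A1"
  call[n_a2 > 0L & n_a1 == 0L] <- "A2"
  mixed <- n_a1 > 0L & n_a2 > 0L
  if (conflict_policy == "drop") {
    call[mixed] <- "CONFLICT"
  } else {
    call[mixed & n_a1 > n_a2] <- "A1"
    call[mixed & n_a2 > n_a1] <- "A2"
    call[mixed & n_a1 == n_a2] <- "CONFLICT"
  }
  tibble(
    read_id = reads$read_id, chrom = reads$chrom,
    start = reads$start, end = reads$end, clone = reads$clone,
    call = factor(call, levels = .calls),
    n_snps_seen = n_a1 + n_a2
  )
}

#' Assign a single read
#'
#' Convenience wrapper around [assign_reads()] for a one-row read tibble.
#'
#' @inheritParams assign_reads
#' @param read One-row read tibble.
#' @param ... Passed on to [assign_reads()].
#' @return One-row allele-call tibble.
#' @export
assign_read <- function(read, snps, ...) {
  read <- as_tibble(read)
  if (nrow(read) != 1L) abort("`read` must be a single read (one row).")
  assign_reads(read, snps, ...)
}

# numeric (chrom, pos) keys: exact for pos < 2^32 under double arithmetic
.match_snp <- function(observations, snps) {
  chrs <- unique(snps$chrom)
  oc <- match(observations$chrom, chrs)
  sc <- match(snps$chrom, chrs)
  match(oc * 2^32 + observations$pos, sc * 2^32 + snps$pos)
}

.check_obs_covered <- function(reads, observations) {
  if (nrow(observations) == 0L) return(invisible())
  ridx <- match(observations$read_id, reads$read_id)
  if (anyNA(ridx)) abort("observation refers to an unknown read_id.")
  bad <- observations$chrom != reads$chrom[ridx] |
    observations$pos < reads$start[ridx] |
    observations$pos >= reads$end[ridx]
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "malformed read %s: observed base at %s:%d outside the read interval.",
      reads$read_id[ridx[i]], observations$chrom[i], observations$pos[i]
    ))
  }
  invisible()
}

#' Parse the semicolon-joined observation column of a reads TSV
#'
#' @param reads Reads tibble carrying an `obs` column
#'   (`"pos:base;pos:base"`); empty string or `NA` means no observations.
#' @return Long tibble `read_id`, `chrom`, `pos`, `base`.
#' @export
parse_observations <- function(reads) {
  if (!"obs" %in% names(reads)) {
    abort("`reads` has no `obs` column and no `observations` were supplied.")
  }
  obs <- reads$obs
  has <- !is.na(obs) & nzchar(obs)
  if (!any(has)) {
    return(tibble(read_id = integer(), chrom = character(),
                  pos = integer(), base = character()))
  }
  parts <- strsplit(obs[has], ";", fixed = TRUE)
  lens <- lengths(parts)
  flat <- unlist(parts, use.names = FALSE)
  pos <- as.integer(sub(":.*$", "", flat))
  base <- sub("^[0-9]+:", "", flat)
  tibble(
    read_id = rep(reads$read_id[has], lens),
    chrom = rep(reads$chrom[has], lens),
    pos = pos, base = base
  )
}

#' Tally allele calls per chromosome and clone
#'
#' Summarises [assign_reads()] output into per-chromosome, per-clone counts
#' of each call category. The categories partition the reads, so the row
#' totals conserve the input read count.
#'
#' @param calls Allele-call tibble from [assign_reads()].
#' @return Tibble with `chrom`, `clone`, `n_a1`, `n_a2`, `n_conflict`,
#'   `n_noninformative`, `n_reads` and the informative A1 fraction
#'   `a1_fraction = n_a1 / (n_a1 + n_a2)`.
#' @export
assignment_summary <- function(calls) {
  calls <- as_tibble(calls)
  if (nrow(calls) == 0L) abort("`calls` is empty.")
  out <- calls |>
    group_by(.data$chrom, .data$clone) |>
    summarise(
      n_a1 = sum(.data$call == "A1"),
      n_a2 = sum(.data$call == "A2"),
      n_conflict = sum(.data$call == "CONFLICT"),
      n_noninformative = sum(.data$call == "NONINFORMATIVE"),
      n_reads = n(),
      .groups = "drop"
    ) |>
    mutate(a1_fraction = ifelse(.data$n_a1 + .data$n_a2 > 0,
                                .data$n_a1 / (.data$n_a1 + .data$n_a2),
                                NA_real_))
  out
}
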