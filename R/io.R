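#' Write and read the reads TSV dialect
#'
#' Reads travel as TSV with columns `read_id`, `chrom`, `start`, `end`,
#' `clone`, `obs`, where `obs` is a semicolon-joined list of `pos:base`
#' observations at the SNPs the read overlaps (empty when non-informative).
#'
#' @param sim A `chip_sim` object, or a reads tibble (then supply
#'   `observations`).
#' @param path Output path.
#' @param observations Long observation tibble when `sim` is a plain tibble.
#' @return `path`, invisibly.
#' @export
write_reads_tsv <- function(sim, path, observations = NULL) {
  if (inherits(sim, "chip_sim")) {
    reads <- sim$reads
    observations <- sim$observations
  } else {
    reads <- as_tibble(sim)
    if (is.null(observations)) abort("supply `observations` with a reads tibble.")
  }
  obs_str <- rep("", nrow(reads))
  if (nrow(observations) > 0L) {
    joined <- observations |>
      mutate(tok = paste0(.data$pos, ":", .data$base)) |>
      group_by(.data$read_id) |>
      summarise(obs = paste(.data$tok, collapse = ";"), .groups = "drop")
    i <- match(joined$read_id, reads$read_id)
    obs_str[i] <- joined$obs
  }
  out <- tibble(
    read_id = reads$read_id, chrom = reads$chrom, start = reads$start,
    end = reads$end, clone = reads$clone, obs = obs_str
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_reads_tsv
#' @return For `read_reads_tsv`: a reads tibble with an `obs` column,
#'   consumable by [assign_reads()] directly.
#' @export
read_reads_tsv <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      read_id = readr::col_integer(), chrom = readr::col_character(),
      start = readr::col_integer(), end = readr::col_integer(),
      clone = readr::col_integer(), obs = readr::col_character()
    )
  ) |>
    mutate(obs = tidyr::replace_na(.data$obs, ""))
}

#' Write intervals as BED6
#'
#' Emits candidate regions (or simulation truth regions) as BED6 via
#' rtracklayer: `name` carries the allelic fold-change (or true A1
#' fraction), `score` is `-10 log10(q)` capped at 1000 (0 for truth
#' records).
#'
#' @param x Regions tibble (`chrom`, `start`, `end` plus `fold`/`q` or
#'   `a1_fraction`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- as_tibble(x)
  if (nrow(x) == 0L) {
    readr::write_lines(character(), path)
    return(invisible(path))
  }
  name <- if ("fold" %in% names(x)) sprintf("fold=%.4g", x$fold)
    else if ("a1_fraction" %in% names(x)) sprintf("a1_fraction=%.4g", x$a1_fraction)
    else sprintf("region%03d", seq_len(nrow(x)))
  score <- if ("q" %in% names(x)) pmin(1000, round(-10 * log10(pmax(x$q, 1e-100))))
    else rep(0L, nrow(x))
  gr <- GenomicRanges::GRanges(
    x$chrom, IRanges::IRanges(x$start + 1L, x$end),
    name = name, score = as.integer(score),
    strand = "*"
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file of regions
#'
#' @param path BED file path.
#' @return Tibble `chrom`, `start` (0-based), `end`, `name`, `score`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else NA_character_,
    score = if (!is.null(gr$score)) gr$score else NA_real_
  )
}

#' Write and read a backcross cohort as TSV
#'
#' The cohort travels as two TSVs: genotypes (`mouse_id`, `affected`,
#' `tumour_count`, then one column per marker) and a marker map (`marker`,
#' `chrom`, `pos`).
#'
#' @param cohort A `cross_cohort`.
#' @param path Genotype TSV path.
#' @param map_path Marker-map TSV path; defaults to `path` with a
#'   `.markers.tsv` suffix.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path,
                             map_path = sub("\\.tsv$", ".markers.tsv", path)) {
  ck <- .as_cohort(cohort)
  wide <- left_join(ck$phenotypes, ck$genotypes, by = "mouse_id")
  readr::write_tsv(wide, path)
  readr::write_tsv(ck$markers, map_path)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @return For `read_cohort_tsv`: a `cross_cohort`.
#' @export
read_cohort_tsv <- function(path,
                            map_path = sub("\\.tsv$", ".markers.tsv", path)) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  markers <- readr::read_tsv(map_path, show_col_types = FALSE)
  structure(
    list(
      genotypes = wide[, c("mouse_id", markers$marker)],
      phenotypes = wide[, c("mouse_id", "affected", "tumour_count")],
      markers = markers,
      truth = NULL
    ),
    class = "cross_cohort"
  )
}

#' Write a machine-readable run report
#'
#' Serialises the report, parameters and baselines of an [run_imbalance()]
#' fit (or any list) as JSON.
#'
#' @param fit An `imbalance_fit` or a list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(fit, path) {
  x <- if (inherits(fit, "imbalance_fit")) {
    list(report = fit$report, params = fit$params,
         baselines = fit$baselines)
  } else {
    fit
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write per-window test results as TSV
#'
#' @param fit An `imbalance_fit` (or its `windows` tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_tsv <- function(fit, path) {
  x <- if (inherits(fit, "imbalance_fit")) fit$windows else as_tibble(fit)
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read aligned reads from SAM text
#'
#' Minimal ingestion of plain-text SAM for allele assignment: for each
#' aligned record the observed base at every reference position it covers
#' is recovered from the `SEQ` field by walking the CIGAR string. Only the
#' operations `M`, `=`, `X` (aligned) and `S` (soft-clip) are supported —
#' the subset sufficient for ungapped short-read ChIP-seq alignments;
#' records whose CIGAR contains any other operation (indels, splices, hard
#' clips) are skipped with a logged count, as are unmapped records.
#' Positions are converted to 0-based half-open coordinates. Only observed
#' bases at positions in `snps` are retained.
#'
#' @param path SAM text file.
#' @param snps SNP table (see [load_snps()]); observations are restricted to
#'   these positions.
#' @param clone Clone identifier to attach to all reads (default 1).
#' @return A list with `reads` (tibble `read_id`, `chrom`, `start`, `end`,
#'   `clone`) and `observations` (long tibble), ready for [assign_reads()].
#' @export
read_sam_reads <- function(path, snps, clone = 1L) {
  snps <- validate_snps(snps)
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  n_skip <- 0L
  reads <- vector("list", length(lines))
  obs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    cigar <- f[6]
    if (bitwAnd(flag, 4L) > 0L || cigar == "*" ||
          grepl("[^0-9MX=S]", cigar)) {
      n_skip <- n_skip + 1L
      next
    }
    chrom <- f[3]
    pos0 <- as.integer(f[4]) - 1L
    seqc <- f[10]
    lens <- as.integer(strsplit(cigar, "[MX=S]")[[1]])
    ops <- strsplit(gsub("[0-9]+", "", cigar), "")[[1]]
    ref_pos <- pos0
    qry_pos <- 0L
    ref_idx <- integer(0)
    qry_idx <- integer(0)
    for (j in seq_along(ops)) {
      if (ops[j] == "S") {
        qry_pos <- qry_pos + lens[j]
      } else {
        ref_idx <- c(ref_idx, ref_pos + seq_len(lens[j]) - 1L)
        qry_idx <- c(qry_idx, qry_pos + seq_len(lens[j]))
        ref_pos <- ref_pos + lens[j]
        qry_pos <- qry_pos + lens[j]
      }
    }
    reads[[i]] <- tibble(
      read_id = i, chrom = chrom, start = pos0, end = ref_pos,
      clone = as.integer(clone)
    )
    at_snp <- ref_idx %in% snps$pos[snps$chrom == chrom]
    if (any(at_snp)) {
      obs[[i]] <- tibble(
        read_id = i, chrom = chrom, pos = ref_idx[at_snp],
        base = toupper(substring(seqc, qry_idx[at_snp], qry_idx[at_snp]))
      )
    }
  }
  if (n_skip > 0L) {
    inform(sprintf(
      "read_sam_reads: skipped %d record(s) (unmapped or unsupported CIGAR).",
      n_skip
    ))
  }
  list(reads = bind_rows(reads), observations = bind_rows(obs))
}
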