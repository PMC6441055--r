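#' Load a strain-SNP table from a minimal VCF
#'
#' Reads the positions at which the two parental haplotypes carry different
#' bases — the sole source of allele informativeness for read assignment. By
#' the package's convention the VCF `REF` column holds the A2 (FVB/N) base
#' and `ALT` the A1 (129P2) base. Multiallelic records and indels are skipped
#' with a logged count, as only biallelic SNVs can vote for a haplotype;
#' records with `REF == ALT` are uninformative and dropped with a warning.
#' Positions are converted from the VCF's 1-based convention to the 0-based
#' half-open coordinates used throughout the package.
#'
#' @param path Path to an (uncompressed) VCF file.
#'
#' @return A tibble with columns `chrom`, `pos` (0-based), `a1_base`,
#'   `a2_base`, sorted by `(chrom, pos)` with unique positions.
#' @export
load_snps <- function(path) {
  raw <- readr::read_lines(path)
  body <- raw[!startsWith(raw, "#") & nzchar(raw)]
  if (length(body) == 0L) {
    if (!any(startsWith(raw, "#"))) abort("not a VCF file: no header lines.")
    return(tibble(chrom = character(), pos = integer(),
                  a1_base = character(), a2_base = character()))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  tab <- tibble(
    chrom = fix$CHROM,
    pos1 = as.integer(fix$POS),
    a2_base = toupper(fix$REF),
    a1_base = toupper(fix$ALT)
  )
  # sortedness is a file-format contract: report the first offending record
  bad <- which(diff(tab$pos1) <= 0 & tab$chrom[-1] == tab$chrom[-nrow(tab)])
  if (length(bad) > 0L) {
    abort(sprintf(
      "SNP table must be position-sorted with unique positions; first violation at %s:%d.",
      tab$chrom[bad[1] + 1L], tab$pos1[bad[1] + 1L]
    ))
  }
  keep_snv <- !is.na(tab$a1_base) & !grepl(",", tab$a1_base, fixed = TRUE) &
    nchar(tab$a1_base) == 1L & nchar(tab$a2_base) == 1L &
    tab$a1_base %in% .bases & tab$a2_base %in% .bases
  if (any(!keep_snv)) {
    inform(sprintf("load_snps: skipped %d multiallelic/indel record(s).",
                   sum(!keep_snv)))
    tab <- tab[keep_snv, , drop = FALSE]
  }
  same <- tab$a1_base == tab$a2_base
  if (any(same)) {
    warn(sprintf("load_snps: dropped %d record(s) with REF == ALT.", sum(same)))
    tab <- tab[!same, , drop = FALSE]
  }
  tibble(
    chrom = tab$chrom, pos = tab$pos1 - 1L,
    a1_base = tab$a1_base, a2_base = tab$a2_base
  )
}

#' Write a strain-SNP table as a minimal VCF
#'
#' Inverse of [load_snps()]: emits a VCF with `REF` = A2 (FVB/N) base and
#' `ALT` = A1 (129P2) base, positions converted back to 1-based.
#'
#' @param snps SNP tibble (`chrom`, `pos` 0-based, `a1_base`, `a2_base`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snps <- function(snps, path) {
  snps <- validate_snps(snps)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=haplochip (REF = FVB/N [A2] base, ALT = 129P2 [A1] base)",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf(
    "%s\t%d\t%s\t%s\t%s\t.\t.\t.",
    snps$chrom, snps$pos + 1L,
    sprintf("snp%06d", seq_len(nrow(snps))),
    snps$a2_base, snps$a1_base
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Validate a strain-SNP table
#'
#' Checks the SnpTable contract: required columns, bases that differ between
#' haplotypes, and positions unique and sorted within each chromosome.
#'
#' @param snps A tibble as returned by [load_snps()].
#' @return The validated tibble (invisibly coerced to the canonical column
#'   order).
#' @export
validate_snps <- function(snps) {
  snps <- as_tibble(snps)
  need <- c("chrom", "pos", "a1_base", "a2_base")
  if (!all(need %in% names(snps))) {
    abort("SNP table needs columns chrom, pos, a1_base, a2_base.")
  }
  if (any(snps$a1_base == snps$a2_base)) {
    abort("SNP table contains records with identical haplotype bases.")
  }
  ord <- order(snps$chrom, snps$pos)
  if (!identical(ord, seq_len(nrow(snps)))) {
    abort("SNP table must be sorted by (chrom, pos).")
  }
  if (anyDuplicated(snps[, c("chrom", "pos")])) {
    abort("SNP positions must be unique per chromosome.")
  }
  snps[, need]
}
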