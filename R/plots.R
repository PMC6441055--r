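#' Plot an allelic-imbalance scan along the genome
#'
#' Shows the pooled A1 (129P2) fraction of every tested window along each
#' chromosome, the per-chromosome median baseline, and the called regions
#' as shaded intervals. Windows passing the FDR threshold are highlighted.
#'
#' @param object An `imbalance_fit` from [run_imbalance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.imbalance_fit <- function(object, ...) {
  w <- object$windows
  w$significant <- w$q < object$params$q_threshold
  p <- ggplot2::ggplot(w, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                       y = .data$pooled_fraction)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant),
                        size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rho), linetype = "dashed",
                       colour = "grey30") +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
      name = sprintf("q < %g", object$params$q_threshold)
    ) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "pooled 129P2 fraction") +
    ggplot2::theme_minimal()
  if (nrow(object$regions) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = object$regions,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, fill = "firebrick", alpha = 0.15,
      inherit.aes = FALSE
    )
  }
  p
}

#' Plot a linkage scan
#'
#' Manhattan-style view of the marker association scan: `-log10(p)` per
#' marker by genomic position, with the Bonferroni threshold drawn as a
#' horizontal line.
#'
#' @param object A `linkage_scan` from [marker_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.linkage_scan <- function(object, ...) {
  thr <- attr(object, "alpha") / nrow(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pos / 1e6,
                                       y = -log10(.data$p))) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "-log10 p (Fisher exact)") +
    ggplot2::theme_minimal()
}

#' Plot allele-specific expression fractions
#'
#' Stacked per-gene bars of the 129P2 (A1) and FVB/N (A2) transcript
#' fractions, annotated with the verdict of [ase_call()].
#'
#' @param ase Tibble from [ase_call()].
#' @return A ggplot object.
#' @export
plot_ase <- function(ase) {
  long <- tidyr::pivot_longer(
    mutate(ase, A1 = .data$fraction, A2 = 1 - .data$fraction),
    c("A1", "A2"),
    names_to = "allele", values_to = "frac"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gene, y = .data$frac,
                                     fill = .data$allele)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(
      data = ase,
      ggplot2::aes(x = .data$gene, y = 1.05, label = as.character(.data$verdict)),
      inherit.aes = FALSE, size = 3
    ) +
    ggplot2::scale_fill_manual(
      values = c(A1 = "#3366aa", A2 = "#33aa66"),
      labels = c(A1 = "129P2", A2 = "FVB/N"), name = "allele"
    ) +
    ggplot2::labs(x = NULL, y = "transcript fraction") +
    ggplot2::theme_minimal()
}
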