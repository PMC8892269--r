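# ggplot2 displays for the main result types.

#' Stacked size-class siRNA coverage plot
#'
#' Plus-strand coverage is stacked upward and minus-strand coverage
#' downward, one fill per size class, as in browser-style small-RNA figures.
#'
#' @param object An [size_profile()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.srna_profile <- function(object, ...) {
  df <- object |>
    mutate(rpm_signed = ifelse(.data$strand == "-", -.data$rpm, .data$rpm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$rpm_signed,
                                   fill = .data$size_class)) +
    ggplot2::geom_col(position = "stack", width = 1) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = sprintf("position on %s (nt)",
                              attr(object, "locus_ref")),
                  y = "coverage (RPM, minus strand down)",
                  fill = "size (nt)") +
    ggplot2::theme_minimal()
}

#' Per-codon stalling score plot
#'
#' @param object A [stall_scores()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stall_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$codon, y = .data$score)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "codon", y = "observed / expected occupancy",
                  title = object$transcript_id) +
    ggplot2::theme_minimal()
}

#' Start-codon metagene plot
#'
#' 5'-end counts around annotated start codons, one panel per read length --
#' the display from which P-site offsets are read off.
#'
#' @param qc A [periodicity_qc()] result.
#' @return A ggplot object.
#' @export
plot_metagene <- function(qc) {
  stopifnot(inherits(qc, "periodicity_qc"))
  ggplot2::ggplot(qc$metagene,
                  ggplot2::aes(x = .data$rel_pos, y = .data$count)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "red") +
    ggplot2::facet_wrap(~length, scales = "free_y") +
    ggplot2::labs(x = "5' end position relative to start codon (nt)",
                  y = "weighted read count") +
    ggplot2::theme_minimal()
}

#' Overlay of stalling scores and siRNA onset for a pipeline run
#'
#' Stalling scores (codon coordinates converted to ORF nucleotides) with the
#' detected siRNA onset and the modal 5'OH breakage end marked.
#'
#' @param run A [run_pipeline()] result.
#' @return A ggplot object.
#' @export
plot_overlay <- function(run) {
  stopifnot(inherits(run, "tds_run"))
  sc <- tidy(run$stall_report_locus) |>
    mutate(orf_nt = 3L * .data$codon - 2L)
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$orf_nt, y = .data$score)) +
    ggplot2::geom_col(width = 3) +
    ggplot2::labs(x = "ORF position (nt)", y = "stalling score") +
    ggplot2::theme_minimal()
  if (!is.na(run$report$onset_orf_nt)) {
    p <- p + ggplot2::geom_vline(xintercept = run$report$onset_orf_nt,
                                 colour = "red", linetype = 2)
  }
  if (!is.na(run$report$modal_end_orf_nt)) {
    p <- p + ggplot2::geom_vline(xintercept = run$report$modal_end_orf_nt,
                                 colour = "blue", linetype = 3)
  }
  p
}
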