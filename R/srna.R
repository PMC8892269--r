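# Size-class/strand-resolved siRNA coverage profiles, isoform attribution,
# change-point onset detection, and genotype dependence ratios.

.size_class <- function(length, classes = c(21L, 22L, 24L)) {
  ifelse(length %in% classes, as.character(length), "other")
}

#' Size-class siRNA coverage profile over a locus
#'
#' Each read adds `weight * 1e6 / library_total` (RPM) to every position it
#' covers, stratified by size class (21/22/24/other) and strand -- the
#' stacked browser-style representation.
#'
#' @param reads Aligned-read tibble.
#' @param locus_ref Reference name of the locus.
#' @param locus_length Length (nt) of the locus.
#' @param library_total Mapped-read count of the library (RPM denominator).
#' @return A tibble of class `srna_profile` with columns `pos`, `strand`,
#'   `size_class`, `rpm` (covered-position coverage) and `start_rpm` (read
#'   5'-boundary positions only, i.e. each read's leftmost covered
#'   coordinate), plus attributes `locus_ref`, `locus_length` and
#'   `library_total`.
#' @export
size_profile <- function(reads, locus_ref, locus_length, library_total) {
  if (library_total <= 0) abort("library_total must be positive")
  reads <- dplyr::filter(reads, .data$ref == locus_ref)
  grid <- tidyr::expand_grid(
    pos = seq_len(locus_length),
    strand = c("+", "-"),
    size_class = c("21", "22", "24", "other")
  )
  if (nrow(reads) > 0L) {
    reads <- mutate(reads, size_class = .size_class(.data$length))
    cov <- reads |>
      group_by(.data$strand, .data$size_class) |>
      dplyr::group_modify(function(d, key) {
        ir <- IRanges::IRanges(
          start = pmax(1L, d$start),
          end = pmin(locus_length, d$start + d$length - 1L)
        )
        keep <- IRanges::width(ir) > 0L
        v <- as.numeric(IRanges::coverage(ir[keep], weight = d$weight[keep],
                                          width = locus_length))
        # leftmost covered coordinate per read (the pattern's 5' boundary)
        p5 <- d$start
        inside <- p5 >= 1L & p5 <= locus_length
        e5 <- numeric(locus_length)
        if (any(inside)) {
          tab <- tapply(d$weight[inside], p5[inside], sum)
          e5[as.integer(names(tab))] <- tab
        }
        tibble(pos = seq_len(locus_length),
               rpm = v * 1e6 / library_total,
               start_rpm = e5 * 1e6 / library_total)
      }) |>
      ungroup()
    out <- grid |>
      left_join(cov, by = c("pos", "strand", "size_class")) |>
      mutate(rpm = dplyr::coalesce(.data$rpm, 0),
             start_rpm = dplyr::coalesce(.data$start_rpm, 0))
  } else {
    out <- mutate(grid, rpm = 0, start_rpm = 0)
  }
  structure(out, class = c("srna_profile", class(out)),
            locus_ref = locus_ref, locus_length = locus_length,
            library_total = library_total)
}

#' Attribute siRNA reads to isoform evidence classes
#'
#' Reads on the spliced transcript that span the exon1-exon2 junction are
#' spliced-isoform evidence; genome-space reads overlapping the intron are
#' unspliced evidence; genome-space reads starting 3' of the premature
#' poly(A) site fall in the unspliced-only region; everything else is
#' ambiguous.
#'
#' @param reads Aligned-read tibble (transcript- and/or genome-space).
#' @param models Locus models from [make_synthetic_locus()] (or any model
#'   tibble carrying a `locus_info` attribute with `spliced_id`, `chrom`,
#'   `junction_tpos`, `intron_gstart`, `intron_gend`, `pcpa_gpos`).
#' @return The reads with an `evidence` column
#'   (`spliced`/`unspliced`/`unspliced_only`/`ambiguous`).
#' @export
attribute_isoform <- function(reads, models) {
  info <- attr(models, "locus_info")
  if (is.null(info) || is.null(info$junction_tpos) || is.null(info$pcpa_gpos)) {
    abort("models lack intron/PCPA annotations (locus_info attribute)")
  }
  reads |>
    mutate(
      end = .data$start + .data$length - 1L,
      evidence = dplyr::case_when(
        .data$ref == info$spliced_id & .data$start <= info$junction_tpos &
          .data$end > info$junction_tpos ~ "spliced",
        .data$ref == info$chrom & .data$start > info$pcpa_gpos ~
          "unspliced_only",
        .data$ref == info$chrom & .data$end >= info$intron_gstart &
          .data$start <= info$intron_gend ~ "unspliced",
        TRUE ~ "ambiguous"
      )
    ) |>
    select(-"end")
}

#' Detect the 5' onset of an siRNA pattern by change-point fitting
#'
#' Fits a single change-point, two-level piecewise-constant model to the
#' pooled both-strand coverage of the chosen size classes by least squares
#' over all candidate breakpoints. The breakpoint (1-based position where
#' the second segment starts) is reported only if the SSE reduction versus
#' the flat model exceeds `min_reduction`.
#'
#' @param profile An [size_profile()] result, or a plain numeric coverage
#'   vector.
#' @param classes Size classes pooled for detection (default 21 and 22 nt,
#'   the RDR6/DCL4/DCL2 classes).
#' @param min_reduction Minimum relative SSE reduction (default 0.25).
#' @param stat Which per-position statistic to segment: `"start"` (read
#'   5'-boundary counts; sharp at the true pattern start, the default) or
#'   `"coverage"` (all covered positions; smeared 3' by up to one read
#'   length).
#' @return List of class `onset_fit`: `position` (`NA` if no onset),
#'   `reduction`, `sse_flat`, `sse_best`, `level_before`, `level_after`.
#' @export
onset_changepoint <- function(profile, classes = c(21L, 22L),
                              min_reduction = 0.25,
                              stat = c("start", "coverage")) {
  stat <- match.arg(stat)
  v <- if (is.numeric(profile)) {
    as.numeric(profile)
  } else {
    stopifnot(inherits(profile, "srna_profile"))
    col <- if (stat == "start") "start_rpm" else "rpm"
    profile |>
      dplyr::filter(.data$size_class %in% as.character(classes)) |>
      group_by(.data$pos) |>
      summarise(v = sum(.data[[col]]), .groups = "drop") |>
      arrange(.data$pos) |>
      pull("v")
  }
  L <- length(v)
  if (L < 3L) abort("coverage vector too short")
  sse_flat <- sum((v - mean(v))^2)
  if (sse_flat <= 0) {
    return(structure(list(position = NA_integer_, reduction = 0,
                          sse_flat = sse_flat, sse_best = sse_flat,
                          level_before = mean(v), level_after = mean(v)),
                     class = "onset_fit"))
  }
  # O(L) scan over all breakpoints via cumulative sums:
  # SSE(k) = sum(v^2) - S1^2/n1 - S2^2/n2 for split before position k.
  cs <- cumsum(v)
  cs2 <- cumsum(v^2)
  k <- 2:L                      # second segment starts at position k
  n1 <- k - 1
  n2 <- L - n1
  s1 <- cs[k - 1]
  s2 <- cs[L] - s1
  sse <- cs2[L] - s1^2 / n1 - s2^2 / n2
  best <- which.min(sse)
  reduction <- (sse_flat - sse[best]) / sse_flat
  pos <- if (reduction > min_reduction) as.integer(k[best]) else NA_integer_
  structure(
    list(position = pos, reduction = reduction, sse_flat = sse_flat,
         sse_best = sse[best],
         level_before = s1[best] / n1[best],
         level_after = s2[best] / n2[best]),
    class = "onset_fit"
  )
}

#' @export
print.onset_fit <- function(x, ...) {
  if (is.na(x$position)) {
    cat(sprintf("<onset_fit> no onset (SSE reduction %.1f%%)\n",
                100 * x$reduction))
  } else {
    cat(sprintf("<onset_fit> onset at position %d (%.3g -> %.3g, SSE reduction %.1f%%)\n",
                x$position, x$level_before, x$level_after, 100 * x$reduction))
  }
  invisible(x)
}

#' Per-size-class log2 dependence ratio between two profiles
#'
#' Summed locus RPM of profile A over profile B, log2, with a pseudocount --
#' a simple normalized ratio standing in for a genotype comparison (e.g.
#' wild type versus an RDR6 mutant).
#'
#' @param profile_a,profile_b [size_profile()] results over the same locus.
#' @param pseudocount Added to both sums before the ratio (default 1).
#' @return Tibble with `size_class`, `rpm_a`, `rpm_b`, `log2_ratio`.
#' @export
dependence_ratio <- function(profile_a, profile_b, pseudocount = 1) {
  sum_by_class <- function(p, nm) {
    p |>
      group_by(.data$size_class) |>
      summarise("{nm}" := sum(.data$rpm), .groups = "drop")
  }
  out <- dplyr::full_join(sum_by_class(profile_a, "rpm_a"),
                          sum_by_class(profile_b, "rpm_b"),
                          by = "size_class") |>
    mutate(
      rpm_a = dplyr::coalesce(.data$rpm_a, 0),
      rpm_b = dplyr::coalesce(.data$rpm_b, 0),
      log2_ratio = log2((.data$rpm_a + pseudocount) /
                          (.data$rpm_b + pseudocount))
    )
  out
}
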