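# Polysome-association scoring, siRNA-quartile partitioning, qPCR relative
# expression and copy-number estimation.

#' Polysome association score
#'
#' Log2 fold-change between a feature's abundance (RPKM) in polysome
#' libraries versus total RNA, with a pseudocount.
#'
#' @param features Tibble with columns `feature_id`, `total_rpkm`,
#'   `polysome_rpkm` (extra columns pass through).
#' @param pseudocount Added to both abundances (default 1).
#' @return The input with a `polysome_score` column.
#' @export
polysome_score <- function(features, pseudocount = 1) {
  mutate(features, polysome_score = log2(
    (.data$polysome_rpkm + pseudocount) / (.data$total_rpkm + pseudocount)
  ))
}

#' Partition features into quartiles of a key (siRNA level by default)
#'
#' Boundaries sit at the empirical 25/50/75 percentiles of the key; a
#' feature's quartile is 1 plus the number of boundaries its key exceeds.
#' Tied keys share a quartile (and features keep their stable input order);
#' if all keys are equal, every feature lands in quartile 1 with a warning.
#'
#' @param features Tibble of features.
#' @param key Column name holding the partitioning key (default
#'   `"sirna_level"`).
#' @return The input with an integer `quartile` column (1-4).
#' @export
quartile_partition <- function(features, key = "sirna_level") {
  k <- features[[key]]
  if (length(unique(k)) == 1L) {
    warn("all keys equal; every feature assigned quartile 1")
    return(mutate(features, quartile = 1L))
  }
  bounds <- stats::quantile(k, c(0.25, 0.5, 0.75), names = FALSE)
  mutate(features, quartile = 1L + (k > bounds[1]) + (k > bounds[2]) +
           (k > bounds[3]))
}

.mean_ct <- function(ct, samples, targets) {
  ct |>
    dplyr::filter(.data$sample %in% samples, .data$target %in% targets) |>
    group_by(.data$sample) |>
    summarise(mean_ct = mean(.data$ct), .groups = "drop")
}

#' qPCR relative expression (delta-Ct against reference genes)
#'
#' Per sample, the level of a target is `2^(mean Ct of the references -
#' mean Ct of the target)`, replicate Cts averaged arithmetically and, with
#' several reference genes, their mean Cts averaged.
#'
#' @param ct Long Ct tibble with columns `sample`, `target`, `ct`.
#' @param targets Character vector of targets of interest.
#' @param references Character vector of reference targets (e.g. `ACT2`,
#'   `GAPC`).
#' @return Tibble `sample`, `target`, `relative_level`.
#' @export
relative_expression <- function(ct, targets, references) {
  samples <- unique(ct$sample)
  ref <- ct |>
    dplyr::filter(.data$target %in% references) |>
    group_by(.data$sample, .data$target) |>
    summarise(t_ct = mean(.data$ct), .groups = "drop") |>
    group_by(.data$sample) |>
    summarise(ref_ct = mean(.data$t_ct), .groups = "drop")
  missing_ref <- setdiff(samples, ref$sample)
  if (length(missing_ref) > 0L) {
    abort(paste0("missing reference Cts for sample: ", missing_ref[1L]))
  }
  ct |>
    dplyr::filter(.data$target %in% targets) |>
    group_by(.data$sample, .data$target) |>
    summarise(target_ct = mean(.data$ct), .groups = "drop") |>
    left_join(ref, by = "sample") |>
    mutate(relative_level = 2^(.data$ref_ct - .data$target_ct)) |>
    select("sample", "target", "relative_level")
}

#' Transposon copy number per haploid genome from genomic-DNA qPCR
#'
#' With `dCt(s) = mean Ct of the reference gene - mean Ct of the element`
#' in sample `s`, the element copy number is
#' `calibrator_copies * 2^(dCt(s) - dCt(calibrator))`; the calibrator is a
#' wild-type-like sample whose inherent copy numbers (2 for the element, 1
#' for the single-copy reference) fix the scale. Amplification efficiency is
#' taken as perfect doubling.
#'
#' @param ct Long Ct tibble with columns `sample`, `target`, `ct`.
#' @param calibrator_sample Sample name(s) serving as calibrator; with
#'   several, their delta-Cts are averaged.
#' @param target Element target name (default `"EVD"`).
#' @param reference Single-copy reference gene (default `"ACT2"`).
#' @param calibrator_copies Element copies in the calibrator (default 2).
#' @return Tibble `sample`, `delta_ct`, `copies`.
#' @export
copy_number <- function(ct, calibrator_sample, target = "EVD",
                        reference = "ACT2", calibrator_copies = 2) {
  dct <- ct |>
    dplyr::filter(.data$target %in% c(!!target, !!reference)) |>
    group_by(.data$sample, .data$target) |>
    summarise(mean_ct = mean(.data$ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "target", values_from = "mean_ct") |>
    mutate(delta_ct = .data[[reference]] - .data[[target]])
  if (!all(calibrator_sample %in% dct$sample)) {
    abort("calibrator sample absent from Ct table")
  }
  dct_cal <- mean(dct$delta_ct[dct$sample %in% calibrator_sample])
  dct |>
    mutate(copies = calibrator_copies * 2^(.data$delta_ct - dct_cal)) |>
    select("sample", "delta_ct", "copies")
}
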