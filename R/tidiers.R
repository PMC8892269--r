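# broom-style tidiers for the package's fitted/report objects.

#' Tidy a stalling report into per-codon rows
#'
#' @param x A [stall_scores()] report.
#' @param ... Unused.
#' @return Tibble `transcript_id`, `codon`, `count`, `score`.
#' @export
tidy.stall_report <- function(x, ...) {
  mutate(x$scores, transcript_id = x$transcript_id, .before = 1L)
}

#' One-row summary of a stalling report
#'
#' @param x A [stall_scores()] report.
#' @param ... Unused.
#' @return One-row tibble: `transcript_id`, `total`, `n_codons`,
#'   `max_score`, `max_codon`, `pair_start`, `pair_fraction`, `qualified`,
#'   `reason`.
#' @export
glance.stall_report <- function(x, ...) {
  tibble(
    transcript_id = x$transcript_id, total = x$total,
    n_codons = nrow(x$scores), max_score = x$max_score,
    max_codon = x$max_codon, pair_start = x$pair[1],
    pair_fraction = x$pair_fraction, qualified = x$qualified,
    reason = x$reason
  )
}

#' Tidy per-length frame fractions of a periodicity QC
#'
#' @param x A [periodicity_qc()] result.
#' @param ... Unused.
#' @return Tibble `length`, `frame`, `fraction`.
#' @export
tidy.periodicity_qc <- function(x, ...) {
  select(x$frames, "length", "frame", "fraction")
}

#' One-row pooled frame fractions
#'
#' @param x A [periodicity_qc()] result.
#' @param ... Unused.
#' @return One-row tibble `frame0`, `frame1`, `frame2`.
#' @export
glance.periodicity_qc <- function(x, ...) {
  tibble(frame0 = x$pooled[1], frame1 = x$pooled[2], frame2 = x$pooled[3])
}

#' One-row summary of an onset change-point fit
#'
#' @param x An [onset_changepoint()] result.
#' @param ... Unused.
#' @return One-row tibble `position`, `detected`, `reduction`,
#'   `level_before`, `level_after`.
#' @export
glance.onset_fit <- function(x, ...) {
  tibble(position = x$position, detected = !is.na(x$position),
         reduction = x$reduction, level_before = x$level_before,
         level_after = x$level_after)
}

#' Tidy codon statistics (dwell time joined with usage)
#'
#' @param x A [dwell_and_usage()] result.
#' @param ... Unused.
#' @return Tibble `codon`, `aa`, `dwell`, `n_instances`, `frequency`.
#' @export
tidy.codon_stats <- function(x, ...) {
  dplyr::full_join(x$dwell, x$usage, by = c("codon", "aa"))
}

#' One-row overlay summary of a pipeline run
#'
#' @param x A [run_pipeline()] result.
#' @param ... Unused.
#' @return The run's one-row overlay report tibble.
#' @export
glance.tds_run <- function(x, ...) {
  x$report
}
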