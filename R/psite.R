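# P-site offset calibration from start-codon metagenes, P-site assignment to
# codons, and triplet-periodicity QC.

#' Estimate length-dependent 5'-to-P-site offsets
#'
#' For each read length `L` with at least `min_support` reads whose candidate
#' P-site can fall on an annotated start codon, the offset is the argmax over
#' candidate distances `d` in `[6, L - 6]` of the weighted number of reads
#' whose 5' end lies exactly `d` nt upstream of a start codon. Ties break to
#' the smallest `d`. Lengths below support are omitted.
#'
#' @param reads Aligned-read tibble in transcript space.
#' @param models Transcript-model tibble with CDS annotations.
#' @param min_support Minimum supporting reads per length (default 100).
#' @return Tibble with columns `length`, `offset`, `support`.
#' @export
estimate_offsets <- function(reads, models, min_support = 100L) {
  cds <- models |>
    dplyr::filter(!is.na(.data$cds_start)) |>
    select(ref = "transcript_id", "cds_start")
  cand <- reads |>
    dplyr::inner_join(cds, by = "ref") |>
    mutate(d = .data$cds_start - .data$start) |>
    dplyr::filter(.data$d >= 6L, .data$d <= .data$length - 6L)
  support <- cand |> count(.data$length, name = "support")
  keep <- support$length[support$support >= min_support]
  if (length(keep) == 0L) abort("no calibratable read length")
  out <- cand |>
    dplyr::filter(.data$length %in% keep) |>
    group_by(.data$length, .data$d) |>
    summarise(w = sum(.data$weight), .groups = "drop_last") |>
    arrange(.data$d, .by_group = TRUE) |>
    summarise(offset = .data$d[which_max_first(.data$w)], .groups = "drop") |>
    left_join(support, by = "length") |>
    arrange(.data$length)
  stopifnot(all(out$offset > 0), all(out$offset < out$length))
  out
}

#' Assign P-sites and compile per-codon occupancy
#'
#' P-site nucleotide = 5' end + offset(length). Reads of lengths absent from
#' `offsets` are dropped (with a message); reads whose P-site falls outside
#' the CDS are discarded. All three frames pool into the codon they fall in:
#' codon index = `floor((psite - cds_start)/3) + 1`. Counts accumulate read
#' weights; every CDS codon (stop included) is reported, zero-filled.
#'
#' @param reads Aligned-read tibble in transcript space.
#' @param offsets Offset tibble from [estimate_offsets()].
#' @param models Transcript-model tibble with CDS annotations.
#' @return Tidy codon-occupancy tibble: `transcript_id`, `codon`, `count`.
#' @export
assign_psites <- function(reads, offsets, models) {
  uncov <- !(reads$length %in% offsets$length)
  if (any(uncov)) {
    message(sum(uncov), " reads of uncalibrated lengths dropped")
    reads <- reads[!uncov, , drop = FALSE]
  }
  cds <- models |>
    dplyr::filter(!is.na(.data$cds_start)) |>
    select(ref = "transcript_id", "cds_start", "cds_end")
  hits <- reads |>
    dplyr::inner_join(select(offsets, "length", "offset"), by = "length") |>
    dplyr::inner_join(cds, by = "ref") |>
    mutate(psite = .data$start + .data$offset) |>
    dplyr::filter(.data$psite >= .data$cds_start,
                  .data$psite <= .data$cds_end) |>
    mutate(codon = (.data$psite - .data$cds_start) %/% 3L + 1L) |>
    group_by(transcript_id = .data$ref, .data$codon) |>
    summarise(count = sum(.data$weight), .groups = "drop")
  # zero-fill every CDS codon of every coding model
  frame <- models |>
    dplyr::filter(!is.na(.data$cds_start)) |>
    mutate(n_codons = (.data$cds_end - .data$cds_start + 1L) %/% 3L) |>
    select("transcript_id", "n_codons") |>
    purrr::pmap_dfr(function(transcript_id, n_codons) {
      tibble(transcript_id = transcript_id, codon = seq_len(n_codons))
    })
  frame |>
    left_join(hits, by = c("transcript_id", "codon")) |>
    mutate(count = dplyr::coalesce(.data$count, 0))
}

#' Triplet-periodicity QC and start-codon metagene
#'
#' @param reads Aligned-read tibble in transcript space.
#' @param offsets Offset tibble from [estimate_offsets()].
#' @param models Transcript-model tibble with CDS annotations.
#' @param flank Metagene half-window around start codons (nt).
#' @return List of class `periodicity_qc`: `frames` (per-length frame
#'   fractions), `pooled` (length-3 numeric, frames 0/1/2), and `metagene`
#'   (5'-end counts at positions `-flank..flank` relative to start codons,
#'   per length).
#' @export
periodicity_qc <- function(reads, offsets, models, flank = 30L) {
  cds <- models |>
    dplyr::filter(!is.na(.data$cds_start)) |>
    select(ref = "transcript_id", "cds_start", "cds_end")
  assigned <- reads |>
    dplyr::inner_join(select(offsets, "length", "offset"), by = "length") |>
    dplyr::inner_join(cds, by = "ref") |>
    mutate(psite = .data$start + .data$offset) |>
    dplyr::filter(.data$psite >= .data$cds_start,
                  .data$psite <= .data$cds_end) |>
    mutate(frame = (.data$psite - .data$cds_start) %% 3L)
  if (nrow(assigned) == 0L) abort("zero assigned P-sites")
  frames <- assigned |>
    group_by(.data$length, .data$frame) |>
    summarise(w = sum(.data$weight), .groups = "drop") |>
    tidyr::complete(length = unique(assigned$length), frame = 0:2,
                    fill = list(w = 0)) |>
    group_by(.data$length) |>
    mutate(fraction = .data$w / sum(.data$w)) |>
    ungroup()
  pooled_w <- vapply(0:2, function(f) {
    sum(assigned$weight[assigned$frame == f])
  }, numeric(1))
  pooled <- pooled_w / sum(pooled_w)
  metagene <- reads |>
    dplyr::inner_join(cds, by = "ref") |>
    mutate(rel_pos = .data$start - .data$cds_start) |>
    dplyr::filter(abs(.data$rel_pos) <= flank) |>
    group_by(.data$length, .data$rel_pos) |>
    summarise(count = sum(.data$weight), .groups = "drop")
  structure(list(frames = frames, pooled = pooled, metagene = metagene),
            class = "periodicity_qc")
}

#' @export
print.periodicity_qc <- function(x, ...) {
  cat(sprintf("<periodicity_qc> frame fractions: %.3f / %.3f / %.3f\n",
              x$pooled[1], x$pooled[2], x$pooled[3]))
  invisible(x)
}
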