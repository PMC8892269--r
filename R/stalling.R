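# Stalling statistics: observed-over-expected per-codon scores, two-codon
# occupancy fractions, transcriptome percentile ranking, codon dwell times
# and codon usage, under the qualification filters (most translated isoform
# per gene, >= 70% codon coverage).

#' Select qualifying isoforms
#'
#' Keeps, per gene, the isoform with the highest total P-site occupancy, and
#' qualifies it only if the fraction of sense codons with nonzero count is at
#' least `min_coverage`. Disqualified isoforms carry a reason.
#'
#' @param occupancies Tidy codon-occupancy tibble from [assign_psites()].
#' @param models Transcript-model tibble (for `gene_id` and CDS flags).
#' @param min_coverage Minimum covered-codon fraction (default 0.70;
#'   `>=` convention, so exactly 0.70 qualifies).
#' @return Tibble with one row per isoform: `transcript_id`, `gene_id`,
#'   `total`, `coverage`, `qualified`, `reason`.
#' @export
select_isoforms <- function(occupancies, models, min_coverage = 0.70) {
  per_tx <- occupancies |>
    group_by(.data$transcript_id) |>
    summarise(
      total = sum(.data$count),
      # stop codon (last index) excluded from the coverage denominator
      coverage = mean(.data$count[.data$codon < max(.data$codon)] > 0),
      .groups = "drop"
    ) |>
    left_join(select(models, "transcript_id", "gene_id", "cds_ok"),
              by = "transcript_id")
  per_tx |>
    group_by(.data$gene_id) |>
    arrange(desc(.data$total), .data$transcript_id, .by_group = TRUE) |>
    mutate(is_top = row_number() == 1L) |>
    ungroup() |>
    mutate(
      qualified = .data$is_top & .data$cds_ok & .data$total > 0 &
        .data$coverage >= min_coverage,
      reason = dplyr::case_when(
        !.data$is_top ~ "not most translated isoform",
        !.data$cds_ok ~ "malformed CDS",
        .data$total <= 0 ~ "no P-site counts",
        .data$coverage < min_coverage ~ "coverage",
        TRUE ~ NA_character_
      )
    ) |>
    select("transcript_id", "gene_id", "total", "coverage", "qualified",
           "reason") |>
    arrange(.data$transcript_id)
}

#' Per-codon stalling scores for one transcript
#'
#' The stalling score of a codon is its observed P-site count over the
#' expected count, the expectation being the mean occupancy over the
#' transcript's included codons. The stop codon is excluded from everything
#' and the stop-containing di-codon from the pair search. The two-codon
#' (pair) fraction is the largest share of the transcript's occupancy
#' carried by two adjacent included codons.
#'
#' @param occupancy Numeric per-codon count vector, or a tidy occupancy
#'   tibble for a single transcript (ordered by `codon`).
#' @param transcript_id Identifier stored in the report.
#' @param has_stop Does the occupancy vector end with the stop codon (to be
#'   excluded)? Default `TRUE`, matching [assign_psites()] output.
#' @return An object of class `stall_report` with elements `transcript_id`,
#'   `scores` (tibble `codon`, `count`, `score`), `total`, `max_score`,
#'   `max_codon`, `pair` (integer pair `c(i, i + 1)`), `pair_fraction`,
#'   `qualified`, `reason`.
#' @export
stall_scores <- function(occupancy, transcript_id = "transcript",
                         has_stop = TRUE) {
  if (is.data.frame(occupancy)) {
    if ("transcript_id" %in% names(occupancy) &&
        length(unique(occupancy$transcript_id)) == 1L) {
      transcript_id <- occupancy$transcript_id[1L]
    }
    occupancy <- occupancy$count[order(occupancy$codon)]
  }
  counts <- as.numeric(occupancy)
  n <- length(counts)
  m <- if (has_stop) n - 1L else n
  if (m < 2L) abort("need at least two included codons")
  inc <- counts[seq_len(m)]
  total <- sum(inc)
  if (total <= 0) {
    return(structure(
      list(transcript_id = transcript_id,
           scores = tibble(codon = seq_len(m), count = inc,
                           score = NA_real_),
           total = 0, max_score = NA_real_, max_codon = NA_integer_,
           pair = c(NA_integer_, NA_integer_), pair_fraction = NA_real_,
           qualified = FALSE, reason = "no P-site counts"),
      class = "stall_report"
    ))
  }
  expectation <- mean(inc)
  scores <- inc / expectation
  max_codon <- which_max_first(scores)
  pair_sums <- inc[-m] + inc[-1L]
  pair_i <- which_max_first(pair_sums)
  structure(
    list(
      transcript_id = transcript_id,
      scores = tibble(codon = seq_len(m), count = inc, score = scores),
      total = total,
      max_score = scores[max_codon],
      max_codon = max_codon,
      pair = c(pair_i, pair_i + 1L),
      pair_fraction = pair_sums[pair_i] / total,
      qualified = TRUE, reason = NA_character_
    ),
    class = "stall_report"
  )
}

#' @export
print.stall_report <- function(x, ...) {
  if (!x$qualified) {
    cat(sprintf("<stall_report> %s: not qualified (%s)\n", x$transcript_id,
                x$reason))
  } else {
    cat(sprintf(
      "<stall_report> %s: max score %.2f at codon %d; pair %d-%d carries %.1f%% of occupancy\n",
      x$transcript_id, x$max_score, x$max_codon, x$pair[1], x$pair[2],
      100 * x$pair_fraction))
  }
  invisible(x)
}

#' Stalling reports for many transcripts
#'
#' @param occupancies Tidy occupancy tibble from [assign_psites()].
#' @param selection Optional tibble from [select_isoforms()]; when given,
#'   non-qualified transcripts are marked unqualified in their reports.
#' @return Tibble with one row per transcript (the [glance.stall_report()]
#'   columns), carrying the individual `stall_report` objects in a `report`
#'   list-column.
#' @export
stall_scores_all <- function(occupancies, selection = NULL) {
  reports <- occupancies |>
    dplyr::group_split(.data$transcript_id) |>
    purrr::map(stall_scores)
  out <- purrr::map_dfr(reports, glance)
  out$report <- reports
  if (!is.null(selection)) {
    qual <- selection$qualified[match(out$transcript_id,
                                      selection$transcript_id)]
    out$qualified <- out$qualified & dplyr::coalesce(qual, FALSE)
  }
  out
}

#' Transcriptome percentile of stalling strength
#'
#' The percentile of a transcript is the percentage of qualified transcripts
#' with a strictly larger maximal stalling score (so the most intensely
#' stalled transcript gets percentile 0).
#'
#' @param reports Tibble with columns `transcript_id`, `max_score`,
#'   `qualified` (e.g. from [stall_scores_all()]).
#' @return The input with a `percentile` column (`NA` for unqualified rows).
#' @export
rank_transcripts <- function(reports) {
  q <- dplyr::filter(reports, .data$qualified)
  if (nrow(q) == 0L) abort("empty qualified set")
  pct <- vapply(reports$max_score, function(s) {
    100 * sum(q$max_score > s) / nrow(q)
  }, numeric(1))
  pct[!reports$qualified] <- NA_real_
  mutate(reports, percentile = pct)
}

#' Codon dwell times and codon usage over qualified transcripts
#'
#' Dwell time of a codon: the mean, over every (transcript, position)
#' instance of that codon among qualified transcripts, of the log-normalized
#' occupancy `ln(count/mean + eps)` with `eps = 0.5/mean` (a half-read
#' pseudo-count). Codon usage: sense-codon frequencies of the qualified
#' CDSs, summing to 1. Stop codons are absent from both maps.
#'
#' @param occupancies Tidy occupancy tibble from [assign_psites()].
#' @param models Transcript-model tibble (for CDS sequences).
#' @param selection Optional [select_isoforms()] tibble restricting the
#'   transcript set; default: all transcripts with nonzero occupancy.
#' @return List of class `codon_stats`: `dwell` (tibble `codon`, `aa`,
#'   `dwell`, `n_instances`) and `usage` (tibble `codon`, `aa`,
#'   `frequency`).
#' @export
dwell_and_usage <- function(occupancies, models, selection = NULL) {
  keep <- if (is.null(selection)) {
    unique(occupancies$transcript_id)
  } else {
    selection$transcript_id[selection$qualified]
  }
  cds_codons <- models |>
    dplyr::filter(.data$transcript_id %in% keep, !is.na(.data$cds_start)) |>
    purrr::pmap_dfr(function(transcript_id, cds_start, cds_end, sequence,
                             ...) {
      cod <- split_codons(substr(sequence, cds_start, cds_end))
      tibble(transcript_id = transcript_id, codon = seq_along(cod),
             triplet = cod)
    })
  inst <- occupancies |>
    dplyr::inner_join(cds_codons, by = c("transcript_id", "codon")) |>
    dplyr::filter(!.data$triplet %in% .stop_codons) |>
    group_by(.data$transcript_id) |>
    dplyr::filter(sum(.data$count) > 0) |>
    mutate(
      norm = .data$count / mean(.data$count),
      lognorm = log(.data$norm + 0.5 / mean(.data$count))
    ) |>
    ungroup()
  dwell <- inst |>
    group_by(triplet = .data$triplet) |>
    summarise(dwell = mean(.data$lognorm), n_instances = n(),
              .groups = "drop")
  usage <- cds_codons |>
    dplyr::filter(!.data$triplet %in% .stop_codons) |>
    count(triplet = .data$triplet, name = "n") |>
    mutate(frequency = .data$n / sum(.data$n)) |>
    select("triplet", "frequency")
  dwell <- dwell |>
    mutate(aa = translate_codons(.data$triplet)) |>
    dplyr::rename(codon = "triplet") |>
    select("codon", "aa", "dwell", "n_instances")
  usage <- usage |>
    mutate(aa = translate_codons(.data$triplet)) |>
    dplyr::rename(codon = "triplet") |>
    select("codon", "aa", "frequency")
  structure(list(dwell = dwell, usage = usage), class = "codon_stats")
}

#' @export
print.codon_stats <- function(x, ...) {
  cat(sprintf("<codon_stats> dwell for %d codons; usage over %d codons (sum %.3f)\n",
              nrow(x$dwell), nrow(x$usage), sum(x$usage$frequency)))
  invisible(x)
}
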