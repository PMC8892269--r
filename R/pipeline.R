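# End-to-end orchestration on synthetic data: simulate -> P-site calibration
# -> stalling -> siRNA onset -> 5'OH ends -> overlay report.

#' Run the full synthetic pipeline
#'
#' Simulates the two-isoform locus with ribosome footprints, siRNAs, RACE
#' clones and count/Ct tables, then runs every analysis stage and overlays
#' the three landmarks -- the maximal stalling codon, the siRNA onset, and
#' the modal 5'OH breakage end -- in one ORF-relative coordinate system.
#' The run is deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @param n_background_genes Synthetic background transcriptome size used
#'   for the percentile ranking (0 skips it and ranks the locus isoforms
#'   only).
#' @param min_support Offset-calibration support threshold (see
#'   [estimate_offsets()]).
#' @param outdir Optional directory; when given, every intermediate table,
#'   bedGraph tracks and a structured run log are written there.
#' @return List of class `tds_run` with the overlay `report` (one-row
#'   tibble) and all intermediates (`offsets`, `occupancy`, `qc`,
#'   `selection`, `stall`, `stall_report_locus`, `srna_profile`, `onset`,
#'   `clone_ends`, `modal`, `features`, `copies`, `models`).
#' @export
run_pipeline <- function(config = sim_config(), n_background_genes = 0L,
                         min_support = 100L, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  locus <- make_synthetic_locus(config)
  info <- attr(locus$models, "locus_info")
  models <- locus$models
  rfp <- simulate_rfp(config, models)

  if (n_background_genes > 0L) {
    bg_models <- sim_transcriptome(n_background_genes,
                                   seed = config$seed + 10L)
    cfg_bg <- config
    cfg_bg$seed <- config$seed + 11L
    cfg_bg$isoform_weights <- NULL
    cfg_bg$stall_multiplier <- 1
    bg_rfp <- simulate_rfp(cfg_bg, bg_models, stall_transcript = "")
    models <- bind_rows(models, bg_models)
    attr(models, "locus_info") <- info
    rfp <- bind_rows(rfp, bg_rfp)
  }

  offsets <- estimate_offsets(rfp, models, min_support = min_support)
  occupancy <- suppressMessages(assign_psites(rfp, offsets, models))
  qc <- periodicity_qc(rfp, offsets, models)
  selection <- select_isoforms(occupancy, models)
  stall <- stall_scores_all(occupancy, selection) |> rank_transcripts()
  locus_row <- match(info$spliced_id, stall$transcript_id)
  stall_locus <- stall$report[[locus_row]]

  srna <- simulate_srna(config, locus$models)
  profile <- size_profile(srna, info$spliced_id, info$spliced_length,
                          library_total = max(1L, config$n_srna))
  onset <- onset_changepoint(profile)

  spliced_seq <- models$sequence[models$transcript_id == info$spliced_id]
  clones <- simulate_race_clones(config, spliced_seq)
  clone_ends <- map_clone_5p(clones, spliced_seq, cds_start = info$cds_start)
  modal <- modal_end_fraction(clone_ends, window = 2L)

  tables <- simulate_counts(config)
  features <- tables$features |> polysome_score() |> quartile_partition()
  calib <- unique(tables$ct$sample[tables$ct$genotype ==
                                     names(config$qpcr_copies)[1]])
  copies <- copy_number(tables$ct, calibrator_sample = calib)

  stall_codon <- stall_locus$max_codon
  stall_orf_nt <- if (is.na(stall_codon)) NA_integer_ else 3L * stall_codon - 2L
  onset_orf_nt <- if (is.na(onset$position)) NA_integer_ else
    onset$position - info$utr5
  modal_end_orf_nt <- modal$mode
  report <- tibble(
    locus = info$spliced_id,
    stall_max_codon = stall_codon,
    stall_max_score = stall_locus$max_score,
    stall_pair = paste(stall_locus$pair, collapse = "-"),
    stall_pair_fraction = stall_locus$pair_fraction,
    stall_percentile = stall$percentile[locus_row],
    stall_orf_nt = stall_orf_nt,
    onset_orf_nt = onset_orf_nt,
    modal_end_orf_nt = modal_end_orf_nt,
    modal_end_codon = nt_to_codon(modal_end_orf_nt),
    modal_end_fraction = modal$fraction,
    d_stall_onset = abs(stall_orf_nt - onset_orf_nt),
    d_stall_break = abs(stall_orf_nt - modal_end_orf_nt),
    d_onset_break = abs(onset_orf_nt - modal_end_orf_nt),
    qualified = stall_locus$qualified
  )

  run <- structure(
    list(config = config, models = models, report = report,
         offsets = offsets, occupancy = occupancy, qc = qc,
         selection = selection, stall = stall,
         stall_report_locus = stall_locus, srna_profile = profile,
         onset = onset, clone_ends = clone_ends, modal = modal,
         features = features, copies = copies),
    class = "tds_run"
  )
  if (!is.null(outdir)) .write_run(run, outdir)
  run
}

#' @export
print.tds_run <- function(x, ...) {
  r <- x$report
  cat("<tds_run>\n")
  cat(sprintf("  locus %s: stall pair %s (max codon %d, score %.1f, %.1f%% of occupancy)\n",
              r$locus, r$stall_pair, r$stall_max_codon, r$stall_max_score,
              100 * r$stall_pair_fraction))
  cat(sprintf("  siRNA onset at ORF nt %s; modal 5'OH end at ORF nt %d (codon %d, %.0f%% of clones)\n",
              ifelse(is.na(r$onset_orf_nt), "none", r$onset_orf_nt),
              r$modal_end_orf_nt, r$modal_end_codon,
              100 * r$modal_end_fraction))
  cat(sprintf("  distances (nt): stall-onset %s, stall-break %s, onset-break %s\n",
              r$d_stall_onset, r$d_stall_break, r$d_onset_break))
  invisible(x)
}

.write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  readr::write_tsv(run$offsets, p("offsets.tsv"))
  readr::write_tsv(run$occupancy, p("occupancy.tsv"))
  readr::write_tsv(run$selection, p("isoform_selection.tsv"))
  readr::write_tsv(select(run$stall, -"report"), p("stall_reports.tsv"))
  readr::write_tsv(as_tibble(run$srna_profile), p("srna_profile.tsv"))
  readr::write_tsv(run$clone_ends, p("clone_ends.tsv"))
  readr::write_tsv(run$features, p("features.tsv"))
  readr::write_tsv(run$copies, p("copy_number.tsv"))
  readr::write_tsv(run$report, p("overlay_report.tsv"))
  info_ref <- attr(run$srna_profile, "locus_ref")
  for (cls in c("21", "22", "24")) {
    v <- run$srna_profile |>
      dplyr::filter(.data$size_class == cls) |>
      group_by(.data$pos) |>
      summarise(v = sum(.data$rpm), .groups = "drop") |>
      arrange(.data$pos) |>
      pull("v")
    write_bedgraph(coverage_track(v, info_ref,
                                  label = paste0("siRNA_", cls, "nt")),
                   p(paste0("srna_", cls, "nt.bedGraph")))
  }
  files <- list.files(outdir, full.names = TRUE)
  sums <- tools::md5sum(files)
  log_lines <- c(
    sprintf("tdsilence %s | R %s", as.character(utils::packageVersion("tdsilence")),
            getRversion()),
    sprintf("seed: %d", run$config$seed),
    "config:",
    sprintf("  %s = %s", names(unclass(run$config)),
            vapply(unclass(run$config), function(v) {
              paste(format(v, trim = TRUE), collapse = ",")
            }, character(1))),
    "output md5:",
    sprintf("  %s  %s", unname(sums), basename(files))
  )
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(run)
}
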