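test_that("simulators are deterministic under a fixed config", {
  cfg <- sim_config(seed = 11, n_rfp = 2000L, n_srna = 2000L)
  a <- make_synthetic_locus(cfg)
  b <- make_synthetic_locus(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$models$sequence, b$models$sequence)
  expect_identical(simulate_rfp(cfg, a$models), simulate_rfp(cfg, b$models))
  expect_identical(simulate_srna(cfg, a$models), simulate_srna(cfg, b$models))
  expect_identical(
    as.character(simulate_race_clones(cfg, a$models$sequence[1])),
    as.character(simulate_race_clones(cfg, b$models$sequence[1]))
  )
  expect_identical(simulate_counts(cfg), simulate_counts(cfg))
})

test_that("the locus is assembled exon1 + intron + exon2 and the ORF is clean", {
  cfg <- sim_config(seed = 5)
  loc <- make_synthetic_locus(cfg)
  info <- attr(loc$models, "locus_info")
  chr <- as.character(loc$genome[[1]])
  spliced <- loc$models$sequence[loc$models$transcript_id == "shTE"]
  # spliced isoform = exon1 + exon2 sequence up to the premature poly(A)
  expect_equal(spliced, paste0(substr(chr, 1, info$junction_tpos),
                               substr(chr, info$intron_gend + 1,
                                      info$pcpa_gpos)))
  # declared ORF translates with no internal stop (independent translation)
  cds <- substr(spliced, info$cds_start, info$cds_end)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
  expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  # stall pair codons are proline then glycine
  pg <- codons_at(cds, cfg$stall_pair)
  expect_equal(pg$aa, c("P", "G"))
  # intron boundaries inconsistent with the ORF error out
  expect_error(make_synthetic_locus(sim_config(intron_donor = 10L)),
               "inconsistent with ORF")
})

test_that("footprints follow the dwell model: null uniformity and stall recovery", {
  models <- sim_transcriptome(1, seed = 2, codon_range = c(200L, 200L))
  null_cfg <- sim_config(seed = 2, n_rfp = 20000L, stall_multiplier = 1,
                         init_boost = 1, periodicity = 1)
  reads <- simulate_rfp(null_cfg, models, stall_transcript = "")
  counts <- tabulate(reads$true_codon, 200)
  # uniform within multinomial error (chi-squared goodness of fit)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 1e-4)

  stall_cfg <- sim_config(seed = 2, n_rfp = 50000L, stall_multiplier = 20,
                          stall_pair = c(148L, 149L))
  sreads <- simulate_rfp(stall_cfg, models,
                         stall_transcript = models$transcript_id[1])
  truth <- tabulate(sreads$true_codon, 200)
  expect_true(which.max(truth) %in% c(148L, 149L))
})

test_that("realized footprint lengths match the configured distribution", {
  cfg <- sim_config(seed = 9, n_rfp = 10000L)
  loc <- make_synthetic_locus(cfg)
  reads <- simulate_rfp(cfg, loc$models)
  obs <- table(factor(reads$length, levels = names(cfg$length_dist)))
  p <- stats::chisq.test(obs, p = cfg$length_dist)$p.value
  expect_gt(p, 0.01)
})

test_that("siRNAs are confined 3' of the breakpoint and sized as configured", {
  cfg <- sim_config(seed = 4, srna_background = 0, n_srna = 10000L)
  loc <- make_synthetic_locus(cfg)
  info <- attr(loc$models, "locus_info")
  reads <- simulate_srna(cfg, loc$models)
  prof <- size_profile(reads, "shTE", info$spliced_length, cfg$n_srna)
  before <- dplyr::filter(prof, pos < info$breakpoint_tpos)
  expect_equal(sum(before$rpm), 0)
  expect_setequal(unique(reads$strand), c("+", "-"))
  frac <- prop.table(table(factor(reads$length,
                                  levels = names(cfg$srna_sizes))))
  expect_true(all(abs(as.numeric(frac) - cfg$srna_sizes) < 0.02))
})

test_that("RACE clones start at the breakpoint except for the noise fraction", {
  cfg <- sim_config(seed = 6, clone_noise = 0)
  loc <- make_synthetic_locus(cfg)
  info <- attr(loc$models, "locus_info")
  ref <- loc$models$sequence[1]
  clones <- simulate_race_clones(cfg, ref)
  bp_seq <- substr(ref, info$breakpoint_tpos, info$breakpoint_tpos + 24L)
  first25 <- substr(as.character(clones), 1, 25)
  expect_true(all(first25 == bp_seq))
  truth <- attr(clones, "truth")
  expect_true(all(truth$true_class == "modal"))
  expect_true(all(Biostrings::width(clones) >= 80 &
                    Biostrings::width(clones) <= 200))
})

test_that("noise-free count tables recover the configured polysome enrichment", {
  cfg <- sim_config(seed = 8, counts_dispersion = 0)
  tabs <- simulate_counts(cfg)
  scored <- polysome_score(tabs$features, pseudocount = 0)
  expect_equal(scored$polysome_score,
               c(1.5, 0, -1, 0.5, -0.5, -2, 2, 0), tolerance = 1e-12)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(srna_sizes = c(`21` = 0.5, `22` = 0.2)),
               "sum to 1")
  expect_error(sim_config(stall_pair = c(1L, 3L)), "consecutive")
  expect_error(sim_config(stall_pair = c(299L, 300L), orf_codons = 299L),
               "outside the ORF")
  expect_error(sim_config(periodicity = 0.2), "periodicity")
  cfg <- sim_config(n_rfp = 0L)
  loc <- make_synthetic_locus(cfg)
  expect_error(simulate_rfp(cfg, loc$models), "n_rfp")
})
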