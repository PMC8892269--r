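occ_tbl <- function(transcript_id, counts) {
  tibble::tibble(transcript_id = transcript_id,
                 codon = seq_along(counts), count = counts)
}

test_that("isoform selection keeps the most translated isoform above 70% coverage", {
  models <- dplyr::bind_rows(
    toy_tx_model("t1a"), toy_tx_model("t1b"), toy_tx_model("t2")
  )
  models$gene_id <- c("g1", "g1", "g2")
  # t1a: total 100, full coverage; t1b: total 40; t2: 60% coverage
  occ <- dplyr::bind_rows(
    occ_tbl("t1a", rep(10, 10)),
    occ_tbl("t1b", rep(4, 10)),
    occ_tbl("t2", c(rep(2, 6), rep(0, 4)))
  )
  sel <- select_isoforms(occ, models)
  expect_true(sel$qualified[sel$transcript_id == "t1a"])
  expect_false(sel$qualified[sel$transcript_id == "t1b"])
  expect_equal(sel$reason[sel$transcript_id == "t1b"],
               "not most translated isoform")
  # t2 coverage = 6/9 sense codons = 0.667 < 0.70
  expect_false(sel$qualified[sel$transcript_id == "t2"])
  expect_equal(sel$reason[sel$transcript_id == "t2"], "coverage")

  # exactly 70% coverage qualifies (>= convention): 7 of 10 sense codons
  m <- toy_tx_model("t3", n_codons = 10)
  m$gene_id <- "g3"
  occ3 <- occ_tbl("t3", c(rep(1, 7), rep(0, 3), 0))  # 11 codons with stop
  sel3 <- select_isoforms(occ3, m)
  expect_equal(sel3$coverage, 0.7)
  expect_true(sel3$qualified)
})

test_that("stalling scores match direct arithmetic on the worked examples", {
  uniform <- stall_scores(rep(4, 10), has_stop = FALSE)
  expect_true(all(uniform$scores$score == 1))
  expect_equal(uniform$pair_fraction, 0.2)

  r <- stall_scores(c(1, 1, 1, 1, 16, 1, 1, 1, 1, 1), has_stop = FALSE)
  expect_equal(r$max_score, 16 / 2.5)
  expect_equal(r$max_codon, 5L)
  expect_true(r$pair[1] %in% c(4L, 5L))
  expect_equal(r$pair_fraction, 17 / 25)

  zero <- stall_scores(rep(0, 10), has_stop = FALSE)
  expect_false(zero$qualified)
})

test_that("stall_scores agrees with the brute-force oracle on random vectors", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    counts <- rpois(n, lambda = runif(1, 0.5, 8))
    if (sum(counts[1:(n - 1)]) == 0) next
    got <- stall_scores(counts, has_stop = TRUE)
    want <- oracle_stall(counts, has_stop = TRUE)
    expect_equal(got$scores$score, want$scores)
    expect_equal(got$max_codon, want$max_codon)
    expect_equal(got$pair_fraction, want$pair_fraction)
    expect_equal(mean(got$scores$score), 1, tolerance = 1e-9)
  }
})

test_that("percentile ranking counts strictly more pronounced transcripts", {
  reports <- tibble::tibble(
    transcript_id = c("A", "B", "C", "D"),
    max_score = c(6.4, 2.0, 1.5, 9.9),
    qualified = TRUE
  )
  ranked <- rank_transcripts(reports)
  expect_equal(ranked$percentile[ranked$transcript_id == "A"], 25)
  expect_equal(ranked$percentile,
               sapply(1:4, function(i) oracle_percentile(reports$max_score, i)))

  single <- rank_transcripts(tibble::tibble(
    transcript_id = "X", max_score = 3, qualified = TRUE))
  expect_equal(single$percentile, 0)

  ties <- rank_transcripts(tibble::tibble(
    transcript_id = c("A", "B", "C"), max_score = c(5, 5, 1),
    qualified = TRUE))
  expect_equal(ties$percentile[1:2], c(0, 0))

  expect_error(rank_transcripts(tibble::tibble(
    transcript_id = "A", max_score = 1, qualified = FALSE)),
    "empty qualified")
})

test_that("lowering a max score never decreases the percentile", {
  set.seed(7)
  scores <- runif(50, 1, 20)
  reports <- tibble::tibble(transcript_id = sprintf("t%02d", 1:50),
                            max_score = scores, qualified = TRUE)
  p1 <- rank_transcripts(reports)$percentile[1]
  reports$max_score[1] <- reports$max_score[1] / 2
  p2 <- rank_transcripts(reports)$percentile[1]
  expect_gte(p2, p1)
  expect_true(all(rank_transcripts(reports)$percentile >= 0))
  expect_true(all(rank_transcripts(reports)$percentile <= 100))
})

test_that("dwell times respond to codon-specific occupancy and exclude stops", {
  # two transcripts whose CCG codons carry 5x occupancy
  cds1 <- paste(c("ATG", "CCG", "GCT", "CCG", "GCT", "GCT", "TAA"),
                collapse = "")
  cds2 <- paste(c("ATG", "GCT", "CCG", "GAT", "GAT", "GCT", "TAA"),
                collapse = "")
  models <- dplyr::bind_rows(
    toy_tx_model("u1", cds_seq = cds1), toy_tx_model("u2", cds_seq = cds2)
  )
  occ <- dplyr::bind_rows(
    occ_tbl("u1", c(1, 5, 1, 5, 1, 1, 0)),
    occ_tbl("u2", c(1, 1, 5, 1, 1, 1, 0))
  )
  cs <- dwell_and_usage(occ, models)
  expect_false(any(cs$dwell$codon %in% c("TAA", "TAG", "TGA")))
  expect_false(any(cs$usage$codon %in% c("TAA", "TAG", "TGA")))
  expect_equal(sum(cs$usage$frequency), 1, tolerance = 1e-12)
  expect_equal(cs$dwell$codon[which.max(cs$dwell$dwell)], "CCG")

  # uniform occupancy: every codon's dwell identical
  occ_u <- dplyr::bind_rows(occ_tbl("u1", c(rep(2, 6), 0)),
                            occ_tbl("u2", c(rep(2, 6), 0)))
  cs_u <- dwell_and_usage(occ_u, models)
  expect_lt(diff(range(cs_u$dwell$dwell)), 1e-12)
})

test_that("a uniquely stalled transcript reaches the minimum percentile", {
  models <- sim_transcriptome(200, seed = 31, codon_range = c(150L, 200L))
  cfg <- sim_config(seed = 31, n_rfp = 50000L, stall_multiplier = 12,
                    isoform_weights = setNames(
                      c(0.05, rep(0.95 / 199, 199)), models$transcript_id))
  reads <- simulate_rfp(cfg, models,
                        stall_transcript = models$transcript_id[1])
  off <- estimate_offsets(reads, models)
  occ <- suppressMessages(assign_psites(reads, off, models))
  sel <- select_isoforms(occ, models)
  ranked <- rank_transcripts(stall_scores_all(occ, sel))
  stalled <- ranked[ranked$transcript_id == models$transcript_id[1], ]
  expect_true(stalled$qualified)
  expect_equal(stalled$percentile,
               min(ranked$percentile[ranked$qualified]))
})
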