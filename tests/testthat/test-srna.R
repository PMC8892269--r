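test_that("size profiles spread RPM over covered positions by class and strand", {
  empty <- size_profile(make_reads("locus", integer(0))[0, ], "locus", 100L,
                        1e6)
  expect_equal(sum(empty$rpm), 0)

  reads <- make_reads("locus", rep(10L, 10), length = 21L)
  prof <- size_profile(reads, "locus", 100L, 1e6)
  p21 <- dplyr::filter(prof, size_class == "21", strand == "+")
  expect_equal(p21$rpm[p21$pos %in% 10:30], rep(10, 21))
  expect_equal(sum(p21$rpm[!p21$pos %in% 10:30]), 0)
  # 5'-boundary track concentrates on the start position
  expect_equal(p21$start_rpm[p21$pos == 10], 10)
  expect_equal(sum(p21$start_rpm), 10)

  half <- make_reads("locus", 10L, length = 21L, weight = 0.5)
  prof_h <- size_profile(half, "locus", 100L, 1e6)
  expect_equal(max(prof_h$rpm), 0.5)

  expect_error(size_profile(reads, "locus", 100L, 0), "library_total")
})

test_that("profile mass conserves read coverage (RPM conservation)", {
  set.seed(12)
  reads <- make_reads("locus", sample(1:480, 300, replace = TRUE),
                      length = sample(c(21L, 22L, 24L, 19L), 300, TRUE),
                      strand = sample(c("+", "-"), 300, TRUE),
                      weight = sample(c(1, 0.5), 300, TRUE))
  lib <- 2.5e6
  prof <- size_profile(reads, "locus", 500L, lib)
  mass <- sum(prof$rpm) * lib / 1e6
  cov_nt <- sum(reads$weight * pmin(500L, reads$start + reads$length - 1L) -
                  reads$weight * (pmax(1L, reads$start) - 1L))
  expect_equal(mass, cov_nt, tolerance = 1e-6)
})

test_that("reads are attributed to isoform evidence classes", {
  cfg <- sim_config(seed = 13)
  loc <- make_synthetic_locus(cfg)
  info <- attr(loc$models, "locus_info")
  reads <- make_reads(
    c("shTE", "synTE", "synTE", "shTE"),
    c(info$junction_tpos - 10L,          # spans the exon1-exon2 junction
      info$intron_gstart + 5L,           # inside the intron
      info$pcpa_gpos + 50L,              # 3' of the premature poly(A)
      info$junction_tpos + 5L),          # unremarkable
    length = 21L
  )
  out <- attribute_isoform(reads, loc$models)
  expect_equal(out$evidence,
               c("spliced", "unspliced", "unspliced_only", "ambiguous"))
  models_bare <- loc$models
  attr(models_bare, "locus_info") <- NULL
  expect_error(attribute_isoform(reads, models_bare), "intron/PCPA")
})

test_that("change-point onset detection finds steps and rejects flat tracks", {
  v <- c(rep(0, 499), rep(10, 300))
  fit <- onset_changepoint(v)
  expect_equal(fit$position, 500L)

  flat <- onset_changepoint(rep(3, 400))
  expect_true(is.na(flat$position))

  noisy_flat <- onset_changepoint(rep(c(2.9, 3.1), 200))
  expect_true(is.na(noisy_flat$position))

  cfg <- sim_config(seed = 14, breakpoint_nt = 441L)
  loc <- make_synthetic_locus(cfg)
  info <- attr(loc$models, "locus_info")
  prof <- size_profile(simulate_srna(cfg, loc$models), "shTE",
                       info$spliced_length, cfg$n_srna)
  est <- onset_changepoint(prof)
  expect_lte(abs(est$position - info$breakpoint_tpos), 15L)
})

test_that("dependence ratios are zero at equality and antisymmetric", {
  cfg <- sim_config(seed = 15, n_srna = 3000L)
  loc <- make_synthetic_locus(cfg)
  info <- attr(loc$models, "locus_info")
  a <- size_profile(simulate_srna(cfg, loc$models), "shTE",
                    info$spliced_length, cfg$n_srna)
  same <- dependence_ratio(a, a)
  expect_true(all(same$log2_ratio == 0))

  b <- a
  b$rpm <- b$rpm / 4
  r <- dependence_ratio(a, b, pseudocount = 1e-9)
  covered <- r$size_class %in% c("21", "22", "24")
  expect_equal(r$log2_ratio[covered], rep(2, sum(covered)), tolerance = 1e-6)
  r_swap <- dependence_ratio(b, a, pseudocount = 1e-9)
  expect_equal(r$log2_ratio, -r_swap$log2_ratio, tolerance = 1e-9)
})
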