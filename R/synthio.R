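# Synthetic-data generators: a two-isoform retroelement locus, ribosome
# footprints with a programmable stall, size-class siRNAs confined 3' of a
# breakpoint, RACE clones anchored at the breakage end, and polysome / qPCR
# tables. Every generator is a pure function of its configuration: the same
# config (including its seed) reproduces identical output.

#' Build a simulation configuration
#'
#' The defaults emulate the study system: a short spliced coding isoform
#' (the translated subgenomic mRNA) sharing its 5' exon with an unspliced
#' full-length isoform, an intense ribosome stall at the consecutive
#' proline-glycine codons 148-149, and RDR6-style siRNA production starting
#' at ORF nucleotide 447 -- the breakage point, which falls inside the stall
#' pair (447 = first nucleotide of codon 149).
#'
#' @param seed Integer seed; all generators derive their RNG stream from it.
#' @param orf_codons Number of sense codons in the spliced isoform's ORF
#'   (start codon included, stop codon extra).
#' @param utr5,utr3 Leader / trailer lengths (nt) of the spliced isoform.
#' @param intron_donor Spliced-transcript position of the last exon-1
#'   nucleotide; the intron is inserted just 3' of it in the genome.
#' @param intron_length Intron length (nt).
#' @param tail_length Genomic sequence 3' of the premature poly(A) site,
#'   transcribed only in the full-length isoform.
#' @param stall_pair Codon index pair `c(i, i+1)` carrying the stall.
#' @param stall_multiplier Dwell-time factor (>= 1) applied to each stall
#'   codon. The default 80 reproduces the observed design point of roughly
#'   35% of ribosomes on the two stall codons of a 300-codon ORF.
#' @param init_boost Dwell-time factor for the initiation codon, emulating
#'   the start-codon peak of ribosome-profiling metagenes.
#' @param periodicity Fraction of footprints whose P-site lands in frame 0.
#' @param length_dist Named probabilities of footprint lengths (25-32 nt).
#' @param offsets_true Named true 5'-to-P-site offsets per footprint length.
#' @param n_rfp,n_srna,n_clones Read/clone counts.
#' @param breakpoint_nt ORF-relative 1-based nucleotide where the siRNA
#'   region (and RNA breakage) begins.
#' @param srna_sizes Named probabilities of siRNA sizes (21/22/24 nt).
#' @param srna_background Fraction of siRNA reads placed uniformly over the
#'   whole locus rather than 3' of the breakpoint.
#' @param isoform_weights Named translation weights of the two isoforms.
#' @param clone_noise Fraction of RACE clones whose 5' ends fall away from
#'   the breakpoint.
#' @param counts_dispersion Negative-binomial dispersion of the simulated
#'   polysome/total count tables (0 = noise-free).
#' @param counts_depth Simulated library depth for the count tables.
#' @param qpcr_copies Named per-genotype transposon copy numbers (the
#'   calibrator genotype carries the 2 genomic copies of a wild-type plant).
#' @param qpcr_noise_sd Gaussian noise sd on each Ct well.
#' @param qpcr_tech_reps,qpcr_bio_reps Technical wells per reaction and
#'   biological samples per genotype.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       orf_codons = 300L,
                       utr5 = 40L,
                       utr3 = 120L,
                       intron_donor = 700L,
                       intron_length = 150L,
                       tail_length = 400L,
                       stall_pair = c(148L, 149L),
                       stall_multiplier = 80,
                       init_boost = 5,
                       periodicity = 0.9,
                       length_dist = c(`25` = 0.02, `26` = 0.05, `27` = 0.10,
                                       `28` = 0.30, `29` = 0.25, `30` = 0.15,
                                       `31` = 0.08, `32` = 0.05),
                       offsets_true = c(`25` = 10, `26` = 10, `27` = 11,
                                        `28` = 12, `29` = 12, `30` = 13,
                                        `31` = 13, `32` = 13),
                       n_rfp = 50000L,
                       n_srna = 20000L,
                       n_clones = 36L,
                       breakpoint_nt = 447L,
                       srna_sizes = c(`21` = 0.5, `22` = 0.3, `24` = 0.2),
                       srna_background = 0.02,
                       isoform_weights = c(shTE = 0.95, flTE = 0.05),
                       clone_noise = 1 / 6,
                       counts_dispersion = 0.05,
                       counts_depth = 2e6,
                       qpcr_copies = c(WT = 2, line1 = 40),
                       qpcr_noise_sd = 0.2,
                       qpcr_tech_reps = 4L,
                       qpcr_bio_reps = 4L) {
  cfg <- list(
    seed = as.integer(seed), orf_codons = as.integer(orf_codons),
    utr5 = as.integer(utr5), utr3 = as.integer(utr3),
    intron_donor = as.integer(intron_donor),
    intron_length = as.integer(intron_length),
    tail_length = as.integer(tail_length),
    stall_pair = as.integer(stall_pair),
    stall_multiplier = stall_multiplier, init_boost = init_boost,
    periodicity = periodicity, length_dist = length_dist,
    offsets_true = offsets_true, n_rfp = as.integer(n_rfp),
    n_srna = as.integer(n_srna), n_clones = as.integer(n_clones),
    breakpoint_nt = as.integer(breakpoint_nt), srna_sizes = srna_sizes,
    srna_background = srna_background, isoform_weights = isoform_weights,
    clone_noise = clone_noise, counts_dispersion = counts_dispersion,
    counts_depth = counts_depth, qpcr_copies = qpcr_copies,
    qpcr_noise_sd = qpcr_noise_sd,
    qpcr_tech_reps = as.integer(qpcr_tech_reps),
    qpcr_bio_reps = as.integer(qpcr_bio_reps)
  )
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.validate_sim_config <- function(cfg) {
  for (nm in c("length_dist", "srna_sizes")) {
    if (abs(sum(cfg[[nm]]) - 1) > 1e-8) {
      abort(paste0(nm, " probabilities must sum to 1"))
    }
  }
  if (cfg$periodicity < 1 / 3 || cfg$periodicity > 1) {
    abort("periodicity must lie in [1/3, 1]")
  }
  if (length(cfg$stall_pair) != 2L ||
      cfg$stall_pair[2] != cfg$stall_pair[1] + 1L) {
    abort("stall_pair must be consecutive codon indices c(i, i + 1)")
  }
  if (any(cfg$stall_pair < 1L) || any(cfg$stall_pair > cfg$orf_codons)) {
    abort("stall_pair outside the ORF")
  }
  if (cfg$stall_multiplier < 1) abort("stall_multiplier must be >= 1")
  spliced_len <- cfg$utr5 + 3L * (cfg$orf_codons + 1L) + cfg$utr3
  if (cfg$breakpoint_nt < 1L ||
      cfg$utr5 + cfg$breakpoint_nt > spliced_len) {
    abort("breakpoint_nt outside the spliced isoform")
  }
  if (!all(names(cfg$length_dist) %in% as.character(25:32))) {
    abort("footprint lengths must lie in 25-32 nt")
  }
  if (!all(names(cfg$length_dist) %in% names(cfg$offsets_true))) {
    abort("offsets_true must cover every length in length_dist")
  }
  invisible(cfg)
}

# Random coding sequence: ATG + sampled sense codons + TAA, with designated
# codons optionally fixed (used to place the Pro-Gly stall pair).
.random_orf <- function(n_sense, fixed = NULL) {
  sense <- .sense_codons()
  codons <- c("ATG", sample(sense, n_sense - 1L, replace = TRUE))
  if (!is.null(fixed)) {
    for (i in seq_along(fixed)) {
      idx <- as.integer(names(fixed)[i])
      if (idx >= 2L && idx <= n_sense) codons[idx] <- fixed[[i]]
    }
  }
  paste(c(codons, "TAA"), collapse = "")
}

.random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate the synthetic two-isoform locus
#'
#' Lays out one chromosome as `exon1 - intron - exon2 - tail`. Model `shTE`
#' is the spliced short isoform ending at the premature poly(A) site; model
#' `flTE` is the unspliced full-length isoform whose reading frame runs into
#' an in-frame stop placed at the intron start. The declared ORF of the
#' spliced isoform contains no internal stop, and the stall pair codons are
#' fixed to proline (CCA) and glycine (GGT).
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (named [Biostrings::DNAStringSet]) and
#'   `models` (transcript-model tibble carrying a `locus_info` attribute
#'   with junction/intron/breakpoint bookkeeping).
#' @export
make_synthetic_locus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cds_len <- 3L * (config$orf_codons + 1L)
  cds_start <- config$utr5 + 1L
  cds_end <- config$utr5 + cds_len
  spliced_len <- cds_end + config$utr3
  donor <- config$intron_donor
  if (donor <= cds_start || donor >= cds_end) {
    abort("intron boundaries inconsistent with ORF: donor must fall inside it")
  }
  with_seed(config$seed, {
    fixed <- NULL
    if (config$stall_pair[2] <= config$orf_codons) {
      fixed <- stats::setNames(list("CCA", "GGT"),
                               as.character(config$stall_pair))
    }
    orf <- .random_orf(config$orf_codons, fixed)
    spliced_seq <- paste0(.random_nt(config$utr5), orf, .random_nt(config$utr3))

    # intron with canonical GT..AG ends and an in-frame stop near its start
    frame_off <- (3L - ((donor - config$utr5) %% 3L)) %% 3L
    intron_body <- .random_nt(config$intron_length)
    intron <- paste0(
      "GT", substr(intron_body, 3L, frame_off + 2L), "TAA",
      substr(intron_body, frame_off + 6L, config$intron_length - 2L), "AG"
    )
    stopifnot(nchar(intron) == config$intron_length)
    tail_seq <- .random_nt(config$tail_length)
    chrom_seq <- paste0(
      substr(spliced_seq, 1L, donor), intron,
      substr(spliced_seq, donor + 1L, spliced_len), tail_seq
    )
  })
  chrom_len <- nchar(chrom_seq)
  genome <- Biostrings::DNAStringSet(c(synTE = chrom_seq))

  spliced_exons <- tibble(
    start = c(1L, donor + config$intron_length + 1L),
    end = c(donor, donor + config$intron_length + (spliced_len - donor))
  )
  m_spliced <- .new_transcript_model("shTE", "TE1", "synTE", "+",
                                     spliced_exons,
                                     .cds_from_tpos(spliced_exons, cds_start,
                                                    cds_end),
                                     genome)

  fl_exons <- tibble(start = 1L, end = chrom_len)
  fl_seq <- chrom_seq
  fl_cds_end <- .first_inframe_stop_end(fl_seq, cds_start)
  m_fl <- .new_transcript_model("flTE", "TE1", "synTE", "+", fl_exons,
                                tibble(start = cds_start, end = fl_cds_end),
                                genome)
  models <- bind_rows(m_spliced, m_fl)
  attr(models, "locus_info") <- list(
    chrom = "synTE", spliced_id = "shTE", unspliced_id = "flTE",
    utr5 = config$utr5, orf_codons = config$orf_codons,
    cds_start = cds_start, cds_end = cds_end,
    spliced_length = spliced_len,
    junction_tpos = donor,
    intron_gstart = donor + 1L,
    intron_gend = donor + config$intron_length,
    pcpa_tpos = spliced_len,
    pcpa_gpos = spliced_len + config$intron_length,
    breakpoint_tpos = config$utr5 + config$breakpoint_nt,
    breakpoint_nt = config$breakpoint_nt
  )
  list(genome = genome, models = models)
}

.cds_from_tpos <- function(exons, t_start, t_end) {
  # plus-strand helper: transcript-local CDS -> genomic pieces
  widths <- exons$end - exons$start + 1L
  cum <- cumsum(c(0L, widths[-length(widths)]))
  pieces <- NULL
  for (i in seq_len(nrow(exons))) {
    t0 <- cum[i] + 1L
    t1 <- cum[i] + widths[i]
    s <- max(t_start, t0)
    e <- min(t_end, t1)
    if (s > e) next
    pieces <- bind_rows(pieces, tibble(start = exons$start[i] + (s - t0),
                                       end = exons$start[i] + (e - t0)))
  }
  pieces
}

.first_inframe_stop_end <- function(seq, cds_start) {
  n <- nchar(seq)
  starts <- seq.int(cds_start, n - 2L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  hit <- which(codons %in% .stop_codons)[1]
  if (is.na(hit)) abort("no in-frame stop found downstream of cds_start")
  starts[hit] + 2L
}

#' Generate a synthetic multi-gene transcriptome
#'
#' Single-isoform coding transcripts in transcript space (each transcript is
#' its own reference), with random stop-free ORFs. Used as the background
#' population for transcriptome-wide stalling percentiles.
#'
#' @param n_genes Number of genes (= transcripts).
#' @param seed Integer seed.
#' @param codon_range Range of sense-codon counts, drawn uniformly.
#' @param utr5,utr3 Flanking UTR lengths (nt).
#' @return A transcript-model tibble (same shape as
#'   [read_transcript_models()]).
#' @export
sim_transcriptome <- function(n_genes = 200L, seed = 1L,
                              codon_range = c(150L, 200L),
                              utr5 = 40L, utr3 = 40L) {
  with_seed(seed, {
    n_codons <- codon_range[1] +
      sample.int(codon_range[2] - codon_range[1] + 1L, n_genes,
                 replace = TRUE) - 1L
    purrr::map_dfr(seq_len(n_genes), function(i) {
      seq <- paste0(.random_nt(utr5), .random_orf(n_codons[i]),
                    .random_nt(utr3))
      len <- nchar(seq)
      tibble(
        transcript_id = sprintf("g%03d.t1", i),
        gene_id = sprintf("g%03d", i),
        chrom = sprintf("g%03d.t1", i), strand = "+",
        exons = list(tibble(start = 1L, end = len)),
        cds_start = utr5 + 1L,
        cds_end = utr5 + 3L * (n_codons[i] + 1L),
        cds_ok = TRUE, sequence = seq
      )
    })
  })
}

#' Simulate ribosome footprints
#'
#' Each footprint picks an isoform by translation weight, a codon by dwell
#' weight (uniform, except the initiation codon times `init_boost` and the
#' stall pair times `stall_multiplier`), and a length from `length_dist`;
#' its 5' end is the codon's first nucleotide minus the true offset for that
#' length, jittered into frames 1/2 with probability `1 - periodicity`.
#' Reads are in transcript space on the plus strand.
#'
#' @param config A [sim_config()].
#' @param models Transcript-model tibble (coding models only are used).
#' @param stall_transcript Transcript carrying the stall pair (default: the
#'   spliced locus isoform `shTE` when present, else the first model).
#' @return Tibble of aligned reads with truth columns `true_codon` and
#'   `true_frame`.
#' @export
simulate_rfp <- function(config, models, stall_transcript = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_rfp <= 0L) abort("n_rfp must be positive")
  models <- dplyr::filter(models, !is.na(.data$cds_start), .data$cds_ok)
  if (nrow(models) == 0L) abort("no coding transcript models")
  if (is.null(stall_transcript)) {
    stall_transcript <- if ("shTE" %in% models$transcript_id) "shTE"
    else models$transcript_id[1L]
  }
  w_iso <- config$isoform_weights
  if (is.null(w_iso) || !all(models$transcript_id %in% names(w_iso))) {
    w_iso <- stats::setNames(rep(1, nrow(models)), models$transcript_id)
  }
  w_iso <- w_iso[models$transcript_id]

  tx_len <- nchar(models$sequence)
  n_sense <- (models$cds_end - models$cds_start + 1L) %/% 3L - 1L

  with_seed(config$seed + 1L, {
    iso <- sample.int(nrow(models), config$n_rfp, replace = TRUE,
                      prob = w_iso)
    codon <- integer(config$n_rfp)
    for (m in unique(iso)) {
      idx <- which(iso == m)
      dw <- rep(1, n_sense[m])
      dw[1L] <- dw[1L] * config$init_boost
      if (models$transcript_id[m] == stall_transcript &&
          config$stall_pair[2] <= n_sense[m]) {
        dw[config$stall_pair] <- dw[config$stall_pair] * config$stall_multiplier
      }
      codon[idx] <- sample.int(n_sense[m], length(idx), replace = TRUE,
                               prob = dw)
    }
    len <- as.integer(sample(names(config$length_dist), config$n_rfp,
                             replace = TRUE, prob = config$length_dist))
    jitter <- sample(0:2, config$n_rfp, replace = TRUE,
                     prob = c(config$periodicity,
                              (1 - config$periodicity) / 2,
                              (1 - config$periodicity) / 2))
    psite <- models$cds_start[iso] + 3L * (codon - 1L) + jitter
    start <- psite - as.integer(config$offsets_true[as.character(len)])
    start <- pmax(1L, pmin(start, tx_len[iso] - len + 1L))
  })
  tibble(
    read_id = sprintf("rfp%07d", seq_len(config$n_rfp)),
    ref = models$transcript_id[iso], start = start, length = len,
    strand = "+", weight = 1,
    true_codon = codon, true_frame = jitter
  )
}

#' Simulate size-class siRNA reads over the locus
#'
#' Signal reads (sizes per `srna_sizes`, both strands with equal
#' probability) have 5' ends uniform on `[breakpoint, 3' end)` of the
#' spliced isoform; a fraction `srna_background` is placed uniformly over
#' the whole isoform.
#'
#' @param config A [sim_config()].
#' @param models Locus models from [make_synthetic_locus()].
#' @return Tibble of aligned reads (transcript space, `ref` = spliced
#'   isoform) with truth column `true_class` (`"signal"`/`"background"`).
#' @export
simulate_srna <- function(config, models) {
  stopifnot(inherits(config, "sim_config"))
  info <- attr(models, "locus_info")
  if (is.null(info)) abort("models lack locus_info (use make_synthetic_locus)")
  L <- info$spliced_length
  bp <- info$breakpoint_tpos
  n <- config$n_srna
  with_seed(config$seed + 2L, {
    size <- as.integer(sample(names(config$srna_sizes), n, replace = TRUE,
                              prob = config$srna_sizes))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    is_bg <- runif(n) < config$srna_background
    start <- integer(n)
    hi <- L - size + 1L
    sig <- which(!is_bg)
    bg <- which(is_bg)
    if (length(sig) > 0L) {
      start[sig] <- bp + floor(runif(length(sig)) * (hi[sig] - bp + 1L))
    }
    if (length(bg) > 0L) {
      start[bg] <- 1L + floor(runif(length(bg)) * hi[bg])
    }
  })
  tibble(
    read_id = sprintf("srna%07d", seq_len(n)), ref = info$spliced_id,
    start = as.integer(start), length = size, strand = strand, weight = 1,
    true_class = ifelse(is_bg, "background", "signal")
  )
}

#' Simulate RACE clones of 5'OH breakage fragments
#'
#' A fraction `1 - clone_noise` of clones start exactly at the breakpoint
#' (ORF coordinate converted to transcript coordinate internally); the rest
#' start uniformly elsewhere on the reference. Clone lengths are uniform on
#' 80-200 nt, truncated at the reference 3' end.
#'
#' @param config A [sim_config()].
#' @param reference Reference sequence (single character string, or a
#'   [Biostrings::DNAStringSet] whose first element is used), normally the
#'   spliced isoform.
#' @param breakpoint_tpos 1-based reference position of the breakage 5' end;
#'   defaults to `utr5 + breakpoint_nt` from the config.
#' @return Named [Biostrings::DNAStringSet] of clone inserts with a `truth`
#'   attribute tibble (`clone_id`, `true_start`, `true_class`).
#' @export
simulate_race_clones <- function(config, reference, breakpoint_tpos = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (methods::is(reference, "DNAStringSet")) {
    reference <- as.character(reference[[1]])
  }
  L <- nchar(reference)
  bp <- breakpoint_tpos %||% (config$utr5 + config$breakpoint_nt)
  stopifnot(bp >= 1L, bp <= L)
  n <- config$n_clones
  with_seed(config$seed + 3L, {
    noisy <- runif(n) < config$clone_noise
    start <- rep(bp, n)
    if (any(noisy)) {
      pool <- setdiff(seq_len(max(1L, L - 80L)), bp)
      start[noisy] <- sample(pool, sum(noisy), replace = TRUE)
    }
    len <- sample(80:200, n, replace = TRUE)
    len <- pmin(len, L - start + 1L)
  })
  seqs <- substring(reference, start, start + len - 1L)
  ids <- sprintf("clone%03d", seq_len(n))
  out <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
  attr(out, "truth") <- tibble(
    clone_id = ids, true_start = as.integer(start),
    true_class = ifelse(noisy, "noise", "modal")
  )
  out
}

#' Simulate polysome/total count tables and qPCR Ct tables
#'
#' Count tables: negative-binomial counts around configured abundances and
#' log2 polysome enrichments (dispersion 0 gives noise-free expected
#' counts). Ct tables: ideal Ct plus Gaussian well noise, for genomic-DNA
#' copy-number qPCR of the element against single-copy and two-copy
#' reference genes.
#'
#' @param config A [sim_config()].
#' @param features Optional tibble (`feature_id`, `length_nt`, `true_rpkm`,
#'   `true_log2_enrichment`, `sirna_level`, `class`); a default panel of the
#'   element plus seven controls is used when omitted.
#' @return List with `features` (per-feature RPKM tibble ready for
#'   [polysome_score()]) and `ct` (long Ct tibble for [copy_number()] /
#'   [relative_expression()]).
#' @export
simulate_counts <- function(config, features = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(features)) {
    features <- tibble(
      feature_id = c("shTE", sprintf("ctrl%d", 1:7)),
      length_nt = c(1100L, 800L, 1200L, 1500L, 900L, 2000L, 700L, 1300L),
      true_rpkm = c(80, 50, 120, 30, 200, 15, 60, 90),
      true_log2_enrichment = c(1.5, 0, -1, 0.5, -0.5, -2, 2, 0),
      sirna_level = c(250, 3, 10, 45, 1, 80, 20, 6),
      class = c("TE", rep("coding", 7))
    )
  }
  disp <- config$counts_dispersion
  depth <- config$counts_depth
  mu_total <- features$true_rpkm * (features$length_nt / 1000) * (depth / 1e6)
  mu_poly <- mu_total * 2^features$true_log2_enrichment
  with_seed(config$seed + 4L, {
    draw <- function(mu) {
      if (disp <= 0) mu
      else stats::rnbinom(length(mu), mu = mu, size = 1 / disp)
    }
    total <- draw(mu_total)
    poly <- draw(mu_poly)

    genotypes <- names(config$qpcr_copies)
    grid <- tidyr::expand_grid(
      genotype = genotypes,
      bio = seq_len(config$qpcr_bio_reps),
      target = c("EVD", "ACT2", "GAPC"),
      rep = seq_len(config$qpcr_tech_reps)
    )
    copies <- config$qpcr_copies[grid$genotype]
    ideal <- dplyr::case_when(
      grid$target == "ACT2" ~ 20,
      grid$target == "GAPC" ~ 22,
      TRUE ~ 20 - log2(copies / 2)
    )
    ct <- tibble(
      sample = sprintf("%s_b%d", grid$genotype, grid$bio),
      genotype = grid$genotype, target = grid$target, rep = grid$rep,
      ct = ideal + rnorm(nrow(grid), sd = config$qpcr_noise_sd),
      is_reference = grid$target %in% c("ACT2", "GAPC")
    )
  })
  feat <- tibble(
    feature_id = features$feature_id,
    class = features$class,
    total_rpkm = total / (features$length_nt / 1000) / (depth / 1e6),
    polysome_rpkm = poly / (features$length_nt / 1000) / (depth / 1e6),
    sirna_level = features$sirna_level
  )
  list(features = feat, ct = ct)
}
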