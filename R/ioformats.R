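# Readers/writers for the standard formats the pipeline touches, plus the
# shared coordinate conventions.
#
# Conventions used throughout the package:
#   * in-memory coordinates are 1-based and inclusive (the R/Bioconductor
#     convention); user-facing reports are likewise 1-based;
#   * on disk, bedGraph and the 6-column tabular alignment format keep their
#     native 0-based conventions and are converted on read/write;
#   * alignment strand is "+" or "-"; multimapping reads carry a fractional
#     weight so that the weights of one physical read sum to 1.

#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are uppercased and RNA `U` is mapped to DNA `T`, so downstream
#' codon arithmetic can assume the `{A,C,G,T,N}` alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    abort(paste0("FASTA file is empty: ", path))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate FASTA id: ", dup[1L]))
  }
  if (any(!nzchar(ids))) abort("FASTA record with empty id")
  s <- toupper(as.character(seqs))
  s <- gsub("U", "T", s, fixed = TRUE)
  out <- Biostrings::DNAStringSet(s)
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs A named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

# ---- transcript models -----------------------------------------------------

.tpos_map <- function(exons, strand) {
  # Returns a function mapping genomic positions to transcript-local 1-based
  # positions. `exons` is a tibble(start, end) in transcript order.
  widths <- exons$end - exons$start + 1L
  cum <- cumsum(c(0L, widths[-length(widths)]))
  function(g) {
    out <- rep(NA_integer_, length(g))
    for (i in seq_len(nrow(exons))) {
      hit <- g >= exons$start[i] & g <= exons$end[i]
      if (strand == "+") {
        out[hit] <- cum[i] + (g[hit] - exons$start[i] + 1L)
      } else {
        out[hit] <- cum[i] + (exons$end[i] - g[hit] + 1L)
      }
    }
    out
  }
}

.spliced_sequence <- function(genome, chrom, exons, strand) {
  if (!chrom %in% names(genome)) {
    abort(paste0("unknown chromosome: ", chrom))
  }
  chr_seq <- genome[[chrom]]
  pieces <- vapply(seq_len(nrow(exons)), function(i) {
    piece <- Biostrings::subseq(chr_seq, exons$start[i], exons$end[i])
    if (strand == "-") piece <- Biostrings::reverseComplement(piece)
    as.character(piece)
  }, character(1))
  paste(pieces, collapse = "")
}

.new_transcript_model <- function(transcript_id, gene_id, chrom, strand,
                                  exons_genomic, cds_genomic, genome) {
  # exons_genomic: tibble(start, end), genomic 1-based inclusive, any order.
  ord <- order(exons_genomic$start)
  if (strand == "-") ord <- rev(ord)
  exons <- exons_genomic[ord, , drop = FALSE]
  tmap <- .tpos_map(exons, strand)
  sequence <- .spliced_sequence(genome, chrom, exons, strand)

  cds_start <- NA_integer_
  cds_end <- NA_integer_
  cds_ok <- TRUE
  if (!is.null(cds_genomic) && nrow(cds_genomic) > 0L) {
    g5 <- if (strand == "+") min(cds_genomic$start) else max(cds_genomic$end)
    g3 <- if (strand == "+") max(cds_genomic$end) else min(cds_genomic$start)
    cds_start <- tmap(g5)
    cds_end <- tmap(g3)
    cds_len <- sum(cds_genomic$end - cds_genomic$start + 1L)
    if (is.na(cds_start) || is.na(cds_end)) {
      warn(paste0(transcript_id, ": CDS outside exons; flagged non-qualifying"))
      cds_ok <- FALSE
    } else if (cds_len %% 3L != 0L) {
      warn(paste0(transcript_id, ": CDS length not divisible by 3; ",
                  "flagged non-qualifying"))
      cds_ok <- FALSE
    }
  }
  tibble(
    transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
    strand = strand, exons = list(tibble(start = exons$start, end = exons$end)),
    cds_start = cds_start, cds_end = cds_end, cds_ok = cds_ok,
    sequence = sequence
  )
}

#' Read transcript models from GFF3 or BED12
#'
#' Builds one record per transcript with the spliced sequence (extracted
#' strand-aware from `genome`), exons in transcript order, and CDS boundaries
#' converted to transcript-local 1-based inclusive coordinates.
#'
#' @param path Path to a GFF3 (`gene`/`mRNA`/`exon`/`CDS`) or BED12 file.
#' @param genome Named [Biostrings::DNAStringSet] of chromosome sequences.
#' @param format `"auto"` (by file extension), `"gff3"` or `"bed12"`.
#' @return A tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `exons` (list of tibbles with genomic `start`/`end`),
#'   `cds_start`, `cds_end` (transcript-local, `NA` for non-coding),
#'   `cds_ok` and `sequence`.
#' @export
read_transcript_models <- function(path, genome,
                                   format = c("auto", "gff3", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed[0-9]*$", path, ignore.case = TRUE)) {
      "bed12"
    } else {
      "gff3"
    }
  }
  if (format == "gff3") {
    .models_from_gff3(path, genome)
  } else {
    .models_from_bed12(path, genome)
  }
}

.models_from_gff3 <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  tx_idx <- which(type %in% c("mRNA", "transcript"))
  if (length(tx_idx) == 0L) abort("no mRNA/transcript features in GFF3")
  out <- purrr::map_dfr(tx_idx, function(i) {
    tid <- as.character(md$ID[i])
    parent <- md$Parent[[i]]
    gid <- if (length(parent) > 0L) as.character(parent)[1L] else tid
    children <- which(vapply(md$Parent, function(p) tid %in% as.character(p),
                             logical(1)))
    ex <- children[type[children] == "exon"]
    cds <- children[type[children] == "CDS"]
    if (length(ex) == 0L) ex <- i  # transcript with implicit single exon
    exons <- tibble(start = GenomicRanges::start(gr)[ex],
                    end = GenomicRanges::end(gr)[ex])
    cds_tbl <- if (length(cds) > 0L) {
      tibble(start = GenomicRanges::start(gr)[cds],
             end = GenomicRanges::end(gr)[cds])
    } else {
      NULL
    }
    .new_transcript_model(
      tid, gid, as.character(GenomicRanges::seqnames(gr))[i],
      as.character(BiocGenerics::strand(gr))[i], exons, cds_tbl, genome
    )
  })
  out
}

.models_from_bed12 <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "bed")
  md <- S4Vectors::mcols(gr)
  purrr::map_dfr(seq_along(gr), function(i) {
    tid <- as.character(md$name[i])
    chrom <- as.character(GenomicRanges::seqnames(gr))[i]
    strand <- as.character(BiocGenerics::strand(gr))[i]
    chrom_start <- GenomicRanges::start(gr)[i]
    blocks <- md$blocks[[i]]
    exons <- tibble(
      start = chrom_start + BiocGenerics::start(blocks) - 1L,
      end = chrom_start + BiocGenerics::end(blocks) - 1L
    )
    cds_tbl <- NULL
    if (!is.null(md$thick)) {
      th_start <- BiocGenerics::start(md$thick)[i]
      th_end <- BiocGenerics::end(md$thick)[i]
      if (!is.na(th_start) && th_end >= th_start) {
        # intersect the thick range with the exon blocks
        cds_tbl <- dplyr::filter(
          tibble(start = pmax(exons$start, th_start),
                 end = pmin(exons$end, th_end)),
          .data$start <= .data$end
        )
        if (nrow(cds_tbl) == 0L) cds_tbl <- NULL
        # a thick range spanning the whole transcript with no distinct
        # boundaries is still treated as CDS (BED has no better signal)
      }
    }
    .new_transcript_model(tid, tid, chrom, strand, exons, cds_tbl, genome)
  })
}

# ---- alignments ------------------------------------------------------------

.empty_reads <- function() {
  tibble(read_id = character(0), ref = character(0), start = integer(0),
         length = integer(0), strand = character(0), weight = numeric(0))
}

#' Read aligned reads from SAM (subset) or the 6-column tabular format
#'
#' The tabular format has a header line and columns
#' `read_id, ref, start, length, strand, n_hits`, with `start` 0-based (it is
#' converted to 1-based in memory). The SAM subset supports header `@SQ`
#' lines, primary/secondary flags, and CIGARs made of `M`/`N`/`D` with
#' optional leading/trailing soft clips; read length is the aligned span on
#' the reference.
#'
#' @param path Input path.
#' @param kind `"tabular"` or `"sam"`.
#' @param multimap Multimapper policy: `"fractional"` weights every reported
#'   alignment by 1/number-of-alignments; `"primary"` keeps primary
#'   alignments only, with weight 1.
#' @return Tibble with columns `read_id`, `ref`, `start` (1-based), `length`,
#'   `strand`, `weight`.
#' @export
read_alignments <- function(path, kind = c("tabular", "sam"),
                            multimap = c("fractional", "primary")) {
  kind <- match.arg(kind)
  multimap <- match.arg(multimap)
  if (kind == "tabular") .reads_from_tabular(path, multimap)
  else .reads_from_sam(path, multimap)
}

.reads_from_tabular <- function(path, multimap) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           read_id = readr::col_character(),
                           ref = readr::col_character(),
                           start = readr::col_integer(),
                           length = readr::col_integer(),
                           strand = readr::col_character(),
                           n_hits = readr::col_integer()
                         ))
  if (nrow(tab) == 0L) return(.empty_reads())
  w <- if (multimap == "fractional") 1 / tab$n_hits else 1
  tibble(read_id = tab$read_id, ref = tab$ref, start = tab$start + 1L,
         length = tab$length, strand = tab$strand, weight = w)
}

.cigar_ref_span <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]$", "", ops))
  kinds <- sub("^[0-9]+", "", ops)
  sum(lens[kinds %in% c("M", "D", "N", "=", "X")])
}

.reads_from_sam <- function(path, multimap) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  refs <- sub(".*\tSN:([^\t]+).*", "\\1", hdr[startsWith(hdr, "@SQ")])
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(body) == 0L) return(.empty_reads())
  fields <- strsplit(body, "\t", fixed = TRUE)
  recs <- purrr::map_dfr(fields, function(f) {
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L) return(NULL)  # unmapped
    nh <- NA_integer_
    if (length(f) > 11L) {
      tag <- grep("^NH:i:", f[12:length(f)], value = TRUE)
      if (length(tag) > 0L) nh <- as.integer(sub("^NH:i:", "", tag[1L]))
    }
    tibble(
      read_id = f[1], ref = f[3], start = as.integer(f[4]),
      length = .cigar_ref_span(f[6]),
      strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+",
      secondary = bitwAnd(flag, 256L) > 0L, n_hits = nh
    )
  })
  if (nrow(recs) == 0L) return(.empty_reads())
  bad <- setdiff(unique(recs$ref), refs)
  if (length(bad) > 0L) {
    abort(paste0("reference absent from SAM header: ", bad[1L]))
  }
  if (multimap == "primary") {
    recs <- dplyr::filter(recs, !.data$secondary)
    recs$weight <- 1
  } else {
    recs <- recs |>
      group_by(.data$read_id) |>
      mutate(weight = 1 / dplyr::coalesce(.data$n_hits[1L], n())) |>
      ungroup()
  }
  select(recs, "read_id", "ref", "start", "length", "strand", "weight")
}

#' Write aligned reads to the 6-column tabular format
#'
#' The inverse of [read_alignments()] for `kind = "tabular"`: `start` is
#' written 0-based and `n_hits` is recovered as `round(1/weight)`.
#'
#' @param reads Tibble of aligned reads.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(reads, path) {
  out <- tibble(
    read_id = reads$read_id, ref = reads$ref,
    start = as.integer(reads$start - 1L), length = as.integer(reads$length),
    strand = reads$strand, n_hits = as.integer(round(1 / reads$weight))
  )
  readr::write_tsv(out, path)
  invisible(path)
}

# ---- coverage tracks -------------------------------------------------------

#' Construct a per-position coverage track
#'
#' @param values Numeric vector of finite, non-negative per-position values.
#' @param ref Reference (chromosome or transcript) name.
#' @param start 1-based position of `values[1]` on `ref`.
#' @param label Free-text label (used as the bedGraph track name).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, ref, start = 1L, label = "coverage") {
  stopifnot(is.numeric(values), all(is.finite(values)), all(values >= 0))
  structure(
    list(ref = ref, values = as.numeric(values), start = as.integer(start),
         label = label),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s:%d-%d  %s  (total %.3g)\n", x$ref, x$start,
              x$start + length(x$values) - 1L, x$label, sum(x$values)))
  invisible(x)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal value are merged and zero-valued runs are omitted; intervals
#' are written in bedGraph's native 0-based half-open convention.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s"', track$label), con)
  r <- rle(track$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  if (any(keep)) {
    # convert run boundaries to 0-based half-open genomic intervals
    g0 <- track$start - 1L + starts[keep] - 1L
    g1 <- track$start - 1L + ends[keep]
    writeLines(sprintf("%s\t%d\t%d\t%s", track$ref, g0, g1,
                       format(r$values[keep], trim = TRUE, digits = 10)), con)
  }
  invisible(path)
}

#' Read a bedGraph file back into a coverage track
#'
#' @param path Path to a bedGraph file.
#' @param ref Reference to extract (default: the only one present).
#' @param span Optional `c(start, end)` 1-based inclusive bounds of the
#'   returned track; defaults to the covered extent.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, ref = NULL, span = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (is.null(ref)) {
    ref <- as.character(unique(GenomicRanges::seqnames(gr)))
    if (length(ref) == 0L) ref <- "empty"
    if (length(ref) > 1L) abort("multiple references; supply `ref`")
  }
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == ref]
  if (is.null(span)) {
    span <- if (length(gr) == 0L) c(1L, 1L) else
      c(min(GenomicRanges::start(gr)), max(GenomicRanges::end(gr)))
  }
  values <- numeric(span[2] - span[1] + 1L)
  if (length(gr) > 0L) {
    for (i in seq_along(gr)) {
      s <- max(GenomicRanges::start(gr)[i], span[1])
      e <- min(GenomicRanges::end(gr)[i], span[2])
      if (s <= e) values[(s:e) - span[1] + 1L] <- gr$score[i]
    }
  }
  coverage_track(values, ref, start = span[1])
}

#' Write transcript models as GFF3
#'
#' Emits `gene`, `mRNA`, `exon` and `CDS` features with `ID`/`Parent`
#' attributes so the file round-trips through [read_transcript_models()].
#'
#' @param models Transcript-model tibble (see [read_transcript_models()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    ex <- m$exons[[1]]
    span <- c(min(ex$start), max(ex$end))
    lines <- c(
      lines,
      sprintf("%s\ttdsilence\tgene\t%d\t%d\t.\t%s\t.\tID=%s", m$chrom,
              span[1], span[2], m$strand, m$gene_id),
      sprintf("%s\ttdsilence\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              m$chrom, span[1], span[2], m$strand, m$transcript_id, m$gene_id),
      sprintf("%s\ttdsilence\texon\t%d\t%d\t.\t%s\t.\tParent=%s", m$chrom,
              ex$start, ex$end, m$strand, m$transcript_id)
    )
    if (!is.na(m$cds_start)) {
      # project the transcript-local CDS back onto genomic exon pieces
      cds <- .cds_genomic_pieces(m)
      lines <- c(lines, sprintf(
        "%s\ttdsilence\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s", m$chrom,
        cds$start, cds$end, m$strand, m$transcript_id
      ))
    }
  }
  # de-duplicate gene lines shared by isoforms
  writeLines(unique(lines), path)
  invisible(path)
}

.cds_genomic_pieces <- function(model) {
  ex <- model$exons[[1]]
  widths <- ex$end - ex$start + 1L
  cum <- cumsum(c(0L, widths[-length(widths)]))
  pieces <- NULL
  for (i in seq_len(nrow(ex))) {
    t0 <- cum[i] + 1L
    t1 <- cum[i] + widths[i]
    s <- max(model$cds_start, t0)
    e <- min(model$cds_end, t1)
    if (s > e) next
    if (model$strand == "+") {
      g0 <- ex$start[i] + (s - t0)
      g1 <- ex$start[i] + (e - t0)
    } else {
      g1 <- ex$end[i] - (s - t0)
      g0 <- ex$end[i] - (e - t0)
    }
    pieces <- bind_rows(pieces, tibble(start = g0, end = g1))
  }
  pieces
}
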