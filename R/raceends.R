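# Mapping RACE-clone 5' ends onto a reference, tallying modal breakage
# positions, nucleotide-to-codon conversion, and 5'-end tracks.

#' Map clone 5' ends by unique anchor matching
#'
#' After stripping an optional 5' adapter and trailing Ns (Sanger-quality
#' trimming), the first `anchor_k` bases of each clone are located in the
#' reference allowing up to `max_mismatch` mismatches. A clone maps only if
#' the anchor occurs exactly once; the mapped 5' end is that position
#' (1-based in the reference coordinate system, or ORF-relative if
#' `cds_start` is given).
#'
#' @param clones Named [Biostrings::DNAStringSet] (or named character
#'   vector) of clone insert sequences.
#' @param reference Reference sequence (string or single-element
#'   `DNAStringSet`).
#' @param anchor_k Anchor length (default 25).
#' @param max_mismatch Maximum mismatches in the anchor (default 1).
#' @param adapter Optional 5' adapter string to strip when present.
#' @param cds_start Optional 1-based reference position of the ORF start;
#'   when given, an `end5_orf` column reports ORF-relative coordinates.
#' @return Tibble `clone_id`, `mapped`, `end5`, `match_len`, `mismatches`
#'   (and `end5_orf` when `cds_start` is given).
#' @export
map_clone_5p <- function(clones, reference, anchor_k = 25L,
                         max_mismatch = 1L, adapter = NULL,
                         cds_start = NULL) {
  if (methods::is(reference, "DNAStringSet")) {
    reference <- as.character(reference[[1]])
  }
  if (nchar(reference) < anchor_k) {
    abort("reference shorter than anchor_k")
  }
  ref <- Biostrings::DNAString(toupper(reference))
  seqs <- toupper(as.character(clones))
  ids <- names(clones) %||% sprintf("clone%03d", seq_along(seqs))
  out <- purrr::map_dfr(seq_along(seqs), function(i) {
    s <- seqs[i]
    if (!is.null(adapter) && startsWith(s, toupper(adapter))) {
      s <- substring(s, nchar(adapter) + 1L)
    }
    s <- sub("N+$", "", s)  # trailing-N trimming
    if (nchar(s) < anchor_k) {
      return(tibble(clone_id = ids[i], mapped = FALSE, end5 = NA_integer_,
                    match_len = nchar(s), mismatches = NA_integer_))
    }
    anchor <- substring(s, 1L, anchor_k)
    hits <- Biostrings::matchPattern(anchor, ref,
                                     max.mismatch = max_mismatch)
    if (length(hits) != 1L) {
      return(tibble(clone_id = ids[i], mapped = FALSE, end5 = NA_integer_,
                    match_len = nchar(s), mismatches = NA_integer_))
    }
    mm <- Biostrings::neditStartingAt(Biostrings::DNAString(anchor), ref,
                                      starting.at = BiocGenerics::start(hits))
    tibble(clone_id = ids[i], mapped = TRUE,
           end5 = BiocGenerics::start(hits), match_len = nchar(s),
           mismatches = as.integer(mm))
  })
  if (!is.null(cds_start)) {
    out <- mutate(out, end5_orf = .data$end5 - cds_start + 1L)
  }
  out
}

#' Modal 5'-end window among mapped clone ends
#'
#' Slides a window of `window` consecutive positions over the mapped 5'
#' ends and returns the interval capturing the most ends (leftmost on
#' ties), its count, and the fraction of mapped clones it captures.
#'
#' @param ends Integer vector of mapped 5'-end positions, or a
#'   [map_clone_5p()] tibble (its mapped `end5` values are used; an
#'   `end5_orf` column takes precedence when present).
#' @param window Window width in nt (default 2, for a two-nucleotide
#'   breakage signature).
#' @return List: `start`, `end` (modal interval), `count`, `mapped_total`,
#'   `fraction`, and `mode` (the single most frequent end position,
#'   leftmost on ties).
#' @export
modal_end_fraction <- function(ends, window = 2L) {
  if (is.data.frame(ends)) {
    col <- if ("end5_orf" %in% names(ends)) "end5_orf" else "end5"
    ends <- ends[[col]][ends$mapped]
  }
  ends <- ends[!is.na(ends)]
  if (length(ends) == 0L) abort("no mapped ends")
  starts <- seq.int(min(ends), max(ends))
  counts <- vapply(starts, function(s) {
    sum(ends >= s & ends <= s + window - 1L)
  }, integer(1))
  best <- which_max_first(counts)
  singles <- vapply(starts, function(s) sum(ends == s), integer(1))
  list(start = starts[best], end = starts[best] + window - 1L,
       count = counts[best], mapped_total = length(ends),
       fraction = counts[best] / length(ends),
       mode = starts[which_max_first(singles)])
}

#' Convert an ORF-relative nucleotide position to a codon index
#'
#' @param orf_nt 1-based nucleotide position(s) within the ORF.
#' @return 1-based codon index: `ceiling(orf_nt / 3)`.
#' @export
nt_to_codon <- function(orf_nt) {
  if (any(orf_nt < 1L)) abort("ORF nucleotide position must be >= 1")
  as.integer(ceiling(orf_nt / 3))
}

#' 5'-end track of a read set over a locus
#'
#' Each read's weight is added at its 5'-most reference position only
#' (start for plus-strand reads, rightmost coordinate for minus-strand
#' reads) -- the arithmetic behind degradome/5'-end library browser tracks.
#'
#' @param reads Aligned-read tibble.
#' @param locus_ref Reference name.
#' @param locus_length Reference length (nt).
#' @return Tibble `pos`, `strand`, `count` over all positions.
#' @export
end5_track <- function(reads, locus_ref, locus_length) {
  reads <- reads |>
    dplyr::filter(.data$ref == locus_ref) |>
    mutate(pos5 = ifelse(.data$strand == "-",
                         .data$start + .data$length - 1L, .data$start)) |>
    dplyr::filter(.data$pos5 >= 1L, .data$pos5 <= locus_length)
  grid <- tidyr::expand_grid(pos = seq_len(locus_length),
                             strand = c("+", "-"))
  counts <- reads |>
    group_by(pos = .data$pos5, .data$strand) |>
    summarise(count = sum(.data$weight), .groups = "drop")
  grid |>
    left_join(counts, by = c("pos", "strand")) |>
    mutate(count = dplyr::coalesce(.data$count, 0))
}
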