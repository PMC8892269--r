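# Sequence-intrinsic feature scans used to probe stall-cause hypotheses:
# codon adaptation index, GC/GC3 windows, G-quadruplex propensity, longest
# ORF content, and codon lookups.

#' Codon adaptation index profile
#'
#' Relative adaptiveness of a codon is its reference frequency over the
#' maximum frequency in its synonymous family; the CAI of the CDS is the
#' geometric mean of these weights over all codons except methionine,
#' tryptophan and stops (single-codon families carry no information).
#'
#' @param cds Coding sequence (nucleotide string, length multiple of 3).
#' @param reference_usage Tibble with columns `codon`, `frequency` (e.g. the
#'   `usage` element of [dwell_and_usage()]), or a named numeric vector.
#' @return List of class `cai_profile`: `weights` (tibble `codon_index`,
#'   `codon`, `w`; `NA` weight for excluded codons) and `cai`.
#' @export
cai_profile <- function(cds, reference_usage) {
  if (is.data.frame(reference_usage)) {
    usage <- stats::setNames(reference_usage$frequency, reference_usage$codon)
  } else {
    usage <- reference_usage
  }
  gc <- .genetic_code()
  sense <- .sense_codons()
  f <- stats::setNames(rep(0, length(sense)), sense)
  f[names(usage)[names(usage) %in% sense]] <-
    usage[names(usage) %in% sense]
  # zero-frequency codons get a small floor so the geometric mean is defined
  if (any(f == 0)) {
    floor_f <- if (any(f > 0)) min(f[f > 0]) / 2 else 1
    f[f == 0] <- floor_f
  }
  fam_max <- vapply(sense, function(cod) max(f[sense[gc[sense] == gc[cod]]]),
                    numeric(1))
  w_all <- f / fam_max

  codons <- split_codons(toupper(cds))
  excluded <- codons %in% c("ATG", "TGG", .stop_codons)
  w <- ifelse(excluded, NA_real_, w_all[codons])
  contributing <- w[!is.na(w)]
  if (length(contributing) == 0L) {
    abort("CDS has no contributing codons for CAI")
  }
  structure(
    list(weights = tibble(codon_index = seq_along(codons), codon = codons,
                          w = unname(w)),
         cai = exp(mean(log(contributing)))),
    class = "cai_profile"
  )
}

#' @export
print.cai_profile <- function(x, ...) {
  cat(sprintf("<cai_profile> CAI %.3f over %d contributing codons\n", x$cai,
              sum(!is.na(x$weights$w))))
  invisible(x)
}

#' Sliding-window GC and GC3 profiles of a CDS
#'
#' Per codon, the GC fraction and the third-position G/C indicator, smoothed
#' with a centred sliding window (truncated at the ends).
#'
#' @param cds Coding sequence (length multiple of 3).
#' @param window_codons Window width in codons (default 15).
#' @return Tibble `codon_index`, `gc`, `gc3` (windowed means).
#' @export
gc_profiles <- function(cds, window_codons = 15L) {
  codons <- split_codons(toupper(cds))
  gc_raw <- vapply(codons, function(cod) {
    mean(strsplit(cod, "")[[1]] %in% c("G", "C"))
  }, numeric(1))
  gc3_raw <- as.numeric(substr(codons, 3, 3) %in% c("G", "C"))
  half <- window_codons %/% 2L
  n <- length(codons)
  win_mean <- function(v) {
    vapply(seq_len(n), function(i) {
      mean(v[max(1L, i - half):min(n, i + half)])
    }, numeric(1))
  }
  tibble(codon_index = seq_len(n), gc = win_mean(gc_raw),
         gc3 = win_mean(gc3_raw))
}

#' G-quadruplex propensity scan
#'
#' Per-base scores: each base in a run of `r` consecutive Gs scores
#' `+min(r, 4)`, each base in a C run `-min(r, 4)`, other bases 0; the track
#' is the sliding-window mean. Hotspots are maximal intervals whose window
#' mean magnitude reaches `threshold` with positive sign (G-quadruplex on
#' the given strand).
#'
#' @param seq Nucleotide string.
#' @param window Window width (default 25, G4Hunter-style).
#' @param threshold Hotspot threshold on the window mean (default 1.2).
#' @return List of class `g4_scan`: `track` (tibble `pos`, `score` for each
#'   full window, `pos` = window start) and `hotspots` (tibble `start`,
#'   `end`, `max_score`).
#' @export
g4_scan <- function(seq, window = 25L, threshold = 1.2) {
  bases <- strsplit(toupper(seq), "")[[1]]
  n <- length(bases)
  if (n < window) abort("sequence shorter than window")
  r <- rle(bases)
  run_score <- ifelse(r$values == "G", pmin(r$lengths, 4L),
                      ifelse(r$values == "C", -pmin(r$lengths, 4L), 0L))
  base_scores <- rep(run_score, r$lengths)
  win <- as.numeric(stats::filter(base_scores, rep(1 / window, window),
                                  sides = 1))
  win <- win[window:n]  # win[i] = mean over positions i..i+window-1
  track <- tibble(pos = seq_len(n - window + 1L), score = win)
  hot <- track$score >= threshold
  hotspots <- if (any(hot)) {
    hr <- rle(hot)
    ends <- cumsum(hr$lengths)
    starts <- ends - hr$lengths + 1L
    idx <- which(hr$values)
    purrr::map_dfr(idx, function(i) {
      rows <- starts[i]:ends[i]
      tibble(start = track$pos[starts[i]],
             end = track$pos[ends[i]] + window - 1L,
             max_score = max(track$score[rows]))
    })
  } else {
    tibble(start = integer(0), end = integer(0), max_score = numeric(0))
  }
  structure(list(track = track, hotspots = hotspots, window = window,
                 threshold = threshold),
            class = "g4_scan")
}

#' @export
print.g4_scan <- function(x, ...) {
  cat(sprintf("<g4_scan> window %d, threshold %.2f: %d hotspot(s)\n",
              x$window, x$threshold, nrow(x$hotspots)))
  invisible(x)
}

.longest_orf_one_strand <- function(seq) {
  n <- nchar(seq)
  best <- 0L
  for (frame in 0:2) {
    starts <- seq.int(1L + frame, n - 2L, by = 3L)
    if (length(starts) == 0L) next
    codons <- substring(seq, starts, starts + 2L)
    atg <- which(codons == "ATG")
    stop_i <- which(codons %in% .stop_codons)
    if (length(atg) == 0L || length(stop_i) == 0L) next
    # for each ATG, the next in-frame stop at or after it
    nxt <- stop_i[findInterval(atg - 1L, stop_i) + 1L]
    ok <- !is.na(nxt)
    if (!any(ok)) next
    best <- max(best, max((nxt[ok] - atg[ok] + 1L) * 3L))
  }
  best
}

#' Longest-ORF length ratio of an element
#'
#' Longest ATG-to-stop open reading frame (stop codon included) over both
#' strands and all frames, as a fraction of the element length.
#'
#' @param element_seq Nucleotide string.
#' @return A number in `[0, 1]` (0 if no complete ORF exists).
#' @export
orf_length_ratio <- function(element_seq) {
  s <- toupper(element_seq)
  best <- max(.longest_orf_one_strand(s), .longest_orf_one_strand(revcomp(s)))
  best / nchar(s)
}

#' Codons and amino acids at given CDS positions
#'
#' @param cds Coding sequence (length multiple of 3).
#' @param indices 1-based codon indices.
#' @return Tibble `codon_index`, `codon`, `aa`.
#' @export
codons_at <- function(cds, indices) {
  codons <- split_codons(toupper(cds))
  if (any(indices < 1L)) abort("codon index must be >= 1")
  if (any(indices > length(codons))) abort("codon index past CDS end")
  tibble(codon_index = as.integer(indices), codon = codons[indices],
         aa = translate_codons(codons[indices]))
}
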