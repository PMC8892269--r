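# Shared helpers: genetic code, codon splitting, seeded evaluation.

# Standard nuclear genetic code, DNA alphabet.
.genetic_code <- function() Biostrings::GENETIC_CODE

.stop_codons <- c("TAA", "TAG", "TGA")

.sense_codons <- function() {
  gc <- .genetic_code()
  names(gc)[gc != "*"]
}

#' Split a coding sequence into codons
#'
#' @param seq A single nucleotide string whose length is a multiple of 3.
#' @return Character vector of codon triplets.
#' @keywords internal
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    abort("sequence length is not a multiple of 3")
  }
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n, by = 3L)
  substring(seq, starts, starts + 2L)
}

# Translate a vector of codons to one-letter amino acids ("*" for stops).
translate_codons <- function(codons) {
  unname(.genetic_code()[codons])
}

# Reverse complement of a plain character string.
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Evaluate an expression under a fixed RNG seed without touching the caller's
# RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Weighted argmax with deterministic smallest-index tie-break.
which_max_first <- function(x) {
  which(x == max(x))[1L]
}

`%||%` <- rlang::`%||%`
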