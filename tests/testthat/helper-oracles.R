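# Independent brute-force oracles and tiny hand-built fixtures, kept free of
# the package's own internals so they can arbitrate its results.

# Brute-force stalling-score recomputation: plain loops, no vectorised
# shortcuts shared with the implementation.
oracle_stall <- function(counts, has_stop = FALSE) {
  m <- if (has_stop) length(counts) - 1 else length(counts)
  inc <- counts[1:m]
  total <- 0
  for (x in inc) total <- total + x
  expectation <- total / m
  scores <- numeric(m)
  for (i in 1:m) scores[i] <- inc[i] / expectation
  best <- 1
  for (i in 1:m) if (scores[i] > scores[best]) best <- i
  best_pair <- 1
  best_pair_sum <- inc[1] + inc[2]
  if (m > 2) {
    for (i in 2:(m - 1)) {
      s <- inc[i] + inc[i + 1]
      if (s > best_pair_sum) {
        best_pair <- i
        best_pair_sum <- s
      }
    }
  }
  list(scores = scores, max_codon = best, max_score = scores[best],
       pair = c(best_pair, best_pair + 1), pair_fraction = best_pair_sum / total)
}

# Percentile by direct counting.
oracle_percentile <- function(max_scores, i) {
  100 * sum(max_scores > max_scores[i]) / length(max_scores)
}

# Offset estimation by explicit nested loops over candidate distances.
oracle_offsets <- function(reads, cds_starts, min_support = 100) {
  out <- list()
  for (L in sort(unique(reads$length))) {
    sub <- reads[reads$length == L, ]
    d_all <- cds_starts[sub$ref] - sub$start
    valid <- !is.na(d_all) & d_all >= 6 & d_all <= L - 6
    if (sum(valid) < min_support) next
    cand <- 6:(L - 6)
    votes <- sapply(cand, function(d) sum(sub$weight[valid][d_all[valid] == d]))
    out[[as.character(L)]] <- cand[which(votes == max(votes))[1]]
  }
  out
}

# A hand-built 20-nt toy locus: two exons on the minus strand.
toy_genome <- function() {
  Biostrings::DNAStringSet(c(chr1 = "ACGTACGTACGGATCCTTAA"))
}

write_toy_gff3 <- function(path, strand = "-") {
  writeLines(c(
    "##gff-version 3",
    sprintf("chr1\ttoy\tgene\t1\t20\t.\t%s\t.\tID=gene1", strand),
    sprintf("chr1\ttoy\tmRNA\t1\t20\t.\t%s\t.\tID=tx1;Parent=gene1", strand),
    sprintf("chr1\ttoy\texon\t1\t8\t.\t%s\t.\tParent=tx1", strand),
    sprintf("chr1\ttoy\texon\t13\t20\t.\t%s\t.\tParent=tx1", strand)
  ), path)
  path
}

# The same two-exon model as coding BED12 / GFF3 on the plus strand, CDS
# covering transcript nt 4..15 (12 nt).
write_equiv_gff3 <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t1\t20\t.\t+\t.\tID=geneE",
    "chr1\ttoy\tmRNA\t1\t20\t.\t+\t.\tID=txE;Parent=geneE",
    "chr1\ttoy\texon\t1\t8\t.\t+\t.\tParent=txE",
    "chr1\ttoy\texon\t13\t20\t.\t+\t.\tParent=txE",
    "chr1\ttoy\tCDS\t4\t8\t.\t+\t0\tParent=txE",
    "chr1\ttoy\tCDS\t13\t19\t.\t+\t1\tParent=txE"
  ), path)
  path
}

write_equiv_bed12 <- function(path) {
  # BED is 0-based half-open: blocks (0,8) and (12,20); thick 3..19
  writeLines(paste(c("chr1", 0, 20, "txE", 0, "+", 3, 19, 0, 2,
                     "8,8", "0,12"), collapse = "\t"), path)
  path
}

# A minimal single-reference transcript model tibble in transcript space.
toy_tx_model <- function(id = "tx", n_codons = 10, utr5 = 20, utr3 = 20,
                         cds_seq = NULL) {
  if (is.null(cds_seq)) {
    cds_seq <- paste(c("ATG", rep("GCT", n_codons - 1), "TAA"), collapse = "")
  }
  seq <- paste0(strrep("T", utr5), cds_seq, strrep("T", utr3))
  tibble::tibble(
    transcript_id = id, gene_id = id, chrom = id, strand = "+",
    exons = list(tibble::tibble(start = 1L, end = nchar(seq))),
    cds_start = utr5 + 1L, cds_end = utr5 + nchar(cds_seq), cds_ok = TRUE,
    sequence = seq
  )
}

make_reads <- function(ref, start, length = 21L, strand = "+", weight = 1) {
  n <- max(length(ref), length(start), length(length), length(strand))
  tibble::tibble(
    read_id = sprintf("r%04d", seq_len(n)),
    ref = rep_len(ref, n), start = as.integer(rep_len(start, n)),
    length = as.integer(rep_len(length, n)),
    strand = rep_len(strand, n), weight = rep_len(weight, n)
  )
}
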