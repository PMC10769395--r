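# in-code fixtures shared across test files

make_peaks <- function(chrom, start, end, summit_offset = NA_integer_,
                       name = sprintf("p%d", seq_along(start))) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             name = name, score = 0, strand = ".", signal = 1,
             pvalue_neglog10 = 2, qvalue_neglog10 = 1,
             summit_offset = as.integer(summit_offset),
             stringsAsFactors = FALSE)
}

make_genes <- function(chrom, start, end, strand,
                       gene_id = sprintf("g%d", seq_along(start))) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             gene_id = gene_id, score = 0, strand = strand,
             stringsAsFactors = FALSE)
}

make_genome <- function(...) {
  Biostrings::DNAStringSet(c(...))
}

# independent regex oracle for maximal motif runs (mirrors nothing in R/)
oracle_runs <- function(sequence, motif) {
  m <- gregexpr(paste0("(?:", motif, ")+"), sequence, perl = TRUE)[[1L]]
  if (m[1L] == -1L)
    return(data.frame(window_offset = integer(), n = integer()))
  data.frame(window_offset = as.integer(m) - 1L,
             n = as.integer(attr(m, "match.length")) %/% 4L)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

make_track <- function(x, y, quality = 150, frame = seq_along(x) - 1L,
                       track_id = "t1") {
  data.frame(track_id = track_id, frame = frame, x = x, y = y,
             quality = rep_len(quality, length(x)), stringsAsFactors = FALSE)
}
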