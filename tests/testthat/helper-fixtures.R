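# Small in-code fixture builders shared across test files.

toy_exons <- function(transcript_id = "t1", gene_id = "g1", gene_name = "G1",
                      biotype = "protein_coding", chrom = "chr1",
                      strand = "+", starts, ends) {
  ord <- if (strand == "-") order(-starts) else order(starts)
  tibble::tibble(
    transcript_id = transcript_id, gene_id = gene_id, gene_name = gene_name,
    biotype = biotype, source = "test", chrom = chrom, strand = strand,
    start = as.integer(starts[ord]), end = as.integer(ends[ord]),
    rank = seq_along(starts)
  )
}

# Random multi-exon transcript on a random genome chunk.
random_transcript <- function(id = "t1", chrom = "chr1", glen = 3000,
                              n_exons = NULL, strand = NULL) {
  strand <- strand %||% sample(c("+", "-"), 1)
  n_exons <- n_exons %||% sample(1:4, 1)
  bounds <- sort(sample(seq(0, glen - 1), 2 * n_exons))
  starts <- bounds[seq(1, length(bounds), 2)]
  ends <- bounds[seq(2, length(bounds), 2)]
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) { starts <- 0L; ends <- as.integer(glen %/% 2) }
  toy_exons(transcript_id = id, chrom = chrom, strand = strand,
            starts = starts, ends = ends)
}

`%||%` <- rlang::`%||%`

# nt string of n codons sampled from a fixed sense-codon pool (no stops)
sense_codons <- function(n) {
  pool <- c("GCC", "GTT", "TCC", "CCG", "CGT", "GGC", "TGC", "TGG", "TTC",
            "CTG")
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
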