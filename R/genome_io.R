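#' Read a genome FASTA into a named sequence set
#'
#' Sequences are uppercased and RNA `U` is converted to `T`. Record names are
#' truncated at the first whitespace. Only `A/C/G/T/N` are accepted.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per chromosome.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort(paste0("genome FASTA not found: ", path))
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) abort(paste0("empty FASTA: ", path))
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate FASTA record name: ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  x <- chartr("u", "U", toupper(as.character(seqs)))
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(paste0("non-ACGTN characters in record(s): ",
                 paste(nm[bad], collapse = ", ")))
  }
  setNames(x, nm)
}

# Chromosome-name matching tolerates a "chr" prefix mismatch between the
# annotation and the genome FASTA; the genome's spelling is canonical.
chrom_key <- function(x) sub("^chr", "", x)

match_chrom <- function(chrom, genome_names) {
  i <- match(chrom, genome_names)
  miss <- is.na(i)
  if (any(miss)) {
    i[miss] <- match(chrom_key(chrom[miss]), chrom_key(genome_names))
  }
  i
}

genome_seq <- function(genome, chrom) {
  i <- match_chrom(chrom, names(genome))
  if (anyNA(i)) {
    abort(paste0("chromosome absent from genome: ",
                 paste(unique(chrom[is.na(i)]), collapse = ", ")))
  }
  unname(genome[i])
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# ---- spliced transcript models ----------------------------------------------
# Transcripts are carried as an exon-level tibble ("exon table"): one row per
# exon with columns transcript_id, gene_id, gene_name, biotype, source, chrom,
# strand, start, end (0-based half-open genomic) and rank (1..n, 5'->3' in
# transcript orientation).

validate_exons <- function(exons) {
  need <- c("transcript_id", "chrom", "strand", "start", "end", "rank")
  missing <- setdiff(need, names(exons))
  if (length(missing)) {
    abort(paste0("exon table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(exons$end <= exons$start)) abort("exon with end <= start")
  invisible(exons)
}

#' Spliced transcript sequences
#'
#' Concatenates exon sequences in 5'->3' transcript order, reverse-
#' complementing minus-strand exons.
#'
#' @param exons Exon table (see [read_annotation()]).
#' @param genome Named sequence set from [read_genome()].
#' @return Tibble with `transcript_id`, `seq` and `width`.
#' @export
spliced_sequence <- function(exons, genome) {
  validate_exons(exons)
  ex <- arrange(exons, .data$transcript_id, .data$rank)
  chrseq <- genome_seq(genome, ex$chrom)
  clen <- nchar(chrseq)
  if (any(ex$start < 0L | ex$end > clen)) abort("exon outside chromosome bounds")
  part <- substr(chrseq, ex$start + 1L, ex$end)
  minus <- ex$strand == "-"
  if (any(minus)) part[minus] <- revcomp(part[minus])
  out <- tibble(transcript_id = ex$transcript_id, part = part) %>%
    group_by(.data$transcript_id) %>%
    summarise(seq = paste(.data$part, collapse = ""), .groups = "drop") %>%
    mutate(width = nchar(.data$seq))
  out
}

# Per-transcript frame of exon offsets: adds t_start (transcript offset of the
# exon's first base, 5'->3') and width.
exon_frame <- function(exons) {
  exons %>%
    arrange(.data$transcript_id, .data$rank) %>%
    group_by(.data$transcript_id) %>%
    mutate(width = .data$end - .data$start,
           t_start = cumsum(lag(.data$width, default = 0L))) %>%
    ungroup()
}

one_transcript <- function(exons, transcript_id) {
  if (!is.null(transcript_id)) {
    exons <- exons[exons$transcript_id == transcript_id, , drop = FALSE]
  }
  if (nrow(exons) == 0L) abort("transcript not found in exon table")
  if (length(unique(exons$transcript_id)) != 1L) {
    abort("exon table holds several transcripts; supply `transcript_id`")
  }
  exons
}

#' Map transcript offsets to genomic positions
#'
#' @param exons Exon table (one transcript, or pass `transcript_id`).
#' @param t_pos Integer vector of 0-based transcript offsets.
#' @param transcript_id Transcript to use when `exons` holds several.
#' @return Integer vector of 0-based genomic positions.
#' @export
map_to_genomic <- function(exons, t_pos, transcript_id = NULL) {
  ex <- exon_frame(one_transcript(exons, transcript_id))
  splen <- sum(ex$width)
  if (any(t_pos < 0L | t_pos >= splen)) {
    abort("transcript offset out of range [0, spliced length)")
  }
  idx <- findInterval(t_pos, ex$t_start)
  off <- t_pos - ex$t_start[idx]
  ifelse(ex$strand[idx] == "+",
         ex$start[idx] + off,
         ex$end[idx] - 1L - off)
}

#' Map genomic positions to transcript offsets
#'
#' @inheritParams map_to_genomic
#' @param g_pos Integer vector of 0-based genomic positions.
#' @param strict Error on positions outside exons (default); otherwise `NA`.
#' @return Integer vector of 0-based transcript offsets.
#' @export
map_to_transcript <- function(exons, g_pos, transcript_id = NULL, strict = TRUE) {
  ex <- exon_frame(one_transcript(exons, transcript_id))
  out <- rep(NA_integer_, length(g_pos))
  for (k in seq_len(nrow(ex))) {
    inside <- g_pos >= ex$start[k] & g_pos < ex$end[k]
    if (!any(inside)) next
    off <- if (ex$strand[k] == "+") g_pos[inside] - ex$start[k]
           else ex$end[k] - 1L - g_pos[inside]
    out[inside] <- as.integer(ex$t_start[k] + off)
  }
  if (strict && anyNA(out)) abort("genomic position outside transcript exons")
  out
}

# Genomic blocks covered by a transcript-coordinate span [t_start, t_end).
# Returns a tibble (chrom, start, end, strand) sorted by genomic start.
transcript_span_to_blocks <- function(exons, t_start, t_end, transcript_id = NULL) {
  ex <- exon_frame(one_transcript(exons, transcript_id))
  splen <- sum(ex$width)
  if (t_start < 0L || t_end > splen || t_end <= t_start) {
    abort("invalid transcript span")
  }
  lo <- pmax(t_start, ex$t_start)
  hi <- pmin(t_end, ex$t_start + ex$width)
  keep <- hi > lo
  ex <- ex[keep, , drop = FALSE]
  lo <- lo[keep]; hi <- hi[keep]
  gs <- ifelse(ex$strand == "+", ex$start + (lo - ex$t_start),
               ex$end - (hi - ex$t_start))
  ge <- gs + (hi - lo)
  tibble(chrom = ex$chrom, start = as.integer(gs), end = as.integer(ge),
         strand = ex$strand) %>%
    arrange(.data$start)
}
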