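#' Translate a coding nucleotide sequence
#'
#' Standard genetic code. A trailing stop codon is dropped; an internal stop
#' or a non-ACGT character is an error.
#'
#' @param nt Character vector of nucleotide sequences, each of length
#'   divisible by 3.
#' @return Character vector of amino-acid sequences.
#' @export
translate_cds <- function(nt) {
  if (!length(nt)) return(character(0))
  if (any(nchar(nt) %% 3L != 0L)) abort("sequence length not divisible by 3")
  if (any(grepl("[^ACGT]", nt))) abort("non-ACGT character in coding sequence")
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                           no.init.codon = TRUE))
  aa <- sub("\\*$", "", aa)
  if (any(grepl("*", aa, fixed = TRUE))) abort("internal stop codon")
  aa
}

locate_all <- function(seq, pattern) {
  m <- stringr::str_locate_all(seq, stringr::fixed(pattern))[[1]]
  if (nrow(m) == 0L) integer(0) else m[, 1L]
}

#' Find ORFs in one spliced sequence
#'
#' Scans all three reading frames 5'->3'. An ORF runs from a start codon to
#' the first in-frame stop codon; the stop is required and is counted in
#' `codon_count`. Within one frame and one stop, only the most 5' start is
#' reported unless `all_starts = TRUE`. A codon containing `N` aborts the ORF
#' it would belong to. ORFs shorter than `min_codons` codons (stop included)
#' are dropped; there is no upper bound, and RNA biotype is never consulted.
#'
#' @param seq Nucleotide string (spliced transcript sequence).
#' @param min_codons Minimum ORF size in codons, stop codon included
#'   (default 30, i.e. proteins of at least 29 residues).
#' @param start_codons Start codon set (default `"ATG"`).
#' @param all_starts Report nested in-frame starts as separate ORFs.
#' @return Tibble with `frame`, `t_start`, `t_end` (0-based half-open
#'   transcript offsets spanning start codon through stop codon) and
#'   `codon_count`.
#' @export
find_orfs <- function(seq, min_codons = 30L, start_codons = "ATG",
                      all_starts = FALSE) {
  stopifnot(length(seq) == 1L, min_codons >= 2L)
  starts <- sort(unique(unlist(lapply(start_codons, locate_all, seq = seq))))
  stops <- sort(unique(unlist(lapply(STOP_CODONS, locate_all, seq = seq))))
  npos <- locate_all(seq, "N")
  res <- vector("list", 3L)
  for (f in 0:2) {
    sf <- starts[(starts - 1L) %% 3L == f]
    tf <- stops[(stops - 1L) %% 3L == f]
    if (!length(sf) || !length(tf)) next
    hits_s <- integer(0); hits_p <- integer(0)
    prev_bound <- 1L
    for (p in tf) {
      if (length(npos)) {
        nbefore <- npos[npos < p]
        lo <- if (length(nbefore)) max(prev_bound, max(nbefore) + 1L) else prev_bound
      } else lo <- prev_bound
      cand <- sf[sf >= lo & sf <= p - 3L]
      if (length(cand)) {
        use <- if (all_starts) cand else cand[1L]
        hits_s <- c(hits_s, use)
        hits_p <- c(hits_p, rep(p, length(use)))
      }
      prev_bound <- p + 3L
    }
    if (length(hits_s)) {
      res[[f + 1L]] <- tibble(
        frame = f,
        t_start = hits_s - 1L,
        t_end = hits_p + 2L,
        codon_count = (hits_p + 3L - hits_s) %/% 3L
      )
    }
  }
  out <- bind_rows(res)
  if (nrow(out) == 0L) {
    return(tibble(frame = integer(0), t_start = integer(0),
                  t_end = integer(0), codon_count = integer(0)))
  }
  out %>%
    filter(.data$codon_count >= min_codons) %>%
    arrange(.data$t_start, .data$t_end)
}

#' Predict ORFs on every transcript
#'
#' Runs [find_orfs()] on the spliced sequence of each transcript, translates
#' each ORF and attaches its genomic blocks.
#'
#' @param exons Exon table from [read_annotation()].
#' @param genome Named sequence set from [read_genome()].
#' @inheritParams find_orfs
#' @return ORF table: one row per ORF with `orf_id`, transcript/gene columns,
#'   `frame`, `t_start`, `t_end`, `codon_count`, `protein`, list-column
#'   `blocks` (tibbles of chrom/start/end/strand) plus `chrom`, `strand`,
#'   `g_start` (genomic start of the first block).
#' @export
predict_orfs <- function(exons, genome, min_codons = 30L, start_codons = "ATG",
                         all_starts = FALSE) {
  validate_exons(exons)
  seqs <- spliced_sequence(exons, genome)
  meta <- exons %>%
    distinct(.data$transcript_id, .data$gene_id, .data$gene_name,
             .data$biotype, .data$chrom, .data$strand)
  ids <- seqs$transcript_id
  per_tx <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    tx <- ids[i]
    hits <- find_orfs(seqs$seq[i], min_codons = min_codons,
                      start_codons = start_codons, all_starts = all_starts)
    if (nrow(hits) == 0L) next
    ex_tx <- exons[exons$transcript_id == tx, , drop = FALSE]
    hits$transcript_id <- tx
    hits$protein <- translate_cds(substr(rep(seqs$seq[i], nrow(hits)),
                                         hits$t_start + 1L, hits$t_end - 3L))
    hits$blocks <- lapply(seq_len(nrow(hits)), function(k) {
      transcript_span_to_blocks(ex_tx, hits$t_start[k], hits$t_end[k])
    })
    per_tx[[i]] <- hits
  }
  out <- bind_rows(per_tx)
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble(orf_id = character(0), transcript_id = character(0),
                  gene_id = character(0), gene_name = character(0),
                  biotype = character(0), chrom = character(0),
                  strand = character(0), frame = integer(0),
                  t_start = integer(0), t_end = integer(0),
                  codon_count = integer(0), protein = character(0),
                  blocks = list(), g_start = integer(0)))
  }
  out %>%
    left_join(meta, by = "transcript_id") %>%
    mutate(g_start = vapply(.data$blocks, function(b) min(b$start), integer(1)),
           orf_id = paste0(.data$transcript_id, ":", .data$t_start, "-",
                           .data$t_end)) %>%
    select("orf_id", "transcript_id", "gene_id", "gene_name", "biotype",
           "chrom", "strand", "frame", "t_start", "t_end", "codon_count",
           "protein", "blocks", "g_start") %>%
    arrange(.data$chrom, .data$g_start, .data$transcript_id, .data$t_start)
}

#' Deduplicate ORFs into protein records
#'
#' One record per distinct amino-acid sequence, with every encoding ORF,
#' transcript and gene attached. Records are ordered by the first genomic
#' block, then sequence, so downstream accession minting is deterministic.
#' Proteins encoded at more than one gene are flagged `multi_locus`.
#'
#' @param orfs ORF table from [predict_orfs()].
#' @return Protein table: `sequence`, `length`, list-columns `orf_ids`,
#'   `transcripts`, `genes`, `gene_names`, plus `chrom`, `g_start`,
#'   `n_orfs`, `multi_locus`.
#' @export
collapse_proteins <- function(orfs) {
  if (nrow(orfs) == 0L) {
    return(tibble(sequence = character(0), length = integer(0),
                  orf_ids = list(), transcripts = list(), genes = list(),
                  gene_names = list(), chrom = character(0),
                  g_start = integer(0), n_orfs = integer(0),
                  multi_locus = logical(0)))
  }
  orfs %>%
    arrange(.data$chrom, .data$g_start, .data$orf_id) %>%
    group_by(.data$protein) %>%
    summarise(
      orf_ids = list(unique(.data$orf_id)),
      transcripts = list(sort(unique(.data$transcript_id))),
      genes = list(sort(unique(.data$gene_id))),
      gene_names = list(sort(unique(.data$gene_name))),
      chrom = first(.data$chrom),
      g_start = first(.data$g_start),
      n_orfs = n(),
      .groups = "drop"
    ) %>%
    rename(sequence = "protein") %>%
    mutate(length = nchar(.data$sequence),
           multi_locus = vapply(.data$genes, function(g) length(g) > 1L,
                                logical(1))) %>%
    arrange(.data$chrom, .data$g_start, .data$sequence) %>%
    select("sequence", "length", "orf_ids", "transcripts", "genes",
           "gene_names", "chrom", "g_start", "n_orfs", "multi_locus")
}
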