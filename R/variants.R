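IMPACT_OF <- c(
  synonymous = "low",
  missense = "moderate",
  inframe_insertion = "moderate",
  inframe_deletion = "moderate",
  stop_gained = "high",
  stop_lost = "high",
  start_lost = "high",
  frameshift = "high",
  non_orf = "modifier"
)

IMPACT_LEVELS <- c("modifier", "low", "moderate", "high")

#' Read genomic variants from a VCF file
#'
#' Multi-allelic lines are split into one record per alternate allele. When a
#' genome is supplied, the reference allele is checked against it and a
#' mismatch is an error naming the position.
#'
#' @param path VCF 4.x file.
#' @param genome Optional named sequence set from [read_genome()].
#' @return Tibble with `variant_id`, `chrom`, `pos` (1-based, as printed),
#'   `start` (0-based), `ref`, `alt`.
#' @export
read_vcf <- function(path, genome = NULL) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(tibble(variant_id = character(0), chrom = character(0),
                  pos = integer(0), start = integer(0),
                  ref = character(0), alt = character(0)))
  }
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n <- lengths(alts)
  out <- tibble(
    chrom = rep(fix$CHROM, n),
    pos = rep(as.integer(fix$POS), n),
    id = rep(fix$ID, n),
    ref = toupper(rep(fix$REF, n)),
    alt = toupper(unlist(alts))
  ) %>%
    mutate(start = .data$pos - 1L,
           variant_id = if_else(is.na(.data$id) | .data$id == ".",
                                paste0(.data$chrom, ":", .data$pos, ":",
                                       .data$ref, ">", .data$alt),
                                .data$id)) %>%
    select("variant_id", "chrom", "pos", "start", "ref", "alt")
  if (!is.null(genome)) {
    g <- genome_seq(genome, out$chrom)
    obs <- substr(g, out$start + 1L, out$start + nchar(out$ref))
    bad <- obs != out$ref
    if (any(bad)) {
      i <- which(bad)[1]
      abort(paste0("REF mismatch at ", out$chrom[i], ":", out$pos[i],
                   " (VCF ", out$ref[i], ", genome ", obs[i], ")"))
    }
  }
  out
}

#' Left-normalize variants against the genome
#'
#' Trims shared suffix/prefix bases and left-shifts pure insertions and
#' deletions through repeat tracts, the usual normalization before
#' consequence annotation.
#'
#' @param variants Tibble from [read_vcf()].
#' @param genome Named sequence set.
#' @return Normalized variant tibble (same columns).
#' @export
normalize_variants <- function(variants, genome) {
  n <- nrow(variants)
  ref <- variants$ref; alt <- variants$alt; pos <- variants$pos
  for (i in seq_len(n)) {
    g <- genome_seq(genome, variants$chrom[i])
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    repeat {
      lr <- nchar(r); la <- nchar(a)
      if (lr > 0 && la > 0 &&
          substr(r, lr, lr) == substr(a, la, la) &&
          (lr > 1 || la > 1)) {
        if (lr == 1 || la == 1) {
          if (p <= 1) break  # cannot extend left past the chromosome start
          b <- substr(g, p - 1, p - 1)
          r <- paste0(b, substr(r, 1, lr - 1))
          a <- paste0(b, substr(a, 1, la - 1))
          p <- p - 1L
        } else {
          r <- substr(r, 1, lr - 1)
          a <- substr(a, 1, la - 1)
        }
      } else break
    }
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r)); a <- substr(a, 2, nchar(a)); p <- p + 1L
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  variants$ref <- ref
  variants$alt <- alt
  variants$pos <- as.integer(pos)
  variants$start <- variants$pos - 1L
  variants
}

# Transcript-space footprint of a variant on one transcript.
# Returns list(status, t_lo, t_hi, alt_t): status is "exonic", "intronic" or
# "boundary". t_lo..t_hi are 0-based inclusive transcript offsets of the REF
# span; alt_t is the alternate allele in transcript orientation.
variant_t_span <- function(ex_tx, v_start, ref, alt) {
  len <- nchar(ref)
  gpos <- v_start + seq_len(len) - 1L
  tpos <- suppressWarnings(
    map_to_transcript(ex_tx, gpos, strict = FALSE)
  )
  if (all(is.na(tpos))) return(list(status = "intronic"))
  if (anyNA(tpos)) return(list(status = "boundary"))
  t_lo <- min(tpos); t_hi <- max(tpos)
  if (t_hi - t_lo != len - 1L || anyDuplicated(tpos)) {
    return(list(status = "boundary"))
  }
  minus <- ex_tx$strand[1] == "-"
  alt_t <- if (minus && nchar(alt)) revcomp(alt) else alt
  list(status = "exonic", t_lo = t_lo, t_hi = t_hi, alt_t = alt_t)
}

# Walk codons of `seq` from 0-based offset start0 to the first stop.
translate_to_stop <- function(seq, start0) {
  n <- nchar(seq)
  aas <- character(0)
  pos <- start0
  while (pos + 3L <= n) {
    cod <- substr(seq, pos + 1L, pos + 3L)
    if (cod %in% STOP_CODONS) {
      return(list(protein = paste(aas, collapse = ""), has_stop = TRUE,
                  stop_at = pos))
    }
    aa <- if (grepl("N", cod, fixed = TRUE)) "X"
          else unname(Biostrings::GENETIC_CODE[cod])
    aas <- c(aas, aa)
    pos <- pos + 3L
  }
  list(protein = paste(aas, collapse = ""), has_stop = FALSE, stop_at = NA_integer_)
}

# Consequence of one exonic edit for one ORF, in transcript space.
consequence_for_orf <- function(txseq, t_start, t_end, ref_protein,
                                span, start_codons = "ATG") {
  t_lo <- span$t_lo; t_hi <- span$t_hi; alt_t <- span$alt_t
  if (!(t_lo < t_end && t_hi >= t_start)) {
    return(list(consequence = "non_orf", note = NA_character_,
                protein_alt = NA_character_))
  }
  mut <- paste0(substr(txseq, 1L, t_lo), alt_t,
                substr(txseq, t_hi + 2L, nchar(txseq)))
  delta <- nchar(alt_t) - (t_hi - t_lo + 1L)
  note <- NA_character_
  # start codon: positions [t_start, t_start + 3) are untouched unless the
  # edit begins at or before t_start + 2
  if (t_lo <= t_start + 2L) {
    sc <- substr(mut, t_start + 1L, t_start + 3L)
    if (!(sc %in% start_codons)) {
      return(list(consequence = "start_lost", note = note,
                  protein_alt = NA_character_))
    }
  }
  tr <- translate_to_stop(mut, t_start)
  if (delta %% 3L != 0L) {
    return(list(consequence = "frameshift", note = note,
                protein_alt = tr$protein))
  }
  if (delta != 0L) {
    return(list(consequence = if (delta > 0L) "inframe_insertion"
                              else "inframe_deletion",
                note = note, protein_alt = tr$protein))
  }
  ref_stop_at <- t_end - 3L
  if (!tr$has_stop) {
    return(list(consequence = "stop_lost", note = "no_new_stop",
                protein_alt = tr$protein))
  }
  if (tr$stop_at < ref_stop_at) {
    return(list(consequence = "stop_gained", note = note,
                protein_alt = tr$protein))
  }
  if (tr$stop_at > ref_stop_at) {
    return(list(consequence = "stop_lost", note = note,
                protein_alt = tr$protein))
  }
  if (identical(tr$protein, ref_protein)) {
    list(consequence = "synonymous", note = note, protein_alt = tr$protein)
  } else {
    list(consequence = "missense", note = note, protein_alt = tr$protein)
  }
}

#' Annotate variants across all ORFs of overlapping transcripts
#'
#' Each variant yields one independent call per ORF of every transcript whose
#' span it overlaps; a variant synonymous in one ORF may be missense in a
#' frame-overlapping ORF and both calls are reported. The edit is applied to
#' the spliced transcript sequence and the ORF re-translated from its start;
#' a variant outside an ORF's genomic blocks (or intronic, or spanning an
#' exon-intron boundary - splice modeling is out of scope) is `non_orf`.
#' Impact classes: synonymous is `low`; missense and in-frame indels are
#' `moderate`; stop gained/lost, start lost and frameshift are `high`;
#' `non_orf` is `modifier`.
#'
#' @param variants Tibble from [read_vcf()] (ideally normalized).
#' @param orfs ORF table from [predict_orfs()].
#' @param exons Exon table.
#' @param genome Named sequence set.
#' @param proteins Optional accessioned protein table; attaches `accession`
#'   and `class` to each call.
#' @param start_codons Start codon set used for start-loss checks.
#' @return Consequence table with one row per (variant, ORF), class
#'   `"orf_consequences"`.
#' @export
annotate_variants <- function(variants, orfs, exons, genome, proteins = NULL,
                              start_codons = "ATG") {
  seqs <- spliced_sequence(exons, genome)
  txseq <- setNames(seqs$seq, seqs$transcript_id)
  tx_span <- exons %>%
    group_by(.data$transcript_id, .data$chrom) %>%
    summarise(lo = min(.data$start), hi = max(.data$end), .groups = "drop")
  acc_map <- NULL
  if (!is.null(proteins)) {
    acc_map <- tibble(
      orf_id = unlist(proteins$orf_ids),
      accession = rep(proteins$accession, lengths(proteins$orf_ids)),
      class = rep(proteins$class, lengths(proteins$orf_ids))
    )
  }
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    reflen <- nchar(v$ref)
    tx_hit <- tx_span$transcript_id[tx_span$chrom == v$chrom &
                                      tx_span$lo < v$start + reflen &
                                      tx_span$hi > v$start]
    for (tx in tx_hit) {
      ex_tx <- exons[exons$transcript_id == tx, , drop = FALSE]
      span <- variant_t_span(ex_tx, v$start, v$ref, v$alt)
      orfs_tx <- orfs[orfs$transcript_id == tx, , drop = FALSE]
      if (nrow(orfs_tx) == 0L) next
      for (k in seq_len(nrow(orfs_tx))) {
        o <- orfs_tx[k, ]
        if (span$status != "exonic") {
          cq <- list(consequence = "non_orf",
                     note = if (span$status == "boundary") "exon_boundary"
                            else "intronic",
                     protein_alt = NA_character_)
        } else {
          cq <- consequence_for_orf(txseq[[tx]], o$t_start, o$t_end,
                                    o$protein, span, start_codons)
        }
        rows[[length(rows) + 1L]] <- tibble(
          variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
          ref = v$ref, alt = v$alt, transcript_id = tx, orf_id = o$orf_id,
          consequence = cq$consequence,
          impact = unname(IMPACT_OF[cq$consequence]),
          note = cq$note, protein_ref = o$protein,
          protein_alt = cq$protein_alt
        )
      }
    }
  }
  out <- bind_rows(rows)
  if (is.null(out) || nrow(out) == 0L) {
    out <- tibble(variant_id = character(0), chrom = character(0),
                  pos = integer(0), ref = character(0), alt = character(0),
                  transcript_id = character(0), orf_id = character(0),
                  consequence = character(0), impact = character(0),
                  note = character(0), protein_ref = character(0),
                  protein_alt = character(0))
  }
  if (!is.null(acc_map)) {
    out <- left_join(out, acc_map, by = "orf_id")
  }
  class(out) <- unique(c("orf_consequences", class(out)))
  out
}

#' Summarize variant impacts
#'
#' Worst impact per variant under the ordering
#' high > moderate > low > modifier, and a tally of calls per impact split by
#' protein class when classes are present.
#'
#' @param calls Consequence table from [annotate_variants()].
#' @return List with `per_variant` (tibble `variant_id`, `worst_impact`) and
#'   `tally` (tibble `class`, `impact`, `n`; `class` absent when unknown).
#' @export
summarize_impacts <- function(calls) {
  lev <- factor(calls$impact, levels = IMPACT_LEVELS, ordered = TRUE)
  per_variant <- tibble(variant_id = calls$variant_id, impact = lev) %>%
    group_by(.data$variant_id) %>%
    summarise(worst_impact = as.character(max(.data$impact)), .groups = "drop")
  if ("class" %in% names(calls)) {
    tally <- calls %>%
      filter(!is.na(.data$class)) %>%
      count(.data$class, .data$impact, name = "n")
  } else {
    tally <- calls %>% count(.data$impact, name = "n")
  }
  list(per_variant = per_variant, tally = tally)
}
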