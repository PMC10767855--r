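#' Write ORFs as BED12
#'
#' One line per ORF; blocks are the genomic exon-intersected ORF segments
#' (0-based half-open), thickStart/thickEnd span the whole ORF, and block
#' sizes always sum to 3x the codon count.
#'
#' @param orfs ORF table from [predict_orfs()].
#' @param path Output BED path.
#' @param names Line names (default `orf_id`).
#' @return `path`, invisibly.
#' @export
write_orf_bed <- function(orfs, path, names = orfs$orf_id) {
  lines <- character(nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    b <- orfs$blocks[[i]]
    b <- b[order(b$start), , drop = FALSE]
    cs <- min(b$start); ce <- max(b$end)
    lines[i] <- paste(
      b$chrom[1], cs, ce, names[i], 0L, b$strand[1], cs, ce, "0,0,0",
      nrow(b),
      paste0(paste(b$end - b$start, collapse = ","), ","),
      paste0(paste(b$start - cs, collapse = ","), ","),
      sep = "\t"
    )
  }
  writeLines(lines, path)
  invisible(path)
}

fasta_wrap <- function(x, width = 60L) {
  vapply(x, function(s) {
    n <- nchar(s)
    paste(substring(s, seq(1L, n, width), pmin(seq(1L, n, width) + width - 1L, n)),
          collapse = "\n")
  }, character(1), USE.NAMES = FALSE)
}

#' Write predicted proteins to FASTA
#'
#' Headers carry the accession, class, gene name(s) and encoding transcripts:
#' `>ACC class GN=GENE TA=tx1,tx2`.
#'
#' @param proteins Accessioned protein table.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  hdr <- paste0(
    proteins$accession, " ", proteins$class,
    " GN=", vapply(proteins$gene_names, paste, character(1), collapse = ","),
    " TA=", vapply(proteins$transcripts, paste, character(1), collapse = ",")
  )
  writeLines(paste0(">", hdr, "\n", fasta_wrap(proteins$sequence)), path)
  invisible(path)
}

#' Write the protein annotation table to TSV
#'
#' One row per protein: accession, class, genes, transcripts, protein length,
#' ORF count, best reference hit and (when supplied) evidence columns.
#' Header comment lines record provenance.
#'
#' @param proteins Accessioned protein table.
#' @param path Output TSV path.
#' @param evidence Optional evidence table from [summarize_evidence()].
#' @param meta Optional named character vector written as `# key=value`
#'   comment lines.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(proteins, path, evidence = NULL, meta = NULL) {
  tab <- tibble(
    accession = proteins$accession,
    class = proteins$class,
    genes = vapply(proteins$gene_names, paste, character(1), collapse = ","),
    transcripts = vapply(proteins$transcripts, paste, character(1),
                         collapse = ","),
    protein_length = proteins$length,
    codon_count = proteins$length + 1L,
    n_orfs = proteins$n_orfs,
    multi_locus = proteins$multi_locus,
    best_ref_hit = proteins$best_ref_hit,
    identity = proteins$identity,
    coverage = proteins$coverage
  )
  if (!is.null(evidence)) {
    tab <- left_join(tab,
                     select(as_tibble(evidence), "accession",
                            "unique_peptides", "riboseq_detections",
                            "detected"),
                     by = "accession")
  }
  write_tsv_with_meta(tab, path, meta)
  invisible(path)
}

# TSV writer with "# key=value" provenance comment lines.
write_tsv_with_meta <- function(tab, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(paste0("# ", names(meta), "=", unname(meta)), con)
  }
  writeLines(readr::format_tsv(tab), con, sep = "")
  invisible(path)
}
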