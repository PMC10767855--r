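#' Target-decoy FDR filtering of peptide-spectrum matches
#'
#' PSMs are ranked by score (higher is better). At every score threshold the
#' FDR among accepted PSMs is `#decoys / #targets`; the most permissive
#' threshold with FDR strictly below `fdr_max` is used and its accepted
#' target PSMs returned. Decoys are never returned. The default reproduces a
#' "FDR < 0.01%" selection (fraction 0.0001) at the PSM level.
#'
#' @param psms Tibble with columns `peptide`, `score`, `is_decoy` (and any
#'   others, preserved).
#' @param fdr_max Maximum false-discovery rate, as a fraction.
#' @return Accepted target PSMs.
#' @export
fdr_filter <- function(psms, fdr_max = 0.0001) {
  stopifnot(all(c("peptide", "score", "is_decoy") %in% names(psms)),
            fdr_max >= 0)
  if (any(!nzchar(psms$peptide))) abort("empty peptide sequence")
  if (nrow(psms) == 0L) return(psms)
  ord <- order(psms$score, decreasing = TRUE)
  x <- psms[ord, , drop = FALSE]
  cum_t <- cumsum(!x$is_decoy)
  cum_d <- cumsum(x$is_decoy)
  # candidate cutoffs: accept everything with score >= s for each distinct s,
  # i.e. the last index of each tied score run
  last_of_run <- which(c(x$score[-1] != x$score[-nrow(x)], TRUE))
  fdr <- ifelse(cum_t[last_of_run] == 0L, Inf,
                cum_d[last_of_run] / cum_t[last_of_run])
  ok <- which(fdr < fdr_max)
  if (!length(ok)) return(x[0, , drop = FALSE])
  best <- last_of_run[ok[which.max(cum_t[last_of_run][ok])]]
  acc <- x[seq_len(best), , drop = FALSE]
  acc[!acc$is_decoy, , drop = FALSE]
}

collapse_il <- function(x) gsub("L", "I", x, fixed = TRUE)

#' Map peptides to proteins with a uniqueness rule
#'
#' A peptide supports a predicted protein only when it occurs as a substring
#' of exactly one predicted protein sequence. For alternative proteins and
#' novel isoforms it must additionally be absent from every reference
#' proteome sequence (uniqueness checked against the reference databases).
#' Isoleucine and leucine are treated as equivalent by default, as the two
#' residues are isobaric in mass spectrometry.
#'
#' @param peptides Character vector of peptide sequences (e.g. accepted PSM
#'   peptides after [fdr_filter()]); duplicates count once.
#' @param proteins Accessioned protein table ([mint_accessions()]).
#' @param reference Tibble from [read_reference_proteome()].
#' @param il_equivalent Treat I and L as indistinguishable (default TRUE).
#' @return Tibble with `accession` and `unique_peptides` for every protein.
#' @export
map_peptides <- function(peptides, proteins, reference, il_equivalent = TRUE) {
  peptides <- unique(peptides)
  xf <- if (il_equivalent) collapse_il else identity
  pep <- xf(peptides)
  pseq <- xf(proteins$sequence)
  rseq <- xf(reference$sequence)
  counts <- integer(nrow(proteins))
  for (k in seq_along(pep)) {
    hits <- which(stringr::str_detect(pseq, stringr::fixed(pep[k])))
    if (length(hits) != 1L) next
    if (proteins$class[hits] != "refprot" &&
        any(stringr::str_detect(rseq, stringr::fixed(pep[k])))) next
    counts[hits] <- counts[hits] + 1L
  }
  tibble(accession = proteins$accession, unique_peptides = counts)
}

#' Detection call from unique peptides and ribo-seq detections
#'
#' A protein is called detected with at least 2 unique peptides, or with
#' 1 unique peptide plus at least one ribo-seq detection.
#'
#' @param unique_peptides,riboseq_detections Non-negative integer vectors.
#' @return Logical vector.
#' @export
evidence_call <- function(unique_peptides, riboseq_detections) {
  if (any(unique_peptides < 0) || any(riboseq_detections < 0)) {
    abort("evidence counts must be non-negative")
  }
  unique_peptides >= 2L |
    (unique_peptides >= 1L & riboseq_detections >= 1L)
}

#' Per-protein evidence summary
#'
#' @param proteins Accessioned protein table.
#' @param peptide_counts Tibble `accession`, `unique_peptides`
#'   (from [map_peptides()]).
#' @param ribo Tibble `accession`, `riboseq_detections`; missing accessions
#'   count as zero.
#' @return Tibble with `accession`, `class`, `unique_peptides`,
#'   `riboseq_detections`, `detected`, carrying class `"orf_evidence"`.
#' @export
summarize_evidence <- function(proteins, peptide_counts, ribo = NULL) {
  out <- tibble(accession = proteins$accession, class = proteins$class) %>%
    left_join(peptide_counts, by = "accession")
  out$unique_peptides[is.na(out$unique_peptides)] <- 0L
  if (!is.null(ribo) && nrow(ribo)) {
    out <- left_join(out, ribo, by = "accession")
  } else {
    out$riboseq_detections <- 0L
  }
  out$riboseq_detections[is.na(out$riboseq_detections)] <- 0L
  out$detected <- evidence_call(out$unique_peptides, out$riboseq_detections)
  class(out) <- unique(c("orf_evidence", class(out)))
  out
}

#' Flag multi-coding transcripts
#'
#' A transcript is multi-coding when at least two of its proteins meet the
#' detection evidence level.
#'
#' @param proteins Accessioned protein table (carries the
#'   protein-to-transcript associations).
#' @param evidence Tibble from [summarize_evidence()].
#' @return Tibble with `transcript_id`, list-column `coding_proteins`
#'   (detected accessions) and `is_multicoding`.
#' @export
flag_multicoding <- function(proteins, evidence) {
  det <- evidence$accession[evidence$detected]
  assoc <- tibble(accession = rep(proteins$accession,
                                  lengths(proteins$transcripts)),
                  transcript_id = unlist(proteins$transcripts))
  assoc %>%
    group_by(.data$transcript_id) %>%
    summarise(coding_proteins = list(sort(intersect(.data$accession, det))),
              .groups = "drop") %>%
    mutate(is_multicoding = lengths(.data$coding_proteins) >= 2L)
}
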