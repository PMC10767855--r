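#' Read a reference proteome FASTA
#'
#' Headers are expected to carry the accession as the first token and,
#' optionally, a `GN=` gene token (`>ACC description GN=GENE`).
#'
#' @param path FASTA of reference protein sequences. Several paths may be
#'   given; the union is returned (reference proteins can be annotated in
#'   more than one source database).
#' @return Tibble with `ref_accession`, `gene`, `sequence`.
#' @export
read_reference_proteome <- function(path) {
  parts <- lapply(path, function(p) {
    if (!file.exists(p)) abort(paste0("reference proteome not found: ", p))
    seqs <- Biostrings::readAAStringSet(p)
    hdr <- names(seqs)
    gn <- stringr::str_match(hdr, "GN=([^ ]+)")[, 2L]
    tibble(ref_accession = sub("\\s.*$", "", hdr),
           gene = gn,
           sequence = unname(as.character(seqs)))
  })
  out <- bind_rows(parts) %>% distinct(.data$ref_accession, .keep_all = TRUE)
  if (anyDuplicated(out$ref_accession)) abort("duplicate reference accessions")
  out
}

#' Local alignment identity and coverage
#'
#' Smith-Waterman local alignment (BLOSUM62, gap open 11 / extend 1).
#' Identity is the fraction of identical positions over the alignment length
#' (gaps included); coverage is the aligned width of the shorter sequence
#' over its full length.
#'
#' @param query,subject Amino-acid strings.
#' @return Tibble with `score`, `identity`, `coverage`.
#' @export
align_similarity <- function(query, subject) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1
  )
  alen <- Biostrings::nchar(al)
  ident <- if (alen > 0) Biostrings::nmatch(al) / alen else 0
  wq <- Biostrings::width(Biostrings::pattern(al))
  ws <- Biostrings::width(Biostrings::subject(al))
  cov <- if (nchar(query) <= nchar(subject)) wq / nchar(query) else ws / nchar(subject)
  tibble(score = Biostrings::score(al), identity = ident, coverage = cov)
}

#' Classify predicted proteins against a reference proteome
#'
#' A protein identical to any reference entry is a reference protein
#' (`refprot`; its source accession is retained, with a cross-locus note if
#' no gene is shared). Otherwise it is aligned against every reference
#' protein of its own gene(s): a best hit with identity >= `id_threshold`
#' over an aligned region covering >= `cov_threshold` of the shorter sequence
#' makes it a novel isoform; anything else is an alternative protein.
#' Similarity thresholds are explicit, tunable conventions.
#'
#' @param proteins Protein table from [collapse_proteins()].
#' @param reference Tibble from [read_reference_proteome()].
#' @param id_threshold Minimum identity for a novel isoform (default 0.80).
#' @param cov_threshold Minimum coverage of the shorter sequence (default 0.50).
#' @return `proteins` with columns `class` (`refprot`/`novel_isoform`/
#'   `altprot`), `best_ref_hit`, `identity`, `coverage`, `note` added,
#'   carrying class `"orf_proteins"`.
#' @export
classify_proteins <- function(proteins, reference, id_threshold = 0.80,
                              cov_threshold = 0.50) {
  n <- nrow(proteins)
  cls <- character(n); hit <- rep(NA_character_, n)
  ident <- rep(NA_real_, n); cov <- rep(NA_real_, n)
  note <- rep(NA_character_, n)
  exact <- match(proteins$sequence, reference$sequence)
  for (i in seq_len(n)) {
    own_genes <- union(proteins$genes[[i]], proteins$gene_names[[i]])
    if (!is.na(exact[i])) {
      cand <- which(reference$sequence == proteins$sequence[i])
      shared <- cand[reference$gene[cand] %in% own_genes]
      j <- if (length(shared)) shared[1L] else cand[1L]
      cls[i] <- "refprot"
      hit[i] <- reference$ref_accession[j]
      ident[i] <- 1; cov[i] <- 1
      if (!length(shared)) note[i] <- "cross_locus_exact_match"
      next
    }
    cand <- which(reference$gene %in% own_genes)
    best <- NULL
    for (j in cand) {
      st <- align_similarity(proteins$sequence[i], reference$sequence[j])
      if (is.null(best) || st$score > best$st$score) best <- list(j = j, st = st)
    }
    if (!is.null(best) &&
        best$st$identity >= id_threshold && best$st$coverage >= cov_threshold) {
      cls[i] <- "novel_isoform"
      hit[i] <- reference$ref_accession[best$j]
      ident[i] <- best$st$identity
      cov[i] <- best$st$coverage
    } else {
      cls[i] <- "altprot"
      if (!is.null(best)) {
        hit[i] <- reference$ref_accession[best$j]
        ident[i] <- best$st$identity
        cov[i] <- best$st$coverage
      }
    }
  }
  out <- proteins
  out$class <- cls
  out$best_ref_hit <- hit
  out$identity <- ident
  out$coverage <- cov
  out$note <- note
  class(out) <- unique(c("orf_proteins", class(out)))
  out
}

#' Mint stable accessions
#'
#' Novel isoforms get `II_` and alternative proteins `IP_` accessions,
#' numbered in deterministic genomic order (chromosome, first genomic block,
#' then sequence); reference proteins keep their source accession. The same
#' input yields the same accessions regardless of row order.
#'
#' @param classified Output of [classify_proteins()].
#' @return Same table with an `accession` column, re-sorted genomically.
#' @export
mint_accessions <- function(classified) {
  out <- classified %>% arrange(.data$chrom, .data$g_start, .data$sequence)
  acc <- rep(NA_character_, nrow(out))
  is_ii <- out$class == "novel_isoform"
  is_ip <- out$class == "altprot"
  acc[is_ii] <- sprintf("II_%06d", seq_len(sum(is_ii)))
  acc[is_ip] <- sprintf("IP_%06d", seq_len(sum(is_ip)))
  acc[out$class == "refprot"] <- out$best_ref_hit[out$class == "refprot"]
  out$accession <- acc
  class(out) <- unique(c("orf_proteins", class(out)))
  out
}

#' Reclassify against a newer reference proteome
#'
#' Proteins whose sequence now matches the new reference become reference
#' proteins; the report counts transitions per original class (predicted
#' proteins entering standard databases).
#'
#' @param classified Accessioned protein table ([mint_accessions()]).
#' @param new_reference Tibble from [read_reference_proteome()].
#' @return List with `proteins` (updated table) and `report`
#'   (tibble of `transition`, `n`).
#' @export
promote_to_reference <- function(classified, new_reference) {
  idx <- match(classified$sequence, new_reference$sequence)
  promoted <- !is.na(idx) & classified$class != "refprot"
  report <- tibble(from = classified$class[promoted]) %>%
    count(.data$from, name = "n") %>%
    mutate(transition = paste0(.data$from, "->refprot")) %>%
    select("transition", "n")
  out <- classified
  out$class[promoted] <- "refprot"
  out$best_ref_hit[promoted] <- new_reference$ref_accession[idx[promoted]]
  out$accession[promoted] <- new_reference$ref_accession[idx[promoted]]
  out$identity[promoted] <- 1
  out$coverage[promoted] <- 1
  list(proteins = out, report = report)
}
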