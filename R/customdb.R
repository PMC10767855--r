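#' Build an expression-ranked custom protein database
#'
#' Transcripts are filtered by the inclusion/exclusion lists and `min_tpm`,
#' ranked by TPM descending (ties broken by transcript id), and admitted
#' whole: a transcript's proteins (plus variant isoforms of its ORFs carrying
#' a moderate/high coding consequence) enter together, stopping before the
#' first transcript that would push the database past `max_proteins`.
#' Variant sequences are emitted alongside the reference sequence with a
#' suffixed accession. Output is deterministic: identical inputs give a
#' byte-identical database.
#'
#' @param expression Tibble with `transcript_id` and `tpm` (>= 0).
#' @param proteins Accessioned protein table ([mint_accessions()]).
#' @param variant_calls Optional consequence table from [annotate_variants()].
#' @param max_proteins Database size cap (default 100000 entries).
#' @param min_tpm Minimum expression to consider a transcript.
#' @param include_list Optional transcript whitelist: only these transcripts
#'   are considered (still ranked and capped).
#' @param exclude_list Optional transcript blacklist.
#' @return Manifest tibble (class `"orf_customdb"`): `entry`, `accession`,
#'   `sequence`, `transcript_id`, `tpm`, `variant_id` (NA for reference
#'   entries). Write it with [write_custom_db()].
#' @export
build_custom_db <- function(expression, proteins, variant_calls = NULL,
                            max_proteins = 100000L, min_tpm = 0,
                            include_list = NULL, exclude_list = NULL) {
  stopifnot(max_proteins >= 1L)
  if (any(expression$tpm < 0)) abort("negative TPM")
  if (!is.null(include_list) && !is.null(exclude_list) &&
      length(intersect(include_list, exclude_list))) {
    abort("include and exclude lists overlap")
  }
  ranked <- expression
  if (!is.null(include_list)) {
    ranked <- ranked %>% filter(.data$transcript_id %in% include_list)
  }
  if (!is.null(exclude_list)) {
    ranked <- ranked %>% filter(!(.data$transcript_id %in% exclude_list))
  }
  ranked <- ranked %>%
    filter(.data$tpm >= min_tpm) %>%
    arrange(dplyr::desc(.data$tpm), .data$transcript_id)

  assoc <- tibble(
    accession = rep(proteins$accession, lengths(proteins$transcripts)),
    sequence = rep(proteins$sequence, lengths(proteins$transcripts)),
    transcript_id = unlist(proteins$transcripts)
  )
  var_entries <- NULL
  if (!is.null(variant_calls) && nrow(variant_calls) &&
      "accession" %in% names(variant_calls)) {
    var_entries <- variant_calls %>%
      filter(.data$impact %in% c("moderate", "high"),
             .data$consequence != "non_orf",
             !is.na(.data$protein_alt), nzchar(.data$protein_alt),
             !is.na(.data$accession)) %>%
      distinct(.data$accession, .data$transcript_id, .data$variant_id,
               .data$protein_alt)
  }

  taken_acc <- character(0)
  taken_var <- character(0)
  entries <- list()
  n_entries <- 0L
  for (r in seq_len(nrow(ranked))) {
    tx <- ranked$transcript_id[r]
    prot_tx <- assoc %>%
      filter(.data$transcript_id == tx, !(.data$accession %in% taken_acc))
    new_vars <- NULL
    if (!is.null(var_entries)) {
      admitted_acc <- union(taken_acc, prot_tx$accession)
      new_vars <- var_entries %>%
        filter(.data$transcript_id == tx,
               .data$accession %in% admitted_acc) %>%
        mutate(key = paste(.data$accession, .data$variant_id)) %>%
        filter(!(.data$key %in% taken_var))
    }
    n_new <- nrow(prot_tx) + if (is.null(new_vars)) 0L else nrow(new_vars)
    if (n_new == 0L) next
    if (n_entries + n_new > max_proteins) break
    if (nrow(prot_tx)) {
      entries[[length(entries) + 1L]] <- tibble(
        accession = prot_tx$accession, sequence = prot_tx$sequence,
        transcript_id = tx, tpm = ranked$tpm[r], variant_id = NA_character_
      )
      taken_acc <- union(taken_acc, prot_tx$accession)
    }
    if (!is.null(new_vars) && nrow(new_vars)) {
      entries[[length(entries) + 1L]] <- tibble(
        accession = paste0(new_vars$accession, "@",
                           gsub("[^A-Za-z0-9_:>.-]", "_", new_vars$variant_id)),
        sequence = new_vars$protein_alt,
        transcript_id = tx, tpm = ranked$tpm[r],
        variant_id = new_vars$variant_id
      )
      taken_var <- union(taken_var, new_vars$key)
    }
    n_entries <- n_entries + n_new
  }
  out <- bind_rows(entries)
  if (is.null(out) || nrow(out) == 0L) {
    out <- tibble(accession = character(0), sequence = character(0),
                  transcript_id = character(0), tpm = numeric(0),
                  variant_id = character(0))
  }
  out <- out %>% mutate(entry = row_number()) %>%
    select("entry", "accession", "sequence", "transcript_id", "tpm",
           "variant_id")
  class(out) <- unique(c("orf_customdb", class(out)))
  out
}

#' Write a custom database to FASTA (plus manifest TSV)
#'
#' @param db Manifest from [build_custom_db()].
#' @param fasta_path Output FASTA path.
#' @param manifest_path Optional manifest TSV path.
#' @return `fasta_path`, invisibly.
#' @export
write_custom_db <- function(db, fasta_path, manifest_path = NULL) {
  hdr <- paste0(db$accession, " TX=", db$transcript_id,
                " TPM=", format(db$tpm, trim = TRUE, scientific = FALSE),
                if_else(is.na(db$variant_id), "",
                        paste0(" VAR=", db$variant_id)))
  writeLines(paste0(">", hdr, "\n", db$sequence), fasta_path, sep = "\n")
  if (!is.null(manifest_path)) {
    readr::write_tsv(as_tibble(db), manifest_path)
  }
  invisible(fasta_path)
}
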