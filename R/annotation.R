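#' Read transcript annotation from GFF3 or GTF
#'
#' Builds the strand-resolved exon table used throughout the package.
#' GFF3/GTF 1-based inclusive coordinates are converted to the internal
#' 0-based half-open convention at this boundary; exon rank is 5'->3' in
#' transcript orientation. Transcripts that declare no exon feature get a
#' single exon spanning the transcript feature. Exons whose parent transcript
#' is unknown are skipped with a warning; a transcript spanning several
#' chromosomes is an error.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or GTF (`.gtf`) file.
#' @param source_label Label recorded in the `source` column, e.g.
#'   `"ensembl-like"` or `"refseq-like"`.
#' @param format Override format detection (`"gff3"` or `"gtf"`).
#' @return Exon table: one row per exon with columns `transcript_id`,
#'   `gene_id`, `gene_name`, `biotype`, `source`, `chrom`, `strand`,
#'   `start`, `end`, `rank`.
#' @export
read_annotation <- function(path, source_label = "ensembl-like", format = NULL) {
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  if (is.null(format)) {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  }
  gr <- rtracklayer::import(path, format = format)
  df <- as_tibble(as.data.frame(gr))
  df$chrom <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  feats <- if (format == "gtf") parse_gtf_features(df) else parse_gff3_features(df)
  build_exon_table(feats, source_label)
}

strip_id_prefix <- function(x) sub("^(gene:|transcript:)", "", x)

first_chr <- function(x) {
  # rtracklayer returns Parent as a CharacterList for GFF3
  if (is.list(x) || methods::is(x, "List")) {
    vapply(as.list(x), function(e) if (length(e)) as.character(e[[1]]) else NA_character_,
           character(1))
  } else as.character(x)
}

col_or_na <- function(df, nm) {
  if (nm %in% names(df)) as.character(df[[nm]]) else rep(NA_character_, nrow(df))
}

coalesce_chr <- function(...) {
  xs <- list(...)
  out <- xs[[1]]
  for (x in xs[-1]) {
    take <- is.na(out) | out == ""
    out[take] <- x[take]
  }
  out
}

# Normalizes either dialect into two frames: tx (one row per transcript) and
# exon rows carrying their parent transcript id.
parse_gtf_features <- function(df) {
  tx_rows <- df[df$type == "transcript", , drop = FALSE]
  ex_rows <- df[df$type == "exon", , drop = FALSE]
  tx <- tibble(
    transcript_id = col_or_na(tx_rows, "transcript_id"),
    gene_id = col_or_na(tx_rows, "gene_id"),
    gene_name = coalesce_chr(col_or_na(tx_rows, "gene_name"),
                             col_or_na(tx_rows, "gene_id")),
    biotype = coalesce_chr(col_or_na(tx_rows, "transcript_biotype"),
                           col_or_na(tx_rows, "gene_biotype")),
    chrom = tx_rows$chrom, strand = tx_rows$strand,
    start = tx_rows$start, end = tx_rows$end
  )
  ex <- tibble(
    transcript_id = col_or_na(ex_rows, "transcript_id"),
    chrom = ex_rows$chrom, strand = ex_rows$strand,
    start = ex_rows$start, end = ex_rows$end
  )
  list(tx = tx, exons = ex)
}

parse_gff3_features <- function(df) {
  gene_types <- c("gene", "pseudogene", "ncRNA_gene")
  tx_like <- !(df$type %in% c(gene_types, "exon", "CDS", "five_prime_UTR",
                              "three_prime_UTR", "start_codon", "stop_codon"))
  genes <- df[df$type %in% gene_types, , drop = FALSE]
  tx_rows <- df[tx_like & !is.na(first_chr(df$Parent)), , drop = FALSE]
  ex_rows <- df[df$type == "exon", , drop = FALSE]
  gene_tbl <- tibble(
    gene_id = strip_id_prefix(col_or_na(genes, "ID")),
    gene_name = coalesce_chr(col_or_na(genes, "Name"),
                             strip_id_prefix(col_or_na(genes, "ID"))),
    gene_biotype = col_or_na(genes, "biotype")
  )
  tx <- tibble(
    transcript_id = strip_id_prefix(col_or_na(tx_rows, "ID")),
    gene_id = strip_id_prefix(first_chr(tx_rows$Parent)),
    biotype = coalesce_chr(col_or_na(tx_rows, "biotype"), as.character(tx_rows$type)),
    chrom = tx_rows$chrom, strand = tx_rows$strand,
    start = tx_rows$start, end = tx_rows$end
  ) %>%
    left_join(gene_tbl, by = "gene_id") %>%
    mutate(gene_name = coalesce_chr(.data$gene_name, .data$gene_id),
           biotype = coalesce_chr(.data$biotype, .data$gene_biotype)) %>%
    select(-"gene_biotype")
  ex <- tibble(
    transcript_id = strip_id_prefix(first_chr(ex_rows$Parent)),
    chrom = ex_rows$chrom, strand = ex_rows$strand,
    start = ex_rows$start, end = ex_rows$end
  )
  list(tx = tx, exons = ex)
}

build_exon_table <- function(feats, source_label) {
  tx <- feats$tx
  ex <- feats$exons
  orphan <- !(ex$transcript_id %in% tx$transcript_id) | is.na(ex$transcript_id)
  if (any(orphan)) {
    warn(paste0("skipping ", sum(orphan), " exon(s) without a parent transcript"))
    ex <- ex[!orphan, , drop = FALSE]
  }
  # transcripts with no exon rows: single exon spanning the transcript
  noex <- tx[!(tx$transcript_id %in% ex$transcript_id), , drop = FALSE]
  if (nrow(noex)) {
    ex <- bind_rows(ex, tibble(
      transcript_id = noex$transcript_id, chrom = noex$chrom,
      strand = noex$strand, start = noex$start, end = noex$end
    ))
  }
  meta <- tx %>% select("transcript_id", "gene_id", "gene_name", "biotype")
  out <- ex %>%
    left_join(meta, by = "transcript_id") %>%
    mutate(start = as.integer(.data$start) - 1L,  # 1-based inclusive -> 0-based half-open
           end = as.integer(.data$end),
           source = source_label)
  multi <- out %>%
    group_by(.data$transcript_id) %>%
    summarise(nchrom = n_distinct(.data$chrom), .groups = "drop") %>%
    filter(.data$nchrom > 1L)
  if (nrow(multi)) {
    abort(paste0("transcript spans multiple chromosomes: ",
                 paste(multi$transcript_id, collapse = ", ")))
  }
  out %>%
    group_by(.data$transcript_id) %>%
    arrange(if_else(.data$strand == "-", -.data$start, .data$start),
            .by_group = TRUE) %>%
    mutate(rank = row_number()) %>%
    ungroup() %>%
    arrange(.data$chrom, .data$transcript_id, .data$rank) %>%
    select("transcript_id", "gene_id", "gene_name", "biotype", "source",
           "chrom", "strand", "start", "end", "rank")
}

#' Merge two annotation sources by gene
#'
#' Genes from different sources are considered the same gene when their
#' `gene_name` matches, or when their genomic spans overlap on the same strand
#' and chromosome. Transcripts of matched genes are pooled under the first
#' source's `gene_id`/`gene_name`; the join rule is a package convention
#' (annotation resources pool Ensembl- and RefSeq-style gene sets without
#' publishing a join rule).
#'
#' @param a,b Exon tables from [read_annotation()].
#' @return Pooled exon table.
#' @export
merge_annotations <- function(a, b) {
  span <- function(x) x %>%
    group_by(.data$gene_id, .data$gene_name, .data$chrom, .data$strand) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  ga <- span(a); gb <- span(b)
  map_id <- setNames(ga$gene_id, ga$gene_name)
  map_name <- setNames(ga$gene_name, ga$gene_name)
  new_id <- gb$gene_id
  new_name <- gb$gene_name
  for (k in seq_len(nrow(gb))) {
    hit <- which(ga$gene_name == gb$gene_name[k])
    if (!length(hit)) {
      hit <- which(ga$chrom == gb$chrom[k] & ga$strand == gb$strand[k] &
                     ga$start < gb$end[k] & ga$end > gb$start[k])
    }
    if (length(hit)) {
      new_id[k] <- ga$gene_id[hit[1]]
      new_name[k] <- ga$gene_name[hit[1]]
    }
  }
  b2 <- b %>%
    left_join(tibble(gene_id = gb$gene_id, .new_id = new_id, .new_name = new_name),
              by = "gene_id") %>%
    mutate(gene_id = .data$.new_id, gene_name = .data$.new_name) %>%
    select(-".new_id", -".new_name")
  dup_tx <- intersect(unique(a$transcript_id), unique(b2$transcript_id))
  if (length(dup_tx)) {
    b2 <- b2 %>% filter(!(.data$transcript_id %in% dup_tx))
  }
  bind_rows(a, b2)
}
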