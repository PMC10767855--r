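#' Pipeline configuration
#'
#' Collects input paths and the tunable thresholds of every stage. All values
#' are recorded verbatim in output metadata (tool version + config hash), so
#' two runs with the same configuration are byte-identical.
#'
#' @param genome,gff Genome FASTA and annotation (GFF3/GTF) paths (required).
#' @param gff2 Optional second annotation source, merged by gene.
#' @param ref_proteome Reference proteome FASTA path(s).
#' @param psm,ribo,disorder,slim,structure,expr,vcf Optional evidence and
#'   annotation table paths (TSV / VCF).
#' @param out_dir Output directory.
#' @param min_codons,start_codons ORF scan parameters.
#' @param id_threshold,cov_threshold Novel-isoform similarity thresholds.
#' @param fdr_max PSM-level FDR cap (fraction; default 0.0001, i.e. < 0.01%).
#' @param idr_min_run Minimum IDR run length in residues.
#' @param disorder_threshold Binarization threshold for disorder propensities.
#' @param max_proteins Custom database size cap.
#' @param min_tpm Custom database expression floor.
#' @param seed Seed recorded for provenance.
#' @return A `orfeome_config` list.
#' @export
orfeome_config <- function(genome, gff, ref_proteome, out_dir,
                           gff2 = NULL, psm = NULL, ribo = NULL,
                           disorder = NULL, slim = NULL, structure = NULL,
                           expr = NULL, vcf = NULL,
                           min_codons = 30L, start_codons = "ATG",
                           id_threshold = 0.80, cov_threshold = 0.50,
                           fdr_max = 0.0001, idr_min_run = 29L,
                           disorder_threshold = 0.5,
                           max_proteins = 100000L, min_tpm = 0,
                           seed = 1L) {
  cfg <- list(genome = genome, gff = gff, gff2 = gff2,
              ref_proteome = ref_proteome, psm = psm, ribo = ribo,
              disorder = disorder, slim = slim, structure = structure,
              expr = expr, vcf = vcf, out_dir = out_dir,
              min_codons = min_codons, start_codons = start_codons,
              id_threshold = id_threshold, cov_threshold = cov_threshold,
              fdr_max = fdr_max, idr_min_run = idr_min_run,
              disorder_threshold = disorder_threshold,
              max_proteins = max_proteins, min_tpm = min_tpm, seed = seed)
  class(cfg) <- "orfeome_config"
  cfg
}

config_hash <- function(cfg) {
  # the hash captures analytic inputs and parameters, not the output location
  cfg <- cfg[setdiff(names(cfg), "out_dir")]
  flat <- vapply(cfg, function(x) paste(format(x), collapse = ","), character(1))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste0(names(flat), "=", flat), tmp)
  unname(tools::md5sum(tmp))
}

run_meta <- function(cfg) {
  c(tool = paste0("orfeome/", as.character(utils::packageVersion("orfeome"))),
    config = config_hash(cfg))
}

#' Run the full annotation pipeline
#'
#' Stages run in order: annotate (genome + transcripts -> ORFs), classify,
#' evidence, postprocess, then optional variant annotation and custom
#' database construction, writing TSV/FASTA/BED outputs under
#' `cfg$out_dir`. Every TSV carries `# tool=` and `# config=` header lines.
#' Missing required inputs abort before any stage runs.
#'
#' @param cfg Configuration from [orfeome_config()].
#' @return An `orfeome_run` list with all result tables, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "orfeome_config"))
  required <- c(genome = cfg$genome, ref_proteome = cfg$ref_proteome[1],
                gff = cfg$gff)
  optional <- c(gff2 = cfg$gff2, psm = cfg$psm, ribo = cfg$ribo,
                disorder = cfg$disorder, slim = cfg$slim,
                structure = cfg$structure, expr = cfg$expr, vcf = cfg$vcf)
  missing <- c(required, optional)[!file.exists(c(required, optional))]
  if (length(missing)) {
    abort(paste0("missing input file(s): ",
                 paste(names(missing), "=", missing, collapse = "; ")))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- run_meta(cfg)
  msg <- function(...) message("[orfeome] ", ...)

  msg("annotate: reading genome and annotation")
  genome <- read_genome(cfg$genome)
  exons <- read_annotation(cfg$gff, source_label = "primary")
  if (!is.null(cfg$gff2)) {
    exons <- merge_annotations(exons,
                               read_annotation(cfg$gff2,
                                               source_label = "secondary"))
  }
  orfs <- predict_orfs(exons, genome, min_codons = cfg$min_codons,
                       start_codons = cfg$start_codons)
  write_orf_bed(orfs, file.path(cfg$out_dir, "orfs.bed"))

  msg("classify: ", nrow(orfs), " ORFs")
  reference <- read_reference_proteome(cfg$ref_proteome)
  proteins <- collapse_proteins(orfs) %>%
    classify_proteins(reference, id_threshold = cfg$id_threshold,
                      cov_threshold = cfg$cov_threshold) %>%
    mint_accessions()
  write_protein_fasta(proteins, file.path(cfg$out_dir, "proteins.fasta"))

  evidence <- NULL; multicoding <- NULL
  if (!is.null(cfg$psm)) {
    msg("evidence: FDR filter + peptide mapping")
    psms <- readr::read_tsv(cfg$psm, show_col_types = FALSE, comment = "#")
    accepted <- fdr_filter(psms, fdr_max = cfg$fdr_max)
    counts <- map_peptides(accepted$peptide, proteins, reference)
    ribo <- if (!is.null(cfg$ribo)) {
      readr::read_tsv(cfg$ribo, show_col_types = FALSE, comment = "#")
    } else NULL
    evidence <- summarize_evidence(proteins, counts, ribo)
    multicoding <- flag_multicoding(proteins, evidence)
    write_tsv_with_meta(as_tibble(evidence),
                        file.path(cfg$out_dir, "evidence.tsv"), meta)
    write_tsv_with_meta(
      multicoding %>%
        mutate(coding_proteins = vapply(.data$coding_proteins, paste,
                                        character(1), collapse = ",")),
      file.path(cfg$out_dir, "multicoding.tsv"), meta)
  }
  write_annotation_tsv(proteins, file.path(cfg$out_dir, "proteins.tsv"),
                       evidence = evidence, meta = meta)

  idrs <- NULL; slims_kept <- NULL; structure <- NULL; prevalence <- NULL
  if (!is.null(cfg$disorder)) {
    msg("postprocess: IDR calling")
    profiles <- read_disorder_tsv(cfg$disorder)
    idrs <- call_idrs(profiles, threshold = cfg$disorder_threshold,
                      min_run = cfg$idr_min_run)
    prevalence <- idr_prevalence(proteins, idrs)
    write_tsv_with_meta(idrs, file.path(cfg$out_dir, "idrs.tsv"), meta)
    write_tsv_with_meta(prevalence,
                        file.path(cfg$out_dir, "idr_prevalence.tsv"), meta)
    if (!is.null(cfg$slim)) {
      slims_kept <- filter_slims(read_slim_tsv(cfg$slim), profiles,
                                 threshold = cfg$disorder_threshold)
      write_tsv_with_meta(slims_kept,
                          file.path(cfg$out_dir, "slims_retained.tsv"), meta)
    }
  }
  if (!is.null(cfg$structure)) {
    structure <- readr::read_tsv(cfg$structure, show_col_types = FALSE,
                                 comment = "#") %>%
      mutate(bin = bin_plddt(.data$plddt),
             predictor = route_predictor(.data$msa_depth))
    write_tsv_with_meta(structure,
                        file.path(cfg$out_dir, "structure_bins.tsv"), meta)
  }

  calls <- NULL; impacts <- NULL
  if (!is.null(cfg$vcf)) {
    msg("variants: annotating")
    variants <- read_vcf(cfg$vcf, genome = genome) %>%
      normalize_variants(genome)
    calls <- annotate_variants(variants, orfs, exons, genome,
                               proteins = proteins,
                               start_codons = cfg$start_codons)
    impacts <- summarize_impacts(calls)
    write_tsv_with_meta(
      as_tibble(calls) %>% select(-"protein_ref", -"protein_alt"),
      file.path(cfg$out_dir, "variant_calls.tsv"), meta)
  }

  customdb <- NULL
  if (!is.null(cfg$expr)) {
    msg("customdb: building")
    expr <- readr::read_tsv(cfg$expr, show_col_types = FALSE, comment = "#")
    customdb <- build_custom_db(expr, proteins, variant_calls = calls,
                                max_proteins = cfg$max_proteins,
                                min_tpm = cfg$min_tpm)
    write_custom_db(customdb, file.path(cfg$out_dir, "customdb.fasta"),
                    file.path(cfg$out_dir, "customdb_manifest.tsv"))
  }

  res <- list(config = cfg, config_hash = unname(meta["config"]),
              exons = exons, orfs = orfs, proteins = proteins,
              evidence = evidence, multicoding = multicoding, idrs = idrs,
              idr_prevalence = prevalence, slims_retained = slims_kept,
              structure = structure, variant_calls = calls,
              impacts = impacts, customdb = customdb)
  class(res) <- "orfeome_run"
  invisible(res)
}

#' @export
print.orfeome_run <- function(x, ...) {
  cat("<orfeome_run>\n")
  cat("  transcripts:", n_distinct(x$exons$transcript_id), "\n")
  cat("  ORFs:       ", nrow(x$orfs), "\n")
  cat("  proteins:   ", nrow(x$proteins),
      sprintf("(%s)", paste(names(table(x$proteins$class)),
                            table(x$proteins$class),
                            sep = "=", collapse = ", ")), "\n")
  if (!is.null(x$evidence)) cat("  detected:   ", sum(x$evidence$detected), "\n")
  invisible(x)
}

#' Tidy a pipeline run into a per-protein table
#'
#' @param x An `orfeome_run`.
#' @param ... Unused.
#' @return Tibble, one row per protein, with class, accession, evidence and
#'   IDR columns.
#' @method tidy orfeome_run
#' @export
tidy.orfeome_run <- function(x, ...) {
  out <- tibble(
    accession = x$proteins$accession,
    class = x$proteins$class,
    gene = vapply(x$proteins$gene_names, paste, character(1), collapse = ","),
    length = x$proteins$length,
    n_orfs = x$proteins$n_orfs,
    multi_locus = x$proteins$multi_locus
  )
  if (!is.null(x$evidence)) {
    out <- left_join(out,
                     select(as_tibble(x$evidence), "accession",
                            "unique_peptides", "riboseq_detections",
                            "detected"),
                     by = "accession")
  }
  if (!is.null(x$idrs)) {
    out$n_idrs <- vapply(out$accession,
                         function(a) sum(x$idrs$accession == a), integer(1))
  }
  out
}

#' One-row summary of a pipeline run
#'
#' @inheritParams tidy.orfeome_run
#' @return One-row tibble of headline counts.
#' @method glance orfeome_run
#' @export
glance.orfeome_run <- function(x, ...) {
  tibble(
    n_transcripts = n_distinct(x$exons$transcript_id),
    n_orfs = nrow(x$orfs),
    n_proteins = nrow(x$proteins),
    n_refprot = sum(x$proteins$class == "refprot"),
    n_novel_isoform = sum(x$proteins$class == "novel_isoform"),
    n_altprot = sum(x$proteins$class == "altprot"),
    n_detected = if (is.null(x$evidence)) NA_integer_
                 else sum(x$evidence$detected),
    n_multicoding = if (is.null(x$multicoding)) NA_integer_
                    else sum(x$multicoding$is_multicoding),
    n_variant_calls = if (is.null(x$variant_calls)) NA_integer_
                      else nrow(x$variant_calls),
    n_customdb = if (is.null(x$customdb)) NA_integer_ else nrow(x$customdb)
  )
}
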