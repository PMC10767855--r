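# Synthetic mini-genome generator -------------------------------------------
#
# Builds a deterministic fixture set (genome, GFF3/GTF twins, reference
# proteome, PSM/ribo-seq/disorder/SLiM/structure/expression tables, VCF) with
# recorded ground truth, so the whole pipeline is testable without downloads.
#
# Construction keeps incidental ORFs out by design: planted ORF bodies use
# only sense codons free of adenine, UTR/filler sequence uses {C,G,T}, starts
# are ATG and stops TAG. With that alphabet no reading frame of a transcript
# contains a start or stop codon other than the planted ones, so every
# transcript carries exactly its planted ORFs (the generator still verifies
# each transcript and retries a bounded number of times).

afree_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  cods <- names(gc)
  cods[!grepl("A", cods, fixed = TRUE) & gc != "*"]
}

rand_codons <- function(n) {
  paste(sample(afree_codons(), n, replace = TRUE), collapse = "")
}

rand_filler <- function(n) {
  paste(sample(c("C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

# Overlapping-frame ORF pair: ORF A (frame 0 of the region) with ORF B planted
# at in-frame offset s (s %% 3 != 0) by overwriting A's body with B's start
# and stop. Retries until the region scans to exactly the two planted ORFs.
make_dual_region <- function(n_a = 50L, n_b = 31L, max_try = 60L) {
  for (try in seq_len(max_try)) {
    body <- rand_codons(n_a - 2L)
    region <- paste0("ATG", body, "TAG")
    k <- sample(1:2, 1L)
    s_min <- 6L
    s_max <- nchar(region) - 3L * n_b - 6L
    if (s_max < s_min) next
    s_choices <- seq(s_min, s_max)
    s_choices <- s_choices[s_choices %% 3L == k]
    if (!length(s_choices)) next
    s <- sample(s_choices, 1L)
    b_end <- s + 3L * n_b  # half-open
    substr(region, s + 1L, s + 3L) <- "ATG"
    substr(region, b_end - 2L, b_end) <- "TAG"
    hits <- find_orfs(region, min_codons = 30L)
    ok <- nrow(hits) == 2L &&
      any(hits$t_start == 0L & hits$t_end == nchar(region)) &&
      any(hits$t_start == s & hits$t_end == b_end)
    if (ok) return(list(region = region, s = s, b_end = b_end))
  }
  abort("failed to construct an overlapping-ORF region")
}

split_exons <- function(spliced_len, n_exons) {
  if (n_exons <= 1L || spliced_len < 40L * n_exons) {
    return(c(0L, spliced_len))
  }
  repeat {
    cuts <- sort(sample(seq(20L, spliced_len - 20L), n_exons - 1L))
    if (all(diff(c(0L, cuts, spliced_len)) >= 20L)) break
  }
  c(0L, cuts, spliced_len)
}

# Appends one gene locus to a chromosome string; returns exon rows (0-based
# half-open genomic) in 5'->3' transcript rank order plus the new chromosome.
place_transcript <- function(chrom_seq, spliced, n_exons, strand,
                             transcript_id, gene_id, gene_name, biotype,
                             chrom_name) {
  bounds <- split_exons(nchar(spliced), n_exons)
  n_ex <- length(bounds) - 1L
  pieces <- substring(spliced, bounds[-length(bounds)] + 1L, bounds[-1])
  introns <- if (n_ex > 1L) vapply(seq_len(n_ex - 1L),
                                   function(i) rand_dna(sample(40:120, 1L)),
                                   character(1)) else character(0)
  locus <- pieces[1]
  for (i in seq_along(introns)) locus <- paste0(locus, introns[i], pieces[i + 1L])
  spacer <- rand_dna(sample(60:150, 1L))
  offset <- nchar(chrom_seq) + nchar(spacer)
  glocus <- if (strand == "-") revcomp(locus) else locus
  chrom_seq <- paste0(chrom_seq, spacer, glocus)
  # transcript-orientation exon spans within the locus
  a <- integer(n_ex); b <- integer(n_ex)
  pos <- 0L
  for (i in seq_len(n_ex)) {
    a[i] <- pos
    b[i] <- pos + nchar(pieces[i])
    pos <- b[i] + if (i < n_ex) nchar(introns[i]) else 0L
  }
  L <- nchar(locus)
  gs <- if (strand == "+") offset + a else offset + L - b
  ge <- if (strand == "+") offset + b else offset + L - a
  exons <- tibble(
    transcript_id = transcript_id, gene_id = gene_id, gene_name = gene_name,
    biotype = biotype, source = "synthetic", chrom = chrom_name,
    strand = strand, start = as.integer(gs), end = as.integer(ge),
    rank = seq_len(n_ex)
  )
  list(chrom_seq = chrom_seq, exons = exons)
}

#' Generate a deterministic synthetic fixture set
#'
#' Builds a mini-genome with planted ORFs spanning all three protein classes
#' (reference proteins, novel isoforms, alternative proteins), overlapping-
#' frame ORF pairs, multi-isoform and duplicated-locus proteins, lncRNA and
#' pseudogene biotypes, and matching evidence, disorder, SLiM, structure,
#' expression and variant tables with recorded ground truth. The same seed
#' yields byte-identical fixtures.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_genes Number of genes (>= 8; kinds are cycled).
#' @param write_dir Optional directory; when given, all fixture files are
#'   written there (see [write_fixture()]).
#' @return List with the in-memory fixture (`genome`, `exons`, `reference`,
#'   `orfs`, `proteins`, `evidence` inputs, `variants`, ...) and `truth`,
#'   a list of ground-truth tables.
#' @export
simulate_orfeome <- function(seed = 1L, n_genes = 24L, write_dir = NULL) {
  stopifnot(n_genes >= 8L)
  set.seed(seed)
  kinds <- rep(c("ref", "novel", "alt", "dual", "lnc", "pseudo"),
               length.out = n_genes)
  kinds[n_genes - 2L] <- "multi_iso"
  kinds[n_genes - 1L] <- "dup_a"
  kinds[n_genes] <- "dup_b"

  chroms <- c("chr1", "chr2")
  chrom_seq <- lapply(seq_along(chroms), function(i) rand_dna(200L))
  names(chrom_seq) <- chroms

  exon_rows <- list()
  ref_rows <- list()
  truth_orfs <- list()
  dup_nt <- NULL
  dual_info <- list()

  for (g in seq_len(n_genes)) {
    kind <- kinds[g]
    gene_id <- sprintf("G%03d", g)
    gene_name <- sprintf("GENE%03d", g)
    chrom <- chroms[(g %% 2L) + 1L]
    strand <- if (kind %in% c("ref", "dual", "multi_iso")) "+"
              else if (kind == "alt") "-"
              else sample(c("+", "-"), 1L)
    n_exons <- if (kind %in% c("ref", "dual", "multi_iso")) 1L
               else sample(1:3, 1L)
    biotype <- switch(kind, lnc = "lncRNA", pseudo = "pseudogene",
                      "protein_coding")
    u5 <- rand_filler(sample(30:60, 1L))
    u3 <- rand_filler(sample(30:60, 1L))
    tx_id <- sprintf("T%03d.1", g)

    if (kind == "dual") {
      dd <- make_dual_region(n_a = sample(48:58, 1L), n_b = sample(30:33, 1L))
      orf_nt <- dd$region
      spliced <- paste0(u5, orf_nt, u3)
      t0 <- nchar(u5)
      orf_defs <- tibble(
        transcript_id = tx_id,
        t_start = c(t0, t0 + dd$s),
        t_end = c(t0 + nchar(orf_nt), t0 + dd$b_end),
        class = c("refprot", "altprot")
      )
      dual_info[[gene_id]] <- list(tx = tx_id, t0 = t0, s = dd$s,
                                   region_len = nchar(orf_nt))
    } else {
      n_body <- switch(kind,
                       ref = sample(60:90, 1L),
                       novel = 119L,
                       multi_iso = sample(45:70, 1L),
                       sample(32:70, 1L))
      body_cods <- sample(afree_codons(), n_body, replace = TRUE)
      if (kind == "ref") body_cods[9L] <- "TGG"  # stop-gain target codon
      if (kind == "dup_b") {
        body_cods <- dup_nt
      } else if (kind == "dup_a") {
        dup_nt <- body_cods
      }
      if (kind == "novel") {
        full_cods <- body_cods
        body_cods <- full_cods[-(40:49)]  # 10-codon internal deletion
      }
      orf_nt <- paste0("ATG", paste(body_cods, collapse = ""), "TAG")
      spliced <- paste0(u5, orf_nt, u3)
      t0 <- nchar(u5)
      cls <- switch(kind,
                    ref = "refprot",
                    novel = "novel_isoform",
                    "altprot")
      orf_defs <- tibble(transcript_id = tx_id, t_start = t0,
                         t_end = t0 + nchar(orf_nt), class = cls)
    }

    pl <- place_transcript(chrom_seq[[chrom]], spliced, n_exons, strand,
                           tx_id, gene_id, gene_name, biotype, chrom)
    chrom_seq[[chrom]] <- pl$chrom_seq
    exon_rows[[length(exon_rows) + 1L]] <- pl$exons

    if (kind == "multi_iso") {
      # second isoform: extra upstream exon of pure filler, same ORF/protein
      tx2 <- sprintf("T%03d.2", g)
      extra <- rand_filler(40L)
      spliced2 <- paste0(extra, spliced)
      pl2 <- place_transcript(chrom_seq[[chrom]], spliced2, 2L, "+",
                              tx2, gene_id, gene_name, biotype, chrom)
      chrom_seq[[chrom]] <- pl2$chrom_seq
      exon_rows[[length(exon_rows) + 1L]] <- pl2$exons
      orf_defs <- bind_rows(orf_defs, tibble(
        transcript_id = tx2, t_start = orf_defs$t_start[1] + 40L,
        t_end = orf_defs$t_end[1] + 40L, class = orf_defs$class[1]
      ))
    }

    # proteins + reference entries
    orf_defs$protein <- NA_character_
    for (i in seq_len(nrow(orf_defs))) {
      spl <- if (orf_defs$transcript_id[i] == tx_id) spliced else spliced2
      orf_defs$protein[i] <- translate_cds(
        substr(spl, orf_defs$t_start[i] + 1L, orf_defs$t_end[i] - 3L))
    }
    orf_defs$gene_id <- gene_id
    orf_defs$gene_name <- gene_name
    orf_defs$biotype <- biotype
    truth_orfs[[length(truth_orfs) + 1L]] <- orf_defs

    if (kind == "ref") {
      ref_rows[[length(ref_rows) + 1L]] <- tibble(
        ref_accession = sprintf("REF_%03d", g), gene = gene_name,
        sequence = orf_defs$protein[1])
    } else if (kind == "novel") {
      q_prot <- translate_cds(paste0("ATG", paste(full_cods, collapse = "")))
      ref_rows[[length(ref_rows) + 1L]] <- tibble(
        ref_accession = sprintf("REF_%03d", g), gene = gene_name,
        sequence = q_prot)
    } else if (kind == "alt") {
      # unrelated same-gene reference protein: the altprot must fail similarity
      decoy <- translate_cds(paste0("ATG", rand_codons(sample(80:110, 1L))))
      ref_rows[[length(ref_rows) + 1L]] <- tibble(
        ref_accession = sprintf("REF_%03d", g), gene = gene_name,
        sequence = decoy)
    } else if (kind == "dual") {
      ref_rows[[length(ref_rows) + 1L]] <- tibble(
        ref_accession = sprintf("REF_%03d", g), gene = gene_name,
        sequence = orf_defs$protein[1])
    }
  }

  genome <- vapply(chrom_seq, identity, character(1))
  exons <- bind_rows(exon_rows)
  reference <- bind_rows(ref_rows)
  truth_orf_tbl <- bind_rows(truth_orfs)

  # verify every transcript scans to exactly its planted ORFs
  seqs <- spliced_sequence(exons, genome)
  for (i in seq_len(nrow(seqs))) {
    hits <- find_orfs(seqs$seq[i])
    want <- truth_orf_tbl[truth_orf_tbl$transcript_id == seqs$transcript_id[i], ]
    if (nrow(hits) != nrow(want) ||
        !all(sort(hits$t_start) == sort(want$t_start))) {
      abort(paste0("fixture self-check failed for ", seqs$transcript_id[i]))
    }
  }

  orfs <- predict_orfs(exons, genome)
  proteins <- mint_accessions(classify_proteins(collapse_proteins(orfs),
                                                reference))

  ev <- plan_evidence(proteins, reference)
  post <- plan_postprocessing(proteins)
  expression <- plan_expression(exons)
  vars <- plan_variants(orfs, exons, genome, proteins, kinds, dual_info)

  fix <- list(
    genome = genome, exons = exons, reference = reference, orfs = orfs,
    proteins = proteins, psms = ev$psms, ribo = ev$ribo,
    disorder = post$disorder, slims = post$slims,
    structure = post$structure, expression = expression,
    variants = vars$variants,
    truth = list(orfs = truth_orf_tbl, evidence = ev$truth,
                 idrs = post$truth_idrs, slims = post$truth_slims,
                 structure = post$truth_structure, variants = vars$truth)
  )
  if (!is.null(write_dir)) fix$paths <- write_fixture(fix, write_dir)
  fix
}

# ---- evidence fixture -------------------------------------------------------

pick_unique_peptide <- function(protein, class, all_pred, all_ref,
                                junction = NA_integer_, max_try = 40L) {
  len <- nchar(protein)
  for (try in seq_len(max_try)) {
    w <- sample(9:12, 1L)
    if (!is.na(junction)) {
      off <- sample(max(1L, junction - w + 2L):min(junction, len - w + 1L), 1L)
    } else {
      if (len < w) return(NA_character_)
      off <- sample(seq_len(len - w + 1L), 1L)
    }
    pep <- substr(protein, off, off + w - 1L)
    hits <- sum(stringr::str_detect(collapse_il(all_pred),
                                    stringr::fixed(collapse_il(pep))))
    in_ref <- any(stringr::str_detect(collapse_il(all_ref),
                                      stringr::fixed(collapse_il(pep))))
    if (hits == 1L && (class == "refprot" || !in_ref)) return(pep)
  }
  NA_character_
}

plan_evidence <- function(proteins, reference) {
  plan <- tibble(
    accession = proteins$accession, class = proteins$class,
    sequence = proteins$sequence
  )
  patterns <- list(c(2L, 0L), c(1L, 1L), c(1L, 0L), c(0L, 2L), c(0L, 0L),
                   c(3L, 1L))
  idx <- ((seq_len(nrow(plan)) - 1L) %% length(patterns)) + 1L
  plan$want_pep <- vapply(idx, function(i) patterns[[i]][1], integer(1))
  plan$want_ribo <- vapply(idx, function(i) patterns[[i]][2], integer(1))
  # novel isoforms share sequence with their reference protein: unique
  # peptides must straddle the deletion junction (residue 40)
  junction <- if_else(plan$class == "novel_isoform", 40L, NA_integer_)
  psm_rows <- list()
  got_pep <- integer(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    k <- 0L
    chosen <- character(0)
    tries <- 0L
    while (k < plan$want_pep[i] && tries < 60L) {
      tries <- tries + 1L
      pep <- pick_unique_peptide(plan$sequence[i], plan$class[i],
                                 proteins$sequence, reference$sequence,
                                 junction[i])
      if (is.na(pep) || pep %in% chosen) next
      chosen <- c(chosen, pep)
      psm_rows[[length(psm_rows) + 1L]] <- tibble(
        peptide = pep, score = round(runif(1, 60, 100), 3),
        is_decoy = FALSE, dataset = "ds1")
      k <- k + 1L
    }
    got_pep[i] <- k
  }
  # a peptide that also occurs in the reference proteome: must count for no one
  novel_i <- which(plan$class == "novel_isoform")
  if (length(novel_i)) {
    shared <- substr(plan$sequence[novel_i[1]], 5L, 14L)
    psm_rows[[length(psm_rows) + 1L]] <- tibble(
      peptide = shared, score = 99.5, is_decoy = FALSE, dataset = "ds1")
  }
  psms <- bind_rows(psm_rows)
  decoys <- psms %>%
    mutate(peptide = vapply(strsplit(.data$peptide, ""),
                            function(x) paste(rev(x), collapse = ""),
                            character(1)),
           score = round(runif(n(), 2, 40), 3), is_decoy = TRUE)
  psms <- bind_rows(psms, decoys)
  psms <- psms[sample(nrow(psms)), , drop = FALSE]
  ribo <- tibble(accession = plan$accession,
                 riboseq_detections = plan$want_ribo) %>%
    filter(.data$riboseq_detections > 0L)
  truth <- tibble(
    accession = plan$accession, class = plan$class,
    unique_peptides = got_pep,
    riboseq_detections = plan$want_ribo,
    detected = got_pep >= 2L | (got_pep >= 1L & plan$want_ribo >= 1L)
  )
  list(psms = psms, ribo = ribo, truth = truth)
}

# ---- disorder / SLiM / structure fixtures -----------------------------------

plan_postprocessing <- function(proteins) {
  n <- nrow(proteins)
  disorder <- vector("list", n)
  idr_rows <- list()
  slim_rows <- list()
  slim_truth <- list()
  for (i in seq_len(n)) {
    len <- proteins$length[i]
    prof <- rep(0, len)
    mode <- (i - 1L) %% 4L
    if (mode == 0L && len >= 31L) {
      run <- sample(29L:min(len - 2L, 60L), 1L)
      st <- sample(seq(1L, len - run), 1L)  # keep a flanking ordered residue
      prof[st:(st + run - 1L)] <- 1
      idr_rows[[length(idr_rows) + 1L]] <- tibble(
        accession = proteins$accession[i], start = st - 1L, end = st - 1L + run)
      # SLiM fully inside the IDR: retained
      sl <- sample(3:8, 1L)
      s0 <- st - 1L + sample(0:(run - sl), 1L)
      slim_rows[[length(slim_rows) + 1L]] <- tibble(
        accession = proteins$accession[i], motif = "LIG_demo",
        start = s0, end = s0 + sl)
      slim_truth[[length(slim_truth) + 1L]] <- TRUE
      # SLiM poking one residue outside: filtered out
      if (st - 1L >= 1L) {
        slim_rows[[length(slim_rows) + 1L]] <- tibble(
          accession = proteins$accession[i], motif = "DOC_demo",
          start = st - 2L, end = st - 2L + sl)
        slim_truth[[length(slim_truth) + 1L]] <- FALSE
      }
    } else if (mode == 1L && len >= 30L) {
      st <- sample(seq(1L, len - 28L), 1L)
      prof[st:(st + 27L)] <- 1  # 28-run: below the 29-residue minimum
    } else if (mode == 2L) {
      slim_rows[[length(slim_rows) + 1L]] <- tibble(
        accession = proteins$accession[i], motif = "MOD_demo",
        start = 2L, end = 8L)
      slim_truth[[length(slim_truth) + 1L]] <- FALSE  # fully ordered span
    }
    disorder[[i]] <- prof
  }
  plddt_cycle <- c(95.5, 91, 90, 80.2, 70, 69.9, 55, 50, 45.1, 30)
  msa_cycle <- c(1L, 12L, 29L, 30L, 31L, 120L)
  plddt <- plddt_cycle[((seq_len(n) - 1L) %% length(plddt_cycle)) + 1L]
  msa <- msa_cycle[((seq_len(n) - 1L) %% length(msa_cycle)) + 1L]
  bin_truth <- ifelse(plddt > 90, "very_high",
                      ifelse(plddt > 70, "high",
                             ifelse(plddt > 50, "medium", "very_low")))
  pred_truth <- ifelse(msa < 30L, "omegafold-like", "alphafold-like")
  idrs <- bind_rows(idr_rows)
  if (is.null(idrs) || nrow(idrs) == 0L) {
    idrs <- tibble(accession = character(0), start = integer(0),
                   end = integer(0))
  }
  slims <- bind_rows(slim_rows)
  if (is.null(slims) || nrow(slims) == 0L) {
    slims <- tibble(accession = character(0), motif = character(0),
                    start = integer(0), end = integer(0))
    slim_truth <- list(logical(0))
  }
  list(
    disorder = tibble(accession = proteins$accession, disorder = disorder),
    slims = slims,
    structure = tibble(accession = proteins$accession, plddt = plddt,
                       msa_depth = msa),
    truth_idrs = idrs %>% mutate(length = .data$end - .data$start),
    truth_slims = slims %>% mutate(retained = unlist(slim_truth)),
    truth_structure = tibble(accession = proteins$accession,
                             bin = bin_truth, predictor = pred_truth)
  )
}

plan_expression <- function(exons) {
  tx <- sort(unique(exons$transcript_id))
  tpm <- round(stats::rlnorm(length(tx), meanlog = 2, sdlog = 1.2), 2)
  if (length(tx) >= 4L) tpm[2L] <- tpm[1L]  # planted tie
  tibble(transcript_id = tx, tpm = tpm)
}

# ---- variant fixture --------------------------------------------------------

# Codon index (1-based, within ORF incl. start) -> transcript offsets.
codon_span <- function(t_start, j) c(t_start + 3L * (j - 1L), t_start + 3L * j - 1L)

fourfold_afree <- c("GC", "GT", "TC", "CC", "CG", "GG")

plant_snv <- function(exons_tx, genome, t_pos, new_base_tx) {
  strand <- exons_tx$strand[1]
  g <- map_to_genomic(exons_tx, t_pos)
  chrom <- exons_tx$chrom[1]
  ref_g <- substr(genome_seq(genome, chrom), g + 1L, g + 1L)
  alt_g <- if (strand == "-") comp_base(new_base_tx) else new_base_tx
  tibble(chrom = chrom, pos = g + 1L, ref = ref_g, alt = alt_g)
}

plan_variants <- function(orfs, exons, genome, proteins, kinds, dual_info) {
  seqs <- spliced_sequence(exons, genome)
  txseq <- setNames(seqs$seq, seqs$transcript_id)
  rows <- list(); truth <- list()
  add <- function(v, orf_id, consequence) {
    v$variant_id <- paste0(v$chrom, ":", v$pos, ":", v$ref, ">", v$alt)
    rows[[length(rows) + 1L]] <<- v
    truth[[length(truth) + 1L]] <<- tibble(
      variant_id = v$variant_id, orf_id = orf_id,
      consequence = consequence,
      impact = unname(IMPACT_OF[consequence]))
  }
  orf_of_tx <- function(tx) orfs[orfs$transcript_id == tx, ][1, ]
  snv_targets <- function(kind_want, strand_want) {
    g <- which(kinds == kind_want)
    if (!length(g)) return(NULL)
    tx <- sprintf("T%03d.1", g[1])
    o <- orf_of_tx(tx)
    if (is.na(o$orf_id)) return(NULL)
    o
  }

  # plus-strand single-exon refprot ORF: SNV + indel plants
  o <- snv_targets("ref", "+")
  if (!is.null(o)) {
    tx <- o$transcript_id
    ex_tx <- exons[exons$transcript_id == tx, ]
    seq <- txseq[[tx]]
    cods <- substring(seq, seq(o$t_start + 1L, o$t_end - 2L, 3L),
                      seq(o$t_start + 3L, o$t_end, 3L))
    # synonymous: third base of a fourfold codon, kept A-free
    j <- which(substr(cods, 1, 2) %in% fourfold_afree &
                 seq_along(cods) > 1L & seq_along(cods) < length(cods))[1]
    tpos <- o$t_start + 3L * j - 1L
    old <- substr(seq, tpos + 1L, tpos + 1L)
    newb <- setdiff(c("C", "G", "T"), old)[1]
    add(plant_snv(ex_tx, genome, tpos, newb), o$orf_id, "synonymous")
    # missense: first base of the same codon family
    j2 <- which(substr(cods, 1, 2) %in% fourfold_afree)[2]
    tpos2 <- o$t_start + 3L * (j2 - 1L)
    old2 <- substr(seq, tpos2 + 1L, tpos2 + 1L)
    new2 <- setdiff(c("C", "G", "T"), old2)[1]
    add(plant_snv(ex_tx, genome, tpos2, new2), o$orf_id, "missense")
    # stop_gained: TGG codon planted at codon 10 -> TAG
    j3 <- which(cods == "TGG")[1]
    if (!is.na(j3)) {
      tpos3 <- o$t_start + 3L * (j3 - 1L) + 1L
      add(plant_snv(ex_tx, genome, tpos3, "A"), o$orf_id, "stop_gained")
    }
    # stop_lost: TAG stop -> TGG (readthrough)
    tstop <- o$t_end - 2L  # middle base of the stop codon
    add(plant_snv(ex_tx, genome, tstop, "G"), o$orf_id, "stop_lost")
    # start_lost: ATG -> CTG
    add(plant_snv(ex_tx, genome, o$t_start, "C"), o$orf_id, "start_lost")
    # non_orf: 5' UTR SNV
    u <- 5L
    oldu <- substr(seq, u + 1L, u + 1L)
    add(plant_snv(ex_tx, genome, u, setdiff(c("C", "G", "T"), oldu)[1]),
        o$orf_id, "non_orf")
    # frameshift: 1-nt insertion after codon 5 (single-exon, plus strand)
    gpos <- map_to_genomic(ex_tx, o$t_start + 15L)
    anchor <- substr(genome_seq(genome, o$chrom), gpos + 1L, gpos + 1L)
    add(tibble(chrom = o$chrom, pos = gpos + 1L, ref = anchor,
               alt = paste0(anchor, "G")), o$orf_id, "frameshift")
    # inframe_deletion: drop codon 7 (anchored 4-base REF)
    gdel <- map_to_genomic(ex_tx, o$t_start + 17L)
    refdel <- substr(genome_seq(genome, o$chrom), gdel + 1L, gdel + 4L)
    add(tibble(chrom = o$chrom, pos = gdel + 1L, ref = refdel,
               alt = substr(refdel, 1, 1)), o$orf_id, "inframe_deletion")
  }

  # minus-strand altprot ORF: synonymous SNV through the strand machinery
  o <- snv_targets("alt", "-")
  if (!is.null(o)) {
    tx <- o$transcript_id
    ex_tx <- exons[exons$transcript_id == tx, ]
    seq <- txseq[[tx]]
    cods <- substring(seq, seq(o$t_start + 1L, o$t_end - 2L, 3L),
                      seq(o$t_start + 3L, o$t_end, 3L))
    j <- which(substr(cods, 1, 2) %in% fourfold_afree &
                 seq_along(cods) > 1L & seq_along(cods) < length(cods))[1]
    if (!is.na(j)) {
      tpos <- o$t_start + 3L * j - 1L
      old <- substr(seq, tpos + 1L, tpos + 1L)
      add(plant_snv(ex_tx, genome, tpos, setdiff(c("C", "G", "T"), old)[1]),
          o$orf_id, "synonymous")
    }
  }

  # dual-coding gene: one SNV, synonymous in ORF A, missense in overlapping B
  if (length(dual_info)) {
    di <- dual_info[[1]]
    tx <- di$tx
    ex_tx <- exons[exons$transcript_id == tx, ]
    seq <- txseq[[tx]]
    o_all <- orfs[orfs$transcript_id == tx, ]
    oA <- o_all[which.min(o_all$t_start), ]
    oB <- o_all[which.max(o_all$t_start), ]
    codsA <- substring(seq, seq(oA$t_start + 1L, oA$t_end - 2L, 3L),
                       seq(oA$t_start + 3L, oA$t_end, 3L))
    # codon of A strictly inside B, away from B's start/stop trios
    gc_tab <- Biostrings::GENETIC_CODE
    js <- which(substr(codsA, 1, 2) %in% fourfold_afree)
    for (j in js) {
      span <- codon_span(oA$t_start, j)
      if (!(span[1] >= oB$t_start + 3L && span[2] <= oB$t_end - 4L)) next
      tpos <- span[2]
      old <- substr(seq, tpos + 1L, tpos + 1L)
      done <- FALSE
      for (newb in setdiff(c("C", "G", "T"), old)) {
        # must change B's residue: rebuild B's codon around this position
        boff <- (tpos - oB$t_start) %% 3L
        bcod_start <- tpos - boff
        bcod <- substr(seq, bcod_start + 1L, bcod_start + 3L)
        bcod_new <- bcod
        substr(bcod_new, boff + 1L, boff + 1L) <- newb
        if (gc_tab[[bcod]] == gc_tab[[bcod_new]] || gc_tab[[bcod_new]] == "*") next
        add(plant_snv(ex_tx, genome, tpos, newb), oA$orf_id, "synonymous")
        truth[[length(truth) + 1L]] <- tibble(
          variant_id = truth[[length(truth)]]$variant_id,
          orf_id = oB$orf_id, consequence = "missense",
          impact = "moderate")
        done <- TRUE
        break
      }
      if (done) break
    }
  }

  variants <- bind_rows(rows)
  if (is.null(variants) || nrow(variants) == 0L) {
    variants <- tibble(chrom = character(0), pos = integer(0),
                       ref = character(0), alt = character(0),
                       variant_id = character(0))
  } else {
    variants <- variants %>%
      distinct(.data$variant_id, .keep_all = TRUE) %>%
      arrange(.data$chrom, .data$pos, .data$alt) %>%
      mutate(start = .data$pos - 1L) %>%
      select("variant_id", "chrom", "pos", "start", "ref", "alt")
  }
  list(variants = variants, truth = bind_rows(truth))
}

# ---- file writers -----------------------------------------------------------

write_gff3 <- function(exons, path) {
  lines <- c("##gff-version 3")
  tx_meta <- exons %>%
    group_by(.data$transcript_id, .data$gene_id, .data$gene_name,
             .data$biotype, .data$chrom, .data$strand) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  gene_meta <- tx_meta %>%
    group_by(.data$gene_id, .data$gene_name, .data$chrom, .data$strand) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              biotype = first(.data$biotype), .groups = "drop") %>%
    arrange(.data$chrom, .data$start)
  for (g in seq_len(nrow(gene_meta))) {
    gm <- gene_meta[g, ]
    lines <- c(lines, paste(
      gm$chrom, "synthetic", "gene", gm$start + 1L, gm$end, ".", gm$strand, ".",
      paste0("ID=gene:", gm$gene_id, ";Name=", gm$gene_name,
             ";biotype=", gm$biotype),
      sep = "\t"))
    txs <- tx_meta[tx_meta$gene_id == gm$gene_id, ]
    for (t in seq_len(nrow(txs))) {
      tm <- txs[t, ]
      lines <- c(lines, paste(
        tm$chrom, "synthetic", "mRNA", tm$start + 1L, tm$end, ".", tm$strand,
        ".",
        paste0("ID=transcript:", tm$transcript_id, ";Parent=gene:", gm$gene_id,
               ";biotype=", tm$biotype),
        sep = "\t"))
      ex <- exons[exons$transcript_id == tm$transcript_id, ]
      for (e in seq_len(nrow(ex))) {
        lines <- c(lines, paste(
          ex$chrom[e], "synthetic", "exon", ex$start[e] + 1L, ex$end[e], ".",
          ex$strand[e], ".",
          paste0("Parent=transcript:", tm$transcript_id),
          sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

write_gtf <- function(exons, path) {
  lines <- character(0)
  tx_meta <- exons %>%
    group_by(.data$transcript_id, .data$gene_id, .data$gene_name,
             .data$biotype, .data$chrom, .data$strand) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") %>%
    arrange(.data$chrom, .data$start)
  attrs <- function(tm) {
    paste0("gene_id \"", tm$gene_id, "\"; transcript_id \"", tm$transcript_id,
           "\"; gene_name \"", tm$gene_name, "\"; transcript_biotype \"",
           tm$biotype, "\";")
  }
  for (t in seq_len(nrow(tx_meta))) {
    tm <- tx_meta[t, ]
    lines <- c(lines, paste(tm$chrom, "synthetic", "transcript",
                            tm$start + 1L, tm$end, ".", tm$strand, ".",
                            attrs(tm), sep = "\t"))
    ex <- exons[exons$transcript_id == tm$transcript_id, ]
    for (e in seq_len(nrow(ex))) {
      lines <- c(lines, paste(ex$chrom[e], "synthetic", "exon",
                              ex$start[e] + 1L, ex$end[e], ".", ex$strand[e],
                              ".", attrs(tm), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

write_vcf <- function(variants, genome, path) {
  lines <- c("##fileformat=VCFv4.2",
             paste0("##contig=<ID=", names(genome), ",length=",
                    nchar(genome), ">"),
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", sep = "\t"))
  if (nrow(variants)) {
    lines <- c(lines, paste(variants$chrom, variants$pos, ".", variants$ref,
                            variants$alt, ".", "PASS", ".", sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

write_genome_fasta <- function(genome, path) {
  writeLines(paste0(">", names(genome), "\n", fasta_wrap(genome)), path)
  invisible(path)
}

write_reference_fasta <- function(reference, path) {
  writeLines(paste0(">", reference$ref_accession, " synthetic GN=",
                    reference$gene, "\n", fasta_wrap(reference$sequence)),
             path)
  invisible(path)
}

#' Write a simulated fixture set to disk
#'
#' @param fix Fixture list from [simulate_orfeome()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(
    genome = file.path(dir, "genome.fa"),
    gff3 = file.path(dir, "annotation.gff3"),
    gtf = file.path(dir, "annotation.gtf"),
    reference = file.path(dir, "reference.fa"),
    psms = file.path(dir, "psms.tsv"),
    ribo = file.path(dir, "ribo.tsv"),
    disorder = file.path(dir, "disorder.tsv"),
    slims = file.path(dir, "slims.tsv"),
    structure = file.path(dir, "structure.tsv"),
    expression = file.path(dir, "expression.tsv"),
    vcf = file.path(dir, "variants.vcf"),
    truth = file.path(dir, "truth.json")
  )
  write_genome_fasta(fix$genome, p[["genome"]])
  write_gff3(fix$exons, p[["gff3"]])
  write_gtf(fix$exons, p[["gtf"]])
  write_reference_fasta(fix$reference, p[["reference"]])
  readr::write_tsv(fix$psms, p[["psms"]])
  readr::write_tsv(fix$ribo, p[["ribo"]])
  readr::write_tsv(
    tibble(accession = fix$disorder$accession,
           disorder = vapply(fix$disorder$disorder, paste,
                             character(1), collapse = ",")),
    p[["disorder"]])
  # SLiM TSV uses 1-based inclusive spans, converted back on read
  readr::write_tsv(
    fix$slims %>% mutate(start = .data$start + 1L),
    p[["slims"]])
  readr::write_tsv(fix$structure, p[["structure"]])
  readr::write_tsv(fix$expression, p[["expression"]])
  write_vcf(fix$variants, fix$genome, p[["vcf"]])
  jsonlite::write_json(lapply(fix$truth, as.data.frame), p[["truth"]],
                       dataframe = "rows", digits = NA)
  invisible(p)
}
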