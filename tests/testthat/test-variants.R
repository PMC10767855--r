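vcf_tmp <- function(rows, contigs = NULL) {
  write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    if (!is.null(contigs)) paste0("##contig=<ID=", contigs, ">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    rows
  ), ".vcf")
}

test_that("read_vcf shifts coordinates, splits multi-allelics and checks REF", {
  g <- c(chr1 = "CCAGTTCCGG")
  p <- vcf_tmp(c("chr1\t101\t.\tA\tG\t.\tPASS\t.",
                 "chr1\t3\t.\tA\tG,T\t.\tPASS\t."))
  v <- read_vcf(p)
  expect_equal(nrow(v), 3)
  expect_equal(v$start[1], 100L)  # 1-based in, 0-based internal
  expect_equal(v$alt[2:3], c("G", "T"))

  p2 <- vcf_tmp("chr1\t3\t.\tA\tG\t.\tPASS\t.")
  expect_equal(nrow(read_vcf(p2, genome = g)), 1)
  p3 <- vcf_tmp("chr1\t3\t.\tT\tG\t.\tPASS\t.")
  expect_error(read_vcf(p3, genome = g), "chr1:3")
})

test_that("variants are left-normalized through repeat tracts", {
  g <- c(chr1 = "CCATTTTTGGC")
  # deletion of one T written at the right edge of the homopolymer
  v <- tibble::tibble(variant_id = "x", chrom = "chr1", pos = 7L, start = 6L,
                      ref = "TT", alt = "T")
  nv <- normalize_variants(v, g)
  expect_equal(nv$pos, 3L)
  expect_equal(c(nv$ref, nv$alt), c("AT", "A"))
  # shared-suffix MNV trims to an SNV
  v2 <- tibble::tibble(variant_id = "y", chrom = "chr1", pos = 2L, start = 1L,
                       ref = "CAT", alt = "CGT")
  nv2 <- normalize_variants(v2, g)
  expect_equal(nv2$pos, 3L)
  expect_equal(c(nv2$ref, nv2$alt), c("A", "G"))
})

# hand-built single-exon plus-strand gene with a TAA-stopped ORF
taa_fixture <- function() {
  set.seed(61)
  orf_nt <- paste0("ATG", sense_codons(38), "TAA")
  genome <- c(chr1 = paste0(strrep("C", 25), orf_nt, strrep("C", 25)))
  ex <- toy_exons(starts = 0, ends = nchar(genome[[1]]))
  orfs <- predict_orfs(ex, genome)
  list(genome = genome, ex = ex, orfs = orfs)
}

test_that("stop and start edits map to the dedicated consequence terms", {
  fx <- taa_fixture()
  o <- fx$orfs
  stop0 <- o$t_start + 3 * (o$codon_count - 1)  # first base of TAA (t==g here)
  v <- tibble::tibble(
    variant_id = c("v_stoplost", "v_startlost", "v_fs", "v_inframe_ins"),
    chrom = "chr1",
    pos = c(stop0 + 1L, o$t_start + 1L, o$t_start + 10L, o$t_start + 13L),
    ref = c("T", "A", substr(fx$genome[[1]], o$t_start + 10L, o$t_start + 10L),
            substr(fx$genome[[1]], o$t_start + 13L, o$t_start + 13L)),
    alt = c("C", "C", NA, NA)
  )
  v$alt[3] <- paste0(v$ref[3], "G")          # 1-nt insertion: frameshift
  v$alt[4] <- paste0(v$ref[4], "GGCCCT")     # 6-nt insertion: in-frame
  v$start <- v$pos - 1L
  calls <- annotate_variants(v, fx$orfs, fx$ex, fx$genome)
  got <- setNames(calls$consequence, calls$variant_id)
  expect_equal(got[["v_stoplost"]], "stop_lost")   # TAA -> CAA readthrough
  expect_equal(got[["v_startlost"]], "start_lost") # ATG -> CTG
  expect_equal(got[["v_fs"]], "frameshift")
  expect_equal(got[["v_inframe_ins"]], "inframe_insertion")
  expect_equal(unname(calls$impact[calls$consequence == "frameshift"]), "high")
})

test_that("a deletion spanning an exon-intron boundary is modifier-only", {
  set.seed(62)
  orf_nt <- paste0("ATG", sense_codons(38), "TAG")
  spl <- paste0(strrep("C", 12), orf_nt, strrep("C", 12))
  genome <- c(chr1 = paste0(substr(spl, 1, 50), random_dna(60),
                            substr(spl, 51, nchar(spl))))
  ex <- toy_exons(starts = c(0, 110), ends = c(50, 110 + nchar(spl) - 50))
  orfs <- predict_orfs(ex, genome)
  # deletion starting in exon 1 and reaching into the intron
  v <- tibble::tibble(
    variant_id = "del", chrom = "chr1", pos = 48L, start = 47L,
    ref = substr(genome[[1]], 48, 55), alt = substr(genome[[1]], 48, 48))
  calls <- annotate_variants(v, orfs, ex, genome)
  expect_equal(calls$consequence, "non_orf")
  expect_equal(calls$impact, "modifier")
  expect_equal(calls$note, "exon_boundary")
  # purely intronic SNV: non_orf, intronic note
  v2 <- tibble::tibble(variant_id = "int", chrom = "chr1", pos = 80L,
                       start = 79L, ref = substr(genome[[1]], 80, 80),
                       alt = "A")
  if (v2$ref == "A") v2$alt <- "C"
  c2 <- annotate_variants(v2, orfs, ex, genome)
  expect_equal(c2$consequence, "non_orf")
  expect_equal(c2$note, "intronic")
})

test_that("planted fixture variants reproduce their designed consequences", {
  fix <- simulate_orfeome(seed = 7, n_genes = 12)
  calls <- annotate_variants(fix$variants, fix$orfs, fix$exons, fix$genome,
                             proteins = fix$proteins)
  chk <- dplyr::left_join(fix$truth$variants, calls,
                          by = c("variant_id", "orf_id"),
                          suffix = c(".want", ".got"))
  expect_false(anyNA(chk$consequence.got))
  expect_equal(chk$consequence.got, chk$consequence.want)
  expect_equal(chk$impact.got, chk$impact.want)
})

test_that("one variant yields independent per-frame calls on overlapping ORFs", {
  fix <- simulate_orfeome(seed = 7, n_genes = 12)
  calls <- annotate_variants(fix$variants, fix$orfs, fix$exons, fix$genome)
  dual <- fix$truth$variants |>
    dplyr::count(variant_id) |>
    dplyr::filter(n == 2)
  expect_gte(nrow(dual), 1)
  for (vid in dual$variant_id) {
    sub <- calls[calls$variant_id == vid &
                   calls$consequence != "non_orf", ]
    expect_equal(nrow(sub), 2)       # both frames reported, never collapsed
    expect_equal(dplyr::n_distinct(sub$consequence), 2)
  }
})

test_that("random variants match the mutate-resplice-retranslate oracle", {
  fix <- simulate_orfeome(seed = 13, n_genes = 12)
  set.seed(63)
  ex_by_tx <- split(fix$exons, fix$exons$transcript_id)
  n_checked <- 0L
  for (rep in 1:60) {
    o <- fix$orfs[sample(nrow(fix$orfs), 1), ]
    ex_tx <- ex_by_tx[[o$transcript_id]]
    chrom <- o$chrom
    # random position inside the transcript span (may hit intron/UTR/ORF)
    lo <- min(ex_tx$start); hi <- max(ex_tx$end)
    g0 <- sample(lo:(hi - 5L), 1)
    ref_len <- sample(c(1, 1, 1, 2, 4), 1)
    ref <- substr(fix$genome[[chrom]], g0 + 1L, g0 + ref_len)
    alt <- if (ref_len == 1 && runif(1) < 0.7) {
      sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    } else if (runif(1) < 0.5) {
      paste0(substr(ref, 1, 1), paste(sample(c("A", "C", "G", "T"),
                                             sample(1:3, 1), replace = TRUE),
                                      collapse = ""))
    } else substr(ref, 1, 1)
    if (alt == ref) next
    v <- tibble::tibble(variant_id = paste0("r", rep), chrom = chrom,
                        pos = g0 + 1L, start = g0, ref = ref, alt = alt)
    calls <- annotate_variants(v, fix$orfs, fix$exons, fix$genome)
    got <- calls[calls$orf_id == o$orf_id & calls$transcript_id == o$transcript_id, ]
    if (nrow(got) != 1) next
    want <- oracle_consequence(fix$genome, ex_tx, o, chrom, g0 + 1L, ref, alt)
    expect_equal(got$consequence, want, info = paste("rep", rep))
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 40)
})

test_that("impact summaries take the per-variant worst and tally by class", {
  calls <- tibble::tibble(
    variant_id = c("v1", "v1", "v2", "v3"),
    impact = c("low", "high", "modifier", "moderate"),
    consequence = c("synonymous", "frameshift", "non_orf", "missense"),
    class = c("refprot", "altprot", "refprot", "novel_isoform")
  )
  s <- summarize_impacts(calls)
  pv <- setNames(s$per_variant$worst_impact, s$per_variant$variant_id)
  expect_equal(pv[["v1"]], "high")
  expect_equal(pv[["v2"]], "modifier")
  expect_equal(s$tally$n[s$tally$class == "altprot" & s$tally$impact == "high"],
               1L)
})
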