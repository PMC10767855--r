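# Minimal protein-table builder (bypasses ORF prediction for speed).
prot_row <- function(sequence, genes = "G1", gene_names = genes,
                     chrom = "chr1", g_start = 0L, transcripts = "t1") {
  tibble::tibble(
    sequence = sequence, length = nchar(sequence),
    orf_ids = list(paste0(transcripts[1], ":0-", 3 * (nchar(sequence) + 1))),
    transcripts = list(transcripts), genes = list(genes),
    gene_names = list(gene_names), chrom = chrom, g_start = g_start,
    n_orfs = 1L, multi_locus = length(unique(genes)) > 1L
  )
}

ref_tbl <- function(...) {
  rows <- list(...)
  tibble::tibble(
    ref_accession = vapply(rows, `[[`, character(1), 1),
    gene = vapply(rows, `[[`, character(1), 2),
    sequence = vapply(rows, `[[`, character(1), 3)
  )
}

test_that("exact sequence identity always yields refprot with the source accession", {
  set.seed(31)
  p <- random_protein(80)
  ref <- ref_tbl(list("REFX", "G1", p))
  got <- classify_proteins(prot_row(p), ref)
  expect_equal(got$class, "refprot")
  expect_equal(got$best_ref_hit, "REFX")
  # irrespective of thresholds
  got2 <- classify_proteins(prot_row(p), ref, id_threshold = 1,
                            cov_threshold = 1)
  expect_equal(got2$class, "refprot")
  # exact match to a different gene's reference: refprot with cross-locus note
  got3 <- classify_proteins(prot_row(p, genes = "G9"), ref)
  expect_equal(got3$class, "refprot")
  expect_equal(got3$note, "cross_locus_exact_match")
})

test_that("an internal deletion of a same-gene reference is a novel isoform", {
  set.seed(32)
  q <- random_protein(200)
  p <- paste0(substr(q, 1, 100), substr(q, 111, 200))  # 10-residue deletion
  ref <- ref_tbl(list("REFQ", "G1", q))
  got <- classify_proteins(prot_row(p), ref)
  expect_equal(got$class, "novel_isoform")
  expect_equal(got$best_ref_hit, "REFQ")
  expect_gt(got$identity, 0.8)
  expect_gt(got$coverage, 0.5)
})

test_that("a protein without same-gene similarity is an altprot", {
  set.seed(33)
  ref <- ref_tbl(list("REFQ", "G1", random_protein(150)))
  got <- classify_proteins(prot_row(random_protein(40)), ref)
  expect_equal(got$class, "altprot")
})

test_that("gene-locality: similarity to another gene's reference never makes an isoform", {
  set.seed(34)
  q <- random_protein(150)
  p <- paste0(substr(q, 1, 70), substr(q, 81, 150))
  ref <- ref_tbl(list("REFQ", "G1", q))
  got <- classify_proteins(prot_row(p, genes = "G2", gene_names = "G2"), ref)
  expect_equal(got$class, "altprot")
})

test_that("identity thresholds sweep a 60%-identity homolog between classes", {
  set.seed(35)
  q <- random_protein(120)
  p <- q
  mut <- sample(120, 48)  # ~60% identity left
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in mut) {
    substr(p, i, i) <- sample(setdiff(aa, substr(q, i, i)), 1)
  }
  ref <- ref_tbl(list("REFQ", "G1", q))
  # verify the construction with the independent DP oracle
  ora <- oracle_local_align(p, q)
  expect_lt(ora$identity, 0.8)
  expect_gt(ora$identity, 0.5)
  low <- classify_proteins(prot_row(p), ref, id_threshold = 0.5)
  high <- classify_proteins(prot_row(p), ref, id_threshold = 0.8)
  expect_equal(low$class, "novel_isoform")
  expect_equal(high$class, "altprot")
})

test_that("every protein gets exactly one class and counts sum to the total", {
  set.seed(36)
  q <- random_protein(100)
  ref <- ref_tbl(list("R1", "G1", q))
  prot <- dplyr::bind_rows(
    prot_row(q),
    prot_row(paste0(substr(q, 1, 50), substr(q, 61, 100))),
    prot_row(random_protein(45), genes = "G2")
  )
  got <- classify_proteins(prot, ref)
  expect_true(all(got$class %in% c("refprot", "novel_isoform", "altprot")))
  expect_equal(sum(table(got$class)), nrow(prot))
})

test_that("alignment identity agrees with an independent quadratic DP", {
  set.seed(37)
  for (rep in 1:25) {
    n1 <- sample(40:120, 1); n2 <- sample(40:120, 1)
    a <- random_protein(n1)
    b <- if (rep %% 2 == 0) random_protein(n2) else {
      # related pair: mutate a few residues so a real alignment exists
      x <- a
      for (i in sample(n1, max(1, n1 %/% 10))) substr(x, i, i) <- "A"
      x
    }
    got <- align_similarity(a, b)
    want <- oracle_local_align(a, b)
    expect_equal(got$score, want$score, info = paste("rep", rep))
    # co-optimal alignments can differ by a residue or two between engines,
    # which moves identity by up to ~1/alignment-length on the short
    # alignments random pairs produce
    expect_lt(abs(got$identity - want$identity), 0.15)
  }
})

test_that("accession minting is deterministic and order-independent", {
  set.seed(38)
  prot <- dplyr::bind_rows(
    prot_row(random_protein(40), chrom = "chr2", g_start = 10L),
    prot_row(random_protein(41), chrom = "chr1", g_start = 500L),
    prot_row(random_protein(42), chrom = "chr1", g_start = 20L)
  )
  ref <- ref_tbl(list("R1", "GX", random_protein(60)))
  m1 <- mint_accessions(classify_proteins(prot, ref))
  expect_equal(m1$accession,
               c("IP_000001", "IP_000002", "IP_000003"))
  expect_equal(m1$g_start, c(20L, 500L, 10L))  # genomic order
  # shuffled input: identical accession per sequence
  m2 <- mint_accessions(classify_proteins(prot[c(3, 1, 2), ], ref))
  expect_equal(m2$accession[match(m1$sequence, m2$sequence)], m1$accession)
  # II_ and IP_ prefixes match classes
  q <- random_protein(100)
  prot2 <- dplyr::bind_rows(
    prot_row(paste0(substr(q, 1, 50), substr(q, 61, 100))),
    prot_row(random_protein(45)))
  m3 <- mint_accessions(classify_proteins(prot2, ref_tbl(list("R1", "G1", q))))
  expect_true(startsWith(m3$accession[m3$class == "novel_isoform"], "II_"))
  expect_true(startsWith(m3$accession[m3$class == "altprot"], "IP_"))
})

test_that("promotion against a newer reference reports transitions", {
  set.seed(39)
  seqs <- replicate(5, random_protein(50))
  prot <- dplyr::bind_rows(lapply(seq_along(seqs), function(i) {
    prot_row(seqs[i], g_start = 10L * i)
  }))
  ref0 <- ref_tbl(list("R0", "GZ", random_protein(70)))
  cur <- mint_accessions(classify_proteins(prot, ref0))
  expect_true(all(cur$class == "altprot"))
  new_ref <- ref_tbl(list("NEW1", "G1", seqs[2]), list("NEW2", "G3", seqs[4]))
  res <- promote_to_reference(cur, new_ref)
  expect_equal(res$report$transition, "altprot->refprot")
  expect_equal(res$report$n, 2L)
  expect_equal(sum(res$proteins$class == "refprot"), 2L)
  expect_setequal(res$proteins$accession[res$proteins$class == "refprot"],
                  c("NEW1", "NEW2"))
  # empty delta: empty report
  res2 <- promote_to_reference(cur, ref0)
  expect_equal(nrow(res2$report), 0L)
})
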