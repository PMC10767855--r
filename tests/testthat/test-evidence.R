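psm_tbl <- function(scores_t, scores_d) {
  tibble::tibble(
    peptide = paste0("PEP", seq_len(length(scores_t) + length(scores_d))),
    score = c(scores_t, scores_d),
    is_decoy = rep(c(FALSE, TRUE), c(length(scores_t), length(scores_d))),
    dataset = "ds"
  )
}

test_that("FDR filter accepts everything with zero decoys and respects the cutoff", {
  t_only <- psm_tbl(c(10, 5, 1), numeric(0))
  expect_equal(nrow(fdr_filter(t_only, 0.0001)), 3)

  x <- psm_tbl(c(10, 9, 8, 7, 6), 8.5)
  got <- fdr_filter(x, fdr_max = 0.25)
  want <- oracle_fdr(x, 0.25)
  expect_setequal(got$peptide, want$peptide)
  # just below the decoy FDR is 0; crossing it costs 1/3 > 0.25 until enough
  # further targets dilute it below the cap again at the bottom of the list
  expect_equal(fdr_filter(x, 0.3)$score, c(10, 9, 8, 7, 6))
  expect_equal(fdr_filter(x, 0.15)$score, c(10, 9))

  # fdr_max = 1 admits the whole list here (1 decoy / 5 targets = 0.2 < 1)
  expect_equal(nrow(fdr_filter(x, 1)), 5)

  all_decoy <- psm_tbl(numeric(0), c(3, 2))
  expect_equal(nrow(fdr_filter(all_decoy, 0.5)), 0)
})

test_that("FDR filter equals the exhaustive-threshold brute force and is monotone", {
  set.seed(41)
  for (rep in 1:120) {
    nt <- sample(3:40, 1); nd <- sample(0:15, 1)
    x <- psm_tbl(round(runif(nt, 0, 20), 1), round(runif(nd, 0, 20), 1))
    x <- x[sample(nrow(x)), ]
    cut1 <- runif(1, 0.01, 0.6)
    got <- fdr_filter(x, cut1)
    want <- oracle_fdr(x, cut1)
    expect_setequal(paste(got$peptide, got$score),
                    paste(want$peptide, want$score))
    # decoys never returned
    expect_false(any(got$is_decoy))
    # monotone: a looser cap never shrinks the accepted set
    got2 <- fdr_filter(x, min(1, cut1 * 2))
    expect_true(all(got$peptide %in% got2$peptide))
  }
})

test_that("peptide uniqueness requires a single predicted hit and no reference hit", {
  prot <- tibble::tibble(
    accession = c("IP_1", "IP_2", "REFA"),
    class = c("altprot", "altprot", "refprot"),
    sequence = c("MKVWREQSTPLN", "MGGHHYYTTRRW", "MAACCDDEEFFG")
  )
  ref <- tibble::tibble(ref_accession = "REFA", gene = "G1",
                        sequence = "MAACCDDEEFFG")
  counts <- function(peps) map_peptides(peps, prot, ref)$unique_peptides

  expect_equal(counts("KVWREQ"), c(1L, 0L, 0L))        # unique to IP_1
  expect_equal(counts("ACCDDEE"), c(0L, 0L, 1L))       # refprot keeps its own
  # present in an altprot and in the reference: counts for no protein at all
  prot2 <- prot; prot2$sequence[1] <- "MKVACCDDEEQQ"
  expect_equal(map_peptides("ACCDDEE", prot2, ref)$unique_peptides,
               c(0L, 0L, 0L))
  # shared between two predicted proteins: counts for neither
  prot3 <- prot
  prot3$sequence[2] <- paste0("MW", substr(prot3$sequence[1], 3, 8), "YyZ")
  expect_equal(map_peptides(substr(prot$sequence[1], 3, 8), prot3,
                            ref)$unique_peptides[1:2], c(0L, 0L))
})

test_that("isoleucine/leucine equivalence rejects near-identical peptides", {
  prot <- tibble::tibble(accession = "IP_1", class = "altprot",
                         sequence = "MKVIREQSTPWN")
  ref <- tibble::tibble(ref_accession = "R", gene = "G",
                        sequence = "GGGKVLREQSTGGG")  # I<->L twin inside
  expect_equal(map_peptides("KVIREQST", prot, ref)$unique_peptides, 0L)
  expect_equal(map_peptides("KVIREQST", prot, ref,
                            il_equivalent = FALSE)$unique_peptides, 1L)
})

test_that("peptide mapping is order-independent and idempotent", {
  set.seed(42)
  prot <- tibble::tibble(
    accession = paste0("IP_", 1:4), class = "altprot",
    sequence = replicate(4, random_protein(60)))
  ref <- tibble::tibble(ref_accession = "R", gene = "G",
                        sequence = random_protein(100))
  peps <- c(substr(prot$sequence[1], 5, 14), substr(prot$sequence[3], 20, 30))
  a <- map_peptides(peps, prot, ref)
  b <- map_peptides(rev(c(peps, peps)), prot, ref)  # duplicates count once
  expect_equal(a, b)
})

test_that("the detection truth table holds on the full grid", {
  for (p in 0:3) for (r in 0:3) {
    want <- (p >= 2) || (p >= 1 && r >= 1)
    expect_identical(evidence_call(p, r), want)
  }
  expect_error(evidence_call(-1, 0), "non-negative")
})

test_that("multi-coding flags require two detected proteins on one transcript", {
  prot <- tibble::tibble(
    accession = c("REFA", "IP_1", "IP_2"),
    class = c("refprot", "altprot", "altprot"),
    sequence = c("MAAA", "MBBB", "MCCC"),
    transcripts = list("t1", c("t1", "t2"), "t2")
  )
  ev <- tibble::tibble(
    accession = prot$accession,
    class = prot$class,
    unique_peptides = c(2L, 1L, 1L),
    riboseq_detections = c(0L, 1L, 0L),
    detected = evidence_call(c(2L, 1L, 1L), c(0L, 1L, 0L))
  )
  mc <- flag_multicoding(prot, ev)
  expect_true(mc$is_multicoding[mc$transcript_id == "t1"])   # REFA + IP_1
  expect_false(mc$is_multicoding[mc$transcript_id == "t2"])  # only IP_1 detected
  expect_setequal(mc$coding_proteins[mc$transcript_id == "t1"][[1]],
                  c("IP_1", "REFA"))
})

test_that("summarize_evidence fills missing counts with zero", {
  prot <- tibble::tibble(accession = c("A", "B"), class = "altprot",
                         sequence = c("MA", "MB"))
  ev <- summarize_evidence(prot,
                           tibble::tibble(accession = "A",
                                          unique_peptides = 2L),
                           ribo = NULL)
  expect_equal(ev$unique_peptides, c(2L, 0L))
  expect_equal(ev$riboseq_detections, c(0L, 0L))
  expect_equal(ev$detected, c(TRUE, FALSE))
})
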