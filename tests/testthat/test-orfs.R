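test_that("the 30-codon minimum (stop included) is a sharp boundary", {
  set.seed(3)
  ok <- paste0("ATG", sense_codons(28), "TAA")   # 30 codons
  hits <- find_orfs(ok)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$codon_count, 30)
  expect_equal(hits$t_end - hits$t_start, 90)
  expect_equal(nchar(translate_cds(substr(ok, 1, 87))), 29)

  short <- paste0("ATG", sense_codons(27), "TAA")  # 29 codons: dropped
  expect_equal(nrow(find_orfs(short)), 0)

  expect_equal(nrow(find_orfs("ATGAAATAA")), 0)  # 3 codons
})

test_that("ORFs require a stop codon and ignore nested in-frame starts by default", {
  set.seed(4)
  no_stop <- paste0("ATG", sense_codons(50))
  expect_equal(nrow(find_orfs(no_stop)), 0)

  nested <- paste0("ATG", sense_codons(10), "ATG", sense_codons(40), "TAA")
  hits <- find_orfs(nested)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$t_start, 0)  # most 5' start wins
  all_hits <- find_orfs(nested, all_starts = TRUE)
  expect_equal(nrow(all_hits), 2)
  expect_setequal(all_hits$t_start, c(0, 33))
})

test_that("start codon set is configurable", {
  set.seed(5)
  seq <- paste0("GTG", sense_codons(40), "TAA")
  expect_equal(nrow(find_orfs(seq)), 0)
  hits <- find_orfs(seq, start_codons = c("ATG", "GTG"))
  expect_equal(nrow(hits), 1)
})

test_that("translate_cds follows the standard code and rejects bad input", {
  expect_equal(translate_cds("ATGGCCTAA"), "MA")
  expect_equal(translate_cds("ATGTAA"), "M")
  expect_error(translate_cds("ATGTAAGCC"), "internal stop")
  expect_error(translate_cds("ATGG"), "divisible")
  expect_error(translate_cds("ATGNNNTAA"), "non-ACGT")
})

test_that("find_orfs agrees with the brute-force oracle on random sequences", {
  set.seed(42)
  for (rep in 1:150) {
    n <- sample(90:1200, 1)
    seq <- random_dna(n, p_n = if (rep %% 5 == 0) 0.01 else 0)
    min_c <- sample(c(2, 5, 30), 1)
    got <- as.data.frame(find_orfs(seq, min_codons = min_c))
    want <- oracle_orf_scan(seq, min_codons = min_c)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = paste("rep", rep))
  }
})

test_that("predict_orfs is blind to RNA biotype", {
  set.seed(6)
  genome <- c(chr1 = paste0(random_dna(40),
                            paste0("ATG", sense_codons(35), "TAG"),
                            random_dna(40)))
  ex <- toy_exons(starts = 0, ends = nchar(genome[[1]]))
  a <- predict_orfs(ex, genome)
  ex$biotype <- "lncRNA"
  b <- predict_orfs(ex, genome)
  expect_equal(a$t_start, b$t_start)
  expect_equal(a$protein, b$protein)
})

test_that("ORFs spanning introns carry correct genomic blocks", {
  set.seed(7)
  orf_nt <- paste0("ATG", sense_codons(38), "TAG")
  spl <- paste0(strrep("C", 10), orf_nt, strrep("C", 10))
  # split the spliced sequence at offset 60 with a 50 nt intron
  genome <- c(chr1 = paste0(substr(spl, 1, 60), random_dna(50),
                            substr(spl, 61, nchar(spl))))
  ex <- toy_exons(starts = c(0, 110), ends = c(60, 110 + nchar(spl) - 60))
  orfs <- predict_orfs(ex, genome)
  expect_equal(nrow(orfs), 1)
  b <- orfs$blocks[[1]]
  expect_equal(nrow(b), 2)
  expect_equal(sum(b$end - b$start), 3 * orfs$codon_count)
})

test_that("collapse_proteins deduplicates by sequence with full associations", {
  set.seed(8)
  orf_nt <- paste0("ATG", sense_codons(32), "TAG")
  genome <- c(chr1 = paste0(strrep("G", 20), orf_nt, strrep("G", 20),
                            orf_nt, strrep("G", 20)))
  L <- nchar(orf_nt)
  # two isoforms of one gene sharing locus 1, a second gene at locus 2
  ex <- dplyr::bind_rows(
    toy_exons(transcript_id = "t1", gene_id = "g1", starts = 20, ends = 20 + L),
    toy_exons(transcript_id = "t2", gene_id = "g1", starts = c(0, 20),
              ends = c(10, 20 + L)),
    toy_exons(transcript_id = "t3", gene_id = "g2", starts = 40 + L,
              ends = 40 + 2 * L)
  )
  prot <- collapse_proteins(predict_orfs(ex, genome))
  expect_equal(nrow(prot), 1)  # one distinct sequence
  expect_setequal(prot$transcripts[[1]], c("t1", "t2", "t3"))
  expect_setequal(prot$genes[[1]], c("g1", "g2"))
  expect_true(prot$multi_locus)
  expect_equal(prot$n_orfs, 3L)
})

test_that("BED12 output round-trips through an independent parser", {
  set.seed(9)
  orf_nt <- paste0("ATG", sense_codons(38), "TAG")
  spl <- paste0(strrep("C", 12), orf_nt, strrep("C", 12))
  genome <- c(chr1 = paste0(substr(spl, 1, 50), random_dna(70),
                            substr(spl, 51, nchar(spl))))
  ex <- toy_exons(starts = c(0, 120), ends = c(50, 120 + nchar(spl) - 50))
  orfs <- predict_orfs(ex, genome)
  path <- tempfile(fileext = ".bed")
  write_orf_bed(orfs, path)
  gr <- rtracklayer::import(path, format = "bed")
  expect_equal(length(gr), nrow(orfs))
  blk <- rtracklayer::blocks(gr)[[1]]
  want <- orfs$blocks[[1]]
  expect_equal(BiocGenerics::start(blk) - 1L, want$start)  # BED is 0-based
  expect_equal(BiocGenerics::end(blk), want$end)
  expect_equal(sum(BiocGenerics::width(blk)), 3 * orfs$codon_count[1])

  # single-exon ORF: one block, chromStart/chromEnd at the ORF span
  g2 <- c(chr1 = paste0("CCC", paste0("ATG", sense_codons(28), "TAA"),
                        "CCCC"))
  ex2 <- toy_exons(starts = 0, ends = nchar(g2[[1]]))
  o2 <- predict_orfs(ex2, g2)
  p2 <- tempfile(fileext = ".bed")
  write_orf_bed(o2, p2)
  f <- strsplit(readLines(p2), "\t")[[1]]
  expect_equal(as.integer(f[2]), 3)
  expect_equal(as.integer(f[3]), 93)
  expect_equal(as.integer(f[10]), 1)
})
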