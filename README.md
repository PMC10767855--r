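# orfeome

Alternative open reading frame (AltORF) annotation and proteogenomic
database construction in R.

Standard genome annotations assume one protein-coding ORF per mRNA — usually
the longest — and no coding potential in "non-coding" RNAs. Proteomics and
ribosome profiling keep contradicting both assumptions: many transcripts
translate additional ORFs in UTRs, in frames overlapping the reference ORF,
or in RNAs labeled non-coding. `orfeome` is for proteogenomics practitioners
who need those proteins in their search space: it enumerates the complete
ORFeome of an annotated genome, classifies the predicted proteins, attaches
mass-spectrometry and ribo-seq evidence, and builds capped, sample-specific
protein FASTA databases.

## What it computes

**ORF enumeration.** Every transcript (any biotype) is scanned in all three
reading frames. An ORF runs from a start codon (default ATG) to the first
in-frame stop, which is required and counted: the minimum size is **30 codons
including the stop** (protein length ≥ 29 aa), with no upper bound. Within
one frame and one stop only the most 5' start is reported (nested starts are
available via `all_starts`).

**Three-class protein taxonomy.** Each deduplicated protein is classified
against a reference proteome:

* `refprot` — exact match to a reference protein (source accession kept);
* `novel_isoform` (accession `II_…`) — unannotated protein with substantial
  similarity to a reference protein *of the same gene* (Smith–Waterman,
  BLOSUM62, gap 11/1; identity ≥ 0.80 over ≥ 0.50 of the shorter sequence,
  both tunable);
* `altprot` (accession `IP_…`) — unannotated protein without such similarity.

**Expression evidence.** PSMs pass a target-decoy FDR filter
(FDR < 0.01% by default, i.e. `#decoys/#targets < 1e-4` at the most
permissive score threshold). A peptide supports a protein only if it occurs
in exactly one predicted protein and — for altprots/novel isoforms — in no
reference protein (I/L treated as equivalent). A protein is *detected* with
≥ 2 unique peptides, or 1 unique peptide plus ≥ 1 ribo-seq detection;
transcripts with ≥ 2 detected proteins are flagged multi-coding.

**Functional post-processing.** IDRs are maximal runs of ≥ 29 consecutive
disordered residues; SLiM matches containing any ordered residue are
filtered out; pLDDT scores bin as very_high (> 90), high (70, 90],
medium (50, 70], very_low (≤ 50); proteins whose MSA has < 30 sequences
route to a single-sequence structure predictor.

**Variant effects across overlapping ORFs.** Each VCF variant is applied to
the spliced transcript sequence and re-translated independently for *every*
ORF of the transcript — a variant synonymous in one frame can be missense in
an overlapping frame, and both calls are reported. Impacts: synonymous → low;
missense/in-frame indel → moderate; stop gain/loss, start loss, frameshift →
high; outside any ORF → modifier.

**Custom databases.** Transcripts are ranked by TPM (ties lexicographic),
filtered by include/exclude lists, and admitted whole until the next
transcript would exceed the cap (default 100 000 entries). Variant proteins
with coding moderate/high consequences are emitted alongside the reference
sequence with suffixed accessions.

A deterministic synthetic mini-genome generator (`simulate_orfeome()`)
produces genome/GFF3/GTF/proteome/PSM/ribo/disorder/SLiM/structure/expression/
VCF fixtures with recorded ground truth, so the whole toolchain is testable
offline.

## Worked example

```r
library(orfeome)

d <- file.path(tempdir(), "demo")
fix <- simulate_orfeome(seed = 42, n_genes = 12, write_dir = d)

cfg <- orfeome_config(
  genome = file.path(d, "genome.fa"), gff = file.path(d, "annotation.gff3"),
  ref_proteome = file.path(d, "reference.fa"), out_dir = file.path(d, "out"),
  psm = file.path(d, "psms.tsv"), ribo = file.path(d, "ribo.tsv"),
  disorder = file.path(d, "disorder.tsv"), vcf = file.path(d, "variants.vcf"),
  expr = file.path(d, "expression.tsv"))
res <- run_pipeline(cfg)
res
#> <orfeome_run>
#>   transcripts: 13
#>   ORFs:        14
#>   proteins:    12 (altprot=7, novel_isoform=2, refprot=3)
#>   detected:    6
```

13 transcripts carry 14 qualifying ORFs that collapse to 12 distinct
proteins: 3 are already in the reference proteome, 2 are isoforms of a
same-gene reference protein (accessions `II_000001`, `II_000002`) and 7 are
alternative proteins (`IP_…`). Six proteins meet the two-peptide /
peptide-plus-ribo-seq evidence level:

```r
head(tidy(res), 3)
#>   accession class         gene    length n_orfs multi_locus unique_peptides
#> 1 II_000001 novel_isoform GENE002    110      1 FALSE                     2
#> 2 REF_004   refprot       GENE004     47      1 FALSE                     1
#> 3 IP_000001 altprot       GENE004     31      1 FALSE                     1

res$impacts$per_variant
#> chr2:324:T>C  -> low       (synonymous in the reference-frame ORF)
#> chr2:331:G>GG -> high      (1-nt insertion: frameshift)
#> chr1:982:T>C  -> moderate  (synonymous in one ORF, missense in the
#>                             overlapping frame: the worst call wins)
```

`autoplot(res$proteins)`, `autoplot(res$evidence)`,
`autoplot(res$variant_calls)` and `plot_plddt_bins(res$structure)` give
ggplot summaries; `glance(res)` returns the one-row run summary. A thin CLI
wraps the same functions:

```sh
exec/orfeome fixtures --seed 3 --n-genes 10 --out fix
exec/orfeome run --genome fix/genome.fa --gff fix/annotation.gff3 \
  --ref-proteome fix/reference.fa --psm fix/psms.tsv --vcf fix/variants.vcf \
  --expr fix/expression.tsv --out-dir out
```

## Further reading

The methods vignette (`vignettes/orfeome-methods.Rmd`) documents the model
and its assumptions, every tunable threshold, what the synthetic generator
does and does not emulate, and known limitations.
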