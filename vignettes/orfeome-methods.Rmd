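---
title: "Methods: alternative ORF annotation, evidence aggregation and variant effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alternative ORF annotation, evidence aggregation and variant effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfeome)
```

## The problem

Conventional genome annotation assigns one coding ORF per mRNA and none to
"non-coding" RNAs. Proteomic and ribosome-profiling evidence shows
translation of additional ORFs — in UTRs, in reading frames overlapping the
canonical ORF, and in lncRNAs and pseudogene transcripts. `orfeome`
implements the computational core needed to work with this extended
proteome: exhaustive ORF enumeration, a three-class protein taxonomy,
evidence aggregation, functional post-filters, multi-ORF variant-effect
prediction, and expression-ranked custom protein databases.

## Coordinate conventions

All internal coordinates are 0-based half-open. GFF3/GTF (1-based inclusive)
are converted at the parser, BED is written natively 0-based, VCF positions
(1-based) are converted at the reader. Chromosome names tolerate a `chr`
prefix mismatch between annotation and genome; the genome FASTA's spelling
is canonical. Exon tables carry a 5'→3' `rank`, so minus-strand transcripts
list their genomically rightmost exon first, and the transcript↔genome
coordinate maps are mutual inverses over the spliced length (a property the
test suite checks exhaustively on random transcripts).

Two annotation sources can be pooled. No public join rule exists for
Ensembl-style and RefSeq-style gene sets, so the package uses an explicit
convention: two genes are the same gene when their names match or when their
genomic spans overlap on the same strand; transcripts of matched genes pool
under the first source's identifiers. This is a design choice of this
package, documented here because results downstream (gene-local isoform
classification) depend on it.

## ORF model

An ORF runs from a start codon to the first in-frame stop codon; the stop is
required and included in the codon count. The minimum size is 30 codons
(protein ≥ 29 aa), a sharp threshold — 29-codon ORFs are dropped — and there
is no maximum. RNA biotype is never consulted. Defaults that matter:

| parameter | default | meaning |
|---|---|---|
| `min_codons` | 30 | minimum ORF size, stop codon included |
| `start_codons` | `ATG` | start codon set; near-cognate starts can be added |
| `all_starts` | `FALSE` | report nested in-frame starts as separate ORFs |

With `all_starts = FALSE` one ORF is reported per (frame, stop): the most 5'
start wins. This keeps the ORFeome tractable; nested starts remain available
as an option because ribosome profiling regularly supports internal
initiation. Codons containing `N` abort the ORF they would belong to rather
than fabricating amino acids: for each stop, only starts downstream of the
last intervening `N` are eligible.

Identical protein sequences are collapsed into one record carrying every
encoding ORF, transcript and gene; a protein encoded at more than one gene is
flagged `multi_locus`. Record order (chromosome, first genomic block,
sequence) fixes accession numbering, so re-runs and row-shuffled inputs mint
identical accessions.

## Protein taxonomy

Classification is gene-local. Exact sequence identity to any reference entry
makes a `refprot` (keeping the source accession; a cross-locus note is added
when no gene is shared, so one sequence never gets two accessions).
Otherwise the protein is aligned (Smith–Waterman, BLOSUM62, gap open 11 /
extend 1, via `Biostrings::pairwiseAlignment`) against every reference
protein of its own gene(s): identity ≥ 0.80 over an aligned region covering
≥ 0.50 of the shorter sequence makes a `novel_isoform`, anything else an
`altprot`. The similarity thresholds quantify "substantial similarity",
which has no published numeric definition; they are explicit arguments,
recorded in output metadata, and swept in the tests (a constructed
60%-identity homolog flips between classes as the threshold crosses its
identity). Identity is computed over the alignment length including gaps;
coverage guards against classifying on short perfect islands, which random
sequences produce routinely. The test suite checks the alignment engine
against an independent quadratic affine-gap DP: scores agree exactly;
identity is compared with a small tolerance because co-optimal alignments
may differ by a residue between engines.

`promote_to_reference()` reclassifies proteins whose sequence enters a newer
reference release and reports the transition counts — the mechanism by which
predicted proteins graduate into standard databases.

## Evidence model

The FDR filter sorts PSMs by score and, at each candidate threshold
(accepting all PSMs scoring at least that value), estimates
FDR = #decoys/#targets among the accepted; it returns the targets of the
most permissive threshold with FDR strictly below the cap (default
`1e-4`, i.e. < 0.01%). This is defined at the PSM level; the cap is an
argument. The filter is checked against exhaustive threshold enumeration and
is monotone in the cap.

Peptide uniqueness: a peptide supports a protein only when it occurs as a
substring of exactly one predicted protein; for altprots and novel isoforms
it must additionally be absent from every reference proteome sequence.
Isoleucine and leucine are collapsed before matching because they are
isobaric and indistinguishable by standard MS — this is common proteomics
practice, and switchable (`il_equivalent = FALSE`).

Detection requires ≥ 2 unique peptides, or 1 unique peptide plus ≥ 1
ribo-seq detection (ribo-seq detections are consumed as per-protein counts
from a table; no read processing happens here). A transcript with ≥ 2
detected proteins is multi-coding.

## Functional post-processing

Disorder profiles (per-residue propensities or 0/1 flags) binarize at 0.5;
flags pass through unchanged. IDRs are maximal runs of ≥ 29 consecutive
disordered residues — 29 rather than the more common 30 because the
shortest proteins in the resource are 29 residues long, and the boundary is
sharp. SLiM matches are retained only when every residue of the span is
disordered. pLDDT bins: very_high (> 90), high (70, 90], medium (50, 70],
very_low (≤ 50). The quoted confidence bands leave boundary membership
undecidable ("90 > pLDDT > 70"), so boundaries go to the lower bin, and the
medium bin is a package convention for the unnamed 50–70 interval.
Predictor routing sends proteins with MSA depth < 30 sequences to a
single-sequence (OmegaFold-like) predictor, ≥ 30 to an MSA-based
(AlphaFold-like) one; the boundary sits at exactly 30. None of the upstream
predictors run here — this module consumes their tabular outputs and
implements the decision rules over them.

## Variant effects

Variants are left-normalized (shared suffix/prefix trim, then left shift of
pure indels through repeat tracts). For every ORF of every transcript the
variant overlaps, the edit is applied to the spliced transcript sequence and
the ORF re-translated from its start: unchanged protein → synonymous;
residue substitutions → missense; a new upstream stop → stop_gained; a
destroyed stop → stop_lost (translation resumes to the next in-frame stop;
a note marks the case where none exists before the transcript end); a
destroyed start → start_lost; length changes not divisible by 3 →
frameshift, divisible → in-frame insertion/deletion. Calls are independent
per ORF — one SNV is routinely synonymous in one frame and missense in an
overlapping frame, and both calls are always reported. The
consequence→impact table (synonymous→low; missense and in-frame
indels→moderate; stop/start/frameshift→high; non-ORF→modifier) follows the
convention used by mainstream variant annotators; the four class names are
fixed vocabulary. Variants in introns or spanning an exon–intron boundary
are modifier-only with a note: no splice-disruption model is attempted, as
there is no computable rule to implement. The annotator is validated against
an independent oracle that mutates the genome, shifts exon coordinates,
resplices and retranslates.

## Custom databases

Transcripts pass include/exclude lists (the include list is a whitelist
restriction; lists overriding the expression threshold is the point of
having them) and a TPM floor, rank by TPM descending with lexicographic tie
breaks, and are admitted whole — a transcript's reference proteins plus the
variant isoforms of its ORFs (moderate/high coding consequences only;
synonymous changes add no sequence) enter together or not at all, stopping
before the first transcript that would exceed `max_proteins`
(default 100 000). Whole-transcript admission reflects that the cap is meant
to restrict the number of *transcripts* accordingly; variant entries count
toward the cap because every FASTA entry inflates the search space the cap
exists to control. Output is deterministic to the byte. Whether a real
search database should contain variant+reference or variant-only entries is
unsettled; both sequences are emitted here, and the variant entries are
tagged in header and manifest so either subset is easy to extract.

## Synthetic fixtures: what they do and do not show

`simulate_orfeome()` builds a mini-genome whose transcripts carry exactly
their planted ORFs. The trick is alphabet control: planted ORF bodies use
only sense codons free of adenine, UTR/filler sequence uses {C,G,T}, starts
are ATG and stops TAG — since every start and stop codon requires an A, no
reading frame contains an unplanned start or stop, in any frame, across any
junction. Overlapping-ORF pairs are built by overwriting a start and stop
into a shifted frame of a host ORF and re-validating (with bounded retries).
The generator plants all three protein classes (reference proteins emitted
into the reference FASTA; novel isoforms as 10-codon internal deletions of a
reference protein; altprots with an unrelated same-gene reference), lncRNA
and pseudogene biotypes, multi-isoform and duplicated-locus proteins,
evidence plans spanning the detection truth table, disorder runs at both
sides of the 29-residue boundary, pLDDT/MSA values at every bin boundary,
expression with planted ties, and variants designed for each consequence
term on both strands, including one SNV with divergent consequences in two
overlapping frames.

Sizes used by the shipped checks: the test suite runs the scanner against a
brute-force oracle on 1000 random sequences of 90–3000 nt, coordinate round
trips on 1000 random multi-exon transcripts, 500 random PSM sets, 1000
random disorder profiles, 500+ random variants (including 50+ with
divergent per-frame consequences), and a 180-gene fixture with 200+ planted
ORFs; the acceptance script uses a 120-gene fixture. These sizes keep the
full suite in the low minutes on one CPU while exercising every rule at its
boundary.

What passing these tests shows: the scanning, mapping, filtering, ranking
and re-translation rules are implemented exactly, with sharp boundaries and
deterministic output. What it does not show: behavior on real genome scale
(repeats, overlapping genes, megabase chromosomes), real MS score
distributions (fixture decoys are reversed peptides with planted score
ranges), real disorder predictors, or splice-variant biology — the fixture
has no alternative splicing beyond isoforms sharing an ORF, and the variant
model deliberately excludes splice disruption.

## Numerical and degenerate-input choices

Ties in PSM scores are accepted or rejected together (thresholds are defined
on score values, not ranks). An all-decoy PSM set yields an empty result.
Proteins with no same-gene reference skip alignment entirely. Empty ORF
sets, empty SLiM lists and zero-row variant tables flow through with typed
empty tibbles. The config hash excludes the output directory, so re-runs
into different directories are comparable; everything else in the
configuration is hashed into every output header.

## Known limitations

* Splice-site disruption and UTR effects on other transcripts are
  modifier-only by design.
* Near-cognate starts are supported but unscored (no Kozak/initiation-site
  model).
* The novel-isoform similarity thresholds are conventions, not estimates;
  sensitivity to them should be reported with any downstream analysis.
* Peptide uniqueness uses exact (I/L-collapsed) substring matching; it does
  not model missed cleavages or modified residues.
* `classify_proteins()` aligns candidate pairs serially; for full-genome
  inputs a batched aligner would be needed.
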