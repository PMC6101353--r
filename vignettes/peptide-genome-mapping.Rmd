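---
title: "Methods: mapping identified peptides onto genome coordinates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping identified peptides onto genome coordinates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepmap)
```

## Problem statement

Mass-spectrometry proteomics reports peptide sequences; genome browsers
display coordinates. `pepmap` bridges the two: for each identified peptide
it locates every occurrence in a translated-protein database, converts the
residue range of each occurrence into spliced genomic blocks using the gene
annotation, classifies how gene-specific the peptide is, and serialises the
result in browser formats (BED12, PTM BED pair, GTF, GCT, track hub).

The annotation GTF and the protein FASTA must come from the same release:
transcripts are joined on the version-stripped transcript identifier, and a
run with zero joins aborts with an error rather than silently mapping
nothing.

## Coordinate model

Three coordinate systems are in play and the conversions are done exactly
once each:

* **GTF** is 1-based, inclusive. At parse time every CDS feature becomes
  0-based half-open (`start-1`, `end`), and the segments of a transcript
  are stored in *translation order* — ascending genomic position on the
  `+` strand, descending on `-`. This single invariant makes everything
  downstream strand-agnostic.
* **Residues** are 1-based inclusive. A residue range `(a1, a2)` becomes a
  coding-nucleotide interval `[(a1−1)·3, a2·3)` by pure codon arithmetic.
* **Genomic blocks** come from walking the translation-order segments,
  keeping a running offset, and slicing out the overlap of each segment
  with the coding interval. On the `-` strand each segment is consumed
  right-to-left (`end − offset` arithmetic). Blocks are returned sorted
  ascending — the BED/browser convention — and always sum to exactly
  `3 × (a2 − a1 + 1)` bases.

**CDS phase assumption (deliberate).** The GTF frame column is ignored and
phase 0 is assumed at the first CDS base. The translated FASTA is treated
as the residue-level ground truth, so any annotation whose protein sequence
matches its FASTA is mapped correctly; annotations with a nonzero initial
phase (e.g. fragmentary models) would be offset by one codon. This keeps
the transform a pure function of the CDS segments and is flagged at parse
time only indirectly: transcripts whose CDS length is not a multiple of 3
are kept with a warning, and residue ranges past the last full codon are
unmappable.

## Peptide search

The protein database is indexed by overlapping k-mers (default `k = 4`)
held in an environment hash of posting matrices `(protein, offset)`.
Searching with up to `m` mismatches (`m ≤ 2`) uses the pigeonhole
principle: the peptide is split into `m + 1` near-equal parts; any match
with at most `m` substitutions must contain at least one exact part, so
each part is looked up in the index and every candidate alignment is
verified by a vectorised Hamming comparison of the full peptide.

Choices and their rationale:

* `k = 4` balances index size against posting-list length for typical
  proteome alphabets; with tryptic peptides of length ≥ 7 even the
  two-mismatch split leaves parts of length ≥ 2–3, and any part shorter
  than `k` triggers a direct scan of all proteins. Correctness never
  depends on the index: the fallback and the indexed path return identical
  results, and the test suite checks both against a brute-force scanner.
* Ambiguous protein residues (`X`, `B`, `Z`, `U`) never match a peptide
  residue; they simply consume mismatch budget. This is conservative: an
  `X` is evidence of absence of sequence, not a wildcard.
* Isoleucine/leucine equivalence (mass-identical residues) is off by
  default and implemented in the direct-scan path only, because indexing
  under an equivalence relation would complicate the posting lists for a
  mode that changes identification semantics and should be an explicit
  user decision.

**Staged mapping.** Allowing mismatches globally would let a variant
peptide also match its reference paralog and inflate multi-mapping.
`staged_mapping()` therefore maps everything at 0 mismatches first,
subtracts the mapped plain sequences, and re-searches only the remainder
at 1 (then optionally 2) mismatches. The stages partition the peptide set;
a peptide mapped at stage *s* is never re-mapped later.

## Uniqueness and colours

Hits are collapsed to genomic loci keyed by (chromosome, strand, block
structure), so the same locus reached through several transcripts counts
once. The tier is then a function of the peptide's complete locus set:

| tier | meaning | itemRgb |
|---|---|---|
| `unique_transcript` | one gene, one transcript | 255,0,0 |
| `unique_gene` | one gene, several transcripts | 0,0,0 |
| `multi_gene` | more than one gene | 128,128,128 |

This is a *per-peptide-set* property, not per-hit: a single BED line for a
multi-gene peptide is grey even though that one line sits in one gene,
because the colour answers "can this peptide alone support this gene?".

## Output encodings

* **BED score** is `min(1000, PSMs × 200)`, i.e. 5 spectra saturate the
  scale. BED scores are capped at 1000 by the format; the ×200 gain keeps
  single-PSM identifications visible (score 200) while letting browsers'
  score-based shading separate 1–5 PSMs, the range where spectral counts
  are actually informative.
* **PTM BED pair.** For each modification type on a peptide, the thick
  region spans the codons of the first through last modified residue,
  projected through the same spliced transform and clipped to the
  peptide's span. Unmodified peptides are written to a `_noptm.bed`
  companion with `thickStart = thickEnd = chromStart` (the BED idiom for
  "no thick region"), so the pair partitions the mapped peptides.
* **GCT** (`#1.2`) has one row per (mapping, block), named
  `peptide@chrom:start-end(strand)`, so per-exon-chunk quantitation can be
  loaded into matrix tools; duplicate names get a `#k` suffix to keep rows
  unique. Columns are the samples in first-appearance order.
* **GTF output** writes one `transcript` feature per mapping and one
  `exon` per block, with attributes recording peptide, gene and transcript
  ids, uniqueness and mismatch count.
* **Track hub**: `hub.txt` → `genomes.txt` → `<assembly>/trackDb.txt`
  referencing `bigBed 12` tracks. Conversion to bigBed requires the
  external `bedToBigBed` binary; the writer only emits text and exposes an
  optional converter hook, disabled by default, so the package stays
  dependency-free and deterministic.

All writers are byte-deterministic: lines are sorted by (chrom, start,
end, name), loci by their structural key, and numbers are formatted with
fixed rules (`format(..., scientific = FALSE, digits = 15)`).

## The fixture generator as a study model

`generate_fixture()` builds a self-consistent miniature study from a seed:
stop-codon-free random CDS (ATG first), a genome assembled by overwriting
background sequence with the (reverse-complemented, on `-`) CDS chunks,
multi-exon and minus-strand transcripts, a duplicated gene (to plant
`multi_gene` peptides), genes with several identical-CDS transcripts (to
plant `unique_gene`), junction-spanning peptides, single-substitution
variants, and `RESIDUE(tag)` modifications. The defaults — seed 42, 20
genes, 200 peptides, 20 % junction-spanning, 10 % variants, 10 %
modified — are the package's own study conditions; they were chosen before
the mapper was finished and are not tuned to it.

Ground truth is computed by independent code paths: a per-nucleotide
position map for coordinates and a character-level brute-force scan for
occurrences, so a shared bug between generator and mapper would have to be
implemented twice in different idioms.

**What passing the suite does and does not show.** It shows the transform
agrees with a per-base oracle on thousands of random exon structures, the
search equals brute force at 0–2 mismatches, and the pipeline recovers
100 % of planted loci with correct tiers and stages on generated data. It
does *not* exercise real-annotation pathologies: nonzero CDS phases,
selenocysteine recoding, trans-splicing, chromosome-name dialect
mismatches between GTF and FASTA, or proteome-scale performance. Problem
sizes in the tests (50 proteins × 200–500 aa for the search oracle, 1,000
random transcripts for the transform) were picked to exercise every branch
within a minutes-scale budget, not to benchmark.

## Reproduction

```sh
Rscript scripts/acceptance.R --seed 42 --out results.json
```

writes the main computed quantities (per-stage mapped counts, ground-truth
agreement, tier counts, round-trip translation identity, format-validity
counts, and a repeat-run byte-identity flag) as JSON numbers; every random
choice derives from `--seed`.
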