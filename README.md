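# pepmap — peptide-to-genome mapping for proteogenomics

`pepmap` maps peptides identified by mass-spectrometry proteomics back onto
the genome they were transcribed from. Given a gene annotation (GTF), the
matching translated-protein FASTA, and a table of identified peptides, it
finds every protein occurrence of each peptide (optionally allowing one or
two amino-acid substitutions), converts the protein residue range into
spliced genomic coordinates, classifies how gene-specific each peptide is,
and writes standard genome-browser formats: BED12, a pair of
post-translational-modification (PTM) BED tracks, GTF, GCT quantitation
matrices, and a UCSC track-hub scaffold.

## The science in brief

Shotgun proteomics identifies peptides, not genes. To co-visualise peptide
evidence with genomic data (variants, RNA-seq coverage, annotation), every
peptide must be placed at the exact genomic bases that encode it. Two things
make this non-trivial:

1. **Splicing.** A peptide can span an exon–exon junction, so one peptide
   maps to several genomic blocks. The mapping walks the transcript's CDS
   segments in translation order (ascending genomic coordinates on the `+`
   strand, descending on `-`), converts the 1-based residue range to coding
   nucleotides by codon arithmetic (`(aa_start−1)·3` to `aa_end·3`), and
   slices those nucleotides out of the CDS structure. Blocks are reported in
   ascending genomic order, the browser convention, regardless of strand.
2. **Ambiguity.** Many peptides occur in several transcripts or genes.
   `pepmap` collapses identical genomic loci and then assigns each peptide a
   uniqueness tier over its *complete* mapping set: `unique_transcript`
   (one gene, one transcript; coloured red 255,0,0), `unique_gene` (one
   gene, several transcripts; black 0,0,0), or `multi_gene` (grey
   128,128,128). The tier is encoded as the BED itemRgb colour.

Peptide search uses a k-mer index over the protein database (default k = 4)
with a pigeonhole strategy for mismatched matching: a peptide searched with
*m* mismatches is split into *m*+1 parts, at least one of which must match
exactly; candidate positions are then verified by a full Hamming comparison.
Matching is literal — ambiguous protein residues (`X`, `B`, `Z`, `U`) never
match and count as mismatches; optional isoleucine/leucine equivalence is
available. Mapping is *staged*: peptides are first mapped exactly, and only
the unmapped remainder is re-searched at one (then optionally two)
mismatches, so a variant peptide can never shadow an exact match.

PTMs are read from a `RESIDUE(tag)` dialect (e.g. `GSS(phospho)PR`); the PTM
BED pair marks the codons from the first to the last modified residue of
each modification type as the thick region, while unmodified peptides go to
a companion `_noptm.bed` with an empty thick region.

## Worked example

The package ships a fixture generator that builds a complete, internally
consistent miniature study — genome FASTA, GTF, translated proteins, and a
peptide table with planted junction-spanning, variant, and modified
peptides — together with independently computed ground truth.

```r
library(pepmap)

fx  <- generate_fixture(fixture_spec(seed = 7L, n_genes = 6L, n_peptides = 30L), "demo_fx")
ann <- parse_gtf(fx$gtf)
ann
#> <pepmap_annotation> 11 coding transcript(s) in 6 gene(s)

db  <- load_fasta(fx$protein_fasta)
idx <- build_index(db)
records <- read_pogo_table(fx$peptide_table)
run <- map_all(records, db, idx, ann)
run
#> <pepmap_run> 30 peptide(s): 27 mapped (37 mappings), 3 unmapped; mm <= 0
```

The three unmapped peptides are the planted single-substitution variants —
they do not exist exactly in any protein. `staged_mapping()` picks them up
at the one-mismatch stage. Writing all formats:

```r
cfg   <- run_config(fx$gtf, fx$protein_fasta, fx$peptide_table,
                    formats = c("BED", "PTMBED", "GTF", "GCT"), out_dir = "demo_out")
paths <- run_pogo(cfg)[[1L]]
cat(head(readLines(paths$bed), 4), sep = "\n")
#> chr1	1362	1401	TNESSGLGLTELR	800	-	1362	1401	128,128,128	1	39	0
#> chr1	1362	1404	FTNESSGLGLTELR	600	-	1362	1404	128,128,128	1	42	0
#> chr1	1365	1559	PLCNRHFTNESSGLGLTEL	1000	-	1365	1559	128,128,128	2	42,15	0,179
#> chr1	1377	1574	LSLHGPLCNRHFTNESSGLG	400	-	1377	1574	128,128,128	2	30,30	0,167
```

The third and fourth lines are junction-spanning peptides: two blocks, grey
because the locus occurs in more than one gene (the fixture plants a
duplicated gene). The score is `min(1000, PSMs × 200)`. The GCT matrix has
one row per (mapping, block) so quantitation can be overlaid per exon chunk:

```r
cat(head(readLines(paths$gct), 4), sep = "\n")
#> #1.2
#> 55	2
#> Name	Description	S2	S1
#> ELQKHVSGRCAPKAILSLHGPLCNR@chr1:1544-1612(-)	G001	7.919
```

A UCSC track-hub scaffold (hub.txt → genomes.txt → trackDb.txt) is produced
by `write_track_hub("demo_out", "myhub", "hg38", "me@example.org", "hub_dir")`.

A command-line interface mirroring the original tool's flags is available
via `pogo_main()` and `inst/scripts/pepmap.R`:

```sh
Rscript inst/scripts/pepmap.R -gtf ann.gtf -fasta proteins.fa -in peptides.tsv \
    -format BED,GCT -mm 1 -out outdir
```

`convert_maxquant()` turns a MaxQuant `evidence.txt`-style table into the
4-column input (`Sample`, `Peptide`, `PSMs`, `Quant`).

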