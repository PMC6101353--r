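# Builds a minimal run by hand: one single-block peptide on chr1 and one
# junction peptide, with controllable records, so every emitted field is
# predictable.
manual_run <- function(records, mappings) {
  structure(list(settings = list(max_mismatches = 0L, stage = 0L),
                 records = records,
                 peptides = unique(records$plain_sequence),
                 mappings = mappings, unmapped = character(0)),
            class = "pepmap_run")
}

mapping_of <- function(peptide, chrom, strand, blocks, tids, gids, tier) {
  blocks <- matrix(as.integer(blocks), ncol = 2L, byrow = TRUE,
                   dimnames = list(NULL, c("start", "end")))
  list(peptide = peptide, chrom = chrom, strand = strand,
       start = blocks[1L, 1L], end = blocks[nrow(blocks), 2L],
       blocks = blocks, transcript_ids = tids, gene_ids = gids,
       uniqueness = tier, n_mismatches = 0L,
       mismatch_positions = integer(0), stage = 0L)
}

records_tbl <- function(lines) {
  read_pogo_table(write_tmp(c("Sample\tPeptide\tPSMs\tQuant", lines), ".pogo"))
}

test_that("BED12 lines carry uniqueness colours, PSM score, and block bookkeeping", {
  # single-block mapping: 6 residues -> 18 nt at chr1:1000-1018
  recs <- records_tbl(c("S1\tMKTAYI\t3\t1.5", "S1\tKTAY\t9\t2.0"))
  run <- manual_run(recs, list(
    MKTAYI = list(mapping_of("MKTAYI", "chr1", "+", c(1000, 1018),
                             "T1", "G1", "unique_transcript")),
    KTAY = list(mapping_of("KTAY", "chr1", "+", c(1003, 1009, 2000, 2006),
                           c("T1", "T2"), "G1", "unique_gene"))))
  f <- tempfile(fileext = ".bed")
  write_bed(run, f)
  lines <- readLines(f)
  expect_length(lines, 2L)
  one <- strsplit(lines[1L], "\t")[[1L]]
  expect_identical(one[c(1, 2, 3, 4, 9, 10, 11)],
                   c("chr1", "1000", "1018", "MKTAYI", "255,0,0", "1", "18"))
  expect_identical(one[5L], "600")        # 3 PSMs x 200
  junction <- strsplit(lines[2L], "\t")[[1L]]
  expect_identical(junction[c(10, 11, 12)], c("2", "6,6", "0,997"))
  expect_identical(junction[5L], "1000")  # 9 PSMs x 200 capped at 1000
  expect_identical(junction[9L], "0,0,0")
  expect_length(validate_bed_lines(lines), 0L)
  # empty runs give empty files
  empty <- manual_run(records_tbl(character(0)), list())
  f2 <- tempfile(fileext = ".bed")
  write_bed(empty, f2)
  expect_length(readLines(f2), 0L)
})

test_that("PTM BED thick blocks cover the modified codons and split by type", {
  # 10-residue peptide on a single block chr1:1000-1030, phospho at residue 4
  recs <- records_tbl("S1\tMKTA(phospho)YIAKQR\t1\t1.0")
  run <- manual_run(recs, list(
    MKTAYIAKQR = list(mapping_of("MKTAYIAKQR", "chr1", "+", c(1000, 1030),
                                 "T1", "G1", "unique_transcript"))))
  base <- tempfile()
  write_ptm_bed(run, base)
  ptm <- readLines(paste0(base, "_ptm.bed"))
  expect_length(ptm, 1L)
  f <- strsplit(ptm, "\t")[[1L]]
  expect_identical(f[7:8], c("1009", "1012"))   # residue 4 codon
  expect_identical(f[9L], "255,0,0")            # phospho is red
  expect_length(readLines(paste0(base, "_noptm.bed")), 0L)

  # multiple sites of one type span first-to-last; distinct types get lines
  recs2 <- records_tbl("S1\tMK(phospho)TAY(phospho)I(acetyl)AKQR\t1\t1.0")
  run2 <- manual_run(recs2, list(
    MKTAYIAKQR = list(mapping_of("MKTAYIAKQR", "chr1", "+", c(1000, 1030),
                                 "T1", "G1", "unique_transcript"))))
  base2 <- tempfile()
  write_ptm_bed(run2, base2)
  ptm2 <- readLines(paste0(base2, "_ptm.bed"))
  expect_length(ptm2, 2L)
  fields <- strsplit(ptm2, "\t")
  acetyl <- fields[[1L]]; phospho <- fields[[2L]]
  expect_identical(phospho[7:8], c("1003", "1015"))  # residues 2..5
  expect_identical(acetyl[7:8], c("1015", "1018"))   # residue 6
  expect_false(identical(acetyl[9L], phospho[9L]))
})

test_that("PTM thick regions cross junctions via the spliced transform", {
  # junction peptide KTAY on blocks (1003,1009)+(2000,2006), phospho at
  # residue 4 -> peptide nt 9..12 -> genomic pieces end in the second block
  recs <- records_tbl("S1\tKTAY(phospho)\t1\t1.0")
  run <- manual_run(recs, list(
    KTAY = list(mapping_of("KTAY", "chr1", "+", c(1003, 1009, 2000, 2006),
                           "T1", "G1", "unique_transcript"))))
  base <- tempfile()
  write_ptm_bed(run, base)
  f <- strsplit(readLines(paste0(base, "_ptm.bed")), "\t")[[1L]]
  expect_identical(f[7:8], c("2003", "2006"))
  expect_length(validate_bed_lines(readLines(paste0(base, "_ptm.bed"))), 0L)
})

test_that("modified and unmodified peptides partition the PTM BED pair", {
  recs <- records_tbl(c("S1\tMKTA(phospho)YI\t1\t1.0", "S1\tKTAY\t1\t1.0"))
  run <- manual_run(recs, list(
    MKTAYI = list(mapping_of("MKTAYI", "chr1", "+", c(1000, 1018),
                             "T1", "G1", "unique_transcript")),
    KTAY = list(mapping_of("KTAY", "chr2", "+", c(500, 512),
                           "T2", "G2", "unique_transcript"))))
  base <- tempfile()
  write_ptm_bed(run, base)
  ptm_peps <- vapply(strsplit(readLines(paste0(base, "_ptm.bed")), "\t"),
                     `[[`, "", 4L)
  noptm_peps <- vapply(strsplit(readLines(paste0(base, "_noptm.bed")), "\t"),
                       `[[`, "", 4L)
  expect_identical(ptm_peps, "MKTAYI")
  expect_identical(noptm_peps, "KTAY")
  expect_length(intersect(ptm_peps, noptm_peps), 0L)
})

test_that("GCT splits junction peptides into per-exon rows sharing quantitation", {
  recs <- records_tbl(c("S1\tKTAY\t1\t2.5", "S2\tKTAY\t2\t0.75"))
  run <- manual_run(recs, list(
    KTAY = list(mapping_of("KTAY", "chr1", "+", c(1003, 1009, 2000, 2006),
                           "T1", "G1", "unique_gene"))))
  f <- tempfile(fileext = ".gct")
  write_gct(run, f)
  lines <- readLines(f)
  expect_identical(lines[1L], "#1.2")
  expect_identical(lines[2L], "2\t2")
  expect_identical(lines[3L], "Name\tDescription\tS1\tS2")
  rows <- strsplit(lines[4:5], "\t")
  expect_identical(rows[[1L]][1L], "KTAY@chr1:1003-1009(+)")
  expect_identical(rows[[2L]][1L], "KTAY@chr1:2000-2006(+)")
  for (r in rows) expect_identical(r[3:4], c("2.5", "0.75"))
})

test_that("GCT emits empty fields for unquantified samples and handles empty runs", {
  recs <- records_tbl(c("S1\tKTAY\t1\t2.5", "S2\tMKTAYI\t1\t1.0"))
  run <- manual_run(recs, list(
    KTAY = list(mapping_of("KTAY", "chr1", "+", c(1003, 1009, 2000, 2006),
                           "T1", "G1", "unique_gene"))))
  f <- tempfile(fileext = ".gct")
  write_gct(run, f)
  lines <- readLines(f)
  rows <- strsplit(lines[4:5], "\t")
  for (r in rows) {
    expect_identical(r[3L], "2.5")
    expect_identical(length(r), 3L)  # trailing S2 field is empty
  }
  empty <- manual_run(records_tbl("S1\tKTAY\t1\t2.5"), list())
  f2 <- tempfile(fileext = ".gct")
  write_gct(empty, f2)
  expect_identical(readLines(f2), c("#1.2", "0\t1", "Name\tDescription\tS1"))
})

test_that("GTF output has one transcript plus one exon per block and round-trips", {
  recs <- records_tbl("S1\tKTAY\t1\t2.5")
  blocks <- c(1003, 1009, 2000, 2006)
  run <- manual_run(recs, list(
    KTAY = list(mapping_of("KTAY", "chr1", "+", blocks, "T1", "G1",
                           "unique_gene"))))
  f <- tempfile(fileext = ".gtf")
  write_gtf(run, f)
  lines <- readLines(f)
  expect_length(lines, 3L)
  feat <- vapply(strsplit(lines, "\t"), `[[`, "", 3L)
  expect_identical(feat, c("transcript", "exon", "exon"))
  # parsing the written exon coordinates back reproduces the blocks
  exon <- strsplit(lines[2:3], "\t")
  got <- t(vapply(exon, function(e) c(as.integer(e[4L]) - 1L, as.integer(e[5L])),
                  integer(2)))
  expect_identical(as.vector(t(got)), as.integer(blocks))
  empty <- manual_run(records_tbl("S1\tKTAY\t1\t2.5"), list())
  f2 <- tempfile(fileext = ".gtf")
  write_gtf(empty, f2)
  expect_length(readLines(f2), 0L)
})

test_that("track hub scaffolding writes a resolvable hub/genomes/trackDb chain", {
  bed_dir <- tempfile(); dir.create(bed_dir)
  writeLines("chr1\t5\t10\tP\t0\t+\t5\t10\t0,0,0\t1\t5\t0",
             file.path(bed_dir, "a.bed"))
  writeLines("chr1\t5\t10\tP\t0\t+\t5\t10\t0,0,0\t1\t5\t0",
             file.path(bed_dir, "b.bed"))
  out <- tempfile()
  hub <- write_track_hub(bed_dir, "myhub", "hg38", "me@example.org", out)
  hub_lines <- readLines(hub)
  expect_true("email me@example.org" %in% hub_lines)
  genomes_file <- sub("^genomesFile ", "",
                      grep("^genomesFile ", hub_lines, value = TRUE))
  genomes <- readLines(file.path(out, genomes_file))
  trackdb_rel <- sub("^trackDb ", "", grep("^trackDb ", genomes, value = TRUE))
  trackdb <- readLines(file.path(out, trackdb_rel))
  expect_identical(sum(grepl("^track ", trackdb)), 2L)
  expect_true(file.exists(file.path(out, "hg38", "a.bed")))
  expect_error(write_track_hub(tempfile(), "h", "hg38", "e", tempfile()),
               "no BED files")
  expect_error(write_track_hub(bed_dir, "h", "hg 38!", "e", tempfile()),
               "assembly")
})

test_that("writers are deterministic across repeated calls", {
  fx <- fixture42()
  ann <- parse_gtf(fx$gtf)
  db <- load_fasta(fx$protein_fasta)
  idx <- build_index(db)
  run <- map_all(fx$records, db, idx, ann)
  out <- replicate(2L, {
    f <- tempfile()
    write_bed(run, paste0(f, ".bed"))
    write_ptm_bed(run, f)
    write_gct(run, paste0(f, ".gct"))
    write_gtf(run, paste0(f, ".gtf"))
    paste(unlist(lapply(paste0(f, c(".bed", "_ptm.bed", "_noptm.bed",
                                    ".gct", ".gtf")), readLines)),
          collapse = "\n")
  })
  expect_identical(out[1L], out[2L])
})
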