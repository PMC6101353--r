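# A compact hand-built reference set used throughout:
#   TXA (gene GA, +): CDS [1000,1009)+[2000,2021) on chr1, protein "MKTAYIAKQR"
#   TXB (gene GA, +): identical CDS, second transcript of the same gene
#   TXC (gene GC, +): single CDS [5000,5030) on chr2, protein "WWSSAYIAGH"
toy_setup <- function(two_tx = FALSE) {
  gtf <- c(gtf_line("chr1", "CDS", 1001L, 1009L, "+", "TXA", "GA"),
           gtf_line("chr1", "CDS", 2001L, 2021L, "+", "TXA", "GA"),
           if (two_tx) c(gtf_line("chr1", "CDS", 1001L, 1009L, "+", "TXB", "GA"),
                         gtf_line("chr1", "CDS", 2001L, 2021L, "+", "TXB", "GA")),
           gtf_line("chr2", "CDS", 5001L, 5030L, "+", "TXC", "GC"))
  ann <- parse_gtf(write_tmp(gtf, ".gtf"))
  seqs <- list(TXA = "MKTAYIAKQR", TXC = "WWSSAYIAGH")
  if (two_tx) seqs$TXB <- "MKTAYIAKQR"
  db <- fasta_db(seqs)
  list(ann = ann, db = db, idx = build_index(db))
}

records_for <- function(peps, sample = "S1") {
  f <- write_tmp(c("Sample\tPeptide\tPSMs\tQuant",
                   sprintf("%s\t%s\t2\t1.0", sample, peps)), ".pogo")
  read_pogo_table(f)
}

test_that("a junction peptide maps to spliced blocks via its transcript", {
  s <- toy_setup()
  run <- map_all(records_for("KTAY"), s$db, s$idx, s$ann)
  mp <- run$mappings$KTAY[[1L]]
  expect_identical(mp$chrom, "chr1")
  expect_identical(unname(mp$blocks),
                   matrix(c(1003L, 1009L, 2000L, 2006L), 2L, byrow = TRUE))
  expect_identical(mp$uniqueness, "unique_transcript")
  expect_identical(length(run$unmapped), 0L)
})

test_that("hits on two transcripts with identical blocks collapse to one unique_gene mapping", {
  s <- toy_setup(two_tx = TRUE)
  run <- map_all(records_for("KTAY"), s$db, s$idx, s$ann)
  expect_length(run$mappings$KTAY, 1L)
  mp <- run$mappings$KTAY[[1L]]
  expect_identical(mp$transcript_ids, c("TXA", "TXB"))
  expect_identical(mp$uniqueness, "unique_gene")
})

test_that("a peptide hitting two genes is classified multi_gene on all its mappings", {
  s <- toy_setup()
  run <- map_all(records_for("AYIA"), s$db, s$idx, s$ann)  # in TXA and TXC
  expect_length(run$mappings$AYIA, 2L)
  expect_identical(unique(vapply(run$mappings$AYIA, `[[`, "", "uniqueness")),
                   "multi_gene")
})

test_that("absent peptides are reported unmapped and the partition invariant holds", {
  s <- toy_setup()
  run <- map_all(records_for(c("KTAY", "PPPPPP")), s$db, s$idx, s$ann)
  expect_identical(run$unmapped, "PPPPPP")
  expect_identical(length(run$mappings) + length(run$unmapped),
                   length(run$peptides))
})

test_that("uniqueness classification follows the three-tier rule", {
  one <- list(list(transcript_ids = "T1", gene_ids = "G1"))
  expect_identical(classify_uniqueness(one), "unique_transcript")
  shared <- list(list(transcript_ids = c("T1", "T2"), gene_ids = "G1"))
  expect_identical(classify_uniqueness(shared), "unique_gene")
  two_genes <- list(list(transcript_ids = "T1", gene_ids = "G1"),
                    list(transcript_ids = "T9", gene_ids = "G2"))
  expect_identical(classify_uniqueness(two_genes), "multi_gene")
  expect_error(classify_uniqueness(list()), "empty")
})

test_that("a fully mismatched FASTA/GTF identifier join is a configuration error", {
  s <- toy_setup()
  db <- fasta_db(list(OTHER1 = "MKTAYIAKQR"))
  expect_error(
    suppressWarnings(map_all(records_for("KTAY"), db, build_index(db), s$ann)),
    "same annotation release")
})

test_that("versioned FASTA keys join unversioned GTF transcript ids", {
  s <- toy_setup()
  f <- write_tmp(c(">x transcript:TXA.3", "MKTAYIAKQR"), ".fa")
  db <- load_fasta(f)
  run <- map_all(records_for("KTAY"), db, build_index(db), s$ann)
  expect_identical(run$mappings$KTAY[[1L]]$transcript_ids, "TXA")
})

test_that("staged mapping maps exactly first, then variants at one mismatch", {
  s <- toy_setup()
  recs <- records_for(c("KTAYIAK", "WSSAYIA", "KTAVIAK"))  # third: Y->V variant
  res <- staged_mapping(recs, s$db, s$idx, s$ann, stages = c(0L, 1L))
  expect_identical(sort(names(res[[1L]]$run$mappings)),
                   c("KTAYIAK", "WSSAYIA"))
  expect_identical(names(res[[2L]]$run$mappings), "KTAVIAK")
  mp <- res[[2L]]$run$mappings$KTAVIAK[[1L]]
  expect_identical(mp$n_mismatches, 1L)
  expect_identical(mp$mismatch_positions, 4L)
  expect_identical(mp$stage, 1L)
  # disjointness and partition at every stage
  expect_length(intersect(names(res[[1L]]$run$mappings),
                          names(res[[2L]]$run$mappings)), 0L)
  for (st in res) {
    expect_identical(length(st$run$mappings) + length(st$run$unmapped),
                     length(st$run$peptides))
  }
})

test_that("when every peptide maps exactly, the mismatch stage is empty", {
  s <- toy_setup()
  res <- staged_mapping(records_for("KTAYIAK"), s$db, s$idx, s$ann)
  expect_identical(length(res[[2L]]$run$peptides), 0L)
  expect_error(staged_mapping(records_for("KTAYIAK"), s$db, s$idx, s$ann,
                              stages = c(1L, 0L)), "increasing")
})
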