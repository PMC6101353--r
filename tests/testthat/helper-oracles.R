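# Independent oracles and small builders shared across the test files.
# These deliberately use different algorithms from the package internals:
# per-nucleotide position tables for coordinate transforms and a
# character-matrix Hamming scan for peptide search.

# ---- coordinate oracle ----------------------------------------------------

# genomic position of every coding nucleotide, in translation order
oracle_position_map <- function(tm) {
  unlist(lapply(seq_len(nrow(tm$cds_segments)), function(i) {
    g0 <- tm$cds_segments[i, 1L]
    g1 <- tm$cds_segments[i, 2L]
    if (tm$strand == "+") g0:(g1 - 1L) else (g1 - 1L):g0
  }), use.names = FALSE)
}

# expected blocks for a coding interval, from the per-base table
oracle_blocks <- function(tm, nt_start, nt_end) {
  if (nt_start == nt_end) return(matrix(integer(0), ncol = 2L,
                                        dimnames = list(NULL, c("start", "end"))))
  pos <- sort(oracle_position_map(tm)[(nt_start + 1L):nt_end])
  brk <- c(0L, which(diff(pos) != 1L), length(pos))
  m <- cbind(start = pos[brk[-length(brk)] + 1L], end = pos[brk[-1L]] + 1L)
  storage.mode(m) <- "integer"
  m
}

# random transcript model: <= max_segments segments, coding length a multiple
# of 3, valid translation order for the sampled strand
random_transcript <- function(id = "TX", max_segments = 10L, max_len = 3000L) {
  n_seg <- sample.int(max_segments, 1L)
  lens <- sample(3:max(3L, max_len %/% max(1L, n_seg)), n_seg, replace = TRUE)
  lens[1L] <- lens[1L] - sum(lens) %% 3L  # total a multiple of 3
  if (lens[1L] < 3L) lens[1L] <- lens[1L] + 3L
  strand <- sample(c("+", "-"), 1L)
  starts <- cumsum(c(sample(1:500, 1L), lens[-n_seg] + sample(10:300, n_seg - 1L,
                                                              replace = TRUE)))
  seg <- cbind(starts, starts + lens)
  if (strand == "-") seg <- seg[rev(seq_len(n_seg)), , drop = FALSE]
  transcript_model(id, paste0(id, "_G"), "chrT", strand, seg)
}

# ---- search oracle --------------------------------------------------------

# brute-force all-substring Hamming scan over a whole database; ambiguous
# protein residues (X/B/Z/U) never match
oracle_scan <- function(db, peptide, max_mm) {
  qc <- strsplit(peptide, "")[[1L]]
  m <- length(qc)
  out <- list()
  for (key in names(db$sequences)) {
    pc <- strsplit(db$sequences[[key]], "")[[1L]]
    pc[pc %in% c("X", "B", "Z", "U")] <- "?"
    n <- length(pc)
    if (n < m) next
    for (s in 1:(n - m + 1L)) {
      mm_pos <- which(pc[s:(s + m - 1L)] != qc)
      if (length(mm_pos) <= max_mm) {
        out[[length(out) + 1L]] <- data.frame(
          protein_key = key, aa_start = s, aa_end = s + m - 1L,
          n_mismatches = length(mm_pos),
          mismatch_positions = I(list(mm_pos)), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(protein_key = character(0), aa_start = integer(0),
                      aa_end = integer(0), n_mismatches = integer(0),
                      mismatch_positions = I(list())))
  }
  res <- do.call(rbind, out)
  res[order(res$protein_key, res$aa_start), , drop = FALSE]
}

hit_signature <- function(hits) {
  if (nrow(hits) == 0L) return(character(0))
  sort(sprintf("%s@%d:%d[%s]", hits$protein_key, hits$aa_start,
               hits$n_mismatches,
               vapply(hits$mismatch_positions, paste, "", collapse = ",")))
}

# ---- tiny input builders --------------------------------------------------

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

gtf_line <- function(chrom, feature, start1, end1, strand, tid, gid = "G1",
                     extra = "") {
  sprintf('%s\ttest\t%s\t%d\t%d\t.\t%s\t0\tgene_id "%s"; transcript_id "%s";%s',
          chrom, feature, start1, end1, strand, gid, tid, extra)
}

fasta_db <- function(seqs) {
  f <- write_tmp(unlist(lapply(names(seqs), function(k) {
    c(paste0(">", k), seqs[[k]])
  })), ext = ".fa")
  load_fasta(f)
}

# two-exon plus-strand transcript used across mapper/writer tests:
# CDS segments [1000,1009) + [2000,2021), 30 coding nt = 10 residues
two_exon_tx <- function() {
  transcript_model("TXA", "GA", "chr1", "+",
                   rbind(c(1000L, 1009L), c(2000L, 2021L)))
}

# ---- BED structural validator (self-contained) ----------------------------

validate_bed_lines <- function(lines) {
  problems <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 12L) {
      problems <- c(problems, paste("not 12 columns:", ln)); next
    }
    start <- as.integer(f[2L]); end <- as.integer(f[3L])
    score <- as.integer(f[5L])
    thick0 <- as.integer(f[7L]); thick1 <- as.integer(f[8L])
    rgb <- as.integer(strsplit(f[9L], ",", fixed = TRUE)[[1L]])
    cnt <- as.integer(f[10L])
    sizes <- as.integer(strsplit(f[11L], ",", fixed = TRUE)[[1L]])
    rel <- as.integer(strsplit(f[12L], ",", fixed = TRUE)[[1L]])
    if (!(start <= thick0 && thick0 <= thick1 && thick1 <= end)) {
      problems <- c(problems, paste("thick outside span:", ln))
    }
    if (score < 0L || score > 1000L) {
      problems <- c(problems, paste("score out of range:", ln))
    }
    if (length(rgb) != 3L || any(rgb < 0L) || any(rgb > 255L)) {
      problems <- c(problems, paste("bad itemRgb:", ln))
    }
    if (length(sizes) != cnt || length(rel) != cnt) {
      problems <- c(problems, paste("block bookkeeping:", ln))
    } else {
      if (rel[1L] != 0L) problems <- c(problems, paste("first blockStart != 0:", ln))
      if (rel[cnt] + sizes[cnt] != end - start) {
        problems <- c(problems, paste("last block does not end at chromEnd:", ln))
      }
      if (cnt > 1L && any(diff(rel) <= 0L)) {
        problems <- c(problems, paste("blocks not ascending:", ln))
      }
      if (!f[6L] %in% c("+", "-")) problems <- c(problems, paste("bad strand:", ln))
    }
  }
  problems
}

# shared seed-42 fixture, generated once per test session
fixture42 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "pepmap-fixture42")
      cache <<- generate_fixture(fixture_spec(seed = 42L), dir)
    }
    cache
  }
})
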