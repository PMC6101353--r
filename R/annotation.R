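# Gene annotation: GTF parsing into transcript models and the spliced
# residue-range -> genomic-block coordinate transform.
#
# Conventions: GTF coordinates are 1-based inclusive; everything internal
# (and all BED output) is 0-based half-open. The conversion happens exactly
# once, at parse time.

#' Construct a transcript model
#'
#' A transcript model holds the coding (CDS) structure of one protein-coding
#' transcript: its chromosome, strand, and CDS segments in translation order,
#' i.e. ascending genomic position on the plus strand and descending on the
#' minus strand. All coordinates are 0-based half-open.
#'
#' @param transcript_id Transcript identifier (string).
#' @param gene_id Gene identifier (string).
#' @param chrom Chromosome / sequence name, passed through verbatim.
#' @param strand `"+"` or `"-"`.
#' @param cds_segments Two-column integer matrix (`start`, `end`), 0-based
#'   half-open, one row per CDS segment in translation order.
#' @param gene_name Optional gene symbol.
#' @return An object of class `pepmap_transcript`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             cds_segments, gene_name = NA_character_) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            nzchar(transcript_id))
  if (!strand %in% c("+", "-")) {
    stop("strand must be '+' or '-' for transcript ", transcript_id)
  }
  seg <- as.matrix(cds_segments)
  if (ncol(seg) != 2L) stop("cds_segments must have two columns (start, end)")
  storage.mode(seg) <- "integer"
  colnames(seg) <- c("start", "end")
  if (any(seg[, "end"] <= seg[, "start"])) {
    stop("empty or inverted CDS segment in transcript ", transcript_id)
  }
  # translation-order invariant: ascending on +, descending on -
  if (nrow(seg) > 1L) {
    d <- diff(seg[, "start"])
    ok <- if (strand == "+") all(d > 0) else all(d < 0)
    if (!ok) {
      stop("cds_segments of transcript ", transcript_id,
           " are not in translation order for strand ", strand)
    }
    asc <- seg[order(seg[, "start"]), , drop = FALSE]
    if (any(asc[-nrow(asc), "end"] > asc[-1L, "start"])) {
      stop("overlapping CDS segments in transcript ", transcript_id)
    }
  }
  len <- sum(seg[, "end"] - seg[, "start"])
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id,
         gene_name = gene_name, chrom = chrom, strand = strand,
         cds_segments = seg, coding_length_nt = as.integer(len)),
    class = "pepmap_transcript"
  )
}

#' @export
print.pepmap_transcript <- function(x, ...) {
  cat(sprintf("<pepmap_transcript> %s (%s) %s:%s, %d CDS segment(s), %d nt\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$cds_segments), x$coding_length_nt))
  invisible(x)
}

gtf_attr <- function(attr_string, key) {
  # tolerant `key "value";` extraction; repeated keys keep the first
  m <- regmatches(attr_string,
                  regexec(paste0('(?:^|;)\\s*', key, '\\s+"([^"]*)"'),
                          attr_string))[[1L]]
  if (length(m) < 2L) NA_character_ else m[2L]
}

#' Parse a GTF gene annotation into transcript models
#'
#' Reads a GENCODE/Ensembl-dialect GTF and returns every transcript that has
#' at least one CDS feature. Only CDS features are used; exon/gene/UTR lines
#' are ignored. GTF 1-based inclusive coordinates are converted to 0-based
#' half-open, and segments are ordered in translation order (by strand).
#' Chromosome names are kept verbatim. The CDS frame field is ignored:
#' translation FASTA sequences are taken as the residue ground truth, with
#' phase 0 assumed at the first CDS base. Transcripts whose summed CDS length
#' is not a multiple of 3 are retained with a warning; residue ranges beyond
#' the last full codon are unmappable.
#'
#' @param file Path to a GTF file (plain or gzip-compressed).
#' @return A `pepmap_annotation` object: `transcripts` (named list of
#'   [transcript_model()] objects) and `gene_index` (named list mapping
#'   gene_id to transcript_id character vectors).
#' @export
parse_gtf <- function(file) {
  con <- gzfile(file, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lnos <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1L]
    stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields, got %d",
                 lnos[bad], nf[bad]))
  }
  feat <- vapply(fields, `[[`, "", 3L)
  cds_i <- which(feat == "CDS")
  if (length(cds_i) == 0L) {
    return(new_annotation(list()))
  }
  recs <- lapply(cds_i, function(i) {
    f <- fields[[i]]
    tid <- gtf_attr(f[9L], "transcript_id")
    if (is.na(tid)) {
      stop(sprintf("GTF line %d: CDS feature without transcript_id attribute",
                   lnos[i]))
    }
    gid <- gtf_attr(f[9L], "gene_id")
    if (is.na(gid)) {
      stop(sprintf("GTF line %d: CDS feature without gene_id attribute",
                   lnos[i]))
    }
    start1 <- suppressWarnings(as.integer(f[4L]))
    end1 <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start1) || is.na(end1)) {
      stop(sprintf("GTF line %d: non-numeric start/end", lnos[i]))
    }
    list(tid = tid, gid = gid, gname = gtf_attr(f[9L], "gene_name"),
         chrom = f[1L], strand = f[7L],
         start0 = start1 - 1L, end0 = end1)
  })
  tids <- vapply(recs, `[[`, "", "tid")
  models <- lapply(split(recs, factor(tids, levels = unique(tids))), function(rs) {
    chrom <- unique(vapply(rs, `[[`, "", "chrom"))
    strand <- unique(vapply(rs, `[[`, "", "strand"))
    if (length(chrom) != 1L || length(strand) != 1L) {
      stop("CDS features of transcript ", rs[[1L]]$tid,
           " disagree on chromosome or strand")
    }
    seg <- cbind(start = vapply(rs, `[[`, 0L, "start0"),
                 end = vapply(rs, `[[`, 0L, "end0"))
    seg <- seg[order(seg[, "start"], decreasing = (strand == "-")), ,
               drop = FALSE]
    tm <- transcript_model(rs[[1L]]$tid, rs[[1L]]$gid, chrom, strand, seg,
                           gene_name = rs[[1L]]$gname)
    if (tm$coding_length_nt %% 3L != 0L) {
      warning(sprintf(
        "transcript %s: CDS length %d is not a multiple of 3; trailing partial codon is unmappable",
        tm$transcript_id, tm$coding_length_nt), call. = FALSE)
    }
    tm
  })
  new_annotation(models)
}

new_annotation <- function(models) {
  if (length(models) == 0L) {
    return(structure(list(transcripts = list(), gene_index = list()),
                     class = "pepmap_annotation"))
  }
  gids <- vapply(models, `[[`, "", "gene_id")
  gene_index <- lapply(split(names(models), factor(gids, levels = unique(gids))),
                       identity)
  structure(list(transcripts = models, gene_index = gene_index),
            class = "pepmap_annotation")
}

#' @export
print.pepmap_annotation <- function(x, ...) {
  cat(sprintf("<pepmap_annotation> %d coding transcript(s) in %d gene(s)\n",
              length(x$transcripts), length(x$gene_index)))
  invisible(x)
}

#' Convert a residue range to coding-nucleotide coordinates
#'
#' Pure codon arithmetic: residues are 1-based inclusive, the returned
#' nucleotide interval is 0-based half-open within the concatenated coding
#' sequence.
#'
#' @param aa_start,aa_end 1-based inclusive residue positions,
#'   `aa_start <= aa_end`.
#' @return Integer vector `c(start, end)`, 0-based half-open.
#' @export
residue_range_to_coding <- function(aa_start, aa_end) {
  stopifnot(aa_start >= 1L, aa_end >= aa_start)
  c(as.integer((aa_start - 1L) * 3L), as.integer(aa_end * 3L))
}

#' Project a coding-nucleotide interval onto the genome
#'
#' Walks the transcript's CDS segments in translation order, accumulating
#' lengths, and returns the genomic blocks covering exactly the requested
#' coding nucleotides. Blocks are split at every CDS segment boundary crossed
#' and returned sorted ascending by genomic start regardless of strand
#' (genome-browser convention).
#'
#' @param transcript A [transcript_model()] object.
#' @param nt_interval Integer `c(start, end)`, 0-based half-open, within
#'   `[0, coding_length_nt]`.
#' @return Two-column integer matrix (`start`, `end`), ascending, whose
#'   summed length equals the interval length.
#' @export
coding_to_genomic <- function(transcript, nt_interval) {
  s <- as.integer(nt_interval[1L]); e <- as.integer(nt_interval[2L])
  stopifnot(s >= 0L, e >= s)
  if (e > transcript$coding_length_nt) {
    stop(sprintf("coding interval [%d,%d) exceeds coding length %d of transcript %s",
                 s, e, transcript$coding_length_nt, transcript$transcript_id))
  }
  walk_blocks(transcript$cds_segments, transcript$strand, s, e)
}

# shared block walker: segments given in translation order, strand decides
# the direction in which each segment is consumed
walk_blocks <- function(segments, strand, s, e) {
  out <- NULL
  off <- 0L
  for (i in seq_len(nrow(segments))) {
    g0 <- segments[i, 1L]; g1 <- segments[i, 2L]
    len <- g1 - g0
    lo <- max(s, off); hi <- min(e, off + len)
    if (lo < hi) {
      piece <- if (strand == "+") {
        c(g0 + (lo - off), g0 + (hi - off))
      } else {
        c(g1 - (hi - off), g1 - (lo - off))
      }
      out <- rbind(out, piece)
    }
    off <- off + len
    if (off >= e) break
  }
  if (is.null(out)) {
    out <- matrix(integer(0), ncol = 2L)
  }
  out <- out[order(out[, 1L]), , drop = FALSE]
  storage.mode(out) <- "integer"
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

# strip a trailing ".N" version suffix from transcript/protein identifiers
strip_version <- function(ids) sub("\\.[0-9]+$", "", ids)
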