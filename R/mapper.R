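# Mapping engine: peptide search composed with the spliced coordinate
# transform, collapse of per-transcript hits into genomic loci, the
# three-tier uniqueness classification, and staged mismatch mapping.

#' Classify the uniqueness of one peptide's mappings
#'
#' Three-tier rule over the peptide's complete mapping set: if the distinct
#' gene identifiers across all mappings exceed one, every mapping is
#' `multi_gene` (grey); with a single gene and a single transcript the
#' mapping is `unique_transcript` (red); with a single gene but several
#' transcripts it is `unique_gene` (black).
#'
#' @param mappings Non-empty list of mapping objects for one peptide, each
#'   carrying `transcript_ids` and `gene_ids`.
#' @return Single string: the tier shared by all of the peptide's mappings.
#' @export
classify_uniqueness <- function(mappings) {
  if (length(mappings) == 0L) {
    stop("classify_uniqueness is undefined for an empty mapping set")
  }
  genes <- unique(unlist(lapply(mappings, `[[`, "gene_ids")))
  txs <- unique(unlist(lapply(mappings, `[[`, "transcript_ids")))
  if (length(genes) > 1L) "multi_gene"
  else if (length(txs) == 1L) "unique_transcript"
  else "unique_gene"
}

new_mapping <- function(peptide, chrom, strand, blocks, transcript_ids,
                        gene_ids, n_mismatches, mismatch_positions,
                        stage = NA_integer_) {
  list(peptide = peptide, chrom = chrom, strand = strand,
       start = blocks[1L, "start"], end = blocks[nrow(blocks), "end"],
       blocks = blocks,
       transcript_ids = sort(unique(transcript_ids)),
       gene_ids = sort(unique(gene_ids)),
       uniqueness = NA_character_,
       n_mismatches = n_mismatches,
       mismatch_positions = mismatch_positions,
       stage = stage)
}

locus_key <- function(chrom, strand, blocks) {
  paste0(chrom, strand, paste(blocks[, "start"], blocks[, "end"],
                              sep = "-", collapse = ","))
}

#' Map all peptide records onto the genome
#'
#' For each distinct plain peptide sequence: locates the peptide in the
#' protein database (see [find_peptide()]), transforms every hit into
#' spliced genomic blocks through the hit's transcript model, collapses hits
#' with identical chromosome, strand and blocks into one genomic mapping
#' (transcript and gene sets are unioned), and classifies uniqueness over
#' the peptide's complete mapping set. Peptides with no resolvable hit are
#' reported as unmapped.
#'
#' Protein keys and annotation transcript identifiers are joined after
#' stripping version suffixes. Proteins that do not resolve to an annotated
#' coding transcript are searchable but yield no mapping (warning); if no
#' protein at all resolves, mapping stops with a configuration error, the
#' usual sign of mismatched FASTA and GTF releases.
#'
#' @param records A `pepmap_peptides` data frame.
#' @param db,index Protein database and k-mer index ([load_fasta()],
#'   [build_index()]).
#' @param annotation A [parse_gtf()] annotation set.
#' @param max_mismatches Maximum amino-acid substitutions per peptide (0-2).
#' @param stage Optional stage label stored on each mapping.
#' @return A `pepmap_run`: `settings`, `records`, `peptides` (distinct plain
#'   sequences), `mappings` (named list, one list of mappings per mapped
#'   peptide), and `unmapped` (character vector of plain sequences).
#' @export
map_all <- function(records, db, index, annotation, max_mismatches = 0L,
                    stage = NA_integer_) {
  tx_ids <- names(annotation$transcripts)
  tx_lookup <- stats::setNames(tx_ids, strip_version(tx_ids))
  resolved <- strip_version(names(db$sequences)) %in% names(tx_lookup)
  if (length(db$sequences) > 0L && !any(resolved)) {
    stop("no protein identifier in the FASTA matches any transcript_id in the GTF; ",
         "check that both files come from the same annotation release")
  }
  peptides <- unique(records$plain_sequence)
  mappings <- list()
  unmapped <- character(0)
  warned <- character(0)
  for (pep in peptides) {
    hits <- find_peptide(index, db, pep, max_mismatches = max_mismatches)
    by_locus <- list()
    if (nrow(hits) > 0L) for (h in seq_len(nrow(hits))) {
      key <- strip_version(hits$protein_key[h])
      tid <- tx_lookup[key]
      if (is.na(tid)) {
        if (!key %in% warned) {
          warned <- c(warned, key)
          warning("protein ", hits$protein_key[h],
                  " has no coding transcript in the annotation; its hits are skipped",
                  call. = FALSE)
        }
        next
      }
      tm <- annotation$transcripts[[tid]]
      nt <- residue_range_to_coding(hits$aa_start[h], hits$aa_end[h])
      if (nt[2L] > tm$coding_length_nt) {
        warning("hit of ", pep, " in ", tid,
                " extends beyond the annotated CDS; skipped", call. = FALSE)
        next
      }
      blocks <- coding_to_genomic(tm, nt)
      lk <- locus_key(tm$chrom, tm$strand, blocks)
      if (is.null(by_locus[[lk]])) {
        by_locus[[lk]] <- new_mapping(
          pep, tm$chrom, tm$strand, blocks,
          transcript_ids = tm$transcript_id, gene_ids = tm$gene_id,
          n_mismatches = hits$n_mismatches[h],
          mismatch_positions = hits$mismatch_positions[[h]],
          stage = stage)
      } else {
        cur <- by_locus[[lk]]
        cur$transcript_ids <- sort(unique(c(cur$transcript_ids,
                                            tm$transcript_id)))
        cur$gene_ids <- sort(unique(c(cur$gene_ids, tm$gene_id)))
        by_locus[[lk]] <- cur
      }
    }
    if (length(by_locus) == 0L) {
      unmapped <- c(unmapped, pep)
    } else {
      by_locus <- by_locus[order(names(by_locus))]
      tier <- classify_uniqueness(by_locus)
      by_locus <- lapply(by_locus, function(mp) { mp$uniqueness <- tier; mp })
      mappings[[pep]] <- unname(by_locus)
    }
  }
  structure(
    list(settings = list(max_mismatches = max_mismatches, stage = stage),
         records = records, peptides = peptides,
         mappings = mappings, unmapped = unmapped),
    class = "pepmap_run"
  )
}

#' @export
print.pepmap_run <- function(x, ...) {
  cat(sprintf(
    "<pepmap_run> %d peptide(s): %d mapped (%d mappings), %d unmapped; mm <= %d\n",
    length(x$peptides), length(x$mappings),
    sum(lengths(x$mappings)), length(x$unmapped),
    x$settings$max_mismatches))
  invisible(x)
}

#' Staged mismatch mapping
#'
#' Runs the staged workflow that keeps variant mapping tractable: map
#' exactly first, remove every peptide that mapped, then re-map the
#' remainder allowing one (and optionally two) amino-acid substitutions.
#' Stage `k` therefore only sees peptides unmapped at all previous stages.
#'
#' @inheritParams map_all
#' @param stages Strictly increasing integer vector of allowed mismatch
#'   counts, e.g. `c(0, 1)` (default) or `c(0, 1, 2)`.
#' @return List with one element per stage: `list(stage = k, run = <run>)`.
#' @export
staged_mapping <- function(records, db, index, annotation, stages = c(0L, 1L)) {
  stages <- as.integer(stages)
  if (any(diff(stages) <= 0L) || any(stages > 2L) || any(stages < 0L)) {
    stop("stages must be strictly increasing and at most 2")
  }
  remaining <- records
  out <- vector("list", length(stages))
  for (i in seq_along(stages)) {
    run <- map_all(remaining, db, index, annotation,
                   max_mismatches = stages[i], stage = stages[i])
    out[[i]] <- list(stage = stages[i], run = run)
    remaining <- subtract_mapped(remaining, names(run$mappings))
  }
  out
}
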