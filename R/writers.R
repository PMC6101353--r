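# Output writers: BED12 with uniqueness colour code, the PTM BED pair with
# thick-block modification highlighting, GTF, GCT v1.2 quantitation
# matrices, and UCSC track-hub scaffolding. All writers are deterministic:
# identical runs produce byte-identical files.

#' Default colour scheme
#'
#' Uniqueness tiers follow the three-colour convention: red
#' (255,0,0) for a mapping unique to a single transcript, black (0,0,0) for
#' a single gene with several transcripts, grey (128,128,128) for a peptide
#' shared between genes. The PTM palette colours phosphorylation red;
#' the remaining canonical types get distinct colours and unknown types fall
#' back to `ptm_default`.
#'
#' @return A `pepmap_colors` list with `uniqueness_rgb` and `ptm_rgb`, each
#'   a named list of length-3 integer RGB vectors (0-255).
#' @export
default_color_scheme <- function() {
  structure(list(
    uniqueness_rgb = list(
      unique_transcript = c(255L, 0L, 0L),
      unique_gene = c(0L, 0L, 0L),
      multi_gene = c(128L, 128L, 128L)),
    ptm_rgb = list(
      phospho = c(255L, 0L, 0L),
      acetyl = c(0L, 102L, 0L),
      oxidation = c(0L, 0L, 255L),
      methyl = c(255L, 165L, 0L),
      ubi = c(128L, 0L, 128L),
      ptm_default = c(0L, 128L, 128L))
  ), class = "pepmap_colors")
}

#' Load a colour-scheme override from a YAML file
#'
#' The file may override any subset of the defaults, e.g.
#' `uniqueness_rgb: {unique_gene: [0, 0, 80]}` or
#' `ptm_rgb: {glyco: [0, 200, 0]}`.
#'
#' @param file YAML path.
#' @return A `pepmap_colors` object.
#' @export
load_color_scheme <- function(file) {
  cfg <- yaml::read_yaml(file)
  scheme <- default_color_scheme()
  for (section in c("uniqueness_rgb", "ptm_rgb")) {
    for (k in names(cfg[[section]])) {
      rgb <- as.integer(cfg[[section]][[k]])
      if (length(rgb) != 3L || anyNA(rgb) || any(rgb < 0L) || any(rgb > 255L)) {
        stop("invalid RGB triple for ", section, "/", k, " in ", file)
      }
      scheme[[section]][[k]] <- rgb
    }
  }
  scheme
}

rgb_field <- function(rgb) paste(rgb, collapse = ",")

ptm_color <- function(scheme, type) {
  rgb <- scheme$ptm_rgb[[type]]
  if (is.null(rgb)) rgb <- scheme$ptm_rgb$ptm_default
  rgb
}

# flat list of all mappings in a run
run_mappings <- function(run) unname(unlist(run$mappings, recursive = FALSE))

# summed PSM count per plain peptide, across all of its records
peptide_psms <- function(run, peptide) {
  sum(run$records$psms[run$records$plain_sequence == peptide])
}

#' BED score encoding of a PSM count
#'
#' Genome browsers shade by a 0-1000 score; spectral counts are mapped as
#' `min(1000, psms * 200)` so that 5 or more peptide-spectrum matches
#' saturate the scale. The factor is configurable.
#'
#' @param psms Integer PSM count(s).
#' @param per_psm Score units per PSM (default 200).
#' @return Integer score(s) in 0-1000.
#' @export
bed_score <- function(psms, per_psm = 200L) {
  as.integer(pmin(1000L, psms * as.integer(per_psm)))
}

bed12_line <- function(chrom, start, end, name, score, strand, thick_start,
                       thick_end, rgb, blocks) {
  sizes <- blocks[, "end"] - blocks[, "start"]
  rel <- blocks[, "start"] - start
  paste(chrom, start, end, name, score, strand, thick_start, thick_end,
        rgb_field(rgb), nrow(blocks),
        paste(sizes, collapse = ","),
        paste(rel, collapse = ","),
        sep = "\t")
}

sort_bed_lines <- function(lines) {
  if (length(lines) == 0L) return(lines)
  f <- strsplit(lines, "\t", fixed = TRUE)
  chrom <- vapply(f, `[[`, "", 1L)
  start <- as.integer(vapply(f, `[[`, "", 2L))
  end <- as.integer(vapply(f, `[[`, "", 3L))
  name <- vapply(f, `[[`, "", 4L)
  lines[order(chrom, start, end, name)]
}

#' Write a mapping run as BED12
#'
#' One line per genomic mapping: the peptide sequence as the feature name,
#' score from the PSM count (see [bed_score()]), itemRgb from the
#' uniqueness tier, and one block per exon-overlapping piece with introns as
#' thin connecting lines. The thick region spans the whole feature. Lines
#' are sorted by chromosome and start.
#'
#' @param run A `pepmap_run`.
#' @param file Output path.
#' @param color_scheme A [default_color_scheme()]-shaped scheme.
#' @return `file`, invisibly.
#' @export
write_bed <- function(run, file, color_scheme = default_color_scheme()) {
  lines <- character(0)
  for (pep in names(run$mappings)) {
    score <- bed_score(peptide_psms(run, pep))
    for (mp in run$mappings[[pep]]) {
      lines <- c(lines, bed12_line(
        mp$chrom, mp$start, mp$end, pep, score, mp$strand,
        mp$start, mp$end,
        color_scheme$uniqueness_rgb[[mp$uniqueness]], mp$blocks))
    }
  }
  writeLines(sort_bed_lines(lines), file)
  invisible(file)
}

# project a peptide-relative nucleotide interval onto the genome through the
# blocks of one mapping (blocks are ascending; translation order follows
# the strand)
peptide_nt_to_genomic <- function(mapping, nt_start, nt_end) {
  blocks <- mapping$blocks
  if (mapping$strand == "-") {
    blocks <- blocks[rev(seq_len(nrow(blocks))), , drop = FALSE]
  }
  walk_blocks(blocks, mapping$strand, nt_start, nt_end)
}

# union of a peptide's PTMs across all of its records, as a data frame
peptide_ptms <- function(run, peptide) {
  rows <- which(run$records$plain_sequence == peptide)
  ptms <- do.call(rbind, run$records$ptms[rows])
  if (is.null(ptms) || nrow(ptms) == 0L) {
    return(data.frame(pos = integer(0), type = character(0)))
  }
  unique(ptms)
}

#' Write the PTM BED pair
#'
#' Splits the mapped peptides into two files: `<base>_noptm.bed` holds every
#' peptide identified without any modification (plain BED12, zero-width
#' thick region), and `<base>_ptm.bed` holds the modified peptides with one
#' line per mapping and modification type. The thick block of a line covers
#' the genomic codons from the first to the last modified residue of that
#' type (a single site highlights exactly its codon), computed through the
#' same spliced transform as the mapping itself and clipped to the feature
#' span; itemRgb encodes the modification type.
#'
#' @param run A `pepmap_run`.
#' @param base Output path base; `_ptm.bed` / `_noptm.bed` are appended.
#' @param color_scheme Colour scheme with a `ptm_rgb` palette.
#' @return Character vector of the two paths, invisibly.
#' @export
write_ptm_bed <- function(run, base, color_scheme = default_color_scheme()) {
  ptm_lines <- character(0)
  noptm_lines <- character(0)
  for (pep in names(run$mappings)) {
    score <- bed_score(peptide_psms(run, pep))
    ptms <- peptide_ptms(run, pep)
    if (any(ptms$pos > nchar(pep))) {
      stop("modification position beyond peptide length for ", pep)
    }
    for (mp in run$mappings[[pep]]) {
      if (nrow(ptms) == 0L) {
        noptm_lines <- c(noptm_lines, bed12_line(
          mp$chrom, mp$start, mp$end, pep, score, mp$strand,
          mp$start, mp$start,
          color_scheme$uniqueness_rgb[[mp$uniqueness]], mp$blocks))
      } else {
        for (type in sort(unique(ptms$type))) {
          pos <- sort(ptms$pos[ptms$type == type])
          nt <- c((min(pos) - 1L) * 3L, max(pos) * 3L)
          pieces <- peptide_nt_to_genomic(mp, nt[1L], nt[2L])
          thick0 <- max(mp$start, min(pieces[, "start"]))
          thick1 <- min(mp$end, max(pieces[, "end"]))
          ptm_lines <- c(ptm_lines, bed12_line(
            mp$chrom, mp$start, mp$end, pep, score, mp$strand,
            thick0, thick1, ptm_color(color_scheme, type), mp$blocks))
        }
      }
    }
  }
  paths <- paste0(base, c("_ptm.bed", "_noptm.bed"))
  writeLines(sort_bed_lines(ptm_lines), paths[1L])
  writeLines(sort_bed_lines(noptm_lines), paths[2L])
  invisible(paths)
}

#' Write per-sample peptide quantitation as GCT v1.2
#'
#' One row per (mapping, block): a peptide spanning a splice junction is
#' split into its exon parts, every part carrying the peptide's quantitation
#' for each sample, so junction peptides are recognisable by identical
#' values on neighbouring exons. Row `Name` is
#' `peptide@chrom:blockStart-blockEnd(strand)`; `Description` joins the
#' owning gene identifiers with `;`. Missing (peptide, sample) combinations
#' are emitted as empty fields.
#'
#' @param run A `pepmap_run`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_gct <- function(run, file) {
  samples <- unique(run$records$sample)
  rows <- character(0)
  used_names <- character(0)
  for (pep in names(run$mappings)) {
    recs <- run$records[run$records$plain_sequence == pep, , drop = FALSE]
    vals <- vapply(samples, function(s) {
      q <- recs$quant[recs$sample == s]
      if (length(q) == 0L) "" else num_field(q[1L])
    }, "")
    for (mp in run$mappings[[pep]]) {
      genes <- paste(mp$gene_ids, collapse = ";")
      for (b in seq_len(nrow(mp$blocks))) {
        nm <- sprintf("%s@%s:%d-%d(%s)", pep, mp$chrom,
                      mp$blocks[b, "start"], mp$blocks[b, "end"], mp$strand)
        if (nm %in% used_names) {
          k <- 2L
          while (paste0(nm, "#", k) %in% used_names) k <- k + 1L
          nm <- paste0(nm, "#", k)
          warning("duplicate GCT row name disambiguated: ", nm, call. = FALSE)
        }
        used_names <- c(used_names, nm)
        rows <- c(rows, paste(c(nm, genes, vals), collapse = "\t"))
      }
    }
  }
  lines <- c("#1.2",
             paste(length(rows), length(samples), sep = "\t"),
             paste(c("Name", "Description", samples), collapse = "\t"),
             rows)
  writeLines(lines, file)
  invisible(file)
}

#' Write a mapping run as GTF
#'
#' Per mapping one `transcript` feature spanning the full locus and one
#' `exon` feature per block (1-based inclusive coordinates), with attributes
#' carrying the peptide sequence, owning gene and transcript identifiers,
#' the uniqueness tier, and the mismatch count.
#'
#' @param run A `pepmap_run`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_gtf <- function(run, file) {
  lines <- character(0)
  for (pep in names(run$mappings)) {
    for (mp in run$mappings[[pep]]) {
      attrs <- sprintf(
        'peptide "%s"; gene_ids "%s"; transcript_ids "%s"; uniqueness "%s"; mismatches "%d";',
        pep, paste(mp$gene_ids, collapse = ";"),
        paste(mp$transcript_ids, collapse = ";"),
        mp$uniqueness, mp$n_mismatches)
      lines <- c(lines, paste(mp$chrom, "pepmap", "transcript",
                              mp$start + 1L, mp$end, ".", mp$strand, ".",
                              attrs, sep = "\t"))
      for (b in seq_len(nrow(mp$blocks))) {
        lines <- c(lines, paste(mp$chrom, "pepmap", "exon",
                                mp$blocks[b, "start"] + 1L,
                                mp$blocks[b, "end"], ".", mp$strand, ".",
                                attrs, sep = "\t"))
      }
    }
  }
  writeLines(lines, file)
  invisible(file)
}

#' Generate a UCSC track-hub directory from a folder of BED files
#'
#' Writes the three-file hub scaffold: `hub.txt` (hub name, labels, contact
#' email, pointer to `genomes.txt`), `genomes.txt` (genome assembly, pointer
#' to `<assembly>/trackDb.txt`), and `<assembly>/trackDb.txt` with one
#' minimal stanza per BED file (type bigBed 12, itemRgb on). Each input BED
#' is coordinate-sorted and copied next to the trackDb. Conversion to the
#' binary bigBed container is delegated to an optional external-tool hook
#' (`converter`), disabled by default so the output is plain text.
#'
#' @param bed_dir Directory containing at least one `.bed` file.
#' @param hub_name Hub name (used in `hub.txt` and as labels).
#' @param assembly Genome assembly string, alphanumeric (e.g. `"hg38"`).
#' @param email Contact email recorded in `hub.txt`.
#' @param out_dir Output hub directory (created if needed).
#' @param converter Optional `function(bed_path, bigbed_path)` invoked per
#'   track to produce the binary container; `NULL` (default) skips it.
#' @return Path of `hub.txt`, invisibly.
#' @export
write_track_hub <- function(bed_dir, hub_name, assembly, email, out_dir,
                            converter = NULL) {
  beds <- sort(list.files(bed_dir, pattern = "\\.bed$", full.names = TRUE))
  if (length(beds) == 0L) stop("no BED files found in ", bed_dir)
  if (!grepl("^[A-Za-z0-9]+$", assembly)) {
    stop("invalid assembly string (must be alphanumeric): ", assembly)
  }
  asm_dir <- file.path(out_dir, assembly)
  dir.create(asm_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c(
    paste("hub", hub_name),
    paste("shortLabel", hub_name),
    paste("longLabel", hub_name, "peptide mappings"),
    "genomesFile genomes.txt",
    paste("email", email)
  ), file.path(out_dir, "hub.txt"))
  writeLines(c(
    paste("genome", assembly),
    paste0("trackDb ", assembly, "/trackDb.txt")
  ), file.path(out_dir, "genomes.txt"))
  stanzas <- character(0)
  for (bed in beds) {
    track <- gsub("[^A-Za-z0-9_]", "_",
                  tools::file_path_sans_ext(basename(bed)))
    sorted <- sort_bed_lines(readLines(bed, warn = FALSE))
    bed_out <- file.path(asm_dir, paste0(track, ".bed"))
    writeLines(sorted, bed_out)
    if (!is.null(converter)) {
      converter(bed_out, file.path(asm_dir, paste0(track, ".bb")))
    }
    stanzas <- c(stanzas,
                 paste("track", track),
                 paste0("bigDataUrl ", track, ".bb"),
                 paste("shortLabel", track),
                 paste("longLabel", track, "peptide mappings"),
                 "type bigBed 12",
                 "itemRgb on",
                 "visibility dense",
                 "")
  }
  writeLines(stanzas, file.path(asm_dir, "trackDb.txt"))
  invisible(file.path(out_dir, "hub.txt"))
}
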