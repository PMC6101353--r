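# Peptide identification tables: the 4-column tab-separated format
# (Sample, Peptide, PSMs, Quant), the inline PTM dialect, MaxQuant
# peptides.txt conversion, and the staged-mapping subtraction step.

CANONICAL_PTMS <- c("phospho", "acetyl", "oxidation", "methyl", "ubi")

#' Parse an inline-modified peptide sequence
#'
#' The modification dialect is `RESIDUE(tag)`: a lowercase alphanumeric tag
#' in parentheses annotates the residue immediately preceding it, e.g.
#' `"GSNK(phospho)R"` marks residue 4 as phosphorylated. Multiple tags on
#' distinct residues are allowed. Canonical tags are
#' phospho, acetyl, oxidation, methyl and ubi; unrecognised tags are kept
#' verbatim as their own modification type.
#'
#' @param s Modified sequence string.
#' @return List with `plain` (tag-free uppercase sequence) and `ptms`
#'   (data frame with `pos`, 1-based within the plain sequence, and `type`).
#' @export
parse_modified_sequence <- function(s) {
  if (startsWith(s, "(")) {
    stop("modification tag with no preceding residue in: ", s)
  }
  toks <- regmatches(s, gregexpr("[A-Z]|\\([a-z0-9]+\\)", s))[[1L]]
  if (paste(toks, collapse = "") != s) {
    stop("cannot parse modified sequence (unbalanced parentheses or invalid characters): ",
         s)
  }
  pos <- 0L
  ptm_pos <- integer(0); ptm_type <- character(0)
  for (t in toks) {
    if (startsWith(t, "(")) {
      ptm_pos <- c(ptm_pos, pos)
      ptm_type <- c(ptm_type, substr(t, 2L, nchar(t) - 1L))
    } else {
      pos <- pos + 1L
    }
  }
  list(plain = gsub("\\([a-z0-9]+\\)", "", s),
       ptms = data.frame(pos = ptm_pos, type = ptm_type,
                         stringsAsFactors = FALSE))
}

new_peptide_records <- function(sample, modified_sequence, psms, quant) {
  parsed <- lapply(modified_sequence, parse_modified_sequence)
  df <- data.frame(
    sample = sample,
    modified_sequence = modified_sequence,
    plain_sequence = vapply(parsed, `[[`, "", "plain"),
    psms = as.integer(psms),
    quant = as.numeric(quant),
    stringsAsFactors = FALSE
  )
  df$ptms <- I(lapply(parsed, `[[`, "ptms"))
  class(df) <- c("pepmap_peptides", "data.frame")
  df
}

aggregate_records <- function(df) {
  # identical (sample, modified_sequence) rows: PSMs summed, Quant from the
  # first occurrence (warn when later values disagree)
  key <- paste(df$sample, df$modified_sequence, sep = "\r")
  if (!anyDuplicated(key)) return(df)
  first <- !duplicated(key)
  psms <- vapply(split(df$psms, factor(key, levels = key[first])), sum, 0L)
  qsplit <- split(df$quant, factor(key, levels = key[first]))
  conflict <- vapply(qsplit, function(q) length(unique(q)) > 1L, FALSE)
  if (any(conflict)) {
    warning("conflicting Quant values for duplicated (Sample, Peptide) rows; keeping the first",
            call. = FALSE)
  }
  out <- df[first, , drop = FALSE]
  out$psms <- unname(psms)
  rownames(out) <- NULL
  out
}

#' Read a peptide table in the 4-column pogo format
#'
#' The format is tab-separated with a fixed-order, case-insensitive header
#' `Sample`, `Peptide`, `PSMs`, `Quant`; blank lines are skipped. Peptides
#' may carry inline modifications (see [parse_modified_sequence()]). Rows
#' with identical sample and modified sequence are aggregated (PSMs summed).
#'
#' @param file Path to a `.pogo`/`.tsv`/`.txt` file.
#' @return A `pepmap_peptides` data frame: `sample`, `modified_sequence`,
#'   `plain_sequence`, `psms`, `quant`, and list column `ptms`.
#' @export
read_pogo_table <- function(file) {
  lines <- readLines(file, warn = FALSE)
  if (length(lines) == 0L) stop("missing header: empty peptide file ", file)
  hdr <- tolower(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]])
  if (!identical(hdr, c("sample", "peptide", "psms", "quant")) &&
      !identical(hdr, c("experiment", "peptide", "psms", "quant"))) {
    stop("missing or malformed header in ", file,
         ": expected Sample<TAB>Peptide<TAB>PSMs<TAB>Quant")
  }
  body <- which(nzchar(trimws(lines)))[-1L]
  if (length(body) == 0L) {
    return(new_peptide_records(character(0), character(0), integer(0),
                               numeric(0)))
  }
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    bad <- which(nf != 4L)[1L]
    stop(sprintf("line %d of %s: expected 4 tab-separated columns, got %d",
                 body[bad], file, nf[bad]))
  }
  psms <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  quant <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  if (anyNA(psms)) {
    stop(sprintf("line %d of %s: non-integer PSMs value",
                 body[which(is.na(psms))[1L]], file))
  }
  if (anyNA(quant)) {
    stop(sprintf("line %d of %s: non-numeric Quant value",
                 body[which(is.na(quant))[1L]], file))
  }
  df <- new_peptide_records(vapply(fields, `[[`, "", 1L),
                            vapply(fields, `[[`, "", 2L), psms, quant)
  aggregate_records(df)
}

#' Write peptide records back to the 4-column pogo format
#'
#' @param records A `pepmap_peptides` data frame.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_pogo_table <- function(records, file) {
  lines <- c("Sample\tPeptide\tPSMs\tQuant",
             sprintf("%s\t%s\t%d\t%s", records$sample,
                     records$modified_sequence, records$psms,
                     num_field(records$quant)))
  writeLines(lines, file)
  invisible(file)
}

# plain decimal rendering, locale- and option-independent
num_field <- function(x) {
  vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE, digits = 15),
         "")
}

#' Convert a MaxQuant peptides.txt to peptide records
#'
#' Reproduces the spreadsheet unpivot of the MaxQuant route: for every
#' peptide row, each `Experiment <name>` column (a PSM-like count) is paired
#' with the `Ratio H/L normalized <name>` column of the identical experiment
#' name; a record is emitted only when both values are present. Sample is
#' the experiment name, PSMs the count, Quant the normalized ratio.
#'
#' @param file Path to a MaxQuant `peptides.txt`.
#' @return A `pepmap_peptides` data frame.
#' @export
convert_maxquant <- function(file) {
  tab <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"Sequence" %in% names(tab)) {
    stop("MaxQuant table ", file, " has no Sequence column")
  }
  exp_cols <- grep("^Experiment .+", names(tab), value = TRUE)
  if (length(exp_cols) == 0L) {
    stop("MaxQuant table ", file, " has no 'Experiment <name>' columns")
  }
  exps <- sub("^Experiment ", "", exp_cols)
  out_sample <- character(0); out_seq <- character(0)
  out_psms <- integer(0); out_quant <- numeric(0)
  for (j in seq_along(exps)) {
    ratio_col <- paste0("Ratio H/L normalized ", exps[j])
    if (!ratio_col %in% names(tab)) next
    cnt <- suppressWarnings(as.numeric(tab[[exp_cols[j]]]))
    rat <- suppressWarnings(as.numeric(tab[[ratio_col]]))
    keep <- !is.na(cnt) & !is.na(rat)
    out_sample <- c(out_sample, rep(exps[j], sum(keep)))
    out_seq <- c(out_seq, tab$Sequence[keep])
    out_psms <- c(out_psms, as.integer(cnt[keep]))
    out_quant <- c(out_quant, rat[keep])
  }
  ord <- order(match(out_seq, tab$Sequence), match(out_sample, exps))
  aggregate_records(new_peptide_records(out_sample[ord], out_seq[ord],
                                        out_psms[ord], out_quant[ord]))
}

#' Remove already-mapped peptides from a record set
#'
#' The subtraction step of staged mapping: given the set of plain sequences
#' that produced at least one mapping in an earlier stage, returns the
#' records whose plain sequence is not in that set, preserving order.
#'
#' @param records A `pepmap_peptides` data frame.
#' @param mapped_plain_sequences Character vector of mapped plain sequences.
#' @return The filtered records.
#' @export
subtract_mapped <- function(records, mapped_plain_sequences) {
  out <- records[!(records$plain_sequence %in% mapped_plain_sequences), ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}
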