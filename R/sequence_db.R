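# Protein sequence database: FASTA loading, k-mer indexing, and exact /
# bounded-mismatch peptide search (pigeonhole candidate generation verified
# by full Hamming comparison).

AA_AMBIGUOUS <- c("X", "B", "Z", "U")

#' Load transcript translation sequences from FASTA
#'
#' Reads a protein FASTA (plain or gzip) and extracts, for every record, the
#' transcript identifier that links the sequence back to the GTF
#' `transcript_id`. Ensembl `pep.all` headers carry a `transcript:ENST...`
#' token; GENCODE pipe-delimited headers carry the ENST token as a field.
#' Version suffixes (`.N`) are stripped so that versioned FASTA and
#' unversioned GTF identifiers (or vice versa) still join. Sequences are
#' uppercased and a trailing stop symbol `*` is removed.
#'
#' @param file Path to a protein FASTA file.
#' @param header_rule One of `"auto"` (default: try the Ensembl
#'   `transcript:` token, then a pipe-delimited ENST-like field, then the
#'   first whitespace token), `"ensembl"`, `"gencode"`, or `"first_token"`.
#' @return A `pepmap_proteindb`: named character vector of sequences
#'   (names are protein keys) wrapped with bookkeeping.
#' @export
load_fasta <- function(file, header_rule = c("auto", "ensembl", "gencode",
                                             "first_token")) {
  header_rule <- match.arg(header_rule)
  aa <- Biostrings::readAAStringSet(file)
  headers <- names(aa)
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*$", "", seqs)
  keys <- vapply(headers, extract_protein_key, "", rule = header_rule,
                 USE.NAMES = FALSE)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    warning("skipping ", sum(empty), " FASTA record(s) with empty sequence: ",
            paste(keys[empty], collapse = ", "), call. = FALSE)
    keys <- keys[!empty]; seqs <- seqs[!empty]
  }
  dup <- unique(keys[duplicated(keys)])
  if (length(dup) > 0L) {
    stop("duplicate protein key(s) in FASTA: ", paste(dup, collapse = ", "))
  }
  names(seqs) <- keys
  structure(list(sequences = seqs), class = "pepmap_proteindb")
}

extract_protein_key <- function(header, rule = "auto") {
  key <- switch(
    rule,
    ensembl = {
      m <- regmatches(header, regexec("transcript:([^[:space:]|]+)", header))[[1L]]
      if (length(m) < 2L) NA_character_ else m[2L]
    },
    gencode = {
      toks <- strsplit(header, "|", fixed = TRUE)[[1L]]
      hit <- grep("^ENST", toks, value = TRUE)
      if (length(hit) > 0L) hit[1L] else if (length(toks) >= 2L) toks[2L] else NA_character_
    },
    first_token = strsplit(header, "[[:space:]]+")[[1L]][1L],
    auto = {
      m <- regmatches(header, regexec("transcript:([^[:space:]|]+)", header))[[1L]]
      if (length(m) >= 2L) m[2L]
      else if (grepl("|", header, fixed = TRUE)) {
        toks <- strsplit(strsplit(header, "[[:space:]]+")[[1L]][1L], "|",
                         fixed = TRUE)[[1L]]
        hit <- grep("^ENST", toks, value = TRUE)
        if (length(hit) > 0L) hit[1L] else toks[1L]
      } else strsplit(header, "[[:space:]]+")[[1L]][1L]
    }
  )
  if (is.na(key) || !nzchar(key)) {
    stop("cannot extract a protein key from FASTA header: ", header)
  }
  strip_version(key)
}

#' @export
print.pepmap_proteindb <- function(x, ...) {
  cat(sprintf("<pepmap_proteindb> %d protein(s), %d aa total\n",
              length(x$sequences), sum(nchar(x$sequences))))
  invisible(x)
}

#' Build a k-mer index over a protein database
#'
#' Enumerates every k-mer occurrence of every protein into a hash of postings
#' `kmer -> (protein, 0-based offset)`. Proteins shorter than `kmer_len` are
#' indexed by their full sequence as a degenerate k-mer so they remain
#' discoverable.
#'
#' @param db A [load_fasta()] database.
#' @param kmer_len Integer k-mer length, default 4. Must not exceed the
#'   shortest peptide the caller intends to search.
#' @return A `pepmap_index` (environment-backed hash).
#' @export
build_index <- function(db, kmer_len = 4L) {
  kmer_len <- as.integer(kmer_len)
  if (is.na(kmer_len) || kmer_len < 1L) stop("kmer_len must be a positive integer")
  env <- new.env(parent = emptyenv(), hash = TRUE)
  seqs <- db$sequences
  for (pi in seq_along(seqs)) {
    s <- seqs[[pi]]
    n <- nchar(s)
    if (n < kmer_len) {
      kmers <- s
      offs <- 0L
    } else {
      starts <- seq_len(n - kmer_len + 1L)
      kmers <- substring(s, starts, starts + kmer_len - 1L)
      offs <- starts - 1L
    }
    sp <- split(offs, kmers)
    for (k in names(sp)) {
      prev <- if (exists(k, envir = env, inherits = FALSE)) get(k, envir = env) else NULL
      assign(k, rbind(prev, cbind(protein = pi, offset = sp[[k]])), envir = env)
    }
  }
  structure(list(postings = env, kmer_len = kmer_len,
                 protein_keys = names(seqs)),
            class = "pepmap_index")
}

#' @export
print.pepmap_index <- function(x, ...) {
  cat(sprintf("<pepmap_index> k=%d, %d distinct k-mers over %d protein(s)\n",
              x$kmer_len, length(ls(x$postings)), length(x$protein_keys)))
  invisible(x)
}

# residue-level comparison codes: ambiguous residues (X/B/Z/U) in a protein
# never match any peptide residue; optional I/L equivalence for peptides,
# since MS cannot distinguish the isobaric pair
protein_codes <- function(s, il_equivalent = FALSE) {
  v <- utf8ToInt(s)
  v[v %in% utf8ToInt(paste(AA_AMBIGUOUS, collapse = ""))] <- 0L
  if (il_equivalent) v[v == utf8ToInt("I")] <- utf8ToInt("L")
  v
}

peptide_codes <- function(p, il_equivalent = FALSE) {
  v <- utf8ToInt(p)
  if (il_equivalent) v[v == utf8ToInt("I")] <- utf8ToInt("L")
  v
}

# full Hamming scan of one protein, vectorised over offsets
scan_protein <- function(prot_codes, pep_codes, max_mm) {
  n <- length(prot_codes); m <- length(pep_codes)
  if (n < m) return(NULL)
  n_off <- n - m + 1L
  idx <- rep(seq_len(n_off), times = m) + rep(0L:(m - 1L), each = n_off)
  neq <- matrix(prot_codes[idx] != rep(pep_codes, each = n_off),
                nrow = n_off, ncol = m)
  d <- rowSums(neq)
  hit <- which(d <= max_mm)
  if (length(hit) == 0L) return(NULL)
  lapply(hit, function(h) {
    list(offset = h - 1L, mismatch_positions = which(neq[h, ]))
  })
}

#' Search a peptide in the protein database
#'
#' Finds every occurrence of `peptide` in the database with Hamming distance
#' at most `max_mismatches` (0, 1, or 2). Candidate positions are generated
#' by the pigeonhole principle: the peptide is split into
#' `max_mismatches + 1` consecutive parts, at least one of which must match
#' exactly and is looked up in the k-mer index; every candidate is then
#' verified by a full Hamming comparison. Peptides (or pigeonhole parts)
#' shorter than the index k-mer length, and searches with I/L equivalence
#' enabled, fall back to a direct scan of all proteins.
#'
#' @param index A [build_index()] index over `db`.
#' @param db The [load_fasta()] database the index was built from.
#' @param peptide Plain upper-case peptide sequence.
#' @param max_mismatches Maximum number of amino-acid substitutions, 0-2.
#' @param il_equivalent If `TRUE`, isoleucine and leucine are treated as
#'   equal when matching. Default `FALSE`: reference translations are
#'   matched literally.
#' @return A data frame with one row per hit: `protein_key`, `aa_start`,
#'   `aa_end` (1-based inclusive residues), `n_mismatches`, and a list
#'   column `mismatch_positions` (1-based positions within the peptide).
#' @export
find_peptide <- function(index, db, peptide, max_mismatches = 0L,
                         il_equivalent = FALSE) {
  max_mismatches <- as.integer(max_mismatches)
  if (is.na(max_mismatches) || max_mismatches < 0L || max_mismatches > 2L) {
    stop("max_mismatches must be 0, 1, or 2")
  }
  if (!grepl("^[A-Z]+$", peptide)) {
    stop("peptide contains characters outside the amino-acid alphabet: ",
         peptide)
  }
  m <- nchar(peptide)
  k <- index$kmer_len
  pep <- peptide_codes(peptide, il_equivalent)
  seqs <- db$sequences
  nparts <- max_mismatches + 1L
  part_len <- m %/% nparts
  use_index <- !il_equivalent && part_len >= k && m >= k
  hits <- list()
  seen <- character(0)
  add_hit <- function(pi, off, mm_pos) {
    key <- paste0(pi, "@", off)
    if (key %in% seen) return(invisible(NULL))
    seen <<- c(seen, key)
    hits[[length(hits) + 1L]] <<- list(
      protein_key = names(seqs)[pi], aa_start = off + 1L, aa_end = off + m,
      n_mismatches = length(mm_pos), mismatch_positions = mm_pos)
    invisible(NULL)
  }
  if (use_index) {
    bounds <- as.integer(c(0L, round(seq_len(nparts) * m / nparts)))
    prot_cache <- vector("list", length(seqs))
    for (p in seq_len(nparts)) {
      p0 <- bounds[p]; p1 <- bounds[p + 1L]           # 0-based part [p0,p1)
      part <- substr(peptide, p0 + 1L, p1)
      kmer <- substr(part, 1L, k)
      post <- if (exists(kmer, envir = index$postings, inherits = FALSE)) {
        get(kmer, envir = index$postings)
      } else NULL
      if (is.null(post)) next
      for (r in seq_len(nrow(post))) {
        pi <- post[r, "protein"]; koff <- post[r, "offset"]
        start <- koff - p0                            # candidate peptide offset
        prot <- seqs[[pi]]
        if (start < 0L || start + m > nchar(prot)) next
        # the part must match exactly (pigeonhole), then verify in full
        if (substr(prot, start + p0 + 1L, start + p1) != part) next
        if (is.null(prot_cache[[pi]])) {
          prot_cache[[pi]] <- protein_codes(prot, il_equivalent)
        }
        window <- prot_cache[[pi]][(start + 1L):(start + m)]
        mm_pos <- which(window != pep)
        if (length(mm_pos) <= max_mismatches) add_hit(pi, start, mm_pos)
      }
    }
  } else {
    for (pi in seq_along(seqs)) {
      sc <- scan_protein(protein_codes(seqs[[pi]], il_equivalent), pep,
                         max_mismatches)
      for (h in sc) add_hit(pi, h$offset, h$mismatch_positions)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(protein_key = character(0), aa_start = integer(0),
                      aa_end = integer(0), n_mismatches = integer(0),
                      mismatch_positions = I(list())))
  }
  out <- data.frame(
    protein_key = vapply(hits, `[[`, "", "protein_key"),
    aa_start = vapply(hits, `[[`, 0L, "aa_start"),
    aa_end = vapply(hits, `[[`, 0L, "aa_end"),
    n_mismatches = vapply(hits, `[[`, 0L, "n_mismatches"),
    mismatch_positions = I(lapply(hits, `[[`, "mismatch_positions")),
    stringsAsFactors = FALSE
  )
  out[order(out$protein_key, out$aa_start), , drop = FALSE]
}
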