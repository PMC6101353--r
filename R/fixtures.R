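# Synthetic fixture generator: random gene structures, a matching genome,
# translation FASTA and peptide table with planted ground-truth mappings
# (junction-spanning, shared-transcript, duplicated-gene, modified and
# single-substitution variant peptides), so the whole mapping workflow is
# testable without any external download.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# size-safe sample(): never interprets a length-1 vector as 1:n
resample <- function(x, size = 1L, replace = FALSE) {
  x[sample.int(length(x), size = size, replace = replace)]
}

#' Describe a synthetic mapping fixture
#'
#' Defaults emulate a small but complete study: 20 genes on two
#' chromosomes, a mix of single- and two-transcript genes plus one
#' duplicated gene pair, and 200 tryptic-length peptides of which 20% span
#' a splice junction, 10% carry modifications and 10% are single-substitution
#' variants that only map once one mismatch is allowed.
#'
#' @param seed Integer RNG seed; all outputs are reproducible from it.
#' @param n_genes Number of genes (>= 2 adds a duplicated gene pair that
#'   plants multi-gene peptides).
#' @param transcripts_per_gene,exons_per_transcript Integer ranges
#'   `c(min, max)`.
#' @param fraction_minus_strand,fraction_junction_spanning,fraction_modified,fraction_variant
#'   Fractions in `[0, 1]`.
#' @param n_peptides Number of distinct peptides to plant.
#' @param samples Character vector of sample labels.
#' @return A `pepmap_fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 20L,
                         transcripts_per_gene = c(1L, 2L),
                         exons_per_transcript = c(1L, 4L),
                         fraction_minus_strand = 0.5,
                         n_peptides = 200L,
                         fraction_junction_spanning = 0.2,
                         fraction_modified = 0.1,
                         fraction_variant = 0.1,
                         samples = c("S1", "S2")) {
  fr <- c(fraction_minus_strand, fraction_junction_spanning,
          fraction_modified, fraction_variant)
  if (any(fr < 0) || any(fr > 1)) stop("fractions must lie in [0, 1]")
  if (n_genes < 1L || n_peptides < 1L) stop("n_genes and n_peptides must be positive")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 transcripts_per_gene = as.integer(transcripts_per_gene),
                 exons_per_transcript = as.integer(exons_per_transcript),
                 fraction_minus_strand = fraction_minus_strand,
                 n_peptides = as.integer(n_peptides),
                 fraction_junction_spanning = fraction_junction_spanning,
                 fraction_modified = fraction_modified,
                 fraction_variant = fraction_variant,
                 samples = samples),
            class = "pepmap_fixture_spec")
}

# per-base genomic position of every coding nucleotide, in translation order
transcript_position_map <- function(tm) {
  unlist(lapply(seq_len(nrow(tm$cds_segments)), function(i) {
    g0 <- tm$cds_segments[i, 1L]; g1 <- tm$cds_segments[i, 2L]
    if (tm$strand == "+") g0:(g1 - 1L) else (g1 - 1L):g0
  }), use.names = FALSE)
}

# ascending blocks from a set of per-base genomic positions
blocks_from_positions <- function(pos) {
  pos <- sort(pos)
  brk <- c(0L, which(diff(pos) != 1L), length(pos))
  out <- cbind(start = pos[brk[-length(brk)] + 1L],
               end = pos[brk[-1L]] + 1L)
  storage.mode(out) <- "integer"
  out
}

# all substring occurrences of `pep` in `prot` with at most `mm` mismatches
# (independent per-position comparison; used only for ground truth)
truth_hits <- function(prot, pep, mm) {
  np <- nchar(prot); m <- nchar(pep)
  if (np < m) return(integer(0))
  pc <- strsplit(prot, "")[[1L]]
  qc <- strsplit(pep, "")[[1L]]
  starts <- integer(0)
  for (s in 1:(np - m + 1L)) {
    if (sum(pc[s:(s + m - 1L)] != qc) <= mm) starts <- c(starts, s)
  }
  starts
}

random_composition <- function(total, parts, min_part) {
  if (parts == 1L) return(total)
  repeat {
    cuts <- sort(resample(seq_len(total - 1L), parts - 1L))
    lens <- diff(c(0L, cuts, total))
    if (all(lens >= min_part)) return(lens)
  }
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

#' Generate a synthetic mapping fixture with ground truth
#'
#' Builds random gene structures, derives their CDS from random stop-free
#' codons, writes the genome so that the strand-oriented concatenation of
#' each transcript's CDS translates exactly to the emitted protein, and
#' samples peptides (7-25 residues) from the proteins. Junction-spanning
#' windows, peptides shared between the transcripts of one gene, peptides
#' from the duplicated gene pair, inline modification tags, and
#' single-substitution variants (guaranteed to have no exact match anywhere)
#' are planted, and the expected genomic loci, uniqueness tiers and mapping
#' stages are recorded independently through a per-nucleotide position map.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return List with paths (`genome_fasta`, `gtf`, `protein_fasta`,
#'   `peptide_table`), the in-memory `records`, transcript `models`,
#'   `proteins`, genome `chromosomes`, and `truth` (per-peptide expected
#'   loci, tier and stage).
#' @export
generate_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "pepmap_fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  gc_table <- Biostrings::GENETIC_CODE
  codons <- names(gc_table)[gc_table != "*"]

  chroms <- c("chr1", "chr2")
  cursor <- stats::setNames(rep(1000L, length(chroms)), chroms)
  inserts <- stats::setNames(vector("list", length(chroms)), chroms)

  n_genes <- spec$n_genes
  dup_pair <- n_genes >= 2L
  genes <- vector("list", n_genes)
  models <- list()
  proteins <- character(0)   # named by transcript_id
  gene_cds <- character(0)   # coding nucleotide string per gene

  place_gene <- function(gid, gname, cds_nt, n_tx) {
    chrom <- resample(chroms)
    strand <- if (stats::runif(1) < spec$fraction_minus_strand) "-" else "+"
    total <- nchar(cds_nt)
    n_ex <- resample(spec$exons_per_transcript[1L]:spec$exons_per_transcript[2L])
    lens <- random_composition(total, n_ex, 6L)
    start <- cursor[[chrom]] + resample(150:400)
    seg_asc <- matrix(integer(0), ncol = 2L)
    pos <- start
    for (l in lens) {
      seg_asc <- rbind(seg_asc, c(pos, pos + l))
      pos <- pos + l + resample(50:200)
    }
    cursor[[chrom]] <<- pos + 100L
    # translation order: ascending on +, descending on -; the CDS is chunked
    # by translation-order segment lengths and each chunk written into its
    # segment (reverse-complemented on -)
    seg_tr <- if (strand == "+") seg_asc else seg_asc[rev(seq_len(nrow(seg_asc))), , drop = FALSE]
    lens_tr <- seg_tr[, 2L] - seg_tr[, 1L]
    chunk_ends <- cumsum(lens_tr)
    chunks <- substring(cds_nt, c(1L, chunk_ends[-length(lens_tr)] + 1L),
                        chunk_ends)
    ins <- inserts[[chrom]]
    for (i in seq_along(lens_tr)) {
      content <- if (strand == "+") chunks[i] else revcomp_chr(chunks[i])
      ins[[length(ins) + 1L]] <- list(start = seg_tr[i, 1L], seq = content)
    }
    inserts[[chrom]] <<- ins
    for (k in seq_len(n_tx)) {
      tid <- sprintf("%s_T%d", gid, k)
      tm <- transcript_model(tid, gid, chrom, strand, seg_tr, gene_name = gname)
      models[[tid]] <<- tm
      proteins[[tid]] <<- as.character(
        Biostrings::translate(Biostrings::DNAString(cds_nt),
                              no.init.codon = TRUE))
    }
    gene_cds[[gid]] <<- cds_nt
    list(gene_id = gid, n_tx = n_tx)
  }

  for (g in seq_len(n_genes)) {
    gid <- sprintf("G%03d", g)
    n_tx <- resample(spec$transcripts_per_gene[1L]:spec$transcripts_per_gene[2L])
    if (dup_pair && g == n_genes) {
      # duplicated gene pair: reuse gene 1's coding sequence at a new locus
      cds_nt <- gene_cds[["G001"]]
      n_tx <- 1L
    } else {
      prot_len <- resample(40:90)
      cds_nt <- paste(c("ATG", resample(codons, prot_len - 1L, replace = TRUE)),
                      collapse = "")
    }
    genes[[g]] <- place_gene(gid, sprintf("GN%03d", g), cds_nt, n_tx)
  }

  # ---- genome sequences -------------------------------------------------
  chrom_seqs <- lapply(chroms, function(ch) {
    len <- cursor[[ch]] + 500L
    s <- resample(c("A", "C", "G", "T"), len, replace = TRUE)
    for (ins in inserts[[ch]]) {
      idx <- (ins$start + 1L):(ins$start + nchar(ins$seq))
      s[idx] <- strsplit(ins$seq, "")[[1L]]
    }
    paste(s, collapse = "")
  })
  names(chrom_seqs) <- chroms

  # ---- peptides ---------------------------------------------------------
  tids <- names(models)
  multi_seg <- tids[vapply(models, function(m) nrow(m$cds_segments) > 1L, FALSE)]
  n <- spec$n_peptides
  n_junction <- round(spec$fraction_junction_spanning * n)
  if (n_junction > 0L && length(multi_seg) == 0L) {
    stop("junction-spanning peptides requested but every transcript is single-exon")
  }
  junction_set <- if (n_junction > 0L) sample.int(n, n_junction) else integer(0)
  n_variant <- round(spec$fraction_variant * n)
  variant_set <- if (n_variant > 0L) sample.int(n, n_variant) else integer(0)
  n_modified <- round(spec$fraction_modified * n)
  modified_set <- if (n_modified > 0L) sample.int(n, n_modified) else integer(0)

  # deliberately planted tiers: a few peptides from the duplicated gene
  # (multi-gene) and from a multi-transcript gene (unique-gene)
  forced_tx <- character(0)
  if (dup_pair) forced_tx <- c(forced_tx, rep("G001_T1", min(3L, n)))
  multi_tx_genes <- tids[vapply(models, function(m) {
    sum(vapply(models, function(o) o$gene_id == m$gene_id, FALSE)) > 1L
  }, FALSE)]
  if (length(multi_tx_genes) > 0L) {
    forced_tx <- c(forced_tx, rep(multi_tx_genes[1L], min(3L, n)))
  }

  exists_exact <- function(pep) {
    any(vapply(proteins, function(p) grepl(pep, p, fixed = TRUE), FALSE))
  }

  plains <- character(0)
  peptide_rows <- list()
  truth <- list()

  for (i in seq_len(n)) {
    is_junction <- i %in% junction_set
    is_variant <- i %in% variant_set
    is_modified <- i %in% modified_set
    pep <- NULL; var_pos <- NA_integer_
    for (try in 1:200) {
      tid <- if (i <= length(forced_tx) && !is_junction) forced_tx[i]
             else if (is_junction) resample(multi_seg)
             else resample(tids)
      prot <- proteins[[tid]]
      lp <- nchar(prot)
      l <- resample(7:min(25L, lp))
      if (is_junction) {
        tm <- models[[tid]]
        lens <- tm$cds_segments[, 2L] - tm$cds_segments[, 1L]
        b <- resample(cumsum(lens)[-length(lens)])        # internal boundary (nt)
        a1_all <- seq_len(lp - l + 1L)
        ok <- (a1_all - 1L) * 3L < b & b < (a1_all + l - 1L) * 3L
        if (!any(ok)) next
        a1 <- resample(a1_all[ok])
      } else {
        a1 <- resample(seq_len(lp - l + 1L))
      }
      cand <- substr(prot, a1, a1 + l - 1L)
      if (is_variant) {
        vp <- resample(seq_len(l))
        orig <- substr(cand, vp, vp)
        sub <- resample(setdiff(AA20, orig))
        cand_v <- cand
        substr(cand_v, vp, vp) <- sub
        if (exists_exact(cand_v) || cand_v %in% plains) next
        pep <- cand_v; var_pos <- vp
      } else {
        if (cand %in% plains) next
        pep <- cand
      }
      break
    }
    if (is.null(pep)) {
      stop("could not plant peptide ", i, " under the requested fixture spec")
    }
    plains <- c(plains, pep)

    mod_seq <- pep
    if (is_modified) {
      n_mods <- resample(1:2)
      pos <- sort(resample(seq_len(nchar(pep)), min(n_mods, nchar(pep))))
      types <- resample(CANONICAL_PTMS, length(pos), replace = TRUE)
      parts <- strsplit(pep, "")[[1L]]
      for (j in seq_along(pos)) {
        parts[pos[j]] <- paste0(parts[pos[j]], "(", types[j], ")")
      }
      mod_seq <- paste(parts, collapse = "")
    }

    sams <- resample(spec$samples)
    if (length(spec$samples) > 1L && stats::runif(1) < 0.3) {
      sams <- c(sams, resample(setdiff(spec$samples, sams)))
    }
    for (s in sams) {
      peptide_rows[[length(peptide_rows) + 1L]] <- list(
        sample = s, modified_sequence = mod_seq,
        psms = resample(1:5), quant = round(stats::runif(1, 0.1, 10), 3))
    }

    # ---- ground truth (per-nucleotide position map, brute-force scan) ---
    stage <- if (is_variant) 1L else 0L
    loci <- list()
    for (tid2 in tids) {
      starts <- truth_hits(proteins[[tid2]], pep, stage)
      tm2 <- models[[tid2]]
      pm <- transcript_position_map(tm2)
      for (a in starts) {
        idx <- (3L * (a - 1L) + 1L):(3L * (a + nchar(pep) - 1L))
        blocks <- blocks_from_positions(pm[idx])
        lk <- locus_key(tm2$chrom, tm2$strand, blocks)
        if (is.null(loci[[lk]])) {
          loci[[lk]] <- list(chrom = tm2$chrom, strand = tm2$strand,
                             blocks = blocks, transcript_ids = tm2$transcript_id,
                             gene_ids = tm2$gene_id)
        } else {
          loci[[lk]]$transcript_ids <- sort(unique(c(loci[[lk]]$transcript_ids,
                                                     tm2$transcript_id)))
          loci[[lk]]$gene_ids <- sort(unique(c(loci[[lk]]$gene_ids,
                                               tm2$gene_id)))
        }
      }
    }
    g_all <- unique(unlist(lapply(loci, `[[`, "gene_ids")))
    t_all <- unique(unlist(lapply(loci, `[[`, "transcript_ids")))
    tier <- if (length(g_all) > 1L) "multi_gene"
            else if (length(t_all) == 1L) "unique_transcript"
            else "unique_gene"
    truth[[pep]] <- list(peptide = pep, modified_sequence = mod_seq,
                         stage = stage, tier = tier,
                         junction = is_junction,
                         variant_position = var_pos,
                         loci = loci[order(names(loci))])
  }

  # ---- write files ------------------------------------------------------
  genome_fasta <- file.path(dir, "genome.fa")
  dna <- Biostrings::DNAStringSet(unlist(chrom_seqs))
  Biostrings::writeXStringSet(dna, genome_fasta, width = 80L)

  gtf <- file.path(dir, "annotation.gtf")
  gtf_lines <- character(0)
  for (tm in models) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                     tm$gene_id, tm$transcript_id, tm$gene_name)
    seg_asc <- tm$cds_segments[order(tm$cds_segments[, 1L]), , drop = FALSE]
    gtf_lines <- c(gtf_lines, paste(tm$chrom, "fixture", "transcript",
                                    min(seg_asc[, 1L]) + 1L, max(seg_asc[, 2L]),
                                    ".", tm$strand, ".", attrs, sep = "\t"))
    for (b in seq_len(nrow(seg_asc))) {
      gtf_lines <- c(gtf_lines,
                     paste(tm$chrom, "fixture", "exon", seg_asc[b, 1L] + 1L,
                           seg_asc[b, 2L], ".", tm$strand, ".", attrs, sep = "\t"),
                     paste(tm$chrom, "fixture", "CDS", seg_asc[b, 1L] + 1L,
                           seg_asc[b, 2L], ".", tm$strand, "0", attrs, sep = "\t"))
    }
  }
  writeLines(gtf_lines, gtf)

  protein_fasta <- file.path(dir, "proteins.fa")
  fa_lines <- character(0)
  for (j in seq_along(proteins)) {
    tid <- names(proteins)[j]
    # alternate versioned / unversioned identifiers to exercise the join
    token <- if (j %% 2L == 0L) paste0(tid, ".1") else tid
    fa_lines <- c(fa_lines,
                  sprintf(">pep_%s transcript:%s gene:%s", tid, token,
                          models[[tid]]$gene_id),
                  proteins[[j]])
  }
  writeLines(fa_lines, protein_fasta)

  records <- new_peptide_records(
    vapply(peptide_rows, `[[`, "", "sample"),
    vapply(peptide_rows, `[[`, "", "modified_sequence"),
    vapply(peptide_rows, function(r) r$psms, 1L),
    vapply(peptide_rows, function(r) r$quant, 1.0))
  peptide_table <- file.path(dir, "peptides.pogo")
  write_pogo_table(records, peptide_table)

  list(spec = spec,
       genome_fasta = genome_fasta, gtf = gtf,
       protein_fasta = protein_fasta, peptide_table = peptide_table,
       records = records, models = models, proteins = proteins,
       chromosomes = chrom_seqs, truth = truth)
}

#' Compare a mapping run against fixture ground truth
#'
#' Exact-set comparison of loci, uniqueness tiers and stage assignments.
#' Accepts either a single `pepmap_run` or the list returned by
#' [staged_mapping()]. Every planted peptide must be recovered at its
#' expected stage with exactly its expected loci and tier, no spurious
#' peptide may be mapped, and no extra locus reported.
#'
#' @param result A `pepmap_run` or [staged_mapping()] output.
#' @param truth The `truth` element of [generate_fixture()].
#' @return Data frame of discrepancies (zero rows when the run agrees),
#'   with columns `peptide`, `field`, `expected`, `observed`.
#' @export
validate_against_truth <- function(result, truth) {
  stages <- if (inherits(result, "pepmap_run")) {
    list(list(stage = result$settings$max_mismatches, run = result))
  } else result
  disc <- list()
  note <- function(pep, field, expected, observed) {
    disc[[length(disc) + 1L]] <<- data.frame(
      peptide = pep, field = field, expected = expected, observed = observed,
      stringsAsFactors = FALSE)
  }
  mapped_stage <- list()
  for (st in stages) {
    for (pep in names(st$run$mappings)) {
      if (!is.null(mapped_stage[[pep]])) next
      mapped_stage[[pep]] <- st$stage
    }
  }
  for (pep in names(truth)) {
    tr <- truth[[pep]]
    obs_stage <- mapped_stage[[pep]]
    if (is.null(obs_stage)) {
      note(pep, "stage", as.character(tr$stage), "unmapped")
      next
    }
    if (obs_stage != tr$stage) {
      note(pep, "stage", as.character(tr$stage), as.character(obs_stage))
      next
    }
    run <- NULL
    for (st in stages) if (st$stage == obs_stage) run <- st$run
    obs <- run$mappings[[pep]]
    obs_keys <- sort(vapply(obs, function(m) locus_key(m$chrom, m$strand, m$blocks), ""))
    exp_keys <- sort(names(tr$loci))
    if (!identical(obs_keys, exp_keys)) {
      note(pep, "loci", paste(exp_keys, collapse = " | "),
           paste(obs_keys, collapse = " | "))
    }
    obs_tier <- unique(vapply(obs, `[[`, "", "uniqueness"))
    if (!identical(obs_tier, tr$tier)) {
      note(pep, "tier", tr$tier, paste(obs_tier, collapse = ","))
    }
  }
  for (pep in names(mapped_stage)) {
    if (is.null(truth[[pep]])) {
      note(pep, "spurious", "absent", sprintf("mapped at stage %d", mapped_stage[[pep]]))
    }
  }
  if (length(disc) == 0L) {
    return(data.frame(peptide = character(0), field = character(0),
                      expected = character(0), observed = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, disc)
}
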