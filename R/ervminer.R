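## Provirus mining: seed-and-extend probe search on a genome, LTR pairing,
## terminal-LTR identity, PBS typing, gag/pol/env ORF integrity calls, and
## the composed miner producing a coordinate-table-style report.

as_dna_set <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.data.frame(x)) {
    out <- Biostrings::DNAStringSet(x$sequence)
    names(out) <- x$id
    return(out)
  }
  out <- Biostrings::DNAStringSet(unlist(x))
  if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
  out
}

#' Find U3-probe hits on a genome
#'
#' Seed-and-extend local search: exact seed words from each probe (both
#' orientations) are located with a preprocessed dictionary, seed hits are
#' clustered by implied probe start (diagonal), and each cluster is refined
#' by a global-local alignment of the complete probe against the candidate
#' window. A hit is kept when it spans at least `min_coverage` of the probe
#' length at identity at least `min_identity` (identity = aligned matches /
#' probe length). Overlapping hits on the same strand are merged, keeping
#' the best identity (ties: leftmost, then probe order).
#'
#' @param genome Named `DNAStringSet` (or named character vector).
#' @param probes U3 records, `DNAStringSet`, or named character vector;
#'   probes must be at least 50 nt.
#' @param min_identity Identity threshold (default 0.98).
#' @param min_coverage Minimum genome-span fraction of probe length
#'   (default 0.9).
#' @param seed_width,seed_step Seed word size and sampling step.
#' @return data.frame: probe_id, chrom, start, end (1-based inclusive),
#'   strand, identity.
#' @export
find_probe_hits <- function(genome, probes, min_identity = 0.98,
                            min_coverage = 0.9, seed_width = 11L,
                            seed_step = 4L) {
  genome <- as_dna_set(genome)
  if (length(genome) == 0 || sum(Biostrings::width(genome)) == 0) {
    stop("empty genome", call. = FALSE)
  }
  probes <- as_dna_set(probes)
  if (any(Biostrings::width(probes) < 50L)) {
    stop("probes must be at least 50 nt", call. = FALSE)
  }

  ## seed dictionary over probes x orientations
  seed_tab <- list()
  for (p in seq_along(probes)) {
    pseq <- as.character(probes[[p]])
    plen <- nchar(pseq)
    offs <- unique(c(seq(1L, plen - seed_width + 1L, by = seed_step),
                     plen - seed_width + 1L))
    for (strand in c("+", "-")) {
      oriented <- if (strand == "+") pseq else revcomp(pseq)
      seed_tab[[length(seed_tab) + 1L]] <- data.frame(
        probe = names(probes)[p], strand = strand, offset = offs,
        word = substring(oriented, offs, offs + seed_width - 1L),
        plen = plen, stringsAsFactors = FALSE)
    }
  }
  seeds <- do.call(rbind, seed_tab)
  pdict <- Biostrings::PDict(Biostrings::DNAStringSet(seeds$word))

  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = FALSE)
  rows <- list()
  for (chr in names(genome)) {
    subject <- genome[[chr]]
    m <- Biostrings::matchPDict(pdict, subject)
    starts_by_seed <- Biostrings::startIndex(m)
    nonzero <- which(lengths(starts_by_seed) > 0)
    if (length(nonzero) == 0) next
    diag_df <- do.call(rbind, lapply(nonzero, function(i) {
      data.frame(probe = seeds$probe[i], strand = seeds$strand[i],
                 plen = seeds$plen[i],
                 implied = starts_by_seed[[i]] - seeds$offset[i] + 1L,
                 stringsAsFactors = FALSE)
    }))
    for (key in unique(paste(diag_df$probe, diag_df$strand))) {
      sel <- diag_df[paste(diag_df$probe, diag_df$strand) == key, ,
                     drop = FALSE]
      plen <- sel$plen[1L]
      imp <- sort(unique(sel$implied))
      cl_id <- cumsum(c(1L, diff(imp) > 30L))
      for (cl in split(imp, cl_id)) {
        win_s <- max(1L, min(cl) - 15L)
        win_e <- min(length(subject), max(cl) + plen + 14L)
        if (win_e - win_s + 1L < seed_width) next
        window <- Biostrings::subseq(subject, win_s, win_e)
        pat <- probes[[sel$probe[1L]]]
        if (sel$strand[1L] == "-") pat <- Biostrings::reverseComplement(pat)
        aln <- Biostrings::pairwiseAlignment(
          pat, window, type = "global-local",
          substitutionMatrix = sub_mat, gapOpening = 4, gapExtension = 1)
        identity <- min(1, Biostrings::nmatch(aln) / plen)
        sub_rng <- IRanges::IRanges(
          Biostrings::start(Biostrings::subject(aln)),
          Biostrings::end(Biostrings::subject(aln)))
        span <- IRanges::width(sub_rng)
        if (identity >= min_identity && span >= min_coverage * plen) {
          rows[[length(rows) + 1L]] <- data.frame(
            probe_id = sel$probe[1L], chrom = chr,
            start = win_s + IRanges::start(sub_rng) - 1L,
            end = win_s + IRanges::end(sub_rng) - 1L,
            strand = sel$strand[1L], identity = identity,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(probe_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), identity = numeric(0)))
  }
  hits <- do.call(rbind, rows)
  merge_overlapping_hits(hits)
}

## Keep the best hit per overlap cluster (same chrom+strand); ties broken by
## leftmost start, then probe id.
merge_overlapping_hits <- function(hits) {
  keep <- list()
  for (key in unique(paste(hits$chrom, hits$strand))) {
    sub <- hits[paste(hits$chrom, hits$strand) == key, , drop = FALSE]
    ir <- IRanges::IRanges(sub$start, sub$end)
    cl <- S4Vectors::subjectHits(
      IRanges::findOverlaps(ir, IRanges::reduce(ir)))
    for (g in split(seq_len(nrow(sub)), cl)) {
      cand <- sub[g, , drop = FALSE]
      cand <- cand[order(-cand$identity, cand$start, cand$probe_id), ,
                   drop = FALSE]
      keep[[length(keep) + 1L]] <- cand[1L, , drop = FALSE]
    }
  }
  out <- do.call(rbind, keep)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair LTR hits into provirus candidates
#'
#' Same-chromosome, same-strand hit pairs whose outer span falls inside the
#' provirus size window become candidates; overlapping candidates are
#' resolved greedily by highest mean identity (ties: leftmost), and each hit
#' is used in at most one pair, so solo LTRs are never promoted to
#' proviruses.
#'
#' @param hits data.frame from [find_probe_hits()].
#' @param size_window Allowed outer span in bp (default `c(5000, 12000)`).
#' @return data.frame: chrom, strand, left_start, left_end, right_start,
#'   right_end, span, left_probe, right_probe, mean_identity.
#' @export
pair_ltrs <- function(hits, size_window = c(5000, 12000)) {
  empty <- data.frame(chrom = character(0), strand = character(0),
                      left_start = integer(0), left_end = integer(0),
                      right_start = integer(0), right_end = integer(0),
                      span = integer(0), left_probe = character(0),
                      right_probe = character(0), mean_identity = numeric(0))
  if (nrow(hits) == 0) return(empty)
  cands <- list()
  for (key in unique(paste(hits$chrom, hits$strand))) {
    sub <- hits[paste(hits$chrom, hits$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    n <- nrow(sub)
    if (n < 2) next
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        span <- sub$end[j] - sub$start[i] + 1L
        if (span < size_window[1] || span > size_window[2]) next
        cands[[length(cands) + 1L]] <- data.frame(
          chrom = sub$chrom[1L], strand = sub$strand[1L],
          left_start = sub$start[i], left_end = sub$end[i],
          right_start = sub$start[j], right_end = sub$end[j],
          span = span, left_probe = sub$probe_id[i],
          right_probe = sub$probe_id[j],
          mean_identity = (sub$identity[i] + sub$identity[j]) / 2,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cands) == 0) return(empty)
  cand <- do.call(rbind, cands)
  cand <- cand[order(-cand$mean_identity, cand$left_start, cand$chrom), ,
               drop = FALSE]
  used <- character(0)
  sel <- logical(nrow(cand))
  hit_key <- function(df, side) {
    paste(df$chrom, df$strand,
          if (side == "l") df$left_start else df$right_start)
  }
  for (i in seq_len(nrow(cand))) {
    kl <- hit_key(cand[i, ], "l")
    kr <- hit_key(cand[i, ], "r")
    if (kl %in% used || kr %in% used) next
    sel[i] <- TRUE
    used <- c(used, kl, kr)
  }
  out <- cand[sel, , drop = FALSE]
  out <- out[order(out$chrom, out$left_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare the two terminal LTRs of a candidate provirus
#'
#' Strand-normalizes both LTR spans (reverse complement on the minus
#' strand), tests exact string equality, and reports the global-alignment
#' identity (matches / alignment length).
#'
#' @param genome `DNAStringSet`.
#' @param pair One row of [pair_ltrs()] output.
#' @return list(identical = logical, identity = numeric).
#' @export
check_ltr_identity <- function(genome, pair) {
  genome <- as_dna_set(genome)
  chr <- genome[[pair$chrom]]
  left <- as.character(Biostrings::subseq(chr, pair$left_start, pair$left_end))
  right <- as.character(Biostrings::subseq(chr, pair$right_start,
                                           pair$right_end))
  if (pair$strand == "-") {
    tmp <- revcomp(left)
    left <- revcomp(right)
    right <- tmp
  }
  if (identical(left, right)) {
    return(list(identical = TRUE, identity = 1.0))
  }
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(left), Biostrings::DNAString(right),
    type = "global", substitutionMatrix = sub_mat,
    gapOpening = 4, gapExtension = 1)
  list(identical = FALSE,
       identity = Biostrings::nmatch(aln) / Biostrings::nchar(aln))
}

#' Type the primer binding site of a candidate provirus
#'
#' Extracts the 18 nt immediately downstream (3') of the 5' LTR on the
#' provirus strand and compares it to each library entry; at most
#' `max_mismatch` substitutions (default 1) assigns that tRNA type,
#' otherwise `"unknown"`.
#'
#' @param genome `DNAStringSet`.
#' @param pair One row of [pair_ltrs()] output.
#' @param pbs_library Named 18-nt sequences, see [load_pbs_library()].
#' @param max_mismatch Allowed substitutions (default 1).
#' @return PBS type string (library name or `"unknown"`).
#' @export
call_pbs <- function(genome, pair, pbs_library = load_pbs_library(),
                     max_mismatch = 1L) {
  genome <- as_dna_set(genome)
  chr <- genome[[pair$chrom]]
  if (pair$strand == "+") {
    s <- pair$left_end + 1L
    e <- pair$left_end + 18L
    if (e > length(chr)) { warning("locus too short for PBS"); return("unknown") }
    pbs <- as.character(Biostrings::subseq(chr, s, e))
  } else {
    s <- pair$right_start - 18L
    e <- pair$right_start - 1L
    if (s < 1L) { warning("locus too short for PBS"); return("unknown") }
    pbs <- revcomp(as.character(Biostrings::subseq(chr, s, e)))
  }
  for (type in names(pbs_library)) {
    if (hamming(pbs, pbs_library[[type]]) <= max_mismatch) return(type)
  }
  "unknown"
}

## ---- ORF calling ----------------------------------------------------------

#' Find open reading frames in a sequence
#'
#' All three forward frames; an ORF runs from the first ATG after the
#' previous stop to the next stop codon (or to the end of the region,
#' counted as unterminated).
#'
#' @param seq DNA string (already oriented).
#' @param min_aa Minimum peptide length to report (default 25).
#' @return data.frame: start, end (1-based nt, inclusive, stop excluded),
#'   frame (0-2), aa.
#' @export
find_orfs <- function(seq, min_aa = 25L) {
  seq <- toupper(seq)
  L <- nchar(seq)
  rows <- list()
  for (frame in 0:2) {
    starts <- seq.int(frame + 1L, L - 2L, by = 3L)
    if (length(starts) == 0) next
    codons <- substring(seq, starts, starts + 2L)
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    seg_id <- cumsum(c(0L, utils::head(is_stop, -1L)))
    for (seg in split(seq_along(codons), seg_id)) {
      seg <- seg[!is_stop[seg]]
      if (length(seg) == 0) next
      atg <- seg[is_atg[seg]]
      if (length(atg) == 0) next
      first <- atg[1L]
      last <- seg[length(seg)]
      aa <- last - first + 1L
      if (aa < min_aa) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = starts[first], end = starts[last] + 2L, frame = frame,
        aa = aa)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), aa = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

#' Classify gag/pol/env coding integrity of a candidate provirus
#'
#' Extracts the internal region between the PBS and the 3' LTR (strand
#' aware), scans all frames for ORFs, and classifies each gene by the
#' longest ORF overlapping its expected cassette window relative to the
#' reference peptide length: intact (`+`) at >= 95%, partial (`P`) at
#' 30-95%, defective (`-`) below (including no ORF at all). Thresholds and
#' the cassette geometry live in the reference model.
#'
#' @param genome `DNAStringSet`.
#' @param pair One row of [pair_ltrs()] output.
#' @param reference_model See [default_reference_model()].
#' @return Named character vector (gag, pol, env) of
#'   `"intact"`/`"partial"`/`"defective"`.
#' @export
call_orfs <- function(genome, pair,
                      reference_model = default_reference_model()) {
  genome <- as_dna_set(genome)
  chr <- genome[[pair$chrom]]
  if (pair$strand == "+") {
    s <- pair$left_end + 19L
    e <- pair$right_start - 1L
    internal <- as.character(Biostrings::subseq(chr, s, e))
  } else {
    s <- pair$left_end + 1L
    e <- pair$right_start - 19L
    internal <- revcomp(as.character(Biostrings::subseq(chr, s, e)))
  }
  classify_gene_orfs(internal, reference_model)
}

classify_gene_orfs <- function(internal, model) {
  orfs <- find_orfs(internal)
  gag_nt <- 3L * (model$gag_aa + 1L)
  pol_nt <- 3L * (model$pol_aa + 1L)
  env_nt <- 3L * (model$env_aa + 1L)
  windows <- list(
    gag = c(model$leader + 1L, model$leader + gag_nt),
    pol = c(model$leader + gag_nt + model$spacer + 1L,
            model$leader + gag_nt + model$spacer + pol_nt),
    env = c(model$leader + gag_nt + 2L * model$spacer + pol_nt + 1L,
            model$leader + gag_nt + 2L * model$spacer + pol_nt + env_nt))
  refs <- c(gag = model$gag_aa, pol = model$pol_aa, env = model$env_aa)
  out <- vapply(names(windows), function(g) {
    w <- windows[[g]]
    hit <- orfs[orfs$start <= w[2] & orfs$end >= w[1], , drop = FALSE]
    best <- if (nrow(hit) == 0) 0L else max(hit$aa)
    ratio <- best / refs[[g]]
    if (ratio >= model$intact_min) "intact"
    else if (ratio >= model$partial_min) "partial"
    else "defective"
  }, "")
  names(out) <- names(windows)
  out
}

orf_symbol <- function(status) {
  c(intact = "+", partial = "P", defective = "-")[status]
}

## ---- composed miner -------------------------------------------------------

#' Mine a genome for proviruses with U3 probes
#'
#' Composition of [find_probe_hits()], [pair_ltrs()],
#' [check_ltr_identity()], [call_pbs()] and [call_orfs()]. Loci are named
#' and sorted by chromosome and start; when probe metadata (condition,
#' cell_type) are available, each locus carries a provenance tag
#' `condition/cell` where each letter is `U` (probes from both levels), `N`
#' or `B` for no-burn-/burn-only probes, and `B`/`T` for cell-exclusive
#' probes.
#'
#' @param genome `DNAStringSet` or named character vector.
#' @param probes U3 records (metadata columns used for provenance) or named
#'   sequences.
#' @param min_identity,min_coverage,size_window,pbs_library,pbs_max_mismatch,reference_model
#'   Stage parameters, see the stage functions.
#' @return data.frame report: name, chrom, start, end, strand, size, pbs,
#'   gag, pol, env (symbols `+`/`P`/`-`), ltr_identical, ltr_identity,
#'   full_length, provenance.
#' @export
mine <- function(genome, probes, min_identity = 0.98, min_coverage = 0.9,
                 size_window = c(5000, 12000),
                 pbs_library = load_pbs_library(), pbs_max_mismatch = 1L,
                 reference_model = default_reference_model()) {
  genome <- as_dna_set(genome)
  meta <- if (is.data.frame(probes)) probes else NULL
  hits <- find_probe_hits(genome, probes, min_identity, min_coverage)
  pairs <- pair_ltrs(hits, size_window)
  n <- nrow(pairs)
  if (n == 0) {
    return(data.frame(name = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), size = integer(0),
                      pbs = character(0), gag = character(0),
                      pol = character(0), env = character(0),
                      ltr_identical = logical(0), ltr_identity = numeric(0),
                      full_length = logical(0), provenance = character(0)))
  }
  rows <- lapply(seq_len(n), function(i) {
    pair <- pairs[i, , drop = FALSE]
    ltr <- check_ltr_identity(genome, pair)
    pbs <- call_pbs(genome, pair, pbs_library, pbs_max_mismatch)
    orf <- call_orfs(genome, pair, reference_model)
    prov <- NA_character_
    if (!is.null(meta) && all(c("condition", "cell_type") %in% names(meta))) {
      pm <- meta[meta$id %in% c(pair$left_probe, pair$right_probe), ,
                 drop = FALSE]
      conds <- unique(pm$condition[!is.na(pm$condition)])
      cells <- unique(pm$cell_type[!is.na(pm$cell_type)])
      if (length(conds) > 0 && length(cells) > 0) {
        burn <- any(grepl("^burn", conds))
        noburn <- any(conds == "no_burn")
        l1 <- if (burn && noburn) "U" else if (burn) "B" else "N"
        l2 <- if (length(cells) > 1L) "U" else cells
        prov <- paste0(l1, "/", l2)
      }
    }
    data.frame(
      chrom = pair$chrom, start = pair$left_start, end = pair$right_end,
      strand = pair$strand, size = pair$right_end - pair$left_start + 1L,
      pbs = pbs, gag = unname(orf_symbol(orf[["gag"]])),
      pol = unname(orf_symbol(orf[["pol"]])),
      env = unname(orf_symbol(orf[["env"]])),
      ltr_identical = ltr$identical, ltr_identity = ltr$identity,
      full_length = all(orf == "intact"), provenance = prov,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(name = sprintf("ERV-%02d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  stopifnot(all(out$size == out$end - out$start + 1L))
  out
}
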