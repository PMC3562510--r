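## Consensus-motif scanning of U3 promoter sequences. A hit requires an
## exact (IUPAC-aware) match of the motif core and an overall position-wise
## match fraction at or above the similarity threshold; both strands are
## scanned, with positions reported on forward coordinates.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

## logical: does concrete base b satisfy IUPAC letter p, vectorized over
## equal-length character vectors.
iupac_match <- function(pattern_chars, base_chars) {
  mapply(function(p, b) b %in% IUPAC_SETS[[p]], pattern_chars, base_chars,
         USE.NAMES = FALSE)
}

#' Scan a sequence for consensus-motif hits
#'
#' For every motif (and variant) in the library, both strands of the
#' sequence are scanned. A window is a hit when (i) every core position
#' matches its IUPAC consensus letter exactly and (ii) the fraction of all
#' consensus positions matched is at least `min_similarity`. Hits are
#' reported non-redundantly per (motif, position, strand): overlapping
#' variant hits keep the best similarity. Positions are 1-based starts on
#' the forward strand.
#'
#' @param u3 A U3 record (one row) or a DNA sequence string; the id is taken
#'   from the record or from `id`.
#' @param motifs Motif library data.frame, see [load_motif_library()].
#' @param min_similarity Overall similarity threshold in (0, 1]
#'   (default 0.75).
#' @param id Sequence id used when `u3` is a bare string.
#' @return data.frame: motif, u3_id, position, strand, similarity.
#' @export
scan_motifs <- function(u3, motifs = load_motif_library(),
                        min_similarity = 0.75, id = "u3") {
  if (is.data.frame(u3)) {
    id <- u3$id[1L]
    seq <- u3$sequence[1L]
  } else {
    seq <- as.character(u3)
  }
  seq <- toupper(seq)
  check_dna_alphabet(seq, id)
  if (min_similarity <= 0 || min_similarity > 1) {
    stop("min_similarity must be in (0, 1]", call. = FALSE)
  }
  check_iupac(motifs$consensus, motifs$name)
  subject <- Biostrings::DNAString(seq)
  rows <- list()
  for (r in seq_len(nrow(motifs))) {
    cons <- motifs$consensus[r]
    core <- c(motifs$core_start[r], motifs$core_end[r])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") cons else revcomp(cons)
      core_idx <- if (strand == "+") seq(core[1], core[2]) else
        seq(nchar(cons) - core[2] + 1L, nchar(cons) - core[1] + 1L)
      hits <- motif_windows(subject, pat, core_idx, min_similarity)
      if (nrow(hits) > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          motif = motifs$name[r], u3_id = id, position = hits$position,
          strand = strand, similarity = hits$similarity,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(motif = character(0), u3_id = character(0),
               position = integer(0), strand = character(0),
               similarity = numeric(0), stringsAsFactors = FALSE)
  ## non-redundant per (motif, position, strand): keep best similarity
  if (nrow(out) > 1) {
    key <- paste(out$motif, out$position, out$strand)
    out <- out[order(key, -out$similarity), , drop = FALSE]
    out <- out[!duplicated(paste(out$motif, out$position, out$strand)), ,
               drop = FALSE]
    out <- out[order(out$motif, out$position, out$strand), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

## Candidate windows for one oriented consensus pattern: Biostrings IUPAC
## matching with a mismatch budget, then exact-core and similarity filters.
motif_windows <- function(subject, pattern, core_idx, min_similarity) {
  m <- nchar(pattern)
  if (m > length(subject)) {
    return(data.frame(position = integer(0), similarity = numeric(0)))
  }
  max_mm <- floor((1 - min_similarity) * m)
  cand <- Biostrings::matchPattern(
    Biostrings::DNAString(pattern), subject, max.mismatch = max_mm,
    fixed = c(pattern = FALSE, subject = TRUE))
  starts <- Biostrings::start(cand)
  if (length(starts) == 0) {
    return(data.frame(position = integer(0), similarity = numeric(0)))
  }
  pat_chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  seq_chars <- strsplit(as.character(subject), "", fixed = TRUE)[[1L]]
  keep <- logical(length(starts))
  sim <- numeric(length(starts))
  for (i in seq_along(starts)) {
    win <- seq_chars[starts[i]:(starts[i] + m - 1L)]
    ok <- iupac_match(pat_chars, win)
    sim[i] <- mean(ok)
    keep[i] <- all(ok[core_idx]) && sim[i] >= min_similarity
  }
  data.frame(position = starts[keep], similarity = sim[keep])
}

#' Scan a whole U3 set for motif hits
#'
#' @param u3set U3 record data.frame.
#' @inheritParams scan_motifs
#' @return Combined hit data.frame over all sequences.
#' @export
scan_motifs_set <- function(u3set, motifs = load_motif_library(),
                            min_similarity = 0.75) {
  rows <- lapply(seq_len(nrow(u3set)), function(i) {
    scan_motifs(u3set[i, , drop = FALSE], motifs, min_similarity)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-motif per-group motif occurrence table
#'
#' Tallies motif occurrences per experimental group. `count = "hits"`
#' (default) sums all hits over the sequences of a group, matching the
#' convention of printed occurrence totals that exceed the group size;
#' `count = "sequences"` counts sequences containing at least one hit, so
#' column sums can never exceed group sizes.
#'
#' @param hits Hit data.frame from [scan_motifs_set()].
#' @param metadata data.frame with columns `u3_id`, `group` covering every
#'   scanned sequence.
#' @param count Counting mode.
#' @return data.frame: one row per motif, one count column per group level.
#' @export
occurrence_table <- function(hits, metadata, count = c("hits", "sequences")) {
  count <- match.arg(count)
  stopifnot(all(c("u3_id", "group") %in% names(metadata)))
  orphan <- setdiff(hits$u3_id, metadata$u3_id)
  if (length(orphan) > 0) {
    stop("no metadata for u3_id: ", orphan[1L], call. = FALSE)
  }
  groups <- sort(unique(as.character(metadata$group)))
  motifs <- sort(unique(hits$motif))
  hit_group <- metadata$group[base::match(hits$u3_id, metadata$u3_id)]
  tab <- matrix(0L, nrow = length(motifs), ncol = length(groups),
                dimnames = list(motifs, groups))
  for (g in groups) {
    sub <- hits[hit_group == g, , drop = FALSE]
    if (nrow(sub) == 0) next
    if (count == "hits") {
      t1 <- table(sub$motif)
    } else {
      t1 <- table(unique(sub[, c("motif", "u3_id")])$motif)
    }
    tab[names(t1), g] <- as.integer(t1)
  }
  out <- data.frame(motif = motifs, tab, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Render a two-group occurrence contrast as "a / b" strings
#'
#' @param occ Occurrence table from [occurrence_table()].
#' @param case,control Column (group) names to contrast.
#' @return data.frame: motif, contrast.
#' @export
render_contrast <- function(occ, case, control) {
  stopifnot(all(c(case, control) %in% names(occ)))
  data.frame(motif = occ$motif,
             contrast = paste(occ[[case]], "/", occ[[control]]),
             stringsAsFactors = FALSE)
}
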