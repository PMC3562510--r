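## Population-diversity statistics for U3 sequence groups: progressive
## multiple alignment, segregating sites, nucleotide diversity (pi),
## Watterson's theta, Tajima's D, and group comparison reports.

SEQ_CODES <- c("-" = 0L, A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)

encode_seq_matrix <- function(seqs) {
  rows <- lapply(seqs, function(s) {
    unname(SEQ_CODES[strsplit(toupper(s), "", fixed = TRUE)[[1L]]])
  })
  do.call(rbind, rows)
}

decode_seq_matrix <- function(m) {
  alpha <- names(SEQ_CODES)
  apply(m, 1L, function(r) paste(alpha[r + 1L], collapse = ""))
}

#' Progressively align a group of U3 sequences
#'
#' Progressive global multiple alignment with sum-of-pairs profile scoring
#' (match +1, mismatch -1, gap -2 per residue pair, gap-gap 0) and a guide
#' tree from k-mer count distances (average linkage). Identical sequences
#' are collapsed before alignment and re-expanded afterwards, so clone
#' multiplicities are preserved in the output rows. For two sequences the
#' result is an optimal Needleman-Wunsch alignment under the same scoring.
#'
#' @param seqs Character vector of sequences (named, or a U3 record
#'   data.frame whose `id`/`sequence` columns are used).
#' @param match,mismatch,gap Scoring parameters.
#' @param kmer Guide-tree k-mer width.
#' @return Character matrix of aligned rows (gap `-`), rownames = ids;
#'   attribute `score` holds the final merge score.
#' @export
align_group <- function(seqs, match = 1, mismatch = -1, gap = -2, kmer = 4) {
  if (is.data.frame(seqs)) seqs <- stats::setNames(seqs$sequence, seqs$id)
  if (length(seqs) < 2) stop("need at least 2 sequences", call. = FALSE)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  seqs <- toupper(seqs)
  check_dna_alphabet(seqs, names(seqs))

  uniq <- unique(seqs)
  key <- base::match(seqs, uniq)  # `match` here is the score parameter
  if (length(uniq) == 1L) {
    m <- matrix(rep(strsplit(uniq, "")[[1L]], length(seqs)),
                nrow = length(seqs), byrow = TRUE)
    rownames(m) <- names(seqs)
    attr(m, "score") <- NA_real_
    return(m)
  }

  enc <- lapply(uniq, function(s) matrix(encode_seq_matrix(list(s)), nrow = 1L))
  ## guide tree over unique sequences
  dss <- Biostrings::DNAStringSet(uniq)
  counts <- Biostrings::oligonucleotideFrequency(dss, width = kmer)
  hc <- stats::hclust(stats::dist(counts), method = "average")

  profiles <- enc                 # profile per active cluster
  members <- as.list(seq_along(uniq))  # unique-seq indices per cluster row order
  merged <- vector("list", nrow(hc$merge))
  merged_members <- vector("list", nrow(hc$merge))
  score <- NA_real_
  for (s in seq_len(nrow(hc$merge))) {
    pick <- function(v) {
      if (v < 0) list(p = profiles[[-v]], m = members[[-v]])
      else list(p = merged[[v]], m = merged_members[[v]])
    }
    a <- pick(hc$merge[s, 1L]); b <- pick(hc$merge[s, 2L])
    m <- align_profiles_cpp(a$p, b$p, match, mismatch, gap)
    score <- attr(m, "score")
    merged[[s]] <- m
    merged_members[[s]] <- c(a$m, b$m)
  }
  final <- merged[[nrow(hc$merge)]]
  order_idx <- merged_members[[nrow(hc$merge)]]

  ## expand unique rows back to the full clone set, in input order
  row_of_uniq <- base::match(seq_along(uniq), order_idx)
  full <- final[row_of_uniq[key], , drop = FALSE]
  out <- matrix(names(SEQ_CODES)[full + 1L], nrow = nrow(full))
  rownames(out) <- names(seqs)
  attr(out, "score") <- as.numeric(score)
  out
}

#' Diversity statistics with Tajima's D for an alignment
#'
#' Applies complete deletion (every column containing a gap or an ambiguous
#' base is removed), then computes the segregating-site count S, nucleotide
#' diversity pi (mean pairwise differences per analysed site), Watterson's
#' theta per site, and Tajima's D with the standard a1/a2/b/c/e constants.
#' D is undefined (NA) when S = 0: no neutrality score is fabricated for an
#' invariant sample.
#'
#' @param msa Character matrix from [align_group()] (or any gapped matrix /
#'   vector of equal-length strings).
#' @return data.frame (one row): n, L, S, pi, theta_w, mean_pairwise,
#'   tajima_d.
#' @export
tajima <- function(msa) {
  if (is.character(msa) && is.null(dim(msa))) {
    stopifnot(length(unique(nchar(msa))) == 1L)
    msa <- do.call(rbind, strsplit(toupper(msa), ""))
  }
  n <- nrow(msa)
  if (is.null(n) || n < 2) stop("need at least 2 aligned sequences",
                                call. = FALSE)
  msa <- toupper(msa)
  keep <- colSums(msa == "-" | msa == "N" | msa == ".") == 0L
  m <- msa[, keep, drop = FALSE]
  L <- ncol(m)
  if (L == 0) stop("no alignment columns left after complete deletion",
                   call. = FALSE)
  S <- sum(apply(m, 2L, function(col) length(unique(col)) > 1L))
  pairs <- utils::combn(n, 2L)
  diffs <- apply(pairs, 2L, function(p) sum(m[p[1L], ] != m[p[2L], ]))
  mean_pairwise <- mean(diffs)
  pi <- mean_pairwise / L
  a1 <- sum(1 / seq_len(n - 1L))
  theta_w <- S / (a1 * L)
  if (S == 0) {
    d <- NA_real_
  } else {
    a2 <- sum(1 / seq_len(n - 1L)^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1
    e2 <- c2 / (a1^2 + a2)
    d <- (mean_pairwise - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  }
  data.frame(n = n, L = L, S = S, pi = pi, theta_w = theta_w,
             mean_pairwise = mean_pairwise, tajima_d = d)
}

#' Per-group diversity statistics for a clone set
#'
#' Groups the clones by the requested metadata columns, aligns each group
#' and computes [tajima()] statistics. By default every clone contributes
#' (so multiplicities weight the estimates); set `unique_only = TRUE` to
#' analyse unique sequences once each.
#'
#' @param clones U3 record data.frame.
#' @param groupby Metadata columns (default `"condition"`).
#' @param unique_only Drop duplicate sequences within each group first?
#' @return data.frame of per-group statistics.
#' @export
diversity_by_group <- function(clones, groupby = "condition",
                               unique_only = FALSE) {
  fac <- interaction(clones[groupby], drop = TRUE, sep = ":")
  res <- lapply(split(clones, fac), function(g) {
    if (unique_only) g <- dedup(g)$unique
    if (nrow(g) < 2) return(NULL)
    msa <- align_group(g)
    cbind(group = as.character(fac[match(g$id[1L], clones$id)]), tajima(msa))
  })
  out <- do.call(rbind, Filter(Negate(is.null), res))
  rownames(out) <- NULL
  out
}

#' Rank diversity statistics across groups
#'
#' Orders groups by nucleotide diversity (most diverse first), flags the
#' sign of Tajima's D, and marks ties in pi. The ordering is a deterministic
#' function of the statistics, invariant under group relabelling.
#'
#' @param stats data.frame from [diversity_by_group()], or a named list of
#'   [tajima()] rows.
#' @return data.frame sorted by decreasing pi with `rank`, `d_sign`
#'   (`"+"`, `"-"`, `"0"`, or `NA`) and `tied_pi` columns.
#' @export
compare_groups <- function(stats) {
  if (is.list(stats) && !is.data.frame(stats)) {
    stats <- do.call(rbind, Map(function(g, s) cbind(group = g, s),
                                names(stats), stats))
  }
  if (nrow(stats) < 2) stop("need at least 2 groups", call. = FALSE)
  ord <- order(-stats$pi, stats$group)  # group id only breaks exact ties
  out <- stats[ord, , drop = FALSE]
  out$rank <- rank(-out$pi, ties.method = "min")
  out$tied_pi <- duplicated(out$pi) | duplicated(out$pi, fromLast = TRUE)
  out$d_sign <- ifelse(is.na(out$tajima_d), NA_character_,
                       ifelse(out$tajima_d > 0, "+",
                              ifelse(out$tajima_d < 0, "-", "0")))
  rownames(out) <- NULL
  out
}

#' Write an alignment as aligned FASTA
#' @param msa Character matrix from [align_group()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(msa, path) {
  seqs <- apply(msa, 1L, paste, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", rownames(msa)[i]), seqs[i]), con)
  }
  invisible(path)
}
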