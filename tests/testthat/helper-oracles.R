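## Independent brute-force oracles used across the suite. These deliberately
## re-derive results with plain loops over character vectors, never through
## the package's own code paths.

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

## naive non-overlapping count of >= threshold identity windows
oracle_count_matches <- function(subject, query, threshold = 0.85) {
  s <- chars(subject); q <- chars(query)
  m <- length(q); n <- length(s)
  if (m > n) return(0L)
  count <- 0L; last_end <- 0L
  for (start in seq_len(n - m + 1L)) {
    if (start <= last_end) next
    ident <- sum(s[start:(start + m - 1L)] == q) / m
    if (ident >= threshold) {
      count <- count + 1L
      last_end <- start + m - 1L
    }
  }
  count
}

## Needleman-Wunsch score, linear gap penalty
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  x <- chars(a); y <- chars(b)
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (x[i] == y[j]) match else mismatch
      S[i + 1, j + 1] <- max(S[i, j] + sub, S[i, j + 1] + gap,
                             S[i + 1, j] + gap)
    }
  }
  S[n + 1, m + 1]
}

## sum-of-pairs score of a 2-row alignment matrix
oracle_pair_alignment_score <- function(msa, match = 1, mismatch = -1,
                                        gap = -2) {
  stopifnot(nrow(msa) == 2)
  total <- 0
  for (j in seq_len(ncol(msa))) {
    a <- msa[1, j]; b <- msa[2, j]
    total <- total + if (a == "-" && b == "-") 0 else
      if (a == "-" || b == "-") gap else
      if (a == b) match else mismatch
  }
  total
}

## diversity statistics by exhaustive pairwise counting
oracle_tajima <- function(rows) {
  m <- do.call(rbind, lapply(rows, chars))
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m); L <- ncol(m)
  S <- 0L
  for (j in seq_len(L)) if (length(unique(m[, j])) > 1) S <- S + 1L
  diffs <- c()
  for (i in seq_len(n - 1)) {
    for (k in (i + 1):n) {
      diffs <- c(diffs, sum(m[i, ] != m[k, ]))
    }
  }
  Pi <- mean(diffs)
  a1 <- sum(1 / seq_len(n - 1))
  D <- NA_real_
  if (S > 0) {
    a2 <- sum(1 / seq_len(n - 1)^2)
    b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    D <- (Pi - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
  }
  list(n = n, L = L, S = S, pi = Pi / L, theta_w = S / (a1 * L),
       mean_pairwise = Pi, tajima_d = D)
}

IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_rc <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[chars(s)]), collapse = "")
}

## exhaustive-window motif scan over both strands; every window is scored,
## with the per-position IUPAC membership test vectorized across windows
oracle_scan <- function(seq, motifs, min_sim = 0.75) {
  s <- chars(seq)
  out <- list()
  for (r in seq_len(nrow(motifs))) {
    L <- nchar(motifs$consensus[r])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") motifs$consensus[r] else
        oracle_rc(motifs$consensus[r])
      core <- if (strand == "+") motifs$core_start[r]:motifs$core_end[r] else
        (L - motifs$core_end[r] + 1):(L - motifs$core_start[r] + 1)
      p <- chars(pat)
      if (L > length(s)) next
      starts <- seq_len(length(s) - L + 1L)
      ok <- matrix(FALSE, nrow = L, ncol = length(starts))
      for (i in seq_len(L)) {
        ok[i, ] <- s[starts + i - 1L] %in% IUPAC_ORACLE[[p[i]]]
      }
      sim <- colMeans(ok)
      core_ok <- colSums(!ok[core, , drop = FALSE]) == 0L
      hit <- which(core_ok & sim >= min_sim)
      if (length(hit) > 0) {
        out[[length(out) + 1L]] <- data.frame(
          motif = motifs$name[r], position = starts[hit], strand = strand,
          similarity = sim[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(motif = character(0), position = integer(0),
                      strand = character(0), similarity = numeric(0)))
  }
  df <- do.call(rbind, out)
  ## non-redundant per (motif, position, strand), best similarity
  df <- df[order(df$motif, df$position, df$strand, -df$similarity), ]
  df <- df[!duplicated(df[, c("motif", "position", "strand")]), ]
  df <- df[order(df$motif, df$position, df$strand), ]
  rownames(df) <- NULL
  df
}

## all-pairs interval scan for neighbor genes
oracle_neighbors <- function(loci, genes, exons, window = 100000,
                             orientation = "locus_strand") {
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    for (g in seq_len(nrow(genes))) {
      if (genes$chrom[g] != loci$chrom[i]) next
      gap <- if (genes$end[g] < loci$start[i]) {
        loci$start[i] - genes$end[g] - 1L
      } else if (genes$start[g] > loci$end[i]) {
        genes$start[g] - loci$end[i] - 1L
      } else 0L
      if (gap > window) next
      if (gap == 0L) {
        ex <- exons[exons$gene_id == genes$gene_id[g] &
                      exons$chrom == loci$chrom[i], , drop = FALSE]
        exon_hit <- any(ex$start <= loci$end[i] & ex$end >= loci$start[i])
        inside <- loci$start[i] >= genes$start[g] &&
          loci$end[i] <= genes$end[g]
        rel <- if (inside && !exon_hit) "intronic" else "exonic_overlap"
      } else {
        gene_left <- genes$end[g] < loci$start[i]
        side5 <- if (orientation == "forward" || loci$strand[i] != "-")
          gene_left else !gene_left
        rel <- if (side5) "upstream" else "downstream"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        locus_name = loci$name[i], gene_id = genes$gene_id[g],
        relation = rel, distance = gap, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(locus_name = character(0), gene_id = character(0),
                      relation = character(0), distance = integer(0)))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$locus_name, df$gene_id), ]
  rownames(df) <- NULL
  df
}

## substitute exactly n positions of a sequence (deterministic under seed)
substitute_n <- function(seq, n) {
  s <- chars(seq)
  pos <- sample(length(s), n)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  paste(s, collapse = "")
}

## GRanges annotation from plain gene/exon data.frames
make_annotation <- function(genes, exons) {
  df <- rbind(cbind(genes, type = "gene"), cbind(exons, type = "exon"))
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = "+")
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  gr
}

## compact clone-library spec for fast pipeline tests
small_clone_spec <- function() {
  spec <- function(cond, cell, n, f, w) {
    list(condition = cond, cell_type = cell, n_clones = n, founders = f,
         founder_weights = w / sum(w), clone_error_rate = 0.001)
  }
  list(spec("no_burn", "T", 10L, c("I", "III", "V", "VII"), rep(1, 4)),
       spec("burn_3h", "T", 10L, c("I", "III", "V", "VII"), rep(1, 4)),
       spec("burn_24h", "T", 10L, c("III", "VII"), c(0.8, 0.2)))
}
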