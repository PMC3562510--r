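## U3 clone toolkit: deduplication, size-driven grouping into phylogenetic
## branches, direct-repeat feature annotation, tropism calling.

#' Construct a set of U3 records
#'
#' Thin validated constructor for the data.frame that all U3-level operations
#' consume. A record is one cloned (or unique) U3 promoter sequence with its
#' experimental-group metadata.
#'
#' @param id Character vector of clone ids.
#' @param sequence DNA sequences (A/C/G/T/N).
#' @param condition One of `no_burn`, `burn_3h`, `burn_24h` (recycled).
#' @param cell_type `B` or `T` (recycled).
#' @param organ Source lymphoid organ (recycled).
#' @param band_id Optional gel-band id (recycled).
#' @return data.frame with columns id, sequence, length, condition,
#'   cell_type, organ, band_id.
#' @export
u3_records <- function(id, sequence, condition = NA_character_,
                       cell_type = NA_character_, organ = NA_character_,
                       band_id = NA_character_) {
  sequence <- toupper(sequence)
  if (length(sequence) != length(id)) stop("id/sequence length mismatch")
  if (any(nchar(sequence) == 0)) stop("empty sequence", call. = FALSE)
  check_dna_alphabet(sequence, id)
  ok_cond <- condition %in% c("no_burn", "burn_3h", "burn_24h") | is.na(condition)
  if (!all(ok_cond)) stop("unknown condition value", call. = FALSE)
  data.frame(id = as.character(id), sequence = sequence,
             length = nchar(sequence),
             condition = rep_len(condition, length(id)),
             cell_type = rep_len(cell_type, length(id)),
             organ = rep_len(organ, length(id)),
             band_id = rep_len(band_id, length(id)),
             stringsAsFactors = FALSE)
}

#' Deduplicate a U3 clone set into unique sequences
#'
#' Exact-string deduplication after uppercasing; near-duplicates are kept
#' distinct deliberately, because single-base differences between clones are
#' the diversity signal analysed downstream, not sequencing noise to be
#' collapsed. The representative of each unique sequence is the first-seen
#' clone; its metadata are retained.
#'
#' @param clones U3 record data.frame (see [u3_records()]).
#' @return A list with `unique` (U3 records of the representatives, plus a
#'   `multiplicity` column) and `members` (named list mapping each
#'   representative id to the ids of all clones sharing its sequence).
#' @export
dedup <- function(clones) {
  if (is.null(clones) || nrow(clones) == 0) stop("empty clone set", call. = FALSE)
  seqs <- toupper(clones$sequence)
  check_dna_alphabet(seqs, clones$id)
  key <- match(seqs, unique(seqs))
  first <- !duplicated(key)
  uni <- clones[first, , drop = FALSE]
  uni$sequence <- seqs[first]
  uni$length <- nchar(uni$sequence)
  uni$multiplicity <- as.integer(tabulate(key, nbins = sum(first)))
  members <- split(clones$id, factor(key, levels = seq_len(sum(first))))
  names(members) <- uni$id
  rownames(uni) <- NULL
  stopifnot(sum(uni$multiplicity) == nrow(clones))
  list(unique = uni, members = members)
}

#' Group unique U3 sequences into phylogenetic branches
#'
#' Builds a pairwise k-mer count distance matrix (Euclidean distance between
#' oligonucleotide count vectors, which captures both composition and
#' length), clusters with average linkage, and cuts the dendrogram at `k`
#' groups. Groups are labelled with roman numerals by descending median
#' sequence length, so group I contains the largest U3s. This reproduces the
#' size-driven branching of the clone libraries without depending on a
#' specific guide-tree program.
#'
#' @param unique_u3 U3 records of unique sequences.
#' @param k Number of branches (default 7).
#' @param kmer k-mer width for the distance (default 6).
#' @return An object of class `u3_branches`: list with `assignment` (named
#'   character vector id -> group label), `k`, and `tree` (newick string of
#'   the dendrogram).
#' @export
group_u3 <- function(unique_u3, k = 7, kmer = 6) {
  n <- nrow(unique_u3)
  if (k < 1 || k > n) stop("k must be between 1 and the number of sequences",
                           call. = FALSE)
  ord <- order(unique_u3$id)  # order-invariant clustering input
  u3 <- unique_u3[ord, , drop = FALSE]
  dss <- Biostrings::DNAStringSet(u3$sequence)
  names(dss) <- u3$id
  counts <- Biostrings::oligonucleotideFrequency(dss, width = kmer)
  d <- stats::dist(counts, method = "euclidean")
  if (n == 1L) {
    assignment <- stats::setNames("I", u3$id)
    tree <- paste0("(", u3$id, ":0);")
    return(structure(list(assignment = assignment, k = 1L, tree = tree),
                     class = "u3_branches"))
  }
  hc <- stats::hclust(d, method = "average")
  cut <- stats::cutree(hc, k = k)
  med_len <- vapply(split(u3$length, cut), stats::median, 0)
  lab_order <- order(-med_len)  # largest first -> group I
  labels <- stats::setNames(roman_labels(k), names(med_len)[lab_order])
  assignment <- stats::setNames(unname(labels[as.character(cut)]), u3$id)
  phy <- ape::as.phylo(hc)
  tree <- ape::write.tree(phy)
  structure(list(assignment = assignment, k = as.integer(k), tree = tree),
            class = "u3_branches")
}

#' @export
print.u3_branches <- function(x, ...) {
  cat("U3 branch assignment:", length(x$assignment), "sequences in",
      x$k, "groups\n")
  print(table(x$assignment))
  invisible(x)
}

## ---- feature profiles -----------------------------------------------------

#' Annotate Tomonaga-style U3 features on a sequence
#'
#' Counts, per feature, the non-overlapping local matches of the library
#' query with identity at or above `threshold` (ungapped windows; overlap
#' resolved greedily left to right), capped at two copies. TATA and the
#' 190-nt insertion are reported as presence/absence under the same identity
#' rule.
#'
#' @param u3 A U3 record (one row) or a single DNA sequence string.
#' @param feature_library Named character vector, see [load_feature_library()].
#' @param threshold Minimum match identity (default 0.85).
#' @return An object of class `u3_feature_profile`: list with `copies`
#'   (named integer vector for repeat_1, unique_2, repeat_4, repeat_5,
#'   repeat_6), `tata` and `insertion_190` logicals.
#' @export
annotate_features <- function(u3, feature_library = load_feature_library(),
                              threshold = 0.85) {
  seq <- if (is.data.frame(u3)) u3$sequence[1L] else as.character(u3)
  seq <- toupper(seq)
  check_dna_alphabet(seq, "u3")
  required <- c("repeat_1", "unique_2", "repeat_4", "repeat_5", "repeat_6",
                "tata", "insertion_190")
  missing <- setdiff(required, names(feature_library))
  if (length(missing) > 0) {
    stop("feature library is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  counts <- vapply(required, function(f) {
    count_feature_matches(seq, feature_library[[f]], threshold)
  }, 0L)
  copies <- pmin(counts[1:5], 2L)
  names(copies) <- required[1:5]
  structure(list(copies = copies,
                 tata = counts[["tata"]] > 0L,
                 insertion_190 = counts[["insertion_190"]] > 0L),
            class = "u3_feature_profile")
}

## Non-overlapping count of ungapped windows with identity >= threshold.
count_feature_matches <- function(subject, query, threshold) {
  m <- nchar(query)
  if (m > nchar(subject)) return(0L)
  max_mm <- floor((1 - threshold) * m)
  hits <- Biostrings::matchPattern(Biostrings::DNAString(query),
                                   Biostrings::DNAString(subject),
                                   max.mismatch = max_mm)
  starts <- sort(Biostrings::start(hits))
  n <- 0L
  last_end <- 0L
  for (s in starts) {  # greedy left-to-right non-overlapping selection
    if (s > last_end) {
      n <- n + 1L
      last_end <- s + m - 1L
    }
  }
  n
}

#' Render a feature profile with the conventional symbols
#'
#' Copy numbers 0/1/2 render as `.`, `+`, `+/+` (the dot standing in for the
#' middle dot of the printed convention); booleans as `.`/`+`.
#'
#' @param profile A `u3_feature_profile`.
#' @return Named character vector of symbols.
#' @export
render_profile <- function(profile) {
  sym <- function(x) c(".", "+", "+/+")[x + 1L]
  c(vapply(profile$copies, sym, ""),
    tata = sym(as.integer(profile$tata)),
    insertion_190 = sym(as.integer(profile$insertion_190)))
}

#' Parse rendered profile symbols back to copy numbers
#' @param x Character vector of symbols (`.`, `·`, `+`, `+/+`).
#' @return Integer vector of copy numbers.
#' @export
parse_copy_symbol <- function(x) {
  out <- ifelse(x %in% c(".", "·", "-", ""), 0L,
         ifelse(x == "+", 1L,
         ifelse(x == "+/+", 2L, NA_integer_)))
  if (any(is.na(out))) stop("unknown profile symbol: ",
                            paste(unique(x[is.na(out)]), collapse = " "),
                            call. = FALSE)
  out
}

#' @export
print.u3_feature_profile <- function(x, ...) {
  print(render_profile(x))
  invisible(x)
}

## ---- tropism --------------------------------------------------------------

profile_slots <- function(profile) {
  c(profile$copies, tata = as.integer(profile$tata),
    insertion_190 = as.integer(profile$insertion_190))
}

reference_slot_matrix <- function(ref) {
  m <- as.matrix(ref[, c("repeat_1", "unique_2", "repeat_4", "repeat_5",
                         "repeat_6")])
  cbind(m, tata = as.integer(ref$tata),
        insertion_190 = as.integer(ref$insertion_190))
}

#' Call the tropism trait from a U3 feature profile
#'
#' The profile is compared to the seven reference branch profiles. An exact
#' profile match returns that row's call; two reference branches share one
#' profile but differ in U3 size, so ties among exact matches are broken by
#' nearest reference size when `length` is supplied (and abstain otherwise
#' unless the tied calls agree). Without an exact match the nearest reference
#' profile by Hamming distance over the seven feature slots is used when that
#' nearest row is unique and at distance 1; larger distances or ties abstain.
#' The class letter is always kept consistent with the 190-nt insertion
#' (`P-*` only with the insertion, `X-*` only without); a nearest-profile
#' call that would violate this abstains.
#'
#' @param profile A `u3_feature_profile`.
#' @param u3_length Optional U3 length in nt, used only to break reference
#'   ties.
#' @param reference Decision table, see [load_tropism_reference()].
#' @return One of `"P-I"`, `"P-II"`, `"X-I"`, `"X-II"`, `"none"`.
#' @export
call_tropism <- function(profile, u3_length = NULL,
                         reference = load_tropism_reference()) {
  slots <- profile_slots(profile)
  refm <- reference_slot_matrix(reference)
  d <- apply(refm, 1L, function(r) sum(r != slots))
  consistent <- function(call) {
    if (call == "none") return(TRUE)
    startsWith(call, "P-") == isTRUE(profile$insertion_190)
  }
  pick <- function(idx) {
    calls <- unique(reference$tropism[idx])
    if (length(calls) == 1L) return(calls)
    if (!is.null(u3_length)) {
      best <- idx[which.min(abs(reference$size_bp[idx] - u3_length))]
      return(reference$tropism[best])
    }
    "none"
  }
  exact <- which(d == 0L)
  if (length(exact) > 0) {
    call <- pick(exact)
  } else {
    near <- which(d == min(d))
    if (min(d) > 1L || length(unique(reference$tropism[near])) > 1L) {
      call <- "none"
    } else {
      call <- reference$tropism[near[1L]]
    }
  }
  if (!consistent(call)) call <- "none"
  call
}
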