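## Loaders for the bundled configuration tables. Every library is a plain TSV
## so users can swap in curated sequences (the repeat/unique-region and PBS
## defaults shipped here are synthetic stand-ins or canonical defaults, not
## measured data; see the package vignette).

#' Load a U3 feature-sequence library
#'
#' The library supplies one query subsequence per Tomonaga-style U3 feature:
#' direct repeats `repeat_1`, `repeat_4`, `repeat_5`, `repeat_6`, the unique
#' region `unique_2`, the TATA box, and the 190-nt insertion that
#' distinguishes polytropic-type promoters. The bundled default
#' (`u3_features_synthetic.tsv`) contains synthetic stand-in sequences used by
#' the simulator so that feature annotation is testable end-to-end; replace it
#' with curated sequences for real data.
#'
#' @param path TSV with columns `feature`, `sequence`; `NULL` for the bundled
#'   default.
#' @return Named character vector of feature query sequences.
#' @export
load_feature_library <- function(path = NULL) {
  if (is.null(path)) path <- ervkit_extdata("u3_features_synthetic.tsv")
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("feature", "sequence") %in% names(df)))
  lib <- toupper(df$sequence)
  names(lib) <- df$feature
  required <- c("repeat_1", "unique_2", "repeat_4", "repeat_5", "repeat_6",
                "tata", "insertion_190")
  missing <- setdiff(required, names(lib))
  if (length(missing) > 0) {
    stop("feature library is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  check_dna_alphabet(lib, names(lib))
  lib
}

#' Load a primer-binding-site (PBS) library
#'
#' Each entry is the 18-nt sequence found immediately downstream of the
#' 5' LTR for one priming tRNA: `Q` (tRNA-Gln) and `P` (tRNA-Pro) here.
#'
#' @param path TSV with columns `type`, `sequence`; `NULL` for the bundled
#'   default.
#' @return Named character vector, names are PBS type codes.
#' @export
load_pbs_library <- function(path = NULL) {
  if (is.null(path)) path <- ervkit_extdata("pbs_library.tsv")
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("type", "sequence") %in% names(df)))
  lib <- toupper(df$sequence)
  names(lib) <- df$type
  if (any(nchar(lib) != 18)) stop("PBS sequences must be 18 nt", call. = FALSE)
  check_dna_alphabet(lib, names(lib))
  lib
}

#' Load a consensus-motif library for promoter scanning
#'
#' Motifs are IUPAC consensus strings whose core is marked by case: the
#' contiguous uppercase run is the core that must match exactly; lowercase
#' flanks contribute to the overall similarity only. The bundled default is
#' the 28-motif transcription-regulatory-element library (with the MAZF
#' consensus split into its two printed variants).
#'
#' @param path TSV with columns `tre`, `variant`, `consensus` (case-marked);
#'   `NULL` for the bundled default.
#' @return data.frame with columns `name`, `variant`, `consensus` (uppercase),
#'   `core_start`, `core_end` (1-based, inclusive) and any extra columns from
#'   the file.
#' @export
load_motif_library <- function(path = NULL) {
  if (is.null(path)) path <- ervkit_extdata("tre_motifs.tsv")
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("tre", "consensus") %in% names(df)))
  if (is.null(df$variant)) df$variant <- 1L
  core <- t(vapply(df$consensus, parse_core_span, c(start = 0L, end = 0L)))
  out <- data.frame(
    name = df$tre,
    variant = as.integer(df$variant),
    consensus = toupper(df$consensus),
    core_start = core[, "start"],
    core_end = core[, "end"],
    stringsAsFactors = FALSE
  )
  extra <- setdiff(names(df), c("tre", "variant", "consensus"))
  for (col in extra) out[[col]] <- df[[col]]
  check_iupac(out$consensus, out$name)
  rownames(out) <- NULL
  out
}

## Find the single contiguous uppercase run marking the motif core.
parse_core_span <- function(consensus) {
  chars <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  up <- chars %in% LETTERS
  if (!any(up)) stop("no uppercase core in consensus: ", consensus, call. = FALSE)
  idx <- which(up)
  if (any(diff(idx) != 1L)) {
    stop("core must be one contiguous uppercase run: ", consensus, call. = FALSE)
  }
  c(start = idx[1L], end = idx[length(idx)])
}

check_iupac <- function(seqs, ids) {
  ok <- grepl("^[ACGTRYSWKMBDHVN]*$", toupper(seqs))
  if (!all(ok)) {
    stop("malformed IUPAC letter in motif '", ids[which(!ok)[1L]], "'",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Load the tropism decision table
#'
#' The seven reference U3 feature profiles (one per phylogenetic branch) with
#' their host-range (tropism) calls: polytropic sub-classes `P-I`/`P-II`
#' (carrying the 190-nt insertion) and xenotropic `X-I`/`X-II`; the branch
#' whose features were too diverse to call carries `none`.
#'
#' @param path TSV; `NULL` for the bundled default.
#' @return data.frame with the group label, probe name, U3 size, numeric
#'   feature copy numbers, logical `tata`/`insertion_190` and the `tropism`
#'   string.
#' @export
load_tropism_reference <- function(path = NULL) {
  if (is.null(path)) path <- ervkit_extdata("u3_tropism_profiles.tsv")
  df <- read.delim(path, stringsAsFactors = FALSE)
  copies <- c("repeat_1", "unique_2", "repeat_4", "repeat_5", "repeat_6")
  for (col in copies) df[[col]] <- parse_copy_symbol(df[[col]])
  df$tata <- parse_copy_symbol(df$tata) > 0
  df$insertion_190 <- parse_copy_symbol(df$insertion_190) > 0
  df
}

#' Load the printed provirus coordinate table
#'
#' Reads the 51-row genomic map of putative MuLV-ERV loci (chromosome,
#' 1-based inclusive coordinates, orientation, size, PBS type, per-gene ORF
#' status, probe-provenance and literature reference) and checks the
#' coordinate arithmetic `size == to - from + 1` row by row. Inconsistent
#' rows are flagged via `size_consistent`, never corrected silently (one
#' printed row has an evidently truncated `from` coordinate).
#'
#' @param path TSV; `NULL` for the bundled transcription of the printed table.
#' @return data.frame with added logical columns `size_consistent` and
#'   `full_length` (gag, pol and env all intact).
#' @export
read_provirus_table <- function(path = NULL) {
  if (is.null(path)) path <- ervkit_extdata("provirus_table.tsv")
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = list(chr = "character"))
  stopifnot(all(c("virus", "chr", "from", "to", "size_bp") %in% names(df)))
  df$size_consistent <- (df$to - df$from + 1L) == df$size_bp
  if (any(!df$size_consistent)) {
    warning("coordinate arithmetic inconsistent for: ",
            paste(df$virus[!df$size_consistent], collapse = ", "),
            call. = FALSE)
  }
  df$full_length <- df$gag == "+" & df$pol == "+" & df$env == "+"
  df
}
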