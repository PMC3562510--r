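## Small shared sequence helpers. Sequences are plain uppercase character
## strings at the module boundaries; Biostrings objects are used internally
## where matching/alignment needs them.

DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA string
#'
#' Uniform i.i.d. A/C/G/T background sequence. Draws from the current RNG
#' stream (callers are responsible for seeding).
#'
#' @param n Length in bases.
#' @return A character scalar of length `n`.
#' @export
random_dna <- function(n) {
  stopifnot(n >= 0)
  if (n == 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Apply random point substitutions to a sequence
#'
#' Each position is substituted with probability `rate`; a substituted base is
#' drawn uniformly from the three alternative bases, so every substitution
#' changes the sequence.
#'
#' @param seq Character scalar (ACGT).
#' @param rate Per-base substitution probability in `[0, 1]`.
#' @return The mutated sequence.
#' @export
mutate_seq <- function(seq, rate) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0 || nchar(seq) == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Reverse complement of a DNA string
#' @param seq Character scalar.
#' @return Character scalar.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## Validate a vector of sequences against an alphabet; returns invisibly or
## stops naming the first offending id.
check_dna_alphabet <- function(seqs, ids = names(seqs), alphabet = c(DNA_BASES, "N")) {
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  pat <- sprintf("^[%s]*$", paste(alphabet, collapse = ""))
  bad <- which(!grepl(pat, seqs))
  if (length(bad) > 0) {
    stop("non-DNA characters in sequence '", ids[bad[1L]], "'", call. = FALSE)
  }
  invisible(TRUE)
}

## Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

## Path to a bundled extdata file.
ervkit_extdata <- function(file) {
  path <- system.file("extdata", file, package = "ervkit")
  if (path == "") stop("bundled file not found: ", file, call. = FALSE)
  path
}

## Roman numeral labels I, II, ... for group labelling.
roman_labels <- function(k) as.character(utils::as.roman(seq_len(k)))
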