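## Neighbor-gene mapping: annotated genes within a flanking window of each
## provirus locus, with intronic-integration flagging.

#' Map genes neighboring provirus loci
#'
#' Interval query of a gene annotation against provirus loci. A gene is
#' reported when its nearest-edge distance to the locus is at most `window`
#' bp (0 when overlapping). Relations: `intronic` when the locus lies wholly
#' inside the gene span and intersects no exon of it; `exonic_overlap` when
#' the locus intersects an exon (or straddles the gene without a clean
#' intronic placement); otherwise `upstream`/`downstream`, by default
#' relative to the provirus strand (the retroviral convention: upstream is
#' the locus's 5' side), or on forward genome coordinates with
#' `orientation = "forward"`.
#'
#' @param loci data.frame with columns name, chrom, start, end, strand
#'   (e.g. [mine()] output or a simulator truth table using its `name`).
#' @param annotation GFF3 file path or a `GRanges` with metadata columns
#'   `type` (gene/exon) and `gene_id`.
#' @param window Flanking window in bp (default 100000).
#' @param orientation `"locus_strand"` (default) or `"forward"`.
#' @return data.frame: locus_name, gene_id, relation, distance.
#' @export
neighbors <- function(loci, annotation, window = 100000,
                      orientation = c("locus_strand", "forward")) {
  orientation <- match.arg(orientation)
  ann <- load_annotation(annotation)
  genes <- ann[ann$type == "gene"]
  exons <- ann[ann$type == "exon"]
  if (length(genes) == 0) stop("annotation has no gene features", call. = FALSE)

  rows <- list()
  for (i in seq_len(nrow(loci))) {
    locus <- GenomicRanges::GRanges(
      loci$chrom[i], IRanges::IRanges(loci$start[i], loci$end[i]))
    same_chr <- genes[as.character(GenomicRanges::seqnames(genes)) ==
                        loci$chrom[i]]
    if (length(same_chr) == 0) next
    d <- GenomicRanges::distance(locus, same_chr, ignore.strand = TRUE)
    near <- which(!is.na(d) & d <= window)
    for (j in near) {
      gene <- same_chr[j]
      gid <- gene$gene_id
      gs <- GenomicRanges::start(gene)
      ge <- GenomicRanges::end(gene)
      overlaps <- loci$start[i] <= ge && loci$end[i] >= gs
      if (overlaps) {
        gene_exons <- exons[exons$gene_id == gid]
        exon_hit <- length(gene_exons) > 0 &&
          any(IRanges::overlapsAny(
            GenomicRanges::ranges(gene_exons),
            IRanges::IRanges(loci$start[i], loci$end[i])) &
            as.character(GenomicRanges::seqnames(gene_exons)) == loci$chrom[i])
        inside <- loci$start[i] >= gs && loci$end[i] <= ge
        relation <- if (inside && !exon_hit) "intronic" else "exonic_overlap"
        dist <- 0L
      } else {
        gene_left <- ge < loci$start[i]
        side5 <- if (orientation == "forward" || is.na(loci$strand[i]) ||
                     loci$strand[i] != "-") gene_left else !gene_left
        relation <- if (side5) "upstream" else "downstream"
        dist <- as.integer(d[j])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        locus_name = loci$name[i], gene_id = gid, relation = relation,
        distance = dist, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(locus_name = character(0), gene_id = character(0),
                      relation = character(0), distance = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$locus_name, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

load_annotation <- function(annotation) {
  if (methods::is(annotation, "GRanges")) {
    if (!all(c("type", "gene_id") %in%
             names(S4Vectors::mcols(annotation)))) {
      stop("annotation GRanges needs 'type' and 'gene_id' columns",
           call. = FALSE)
    }
    return(annotation)
  }
  gr <- tryCatch(
    rtracklayer::import(annotation, format = "gff3"),
    error = function(e) stop("malformed annotation record: ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(gr$gene_id)) {
    gr$gene_id <- if (!is.null(gr$ID)) as.character(gr$ID) else
      as.character(gr$Parent)
  }
  gr$type <- as.character(gr$type)
  gr
}

#' Write a gene annotation as GFF3
#'
#' @param ann `GRanges` with `type` and `gene_id` metadata columns (as from
#'   [build_gene_annotation()]).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(ann, path) {
  df <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(ann)),
    source = "ervkit",
    type = ann$type,
    start = GenomicRanges::start(ann),
    end = GenomicRanges::end(ann),
    score = ".",
    strand = as.character(GenomicRanges::strand(ann)),
    phase = ".",
    attributes = ifelse(ann$type == "gene",
                        paste0("ID=", ann$gene_id, ";gene_id=", ann$gene_id),
                        paste0("Parent=", ann$gene_id, ";gene_id=",
                               ann$gene_id)),
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
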