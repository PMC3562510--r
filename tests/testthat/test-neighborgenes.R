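test_that("window membership and directional relations are correct", {
  loci <- data.frame(name = "ERV_01", chrom = "chr1", start = 500000L,
                     end = 508000L, strand = "+", stringsAsFactors = FALSE)
  genes <- data.frame(
    chrom = "chr1",
    start = c(430000L, 260000L, 560001L),
    end = c(449999L, 280000L, 580000L),
    gene_id = c("near_left", "far_left", "near_right"),
    stringsAsFactors = FALSE)
  exons <- genes  # single-exon genes
  ann <- make_annotation(genes, exons)
  nb <- neighbors(loci, ann)
  ## 50 kb gap on the left, in window; 220 kb gap out of window
  expect_setequal(nb$gene_id, c("near_left", "near_right"))
  left <- nb[nb$gene_id == "near_left", ]
  expect_equal(left$relation, "upstream")
  expect_equal(left$distance, 50000L)
  expect_equal(nb$relation[nb$gene_id == "near_right"], "downstream")
  ## minus-strand locus flips upstream/downstream under the default
  loci_m <- transform(loci, strand = "-")
  nb_m <- neighbors(loci_m, ann)
  expect_equal(nb_m$relation[nb_m$gene_id == "near_left"], "downstream")
  expect_equal(nb_m$relation[nb_m$gene_id == "near_right"], "upstream")
  ## forward-coordinate convention ignores the locus strand
  nb_f <- neighbors(loci_m, ann, orientation = "forward")
  expect_equal(nb_f$relation[nb_f$gene_id == "near_left"], "upstream")
})

test_that("intronic and exonic overlaps are distinguished", {
  loci <- data.frame(name = "ERV_01", chrom = "chr1", start = 50000L,
                     end = 58000L, strand = "+", stringsAsFactors = FALSE)
  genes <- data.frame(chrom = "chr1", start = 40000L, end = 70000L,
                      gene_id = "host", stringsAsFactors = FALSE)
  intron_exons <- data.frame(chrom = "chr1",
                             start = c(40000L, 60000L),
                             end = c(45000L, 70000L),
                             gene_id = "host", stringsAsFactors = FALSE)
  nb <- neighbors(loci, make_annotation(genes, intron_exons))
  expect_equal(nb$relation, "intronic")
  expect_equal(nb$distance, 0L)
  ## an exon under the locus switches the relation
  exonic <- data.frame(chrom = "chr1", start = 52000L, end = 53000L,
                       gene_id = "host", stringsAsFactors = FALSE)
  nb2 <- neighbors(loci, make_annotation(genes, exonic))
  expect_equal(nb2$relation, "exonic_overlap")
})

test_that("results equal the brute-force all-pairs oracle on random layouts", {
  for (seed in 1:6) {
    set.seed(seed)
    n_loci <- sample(2:4, 1)
    loci <- data.frame(
      name = sprintf("L%02d", seq_len(n_loci)), chrom = "chr1",
      start = sort(sample(seq(1e5, 2e6, by = 1e4), n_loci)),
      strand = sample(c("+", "-"), n_loci, TRUE),
      stringsAsFactors = FALSE)
    loci$end <- loci$start + sample(5000:9000, n_loci)
    n_genes <- sample(8:20, 1)
    gs <- sample(seq(1, 2.2e6), n_genes)
    genes <- data.frame(chrom = "chr1", start = gs,
                        end = gs + sample(2000:30000, n_genes,
                                          replace = TRUE),
                        gene_id = sprintf("G%02d", seq_len(n_genes)),
                        stringsAsFactors = FALSE)
    exons <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
      data.frame(chrom = "chr1",
                 start = c(genes$start[g], genes$end[g] - 500L),
                 end = c(genes$start[g] + 500L, genes$end[g]),
                 gene_id = genes$gene_id[g], stringsAsFactors = FALSE)
    }))
    got <- neighbors(loci, make_annotation(genes, exons))
    want <- oracle_neighbors(loci, genes, exons)
    expect_equal(got, want, info = seed)
  }
})

test_that("shrinking the window never adds neighbors", {
  cfg <- synthetic_config(seed = 3, chrom_length = 4e5, n_proviruses = 2)
  sim <- build_genome(cfg)
  ann <- build_gene_annotation(sim$truth, 4e5, seed = 4)
  wide <- neighbors(sim$truth, ann, window = 100000)
  narrow <- neighbors(sim$truth, ann, window = 40000)
  key <- function(df) paste(df$locus_name, df$gene_id)
  expect_true(all(key(narrow) %in% key(wide)))
  expect_lte(nrow(narrow), nrow(wide))
})

test_that("planted intronic integrations are flagged over random layouts", {
  hits <- 0L
  for (seed in 1:4) {
    cfg <- synthetic_config(seed = seed + 100, chrom_length = 3e5,
                            n_proviruses = 2)
    sim <- build_genome(cfg)
    ann <- build_gene_annotation(sim$truth, 3e5,
                                 intronic = c(TRUE, FALSE), seed = seed)
    nb <- neighbors(sim$truth, ann)
    planted <- paste0("hostgene_", sim$truth$name)
    flagged <- nb[nb$relation == "intronic" & nb$gene_id %in% planted, ]
    ## exactly the wrapped provirus is intronic in its host gene
    expect_equal(nrow(flagged), 1L)
    hits <- hits + nrow(flagged)
  }
  expect_equal(hits, 4L)
})

test_that("malformed annotation input raises a loader error", {
  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chr1\tx\tgene\tnot_a_number\t10\t.\t+\t."),
             bad)
  loci <- data.frame(name = "L1", chrom = "chr1", start = 1L, end = 10L,
                     strand = "+")
  expect_error(neighbors(loci, bad), "malformed")
})
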