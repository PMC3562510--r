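test_that("a motif hits its own consensus exactly once, forward", {
  motifs <- load_motif_library()
  for (r in c(1, 7, 16)) {
    m <- motifs[r, , drop = FALSE]
    hits <- scan_motifs(m$consensus, m)
    fwd <- hits[hits$strand == "+", ]
    expect_equal(nrow(fwd), 1L)
    expect_equal(fwd$position, 1L)
    expect_equal(fwd$similarity, 1.0)
  }
})

test_that("the reverse complement of a consensus gives one minus-strand hit", {
  motifs <- load_motif_library()
  m <- motifs[motifs$name == "BRNF", , drop = FALSE]
  hits <- scan_motifs(revcomp(m$consensus), m)
  minus <- hits[hits$strand == "-", ]
  expect_equal(nrow(minus), 1L)
  expect_equal(minus$position, 1L)
  expect_equal(minus$similarity, 1.0)
})

test_that("scan equals the exhaustive-window oracle on random sequences", {
  motifs <- load_motif_library()
  for (seed in 1:5) {
    set.seed(seed)
    seq <- random_dna(2000)
    got <- scan_motifs(seq, motifs, min_similarity = 0.75)
    want <- oracle_scan(seq, motifs, 0.75)
    got_key <- got[order(got$motif, got$position, got$strand),
                   c("motif", "position", "strand", "similarity")]
    rownames(got_key) <- NULL
    expect_equal(got_key, want, info = seed)
  }
})

test_that("IUPAC ambiguity codes in consensus are honoured", {
  motifs <- data.frame(name = "AMB", variant = 1L, consensus = "AARRTCA",
                       core_start = 3L, core_end = 4L)
  hits <- scan_motifs("TTAAGGTCATT", motifs, min_similarity = 0.9)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$position, 3L)
  expect_equal(fwd$similarity, 1.0)
  bad <- data.frame(name = "BAD", variant = 1L, consensus = "ACGZ",
                    core_start = 1L, core_end = 2L)
  expect_error(scan_motifs("ACGT", bad), "IUPAC")
})

test_that("self-concatenation at least doubles hit counts", {
  motifs <- load_motif_library()
  m <- motifs[motifs$name == "GATA", , drop = FALSE]
  set.seed(3)
  seq <- paste0(random_dna(50), m$consensus, random_dna(50))
  one <- nrow(scan_motifs(seq, m))
  two <- nrow(scan_motifs(paste0(seq, seq), m))
  expect_gte(two, 2 * one)
})

test_that("occurrence table counts per group with both counting modes", {
  motifs <- load_motif_library()
  m <- motifs[motifs$name == "DMRT", , drop = FALSE]
  set.seed(6)
  bg <- function() paste(sample(c("C", "G"), 60, TRUE), collapse = "")
  seqs <- c(b1 = paste0(bg(), m$consensus, bg()),
            b2 = paste0(bg(), m$consensus, bg(), m$consensus, bg()),
            b3 = bg(), n1 = bg(), n2 = bg(), n3 = bg())
  recs <- u3_records(names(seqs), unname(seqs))
  hits <- scan_motifs_set(recs, m)
  meta <- data.frame(u3_id = names(seqs),
                     group = rep(c("burn", "no_burn"), each = 3))
  occ_seq <- occurrence_table(hits, meta, count = "sequences")
  expect_equal(occ_seq$burn, 2L)
  expect_equal(occ_seq$no_burn, 0L)
  expect_equal(render_contrast(occ_seq, "burn", "no_burn")$contrast, "2 / 0")
  occ_hits <- occurrence_table(hits, meta, count = "hits")
  expect_equal(occ_hits$burn, 3L)
  ## sequence-mode counts never exceed the group size
  expect_true(all(occ_seq$burn <= 3 & occ_seq$no_burn <= 3))
  ## orphan ids are an error
  expect_error(occurrence_table(hits, meta[-1, ]), "no metadata")
})

test_that("a planted burn-founder motif shows the burn-skewed contrast", {
  lib <- load_feature_library()
  motifs <- load_motif_library()
  m <- motifs[motifs$name == "DMRT", , drop = FALSE]
  tpl <- u3_templates(lib)
  planted <- paste0(substr(tpl[["III"]], 1, 200), m$consensus,
                    substr(tpl[["III"]], 201 + nchar(m$consensus), 440))
  spec <- list(
    list(condition = "burn_24h", cell_type = "B", n_clones = 10L,
         founders = "planted", founder_weights = 1, clone_error_rate = 0.001),
    list(condition = "no_burn", cell_type = "B", n_clones = 10L,
         founders = "III", founder_weights = 1, clone_error_rate = 0.001))
  cfg <- synthetic_config(seed = 12, clone_library = spec,
                          founder_templates = c(u3_templates(),
                                                planted = unname(planted)))
  clones <- build_clone_library(cfg)
  hits <- scan_motifs_set(clones, m)
  meta <- data.frame(u3_id = clones$id,
                     group = ifelse(clones$condition == "no_burn",
                                    "no_burn", "burn"))
  occ <- occurrence_table(hits, meta, count = "sequences")
  expect_gte(occ$burn[occ$motif == "DMRT"], 8L)
  expect_lte(occ$no_burn[occ$motif == "DMRT"], 1L)
})
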