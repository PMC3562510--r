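probe_tpl <- u3_templates()[["III"]]  # 440 nt

plant_in_background <- function(piece, at, len = 5e4, seed = 1) {
  set.seed(seed)
  bg <- random_dna(len)
  paste0(substr(bg, 1, at - 1), piece,
         substr(bg, at + nchar(piece), len))
}

test_that("a verbatim planted probe is recovered with exact coordinates", {
  genome <- c(chr1 = plant_in_background(probe_tpl, 10001, seed = 2))
  hits <- find_probe_hits(genome, c(u3 = probe_tpl))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 10001L)
  expect_equal(hits$end, 10001L + nchar(probe_tpl) - 1L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$identity, 1.0)
  ## minus strand
  genome_rc <- c(chr1 = plant_in_background(revcomp(probe_tpl), 10001,
                                            seed = 3))
  hits_rc <- find_probe_hits(genome_rc, c(u3 = probe_tpl))
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$start, 10001L)
  expect_error(find_probe_hits(Biostrings::DNAStringSet(), c(u3 = probe_tpl)),
               "empty genome")
  expect_error(find_probe_hits(genome, c(short = "ACGTACGT")), "50")
})

test_that("the 98% identity threshold separates 1% from 5% divergence", {
  set.seed(21)
  near <- substitute_n(probe_tpl, 4)   # ~0.991 identity
  far <- substitute_n(probe_tpl, 22)   # ~0.95 identity
  g1 <- c(chr1 = plant_in_background(near, 20001, seed = 4))
  h1 <- find_probe_hits(g1, c(u3 = probe_tpl))
  expect_equal(nrow(h1), 1L)
  expect_gte(h1$identity, 0.98)
  expect_equal(h1$identity, (440 - 4) / 440)
  g2 <- c(chr1 = plant_in_background(far, 20001, seed = 5))
  h2 <- find_probe_hits(g2, c(u3 = probe_tpl))
  expect_equal(nrow(h2), 0L)
})

test_that("LTR pairing respects the size window and leaves solos unpaired", {
  hits <- data.frame(
    probe_id = "u3", chrom = "chr1",
    start = c(1000L, 9000L, 20000L),
    end = c(1439L, 9439L, 20439L),
    strand = "+", identity = 1.0, stringsAsFactors = FALSE)
  pairs <- pair_ltrs(hits)
  ## 1000-9439 spans 8440 (in window); 9000-20439 spans 11440 (in window)
  ## but hit 2 is already used by the better-left pair; 1000-20439 too long
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$left_start, 1000L)
  expect_equal(pairs$right_end, 9439L)
  ## single hit: no pair
  expect_equal(nrow(pair_ltrs(hits[1, ])), 0L)
  ## two proviruses ~3.5 kb apart: every cross pair falls outside the size
  ## window (verified by enumerating all 6 pairs), so no cross-pairing
  hits2 <- data.frame(
    probe_id = "u3", chrom = "chr1",
    start = c(1000L, 10000L, 14000L, 23000L),
    end = c(1439L, 10439L, 14439L, 23439L),
    strand = "+", identity = c(1, 1, 0.99, 0.99), stringsAsFactors = FALSE)
  in_window <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    span <- hits2$end[j] - hits2$start[i] + 1L
    if (span >= 5000 && span <= 12000) in_window <- rbind(in_window, c(i, j))
  }
  expect_equal(nrow(in_window), 2L)  # only the two true pairs qualify
  pairs2 <- pair_ltrs(hits2)
  expect_equal(nrow(pairs2), 2L)
  expect_equal(pairs2$left_start, c(1000L, 14000L))
  expect_equal(pairs2$right_end, c(10439L, 23439L))
})

test_that("terminal-LTR comparison counts point mutations and is strand-safe", {
  set.seed(33)
  ltr <- probe_tpl
  ltr_mut <- substitute_n(ltr, 2)
  spacer <- random_dna(7000)
  construct <- paste0(ltr, spacer, ltr_mut)
  for (strand in c("+", "-")) {
    piece <- if (strand == "+") construct else revcomp(construct)
    genome <- c(chr1 = plant_in_background(piece, 5001, len = 2e4, seed = 6))
    pair <- data.frame(chrom = "chr1", strand = strand,
                       left_start = 5001L, left_end = 5000L + 440L,
                       right_start = 5001L + 440L + 7000L,
                       right_end = 5000L + nchar(construct))
    res <- check_ltr_identity(genome, pair)
    expect_false(res$identical)
    expect_equal(res$identity, (440 - 2) / 440)
  }
  ## zero divergence
  genome0 <- c(chr1 = plant_in_background(paste0(ltr, spacer, ltr), 5001,
                                          len = 2e4, seed = 7))
  pair0 <- data.frame(chrom = "chr1", strand = "+",
                      left_start = 5001L, left_end = 5440L,
                      right_start = 5001L + 7440L, right_end = 5000L + 7880L)
  expect_true(check_ltr_identity(genome0, pair0)$identical)
})

test_that("PBS typing tolerates one substitution and abstains otherwise", {
  pbs <- load_pbs_library()
  set.seed(41)
  mk_genome <- function(pbs_seq) {
    construct <- paste0(probe_tpl, pbs_seq, random_dna(7000), probe_tpl)
    list(g = c(chr1 = plant_in_background(construct, 3001, len = 2e4,
                                          seed = 8)),
         pair = data.frame(chrom = "chr1", strand = "+",
                           left_start = 3001L, left_end = 3440L,
                           right_start = 3001L + 440L + 18L + 7000L,
                           right_end = 3000L + 2 * 440L + 18L + 7000L))
  }
  exact <- mk_genome(pbs[["Q"]])
  expect_equal(call_pbs(exact$g, exact$pair, pbs), "Q")
  one_off <- mk_genome(substitute_n(pbs[["Q"]], 1))
  expect_equal(call_pbs(one_off$g, one_off$pair, pbs), "Q")
  random18 <- mk_genome(random_dna(18))
  expect_equal(call_pbs(random18$g, random18$pair, pbs), "unknown")
})

test_that("ORF classification matches planted gene status and translation", {
  cfg <- synthetic_config(
    seed = 19, chrom_length = 2e5, n_proviruses = 1,
    provirus_spec = data.frame(class = "III", strand = "+", pbs_type = "Q",
                               gag = "intact", pol = "partial",
                               env = "defective"))
  sim <- build_genome(cfg)
  tr <- sim$truth
  pair <- data.frame(chrom = tr$chrom, strand = tr$strand,
                     left_start = tr$start, left_end = tr$start + 439L,
                     right_start = tr$end - 439L, right_end = tr$end)
  orf <- call_orfs(sim$genome, pair, cfg$reference_model)
  expect_equal(unname(orf), c("intact", "partial", "defective"))
  ## translation oracle: the pol gene's peptide stops near 50% of its length
  chr <- as.character(sim$genome[[tr$chrom]])
  internal <- substr(chr, tr$start + 440 + 18, tr$end - 440)
  model <- cfg$reference_model
  pol_start <- model$leader + 3 * (model$gag_aa + 1) + model$spacer + 1
  pol_nt <- substr(internal, pol_start, pol_start + 3 * (model$pol_aa + 1) - 1)
  pep <- as.character(Biostrings::translate(Biostrings::DNAString(pol_nt)))
  stop_at <- regexpr("*", pep, fixed = TRUE)[1]
  expect_equal(stop_at, floor(model$pol_aa * 0.5))
  ## gag translates clean to its terminal stop
  gag_nt <- substr(internal, model$leader + 1,
                   model$leader + 3 * (model$gag_aa + 1))
  gag_pep <- as.character(Biostrings::translate(Biostrings::DNAString(gag_nt)))
  expect_equal(regexpr("*", gag_pep, fixed = TRUE)[1], model$gag_aa + 1)
})

test_that("zero-noise mining recovers planted proviruses and ignores solo LTRs", {
  cfg <- synthetic_config(seed = 23, chrom_length = 6e5, n_proviruses = 4,
                          n_solo_ltrs = 2)
  sim <- build_genome(cfg)
  probes <- u3_records(names(cfg$founder_templates),
                       unname(cfg$founder_templates))
  rep <- mine(sim$genome, probes, pbs_library = cfg$pbs_library,
              reference_model = cfg$reference_model)
  tr <- sim$truth
  expect_equal(nrow(rep), nrow(tr))
  expect_equal(rep$start, tr$start)
  expect_equal(rep$end, tr$end)
  expect_equal(rep$strand, tr$strand)
  expect_equal(rep$size, tr$size)
  expect_equal(rep$pbs, tr$pbs_type)
  expect_equal(rep$gag, unname(c(intact = "+", partial = "P",
                                 defective = "-")[tr$gag]))
  expect_equal(rep$pol, unname(c(intact = "+", partial = "P",
                                 defective = "-")[tr$pol]))
  expect_equal(rep$env, unname(c(intact = "+", partial = "P",
                                 defective = "-")[tr$env]))
  expect_equal(rep$ltr_identical, tr$ltr_identical)
  expect_equal(rep$full_length,
               tr$gag == "intact" & tr$pol == "intact" & tr$env == "intact")
  ## no reported locus overlaps a solo LTR decoy
  for (j in seq_len(nrow(sim$solo_ltrs))) {
    solo <- sim$solo_ltrs[j, ]
    expect_false(any(rep$chrom == solo$chrom &
                       rep$start <= solo$end & rep$end >= solo$start))
  }
})

test_that("1% body mutation leaves LTR boundary coordinates exact", {
  cfg <- synthetic_config(seed = 29, chrom_length = 6e5, n_proviruses = 4,
                          point_mutation_rate = 0.01)
  sim <- build_genome(cfg)
  probes <- u3_records(names(cfg$founder_templates),
                       unname(cfg$founder_templates))
  rep <- mine(sim$genome, probes, pbs_library = cfg$pbs_library,
              reference_model = cfg$reference_model)
  tr <- sim$truth
  expect_gte(nrow(rep), nrow(tr) - 1L)
  matched <- merge(rep, tr, by = c("chrom", "start"))
  expect_gte(nrow(matched), nrow(tr) - 1L)
  expect_equal(matched$end.x, matched$end.y)
  expect_equal(matched$strand.x, matched$strand.y)
})
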