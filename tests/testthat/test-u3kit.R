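test_that("dedup performs exact-string collapse with multiplicities", {
  recs <- u3_records(c("c1", "c2", "c3"), c("ACGT", "acgt", "ACGA"))
  dd <- dedup(recs)
  expect_equal(nrow(dd$unique), 2L)
  expect_equal(dd$unique$multiplicity, c(2L, 1L))
  expect_equal(dd$unique$id, c("c1", "c3"))
  expect_equal(dd$members$c1, c("c1", "c2"))
  ## idempotent
  dd2 <- dedup(dd$unique)
  expect_equal(nrow(dd2$unique), 2L)
  expect_error(dedup(recs[0, ]), "empty")
})

test_that("dedup names the offending id on non-DNA input", {
  recs <- data.frame(id = c("ok", "bad"), sequence = c("ACGT", "ACXT"))
  expect_error(dedup(recs), "bad")
})

test_that("dedup unique count equals the hash-set oracle on a full library", {
  cfg <- synthetic_config(seed = 17)
  clones <- build_clone_library(cfg)
  dd <- dedup(clones)
  expect_equal(nrow(dd$unique), length(unique(toupper(clones$sequence))))
  expect_lte(nrow(dd$unique), nrow(clones))
  expect_equal(sum(dd$unique$multiplicity), nrow(clones))
})

test_that("seven size classes cluster into seven size-ordered branches", {
  tpl <- u3_templates()
  set.seed(31)
  recs <- do.call(rbind, lapply(names(tpl), function(cl) {
    u3_records(id = paste0(cl, "_", 1:3),
               sequence = c(tpl[[cl]],
                            mutate_seq(tpl[[cl]], 0.01),
                            mutate_seq(tpl[[cl]], 0.01)))
  }))
  recs <- dedup(recs)$unique
  br <- group_u3(recs, k = 7)
  ## every sequence of one class shares one group label
  class_of <- sub("_.*", "", names(br$assignment))
  tab <- table(class_of, br$assignment)
  expect_true(all(rowSums(tab > 0) == 1L))
  ## labels ordered by descending size: class I (615 nt) -> group I, etc.
  for (cl in names(tpl)) {
    expect_equal(unname(br$assignment[[paste0(cl, "_1")]]), cl)
  }
  expect_match(br$tree, "^\\(")
})

test_that("branch assignment is invariant under input order", {
  tpl <- u3_templates()
  set.seed(77)
  recs <- do.call(rbind, lapply(names(tpl), function(cl) {
    u3_records(id = paste0(cl, "_", 1:2),
               sequence = c(tpl[[cl]], mutate_seq(tpl[[cl]], 0.02)))
  }))
  br1 <- group_u3(recs, k = 7)
  perm <- recs[sample(nrow(recs)), ]
  br2 <- group_u3(perm, k = 7)
  expect_equal(br1$assignment[sort(names(br1$assignment))],
               br2$assignment[sort(names(br2$assignment))])
})

test_that("degenerate grouping inputs behave", {
  recs <- u3_records(c("a", "b"), c(strrep("ACGT", 30), strrep("ACGT", 30)))
  br <- group_u3(recs, k = 1)
  expect_equal(unname(br$assignment), c("I", "I"))
  expect_error(group_u3(recs, k = 5), "between 1")
  expect_error(group_u3(recs, k = 0), "between 1")
})

test_that("feature copy numbers match the brute-force sliding-window oracle", {
  lib <- load_feature_library()
  tpl <- u3_templates(lib)
  set.seed(13)
  seqs <- c(unname(tpl), vapply(unname(tpl), mutate_seq, "", rate = 0.02))
  feats <- c("repeat_1", "unique_2", "repeat_4", "repeat_5", "repeat_6",
             "tata", "insertion_190")
  for (s in seqs) {
    prof <- annotate_features(s, lib)
    got <- c(prof$copies, tata = as.integer(prof$tata),
             insertion_190 = as.integer(prof$insertion_190))
    for (f in feats) {
      want <- oracle_count_matches(s, lib[[f]], 0.85)
      if (f %in% c("tata", "insertion_190")) want <- as.integer(want > 0)
      else want <- min(want, 2L)
      expect_equal(unname(got[[f]]), want, info = f)
    }
  }
})

test_that("featureless sequence yields an all-zero profile", {
  set.seed(4)
  gc_only <- paste(sample(c("C", "G"), 400, replace = TRUE), collapse = "")
  prof <- annotate_features(gc_only)
  expect_true(all(prof$copies == 0L))
  expect_false(prof$tata)
  expect_false(prof$insertion_190)
  expect_equal(call_tropism(prof), "none")
})

test_that("profile rendering round-trips", {
  prof <- annotate_features(u3_templates()[["V"]])
  sym <- render_profile(prof)
  expect_equal(unname(sym[1:5]), c("+/+", "+", "+", "+/+", "+/+"))
  expect_equal(unname(parse_copy_symbol(sym[1:5])), unname(prof$copies))
  expect_error(parse_copy_symbol("++"), "unknown")
})

test_that("tropism decision table reproduces every reference branch", {
  ref <- load_tropism_reference()
  want <- c("P-II", "P-I", "X-II", "X-II", "X-I", "none", "X-II")
  for (i in seq_len(nrow(ref))) {
    prof <- structure(list(
      copies = c(repeat_1 = ref$repeat_1[i], unique_2 = ref$unique_2[i],
                 repeat_4 = ref$repeat_4[i], repeat_5 = ref$repeat_5[i],
                 repeat_6 = ref$repeat_6[i]),
      tata = ref$tata[i], insertion_190 = ref$insertion_190[i]),
      class = "u3_feature_profile")
    expect_equal(call_tropism(prof, u3_length = ref$size_bp[i]), want[i])
  }
})

test_that("near-miss profiles fall back to nearest branch or abstain", {
  ref <- load_tropism_reference()
  mk <- function(r1, u2, r4, r5, r6, tata, ins) {
    structure(list(copies = c(repeat_1 = r1, unique_2 = u2, repeat_4 = r4,
                              repeat_5 = r5, repeat_6 = r6),
                   tata = tata, insertion_190 = ins),
              class = "u3_feature_profile")
  }
  ## distance 1 from branch VII only -> inherits X-II
  expect_equal(call_tropism(mk(2, 0, 2, 0, 2, TRUE, FALSE)), "X-II")
  ## branch I profile without the insertion: tied/inconsistent -> abstain
  expect_equal(call_tropism(mk(2, 1, 1, 1, 2, TRUE, FALSE)), "none")
  ## far from everything -> abstain
  expect_equal(call_tropism(mk(0, 0, 0, 0, 0, FALSE, FALSE)), "none")
  ## shared branch III/V profile without a length: conflicting calls -> abstain
  expect_equal(call_tropism(mk(2, 1, 1, 2, 2, TRUE, FALSE)), "none")
  ## with a length the nearer printed size wins
  expect_equal(call_tropism(mk(2, 1, 1, 2, 2, TRUE, FALSE), u3_length = 440),
               "X-II")
  expect_equal(call_tropism(mk(2, 1, 1, 2, 2, TRUE, FALSE), u3_length = 392),
               "X-I")
})
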