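rec <- function(nt_start, nt_stop, sense = "sense", clone_id = "c1") {
  list(clone_id = clone_id, nt_start = nt_start, nt_stop = nt_stop,
       sense = sense)
}

test_that("frame classification follows the codon-boundary rule", {
  orf <- reference_orfs("g", paste(rep("ATGGCTGCA", 70), collapse = ""))
  expect_equal(classify_frame(rec(37, 522), orf), "IF")   # 36 %% 3 == 0
  expect_equal(classify_frame(rec(38, 522), orf), "OOF")  # 37 %% 3 == 1
  expect_equal(classify_frame(rec(39, 522), orf), "OOF")
  expect_equal(classify_frame(rec(37, 522, sense = "antisense"), orf), "OOF")
  expect_error(classify_frame(rec(700, 800), orf),
               class = "sidmap_validation_error")

  # invariance under +3 shifts within the CDS; UTR starts clamp to cds_start
  utr_orf <- reference_orfs("u", paste0("GGGGG",
                                        paste(rep("ATGGCTGCA", 20), collapse = "")),
                            cds_start = 6L, cds_stop = 185L)
  set.seed(3)
  for (k in 1:30) {
    s <- sample(6:150, 1)
    f1 <- classify_frame(rec(s, 180), utr_orf)
    f2 <- classify_frame(rec(s + 3L, 183), utr_orf)
    expect_identical(f1, f2)
  }
  expect_equal(classify_frame(rec(2, 100), utr_orf),
               classify_frame(rec(6, 100), utr_orf))
})

test_that("residue projection clamps to the CDS and drops partial codons", {
  orf <- reference_orfs("Rab6a", paste(rep("ATGGCTGCA", 70), collapse = ""),
                        cds_start = 1L, cds_stop = 624L)
  iv <- to_residue_interval(rec(37, 522), orf)
  expect_equal(c(iv$aa_start, iv$aa_stop), c(13L, 174L))
  iv <- to_residue_interval(rec(1, 624), orf)
  expect_equal(c(iv$aa_start, iv$aa_stop), c(1L, 208L))
  iv <- to_residue_interval(rec(4, 11), orf)  # 8 nt -> 2 complete codons
  expect_equal(c(iv$aa_start, iv$aa_stop), c(2L, 3L))
  # clamping over the 3' end
  iv <- to_residue_interval(rec(616, 630), orf)
  expect_equal(c(iv$aa_start, iv$aa_stop), c(206L, 208L))
  expect_error(to_residue_interval(rec(38, 522), orf),
               class = "sidmap_usage_error")
  expect_error(to_residue_interval(rec(622, 623), orf),
               class = "sidmap_validation_error")

  # interval length is bounded by ceil(nt len / 3) and monotone in nt length
  set.seed(7)
  for (k in 1:40) {
    s <- 3L * sample(0:100, 1) + 1L
    len1 <- sample(3:200, 1)
    len2 <- len1 + sample(1:100, 1)
    iv1 <- to_residue_interval(rec(s, min(624, s + len1 - 1L)), orf)
    iv2 <- to_residue_interval(rec(s, min(624, s + len2 - 1L)), orf)
    w1 <- iv1$aa_stop - iv1$aa_start + 1L
    w2 <- iv2$aa_stop - iv2$aa_start + 1L
    expect_lte(w1, ceiling(len1 / 3))
    expect_gte(w2, w1)
  }
})

test_that("prey assignment recovers planted fragments and honours thresholds", {
  set.seed(19)
  refs <- reference_orfs(
    sprintf("R%02d", 1:5),
    vapply(1:5, function(i) paste(sample(c("A", "C", "G", "T"), 900,
                                         replace = TRUE), collapse = ""),
           character(1))
  )
  pol <- mapping_policy("exact_match", allow_antisense = TRUE)

  frag <- substr(refs$mrna_seq[3], 100, 400)
  hit <- assign_prey(frag, refs, pol)
  expect_equal(hit$orf_id, "R03")
  expect_equal(c(hit$nt_start, hit$nt_stop), c(100L, 400L))
  expect_equal(hit$sense, "sense")

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
  hit <- assign_prey(rc, refs, pol)
  expect_equal(c(hit$orf_id, hit$sense), c("R03", "antisense"))
  expect_equal(c(hit$nt_start, hit$nt_stop), c(100L, 400L))

  short <- substr(refs$mrna_seq[1], 50, 69)  # 20 nt < min_match_nt
  expect_true(is.na(assign_prey(short, refs, pol)$orf_id))

  expect_error(assign_prey(frag, refs[0, ], pol), class = "sidmap_usage_error")
  expect_error(mapping_policy("exact_match", min_match_nt = 20),
               class = "sidmap_usage_error")

  # property: random cuts >= min_match_nt come back exactly, both modes
  for (mode in c("exact_match", "seeded_match")) {
    polm <- mapping_policy(mode, allow_antisense = FALSE)
    for (k in 1:15) {
      ri <- sample(1:5, 1)
      s <- sample(1:600, 1)
      e <- s + sample(30:250, 1)
      hit <- assign_prey(substr(refs$mrna_seq[ri], s, e), refs, polm)
      expect_equal(hit$orf_id, refs$id[ri])
      expect_equal(c(hit$nt_start, hit$nt_stop), c(s, e))
    }
  }
})

test_that("map_screen keeps OOF/antisense clones in totals but not intervals", {
  refs <- tiny_refs()
  sc <- make_screen(
    prey = c("ORF1", "ORF1", "ORF2", "nohit"),
    acc = c("ORF1", "ORF1", "ORF2", "XX"),
    nt_start = c(4L, 5L, 6L, 1L),
    nt_stop = c(30L, 30L, 20L, 10L),
    sense = c("sense", "sense", "antisense", "sense")
  )
  m <- map_screen(sc, refs)
  expect_equal(nrow(m$records), 4L)
  expect_equal(m$records$frame, c("IF", "OOF", "OOF", "IF"))
  expect_equal(nrow(m$intervals), 1L)
  expect_equal(m$intervals$aa_start, 2L)
})
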