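test_that("clusters are connected components under shared-residue overlap", {
  iv <- make_intervals("G", c(2, 5, 300), c(190, 178, 350))
  cl <- cluster_fragments(iv)
  expect_length(cl, 2L)
  expect_equal(nrow(cl[[1]]$members), 2L)
  expect_equal(nrow(cl[[2]]$members), 1L)

  # abutting intervals share no residue
  cl <- cluster_fragments(make_intervals("G", c(1, 11), c(10, 20)))
  expect_length(cl, 2L)

  # transitive chaining
  cl <- cluster_fragments(make_intervals("G", c(1, 40, 80), c(50, 90, 120)))
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1]]$members), 3L)

  expect_length(cluster_fragments(make_intervals(character(), integer(),
                                                 integer(), character())), 0L)

  # deterministic ordering by (orf_id, min aa_start)
  iv <- make_intervals(c("B", "A", "A"), c(5, 100, 1), c(10, 120, 4))
  cl <- cluster_fragments(iv)
  expect_equal(vapply(cl, `[[`, character(1), "orf_id"), c("A", "A", "B"))
  expect_equal(vapply(cl, function(x) min(x$members$aa_start), numeric(1)),
               c(1, 100, 5))
})

test_that("SID equals the shared region, with a deepest-plateau fallback", {
  cl <- cluster_fragments(make_intervals("G", c(2, 5, 13), c(190, 178, 174)))
  sid <- compute_sid(cl[[1]])
  expect_equal(c(sid$aa_start, sid$aa_stop), c(13L, 174L))
  expect_equal(sid$support, 3L)
  expect_true(sid$complete)

  cl <- cluster_fragments(make_intervals("G", c(1, 40, 80), c(50, 90, 120)))
  sid <- compute_sid(cl[[1]])
  expect_equal(c(sid$aa_start, sid$aa_stop), c(40L, 50L))
  expect_equal(sid$support, 2L)
  expect_false(sid$complete)

  sid <- compute_sid(list(orf_id = "G",
                          members = make_intervals("G", 100, 200)))
  expect_equal(c(sid$aa_start, sid$aa_stop, sid$support), c(100L, 200L, 1L))
  expect_true(sid$complete)
})

test_that("SID matches the per-residue coverage oracle on random clusters", {
  set.seed(41)
  for (k in 1:200) {
    n <- sample(1:8, 1)
    L <- sample(30:500, 1)
    s <- sample.int(L, n, replace = TRUE)
    e <- pmin(L, s + sample.int(60, n, replace = TRUE))
    for (cl in cluster_fragments(make_intervals("G", s, e))) {
      sid <- compute_sid(cl)
      orc <- sid_oracle(cl$members$aa_start, cl$members$aa_stop)
      expect_equal(sid$aa_start, orc$aa_start)
      expect_equal(sid$aa_stop, orc$aa_stop)
      expect_equal(sid$support, orc$support)
      expect_equal(sid$complete, orc$complete)
    }
  }
})

test_that("adding fragments narrows a complete SID monotonically", {
  set.seed(43)
  for (k in 1:40) {
    base <- make_intervals("G", c(50, 60), c(200, 220))
    sid0 <- compute_sid(cluster_fragments(base)[[1]])
    # a fragment containing the SID leaves it unchanged
    sup <- make_intervals("G", sid0$aa_start - sample.int(40, 1),
                          sid0$aa_stop + sample.int(40, 1), "sup")
    sid1 <- compute_sid(cluster_fragments(rbind(base, sup))[[1]])
    expect_equal(c(sid1$aa_start, sid1$aa_stop),
                 c(sid0$aa_start, sid0$aa_stop))
    # a fragment partially overlapping it can only shrink it
    cut <- make_intervals("G", sid0$aa_start + sample.int(100, 1),
                          sid0$aa_stop + sample.int(200, 1), "cut")
    sid2 <- compute_sid(cluster_fragments(rbind(base, cut))[[1]])
    expect_gte(sid2$aa_start, sid0$aa_start)
    expect_lte(sid2$aa_stop, sid0$aa_stop)
  }
})

test_that("per-gene report computes rounded screen percentages", {
  refs <- tiny_refs()
  # 2 of 3 clones on one prey gene: 67%
  sc <- make_screen(prey = c("ORF1", "ORF1", "ORF2"),
                    acc = c("ORF1", "ORF1", "ORF2"),
                    nt_start = c(1L, 4L, 6L), nt_stop = c(72L, 60L, 41L))
  rep <- sid_report(sc, refs)
  expect_equal(rep$percent[rep$gene == "ORF1"], 67)
  expect_equal(rep$percent[rep$gene == "ORF2"], 33)

  # rounding is half-up: 4/8 -> 50, and 152/191 -> 80
  expect_equal(sidmap:::round_half_up(100 * 4 / 8), 50)
  expect_equal(sidmap:::round_half_up(100 * 152 / 191), 80)
  expect_equal(sidmap:::round_half_up(100 * 1 / 200), 1)
  expect_equal(sidmap:::round_half_up(0.5), 1)

  # SID of the ORF1 group: intersection of the two in-frame clones
  row1 <- rep[rep$gene == "ORF1", ]
  expect_equal(c(row1$sid_start, row1$sid_stop), c(2L, 20L))
  expect_true(row1$sid_complete)
})
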