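calls_df <- function(aa_start, aa_stop, outcome, orf = "GOLGB1") {
  data.frame(orf_id = orf, aa_start = aa_start, aa_stop = aa_stop,
             outcome = outcome, stringsAsFactors = FALSE)
}

test_that("narrowing intersects positives and subtracts negatives", {
  nd <- narrow_domain(calls_df(c(1399, 1430, 1462, 1399),
                               c(1641, 1700, 1540, 1461),
                               c("positive", "positive", "positive", "negative")))
  expect_equal(c(nd$aa_start, nd$aa_stop), c(1462L, 1540L))
  expect_equal(nd$length, 79L)

  nd <- narrow_domain(calls_df(c(100, 150, 160), c(200, 250, 170),
                               c("positive", "positive", "negative")))
  expect_equal(c(nd$aa_start, nd$aa_stop), c(171L, 200L))

  expect_error(narrow_domain(calls_df(c(1, 50), c(20, 80),
                                      c("positive", "positive"))),
               "positives", class = "sidmap_validation_error")
  expect_error(narrow_domain(calls_df(c(10, 5), c(50, 60),
                                      c("positive", "negative"))),
               "negatives", class = "sidmap_validation_error")
  expect_error(narrow_domain(calls_df(10, 50, "negative")),
               class = "sidmap_usage_error")
})

test_that("narrowing agrees with the residue-set oracle and is monotone", {
  set.seed(17)
  for (k in 1:60) {
    n_pos <- sample(2:5, 1)
    n_neg <- sample(0:4, 1)
    ps <- sample.int(100, n_pos)
    pe <- ps + 120 + sample.int(80, n_pos)
    ns <- sample.int(250, n_neg)
    ne <- ns + sample.int(40, n_neg)
    calls <- calls_df(c(ps, ns), c(pe, ne),
                      rep(c("positive", "negative"), c(n_pos, n_neg)))
    pos <- calls[calls$outcome == "positive", ]
    neg <- calls[calls$outcome == "negative", ]
    left <- narrow_oracle(pos, neg)
    if (max(pos$aa_start) > min(pos$aa_stop) || length(left) == 0) {
      expect_error(narrow_domain(calls), class = "sidmap_validation_error")
      next
    }
    nd <- narrow_domain(calls)
    run <- nd$aa_start:nd$aa_stop
    expect_true(all(run %in% left))
    # longest contiguous run of the oracle's residue set
    runs <- split(left, cumsum(c(1, diff(left) != 1)))
    expect_equal(nd$length, max(lengths(runs)))

    # adding a further negative never grows the result
    extra <- calls_df(max(pos$aa_start), max(pos$aa_start) + 5, "negative")
    nd2 <- tryCatch(narrow_domain(rbind(calls, extra)),
                    error = function(e) NULL)
    if (!is.null(nd2)) expect_lte(nd2$length, nd$length)
  }
})

test_that("tiling designs cover the region with the requested tile count", {
  region <- list(orf_id = "G", aa_start = 1399L, aa_stop = 1641L)  # 243 aa
  tiles <- design_tiling(region, n_tiles = 17, seed = 3)
  expect_equal(nrow(tiles), 17L)
  covered <- rep(FALSE, 243)
  for (i in 1:17) {
    covered[(tiles$aa_start[i] - 1398L):(tiles$aa_stop[i] - 1398L)] <- TRUE
  }
  expect_true(all(covered))
  expect_true(all(tiles$aa_start >= 1399 & tiles$aa_stop <= 1641))
  expect_identical(tiles, design_tiling(region, n_tiles = 17, seed = 3))

  r2 <- list(orf_id = "G", aa_start = 1L, aa_stop = 100L)
  t2 <- design_tiling(r2, n_tiles = 4, overlap_frac = 0.25, seed = 1)
  expect_equal(min(t2$aa_start), 1L)
  expect_equal(max(t2$aa_stop), 100L)

  expect_error(design_tiling(r2, n_tiles = 4, min_len = 200),
               class = "sidmap_usage_error")
  expect_error(design_tiling(r2, n_tiles = 1), class = "sidmap_usage_error")
})

test_that("simulated tiling deconvolution recovers the planted epitope", {
  for (i in 1:40) {
    set.seed(700 + i)
    L0 <- sample(150:400, 1)
    a <- sample(1:1200, 1)
    region <- list(orf_id = "G", aa_start = a, aa_stop = a + L0 - 1)
    ep_len <- sample(5:30, 1)
    ep_s <- sample(a:(region$aa_stop - ep_len + 1), 1)
    ep <- c(ep_s, ep_s + ep_len - 1)
    calls <- simulate_tiling_calls(region, ep, n_tiles = 17, seed = 800 + i)
    nd <- narrow_domain(calls)
    expect_lte(nd$aa_start, ep[1])
    expect_gte(nd$aa_stop, ep[2])
    neg <- calls[calls$outcome == "negative", ]
    expect_true(all(neg$aa_stop < nd$aa_start | neg$aa_start > nd$aa_stop))
  }
})

test_that("global alignment identities behave like percent identity", {
  expect_equal(align_sids(c(a = "MKLVAT", b = "MKLVAT"))$identity["a", "b"], 100)
  expect_equal(align_sids(c(a = "ACDEF", b = "ACDFF"))$identity["a", "b"], 80)
  aln <- align_sids(c(x = "MKWVTFISLLFLFSSAYS", y = "MKWVTAISLLFLASSAYS",
                      z = "MKWVTFISLL"))
  expect_true(isSymmetric(aln$identity))
  expect_equal(diag(aln$identity), c(x = 100, y = 100, z = 100))
  expect_lt(aln$identity["x", "y"], 100)
  expect_error(align_sids(c(a = "ACDEF", b = "ACD2F")),
               class = "sidmap_validation_error")
  expect_error(align_sids(c(a = "ACDEF")), class = "sidmap_usage_error")
})

test_that("homologue SIDs reduce to their common aligned block", {
  expect_equal(common_sid(data.frame(aa_start = c(10, 16, 5),
                                     aa_stop = c(44, 48, 74))),
               list(aa_start = 16, aa_stop = 44, length = 29L))
  expect_null(common_sid(data.frame(aa_start = c(1, 50), aa_stop = c(10, 60))))
  expect_equal(common_sid(data.frame(aa_start = c(10, 20),
                                     aa_stop = c(20, 30)))$length, 1L)

  # designed homologues: substrings of one window, one substitution each
  set.seed(23)
  w <- paste(sample(sidmap:::aa_alphabet, 90, replace = TRUE), collapse = "")
  s1 <- substr(w, 30, 64)                     # 35 aa
  s2 <- substr(w, 36, 68); substr(s2, 10, 10) <- "W"  # 33 aa
  s3 <- substr(w, 10, 79); substr(s3, 41, 41) <- "Y"  # 70 aa
  aln <- align_sids(c(h9 = s1, h10 = s2, h11 = s3))
  blk <- common_sid_block(aln)
  expect_equal(blk$block_length, 29L)
  expect_true(all(blk$identity[upper.tri(blk$identity)] >= 93))
})
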