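test_that("independent fragments are counted by distinct 5' starts", {
  expect_equal(count_independent(make_intervals("G", c(13, 13, 20),
                                                c(174, 190, 174))), 2L)
  expect_equal(count_independent(make_intervals("G", 5, 50)), 1L)
  expect_equal(count_independent(make_intervals("G", 1:7, 20 + 1:7)), 7L)
})

test_that("overlap probability is exact under enumeration", {
  expect_identical(overlap_probability(10, 10), 1.0)            # n = 1
  expect_equal(overlap_probability(c(3, 3), 10), 34 / 64)       # enumerated
  expect_equal(overlap_probability(c(20, 20), 20), 1.0)         # forced
  expect_error(overlap_probability(c(30, 5), 20),
               class = "sidmap_validation_error")

  # against the residue-membership oracle on small instances
  set.seed(5)
  for (k in 1:20) {
    L <- sample(5:20, 1)
    n <- sample(2:3, 1)
    lens <- sample.int(L, n, replace = TRUE)
    expect_equal(overlap_probability(lens, L), overlap_oracle(lens, L))
  }
})

test_that("Monte-Carlo overlap estimates agree with enumeration within 3 SE", {
  set.seed(6)
  for (k in 1:12) {
    L <- sample(10:50, 1)
    n <- sample(2:3, 1)
    lens <- pmax(2L, sample.int(L, n, replace = TRUE))
    exact <- overlap_probability(lens, L)  # state space small: enumerated
    mc <- sidmap:::with_seed(100 + k, {
      draws <- 4000L
      starts <- vapply(L - lens + 1L,
                       function(s) sample.int(s, draws, replace = TRUE),
                       integer(draws))
      hits <- sum(apply(starts, 1, max) <=
                    apply(sweep(starts, 2, lens - 1L, `+`), 1, min))
      (hits + 1) / (draws + 2)
    })
    se <- sqrt(exact * (1 - exact) / 4000) + 1e-4
    expect_lt(abs(mc - exact), 3 * se + 3e-3)
  }
  # the Monte-Carlo branch itself (huge state space) is deterministic under
  # a seed and stays within (0, 1]
  p1 <- overlap_probability(c(200, 250, 220, 210), 3000, seed = 9)
  p2 <- overlap_probability(c(200, 250, 220, 210), 3000, seed = 9)
  expect_identical(p1, p2)
  expect_gt(p1, 0)
  expect_lte(p1, 1)
})

test_that("gene scores combine an exact binomial tail with overlap odds", {
  refs <- reference_orfs(
    sprintf("G%02d", 1:10),
    vapply(c(300L, rep(100L, 9)), function(l) {
      paste(rep("GCA", l), collapse = "")
    }, character(1))
  )
  null <- null_model(refs, n_clones = 300L, seed = 2)
  expect_equal(sum(null$w), 1)
  expect_equal(null$w[["G01"]], 300 / 1200)

  members <- make_intervals("G01", c(10, 10, 25, 40, 41, 60, 70, 80, 90, 100, 110),
                            c(150, 160, 170, 180, 181, 190, 200, 210, 220, 230, 240))
  sc <- score_gene(list(orf_id = "G01", members = members), null)
  expect_equal(sc$n_independent, 10L)
  expect_equal(sc$p_count, binom_tail_oracle(10, 300, 0.25), tolerance = 1e-12)
  expect_equal(sc$evalue, 10 * sc$p_count * sc$p_overlap)
  expect_lte(sc$evalue, null$G)

  # duplicated starts never change the count term
  dup <- rbind(members, make_intervals("G01", 10, 140, "dup"))
  sc2 <- score_gene(list(orf_id = "G01", members = dup), null)
  expect_equal(sc2$p_count, sc$p_count)

  expect_error(score_gene(list(orf_id = "ZZ", members = members), null),
               class = "sidmap_usage_error")

  # monotonicity: p_count non-increasing in n_d, non-decreasing in w
  tails <- sapply(1:12, function(nd) {
    stats::pbinom(nd - 1, 300, 0.02, lower.tail = FALSE)
  })
  expect_true(all(diff(tails) < 0))
  tails_w <- sapply(c(0.01, 0.05, 0.1, 0.3), function(w) {
    stats::pbinom(4, 300, w, lower.tail = FALSE)
  })
  expect_true(all(diff(tails_w) > 0))
})

test_that("category assignment respects F > E > singleton-D > thresholds", {
  expect_equal(assign_category("g", 50, 1e-30, artifacts = "g"), "F")
  expect_equal(assign_category("g", 50, 1e-30,
                               connectivity = c(g = 0.30), tau = 0.25), "E")
  expect_equal(assign_category("g", 1, 1e-30), "D")
  expect_equal(assign_category("g", 5, 1e-12), "A")
  expect_equal(assign_category("g", 5, 1e-7), "B")
  expect_equal(assign_category("g", 5, 1e-3), "C")
  expect_equal(assign_category("g", 5, 0.5), "D")
  expect_error(assign_category("g", 5, 1, thresholds = c(1e-2, 1e-5, 1e-10)),
               class = "sidmap_usage_error")
})

test_that("connectivity index is the fraction of screens retaining a gene", {
  reg <- data.frame(screen_id = c("s1", "s1", "s2", "s3", "s4"),
                    orf_id = c("a", "b", "a", "a", "b"))
  ci <- connectivity_index(reg)
  expect_equal(ci[["a"]], 3 / 4)
  expect_equal(ci[["b"]], 2 / 4)
})
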