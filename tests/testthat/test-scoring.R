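test_that("single-match probability is the relative characteristic size", {
  expect_identical(single_match_probability(50, 1000), 0.05)
  expect_identical(single_match_probability(7, 7), 1)
  expect_error(single_match_probability(1, 0), class = "cclid_data_error")
  expect_error(single_match_probability(0, 10), class = "cclid_data_error")
  expect_error(single_match_probability(11, 10), class = "cclid_data_error")
})

test_that("p_l sums to 1 for disjoint profiles and exceeds 1 with overlap", {
  set.seed(21)
  disjoint <- build_library(lapply(1:4, function(i) {
    ccl_profile(sprintf("D%d", i), "L",
                sprintf("1:%d:%d", (i - 1) * 100 + 1:50, (i - 1) * 100 + 1:50))
  }))
  idx <- cclid:::.char_index(disjoint, 0.0)
  expect_equal(sum(idx$sizes / idx$pool_size), 1)
  shared <- rand_library(6, max_vars = 150, space = 300)  # dense overlap
  idx2 <- cclid:::.char_index(shared, 0.0)
  expect_gt(sum(idx2$sizes / idx2$pool_size), 1)
})

test_that("binomial tail matches closed forms and the pmf-summation oracle", {
  expect_identical(binomial_tail(0, 10, 0.3), 1)
  expect_equal(binomial_tail(10, 10, 0.5), 2^-10)
  expect_equal(binomial_tail(3, 10, 0.1), oracle_binom_tail(3, 10, 0.1),
               tolerance = 1e-12)
  # spot grid (the full m_L <= 25 sweep runs in the acceptance suite)
  for (p in c(0.05, 0.5, 0.9)) {
    for (m_L in c(5, 12)) {
      for (m_l in 0:m_L) {
        expect_equal(binomial_tail(m_l, m_L, p), oracle_binom_tail(m_l, m_L, p),
                     tolerance = 1e-9)
      }
    }
  }
  expect_error(binomial_tail(2, 10, 0), class = "cclid_data_error")
  expect_error(binomial_tail(11, 10, 0.5), class = "cclid_data_error")
})

test_that("tail probability is monotone in the overlap and floored", {
  P <- binomial_tail(0:20, 20, 0.3)
  expect_true(all(diff(P) <= 0))
  cs <- confidence_score(P)
  expect_true(all(diff(cs) >= 0))
  # huge self-match underflows to the floor instead of -Inf scores
  expect_identical(binomial_tail(5000, 5000, 0.01), 1e-300)
  expect_true(is.finite(confidence_score(binomial_tail(5000, 5000, 0.01))))
})

test_that("confidence score is -ln(P) with the documented boundary", {
  expect_identical(confidence_score(1), 0)
  expect_equal(confidence_score(exp(-3)), 3)
  expect_equal(confidence_score(0.01), 4.605170186, tolerance = 1e-9)
  expect_error(confidence_score(0), class = "cclid_data_error")
  # condition A boundary: cs >= t iff P <= exp(-t)
  P <- c(0.001, exp(-3), 0.05, 0.2, 1)
  expect_identical(confidence_score(P) >= 3, P <= exp(-3))
})

test_that("spuriousness matches beta-function identities and the integer oracle", {
  expect_identical(spuriousness(1, 1), 1)
  expect_equal(spuriousness(1, 2), 0.5)
  for (n in c(2, 5, 17)) {
    expect_equal(spuriousness(1, n), 1 / n, tolerance = 1e-12)
  }
  expect_equal(spuriousness(3, 7), spuriousness(7, 3))  # symmetric
  expect_equal(spuriousness(20, 500), oracle_beta_int(500, 20),
               tolerance = 1e-9)
  expect_error(spuriousness(0, 5), class = "cclid_data_error")
})

test_that("overlap threshold follows its algebra and degenerates to Inf", {
  expect_equal(overlap_threshold(10, 100, 0.5), 120)
  expect_equal(overlap_threshold(10, 100, 1e-13), 10, tolerance = 1e-9)
  expect_identical(overlap_threshold(1, 1, spuriousness(1, 1)), Inf)
  expect_error(overlap_threshold(1, 1, 0), class = "cclid_data_error")
})

test_that("match counts cover self-match, disjoint and oracle cases", {
  set.seed(22)
  lib <- build_library(lapply(1:5, function(i) {
    ccl_profile(sprintf("M%d", i), "L",
                sprintf("1:%d:%d", (i - 1) * 1000 + 1:80, (i - 1) * 1000 + 1:80))
  }))
  r <- lib$profiles[["M3"]]
  mc <- match_counts(r, lib, 0.5)   # all variants unique -> all characteristic
  expect_identical(mc$counts[ccl_id == "M3", m_l], length(r$variants))
  expect_identical(mc$m_L, length(r$variants))
  disj <- ccl_profile("Q", "q", sprintf("2:%d:%d", 1:50, 1:50))
  mc2 <- match_counts(disj, lib, 0.5)
  expect_true(all(mc2$counts$m_l == 0L))
  expect_identical(mc2$m_L, 0L)
  # random library: m_L equals brute-force union intersection
  for (rep in 1:5) {
    rl <- rand_library(20, max_vars = 100, space = 2000)
    q <- ccl_profile("Q", "q", rand_keys(150, space = 2000))
    mc3 <- match_counts(q, rl, 0.5)
    pool <- unique(unlist(characteristic_variants(rl, 0.5)))
    expect_identical(mc3$m_L, length(intersect(q$variants, pool)))
    for (id in sample(names(rl$profiles), 4)) {
      ch <- characteristic_variants(rl, 0.5)[[id]]
      expect_identical(mc3$counts[ccl_id == id, m_l],
                       length(intersect(ch, q$variants)))
    }
  }
})

test_that("a self-query identifies its reference and nothing else", {
  set.seed(23)
  # r has private characteristic variants; others share nothing with it
  profs <- lapply(1:8, function(i) {
    ccl_profile(sprintf("S%d", i), "L",
                sprintf("1:%d:%d", (i - 1) * 500 + 1:60, (i - 1) * 500 + 1:60))
  })
  lib <- build_library(profs)
  calls <- identify_ccl(profs[[4]], lib)
  expect_identical(calls[identified == TRUE, ccl_id], "S4")
  expect_identical(calls[rank == 1, ccl_id], "S4")
  # disjoint query: zero identifications
  q <- ccl_profile("Q", "q", sprintf("9:%d:%d", 1:100, 1:100))
  expect_identical(sum(identify_ccl(q, lib)$identified), 0L)
  # empty query warns and is all-negative
  expect_warning(e <- identify_ccl(ccl_profile("E", "q"), lib), "empty")
  expect_identical(sum(e$identified), 0L)
})

test_that("at most k profiles satisfy condition B and output is deterministic", {
  set.seed(24)
  lib <- rand_library(15, max_vars = 150, space = 600)
  q <- ccl_profile("Q", "q", rand_keys(200, space = 600))
  for (k in c(1, 2, 5)) {
    calls <- identify_ccl(q, lib, scoring_params(top_k = k))
    expect_identical(sum(calls$cond_b), as.integer(min(k, nrow(calls))))
  }
  c1 <- identify_ccl(q, lib)
  c2 <- identify_ccl(q, lib)
  expect_identical(c1, c2)
  expect_identical(c1$rank, seq_len(nrow(c1)))
})

test_that("identification verdicts equal the straight-line oracle", {
  set.seed(25)
  for (rep in 1:30) {
    n <- sample(3:15, 1)
    lib <- rand_library(n, max_vars = 200, space = sample(c(500, 2000), 1))
    src <- sample(names(lib$profiles), 1)
    q_vars <- unique(c(
      sample(lib$profiles[[src]]$variants,
             ceiling(0.6 * length(lib$profiles[[src]]$variants))),
      rand_keys(30, space = 2000, chrom = "7")))
    q <- ccl_profile("Q", "q", q_vars)
    thr <- sample(c(1, 0.5, 0.25, 0), 1)
    got <- suppressWarnings(
      identify_ccl(q, lib, scoring_params(weight_threshold = thr)))
    want <- oracle_identify(q$variants,
                            lapply(lib$profiles, `[[`, "variants"),
                            thr = thr)
    got <- got[order(ccl_id)]
    want <- want[order(want$ccl_id), ]
    expect_identical(got$ccl_id, want$ccl_id)
    expect_identical(got$m_l, want$m_l)
    expect_identical(got$rank, want$rank)
    expect_equal(got$cs, want$cs, tolerance = 1e-9)
    expect_identical(got$identified, want$identified)
  }
})
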