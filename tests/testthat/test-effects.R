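test_that("rank-biserial handles separation, full ties, and a hand-counted case", {
  expect_equal(rank_biserial(c(5, 6, 7), c(1, 2, 3))$estimate, 1)
  expect_equal(rank_biserial(rep(2, 4), rep(2, 5))$estimate, 0)
  # 3 vs 3 with one tie: count the 9 pairs by hand
  a <- c(1, 4, 6)
  b <- c(2, 4, 5)
  es <- rank_biserial(a, b)
  expect_equal(es$estimate, rb_brute_force(a, b))
  expect_equal(es$estimate, 1 - 2 * es$u_b / (es$n1 * es$n2))
  expect_equal(es$magnitude, abs(es$estimate))
  expect_error(rank_biserial(numeric(0), 1:3), "non-empty")
})

test_that("rank-biserial equals brute-force pair enumeration on random instances", {
  set.seed(71)
  for (i in 1:200) {
    n1 <- sample(2:40, 1)
    n2 <- sample(2:40, 1)
    # integer values force ties regularly
    a <- sample(0:8, n1, replace = TRUE)
    b <- sample(0:8, n2, replace = TRUE)
    expect_equal(rank_biserial(a, b)$estimate, rb_brute_force(a, b),
                 tolerance = 1e-12)
  }
})

test_that("bootstrap interval is seeded, bounded by the support, and sane", {
  a <- rnorm(20, 3)
  b <- rnorm(20, 0)
  ci1 <- rank_biserial_ci(a, b, seed = 5, n_boot = 500)
  ci2 <- rank_biserial_ci(a, b, seed = 5, n_boot = 500)
  expect_identical(ci1, ci2)
  # complete separation: the bootstrap cannot exceed the support
  a2 <- 101:120
  b2 <- 1:20
  ci3 <- rank_biserial_ci(a2, b2, seed = 1, n_boot = 500)
  expect_equal(unname(ci3[2]), 1)
  expect_warning(rank_biserial_ci(a, b, n_boot = 50, seed = 1), "unstable")
  cin <- rank_biserial_ci(a, b, method = "normal")
  expect_true(cin[1] <= cin[2] && cin[1] >= -1 && cin[2] <= 1)
})

test_that("Cramer's V reproduces the published worked example and limits", {
  # chi-square 16.5 on a 3x3 table with N = 60
  expect_equal(round(sqrt(16.5 / (60 * 2)), 2), 0.37)
  perfect <- diag(c(10, 10, 10))
  expect_equal(cramers_v(perfect)$estimate, 1)
  indep <- outer(c(10, 20, 30), c(1, 2, 3))
  es <- cramers_v(indep)
  expect_equal(es$chi2, 0, tolerance = 1e-12)
  expect_equal(es$estimate, 0, tolerance = 1e-9)
  expect_error(cramers_v(matrix(c(1, -1, 2, 3), 2)), "non-negative")
})

test_that("Cramer's V is invariant to transpose and permutations; empty margins drop", {
  set.seed(5)
  m <- matrix(rpois(12, 6), 3, 4)
  v0 <- cramers_v(m)$estimate
  expect_equal(cramers_v(t(m))$estimate, v0)
  expect_equal(cramers_v(m[sample(3), sample(4)])$estimate, v0)
  m2 <- rbind(m, 0)
  expect_warning(es <- cramers_v(m2), "zero-margin")
  expect_equal(es$estimate, v0)
})

test_that("noncentral inversion interval matches a grid-search oracle", {
  for (case in list(c(16.5, 4, 60, 2), c(8.2, 1, 40, 1), c(30, 9, 120, 3))) {
    ci <- cramers_v_ci(case[1], case[2], case[3], case[4])
    lam_lo <- ncp_grid_search(case[1], case[2], 0.975)
    lam_hi <- ncp_grid_search(case[1], case[2], 0.025)
    expect_equal(unname(ci[1]), sqrt(lam_lo / (case[3] * case[4])),
                 tolerance = 1e-3)
    expect_equal(unname(ci[2]), sqrt(lam_hi / (case[3] * case[4])),
                 tolerance = 1e-3)
  }
  # chi2 at 0 floors the lower bound
  ci0 <- cramers_v_ci(0, 4, 60, 2)
  expect_equal(unname(ci0[1]), 0)
  # nesting: higher confidence widens the interval
  ci95 <- cramers_v_ci(16.5, 4, 60, 2, confidence = 0.95)
  ci99 <- cramers_v_ci(16.5, 4, 60, 2, confidence = 0.99)
  expect_lte(ci99[1], ci95[1])
  expect_gte(ci99[2], ci95[2])
})

test_that("Delphi round comparison: identity, uniform shift, and validation", {
  set.seed(88)
  m1 <- rating_matrix(matrix(sample(4:7, 40, replace = TRUE), 8, 5,
                             dimnames = list(paste0("r", 1:8),
                                             paste0("c", 1:5))),
                      n_categories = 7, dimension = "ergonomics", round = 1)
  cmp_same <- compare_delphi_rounds(m1, m1)
  expect_equal(cmp_same$effect_rb, rep(0, 5))
  expect_equal(cmp_same$p_value, rep(1, 5))
  expect_true(all(cmp_same$decision == "no_difference"))

  m2 <- rating_matrix(matrix(pmin(unclass(m1) + 1L, 7L), 8, 5,
                             dimnames = dimnames(m1)),
                      n_categories = 7, dimension = "ergonomics", round = 2)
  cmp_up <- compare_delphi_rounds(m1, m2)
  expect_equal(cmp_up$effect_rb, rep(1, 5))

  m3 <- rating_matrix(matrix(4, 6, 5), n_categories = 7)
  expect_error(compare_delphi_rounds(m1, m3), "same raters and items")
})

test_that("Delphi comparison keeps its false-positive rate near nominal under the null", {
  set.seed(404)
  reject <- 0
  n_rep <- 400
  for (i in seq_len(n_rep)) {
    r1 <- matrix(sample(1:7, 20, replace = TRUE), 20, 1)
    r2 <- matrix(sample(1:7, 20, replace = TRUE), 20, 1)
    m1 <- rating_matrix(r1, n_categories = 7)
    m2 <- rating_matrix(r2, n_categories = 7)
    if (compare_delphi_rounds(m1, m2)$p_value < 0.05) reject <- reject + 1
  }
  # normal approximation on tied ordinal data: close to, and not above,
  # the nominal rate by much
  expect_lt(reject / n_rep, 0.08)
  expect_gt(reject / n_rep, 0.01)
})
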