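test_that("contingency tables cross-tabulate pairwise-complete records", {
  ids <- sprintf("r%02d", 1:10)
  cats <- rep(c("negative", "neutral", "positive"), c(4, 3, 3))
  a <- stats::setNames(cats, ids)
  tab <- build_table(a, a)
  expect_identical(unname(diag(unclass(tab)[1:3, 1:3])), c(4L, 3L, 3L))
  expect_identical(attr(tab, "n"), 10L)
  expect_error(build_table(c(x = "neutral"), c(y = "neutral")),
               "no records categorized by both")
})

test_that("the published human-human table reproduces its printed margins", {
  # rebuild the 3x3 table from per-record category pairs
  a <- character(0); b <- character(0)
  lv <- rownames(published_xtab)
  for (i in 1:3) for (j in 1:3) {
    k <- published_xtab[i, j]
    a <- c(a, rep(lv[i], k)); b <- c(b, rep(lv[j], k))
  }
  ids <- sprintf("r%03d", seq_along(a))
  tab <- build_table(stats::setNames(a, ids), stats::setNames(b, ids))
  expect_identical(attr(tab, "n"), 263L)
  expect_equal(unname(rowSums(tab)), c(125, 61, 77))
  expect_equal(unname(colSums(tab)), c(127, 70, 66))
  pct <- xtab_percent(tab)
  expect_identical(pct["negative", "negative"], "106 (83.5%)")
  expect_identical(pct["positive", "positive"], "57 (86.4%)")
  expect_identical(pct["negative", "Total"], "125 (47.5%)")
  expect_identical(pct["Total", "Total"], "263")
})

test_that("kappa is 1 under perfect agreement and 0 under independence", {
  for (w in c("unweighted", "linear", "quadratic")) {
    expect_equal(weighted_kappa(diag(c(10, 10, 10)), w)$estimate, 1)
    expect_equal(weighted_kappa(matrix(25, 2, 2), w)$estimate, 0)
  }
  expect_error(weighted_kappa(matrix(c(10, 0, 0, 0), 2)), "degenerate")
})

test_that("weighted kappa on the published table matches the brute-force oracle", {
  frozen <- c(unweighted = 0.6588458, linear = 0.7071695,
              quadratic = 0.7504922)
  for (w in names(frozen)) {
    est <- weighted_kappa(published_xtab, w)
    expect_equal(est$estimate, oracle_kappa(published_xtab, w),
                 tolerance = 1e-12)
    expect_equal(est$estimate, frozen[[w]], tolerance = 1e-6)
  }
  # asymptotic SE frozen against an external large-sample implementation
  expect_equal(weighted_kappa(published_xtab, "linear")$se, 0.0372143,
               tolerance = 1e-5)
})

test_that("kappa is symmetric and scale-invariant, with SE shrinking ~ 1/sqrt(n)", {
  set.seed(17)
  m <- matrix(rpois(9, 12) + 1, 3, 3)
  for (w in c("unweighted", "linear", "quadratic")) {
    e <- weighted_kappa(m, w)
    expect_equal(weighted_kappa(t(m), w)$estimate, e$estimate)
    e4 <- weighted_kappa(4 * m, w)
    expect_equal(e4$estimate, e$estimate)
    expect_equal(e4$se, e$se / 2, tolerance = 1e-12)
  }
})

test_that("bootstrap kappa CI brackets the estimate", {
  set.seed(19)
  e <- weighted_kappa(published_xtab, "linear", ci = "bootstrap", n_boot = 300)
  expect_lte(e$ci_lo, e$estimate)
  expect_gte(e$ci_hi, e$estimate)
  expect_lt(e$ci_hi - e$ci_lo, 0.3)
})

test_that("ICC(A,1) handles exact agreement and penalizes constant offsets", {
  x <- c(1, 2, 3, 4, 6, 8)
  perfect <- icc_a1(cbind(x, x))
  expect_equal(perfect$estimate, 1)
  offset <- icc_a1(cbind(x, x + 2))
  expect_lt(offset$estimate, perfect$estimate)
  # textbook closed form: [[1,2],[2,3],[3,4],[4,5]] -> 10/13 with MSE = 0
  m <- matrix(c(1, 2, 2, 3, 3, 4, 4, 5), ncol = 2, byrow = TRUE)
  e <- icc_a1(m)
  expect_equal(e$estimate, 10 / 13, tolerance = 1e-12)
  expect_equal(e$estimate, oracle_icc_a1(m), tolerance = 1e-12)
  expect_error(icc_a1(matrix(1:4, ncol = 2)), "at least 3")
  expect_error(icc_a1(matrix(5, 4, 2)), "no variance")
})

test_that("ICC ANOVA route equals the sums-of-squares oracle on random matrices", {
  set.seed(29)
  for (i in 1:100) {
    n <- sample(3:8, 1); k <- sample(2:3, 1)
    x <- matrix(rnorm(n * k, sd = sample(c(0.5, 1, 3), 1)), n, k)
    e <- icc_a1(x)
    expect_equal(e$estimate, oracle_icc_a1(x), tolerance = 1e-10)
    expect_lte(e$ci_lo, e$estimate + 1e-12)
    expect_gte(e$ci_hi, e$estimate - 1e-12)
    expect_identical(e$df1, nrow(x) - 1L)
    expect_identical(e$df2, (nrow(x) - 1L) * (ncol(x) - 1L))
  }
})

test_that("ICC F statistic and CI agree with an external reference case", {
  # frozen reference values computed with an independent ICC implementation
  x <- matrix(c(1, 2, 2, 3, 3, 4, 4, 5, 6, 5, 2, 7, 4, 1, 3, 3),
              ncol = 2, byrow = TRUE)
  e <- icc_a1(x)
  expect_equal(e$estimate, 0.16, tolerance = 1e-6)
  expect_equal(e$f_value, 1.362369, tolerance = 1e-5)
  expect_equal(e$ci_lo, -0.61, tolerance = 0.005)
  expect_equal(e$ci_hi, 0.75, tolerance = 0.005)
  expect_equal(e$p_value, 0.346787, tolerance = 1e-5)
})

test_that("per-patient ICC stratifies, reports df = n-1, and skips tiny strata", {
  set.seed(31)
  df <- data.frame(
    patient_id = rep(c("p1", "p2", "p3"), c(50, 10, 2)),
    x = rnorm(62))
  df$y <- df$x + rnorm(62, sd = 0.3)
  expect_warning(out <- per_patient_icc(df), "only 2 complete pairs")
  expect_identical(out$n_pairs, c(50L, 10L, 2L))
  expect_identical(out$df1[1], 49L)
  expect_identical(out$df2[1], 49L)
  expect_true(is.na(out$estimate[3]))
  # identical series give ICC 1
  same <- data.frame(patient_id = "p9", x = rnorm(5))
  same$y <- same$x
  expect_equal(per_patient_icc(same)$estimate, 1)
})
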