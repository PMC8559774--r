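test_that("rmse matches its definition on worked cases", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  x <- runif(20, 0, 50)
  expect_equal(rmse(x, x + 7), 7)
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("Lin's concordance penalizes shifts and is bounded by Pearson's r", {
  expect_equal(lin_rc(c(1, 5, 9), c(1, 5, 9)), 1)
  expect_equal(lin_rc(c(1, 2, 3), c(2, 3, 4)), 4 / 7)
  expect_equal(lin_rc(c(-1, 0, 1), c(1, 0, -1)), -1)
  expect_error(lin_rc(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  set.seed(8)
  for (i in 1:50) {
    x <- rnorm(15, 50, 12)
    y <- rnorm(15, 45, 9) + 0.5 * x
    expect_lte(abs(lin_rc(x, y)), abs(pearson_r(x, y)) + 1e-12)
  }
  # equality when means and variances match exactly
  x <- c(1, 2, 3, 4)
  y <- c(2, 1, 4, 3)  # same mean and variance
  expect_equal(lin_rc(x, y), pearson_r(x, y))
})

test_that("correlations respect their affine-invariance properties", {
  set.seed(9)
  x <- rnorm(25, 100, 20)
  y <- 0.8 * x + rnorm(25, 0, 5)
  # Pearson: invariant under separate positive-slope affine maps
  expect_equal(pearson_r(2 * x + 3, 0.5 * y - 10), pearson_r(x, y))
  expect_equal(pearson_r(x, 2 * x), 1)
  # Lin: invariant only under the identical map applied to both
  expect_equal(lin_rc(2 * x + 3, 2 * y + 3), lin_rc(x, y))
  expect_false(isTRUE(all.equal(lin_rc(x, y + 15), lin_rc(x, y))))
})

test_that("the paired t-test follows the textbook definition and handles degeneracy", {
  x <- c(10, 20, 30, 40)
  pt0 <- paired_t(x, x)
  expect_equal(pt0$t, 0)
  expect_equal(pt0$p, 1)
  # antisymmetric differences sum to zero
  expect_equal(paired_t(x, x + c(-2, 2, -1, 1))$t, 0)
  # constant nonzero differences: p -> 0 with a flag
  deg <- paired_t(x, x + 5)
  expect_equal(deg$p, 0)
  expect_true(deg$degenerate)
  set.seed(10)
  a <- rnorm(12, 50, 10); b <- a + rnorm(12, 3, 4)
  got <- paired_t(a, b)
  want <- oracle_paired_t(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
})

test_that("Bland-Altman bias and limits match hand evaluation and cover ~95%", {
  x <- c(5, 9)
  ba <- bland_altman(x, x + c(-1, 1))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_high, 1.96 * sqrt(2))
  expect_equal(ba$loa_low, -1.96 * sqrt(2))
  ba0 <- bland_altman(x, x)
  expect_equal(c(ba0$bias, ba0$loa_low, ba0$loa_high), c(0, 0, 0))
  set.seed(11)
  d <- rnorm(10000, 2, 5)
  x <- rnorm(10000, 60, 10)
  ba <- bland_altman(x, x + d)
  inside <- mean(ba$differences >= ba$loa_low &
                   ba$differences <= ba$loa_high)
  expect_lt(abs(inside - 0.95), 3 * sqrt(0.95 * 0.05 / 10000))
})

test_that("paired sample size reproduces the 13-image design and is monotone", {
  expect_equal(paired_sample_size(10, 10.12, 0.05, 0.9), 13L)
  expect_equal(paired_sample_size(10, 1e-9), 2L)
  n_base <- paired_sample_size(10, 10.12)
  expect_gt(paired_sample_size(10, 2 * 10.12), n_base)
  expect_lte(paired_sample_size(20, 10.12), n_base)
  expect_lte(paired_sample_size(10, 10.12, alpha = 0.10), n_base)
  expect_gte(paired_sample_size(10, 10.12, power = 0.95), n_base)
  # the returned n is minimal: n-1 violates the t-based inequality
  n <- paired_sample_size(10, 10.12)
  need <- function(m) (qt(0.975, m - 1) + qt(0.9, m - 1))^2 * (10.12 / 10)^2
  expect_gte(n, need(n))
  expect_lt(n - 1, need(n - 1))
})

test_that("percent error reproduces the printed summation ratios", {
  expect_equal(percent_error(682, 655), 4.0)
  expect_equal(percent_error(682, 687), 0.7)
  expect_equal(percent_error(682, 508), 25.5)
  expect_equal(percent_error(682, 734), 7.6)
  expect_equal(percent_error(123.4, 123.4), 0)
  expect_error(percent_error(0, 5), "> 0")
})

test_that("all statistics agree with definitional evaluations on random samples", {
  set.seed(12)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    x <- rnorm(n, 60, 15)
    y <- 0.9 * x + rnorm(n, 5, 8)
    expect_equal(rmse(x, y), oracle_rmse(x, y), tolerance = 1e-10)
    expect_equal(pearson_r(x, y), oracle_pearson(x, y), tolerance = 1e-10)
    expect_equal(lin_rc(x, y), oracle_lin(x, y), tolerance = 1e-10)
    ba <- bland_altman(x, y)
    ob <- oracle_bland_altman(x, y)
    expect_equal(ba$bias, ob$bias, tolerance = 1e-10)
    expect_equal(ba$loa_low, ob$loa_low, tolerance = 1e-10)
    expect_equal(ba$loa_high, ob$loa_high, tolerance = 1e-10)
  }
})

test_that("comparison reports star significant rows and label the carb source", {
  set.seed(13)
  ref <- rnorm(20, 40, 10)
  est <- list(system = ref + rnorm(20, 8, 2),   # biased: significant
              rd1 = ref + rnorm(20, 0, 1))
  rep <- comparison_report(ref, est)
  expect_equal(rep$estimator, c("system", "rd1"))
  expect_true(rep$significant[1])
  expect_equal(attr(rep, "carb_source"), "recomputed")
  txt <- format(rep)
  expect_match(txt, "recomputed")
  expect_match(txt, "\\*")
  # reference against itself: zero error, flagged perfect agreement
  self <- comparison_report(ref, list(self = ref), carb_source = "as_stated")
  expect_equal(self$rmse, 0)
  expect_equal(self$lin_rc, 1)
  expect_equal(self$p, 1)
  expect_true(self$degenerate)
  # CSV export and paired-CSV reader round trip
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(measured = ref, system = est$system,
                              rd1 = est$rd1), path, row.names = FALSE)
  paired <- read_paired_csv(path)
  expect_equal(paired$reference, ref)
  expect_equal(names(paired$estimators), c("system", "rd1"))
})
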