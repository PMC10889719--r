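test_that("Spearman is exactly 1 for any strictly increasing transform", {
  set.seed(1)
  for (rep in 1:10) {
    x <- rnorm(20)
    f <- sample(list(exp, function(v) v^3, function(v) atan(v) + 2 * v,
                     function(v) rank(v)), 1)[[1]]
    expect_equal(spearman_cor(x, f(x))$rho, 1)
  }
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
})

test_that("the five-point example reproduces the hand-computed rho of 0.8", {
  res <- spearman_cor(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  # rank differences d = (0, 1, -1, 1, -1), sum(d^2) = 4
  expect_equal(res$rho, 1 - 6 * 4 / (5 * 24))  # 1 - 6 * sum(d^2) / (n (n^2-1))
  expect_equal(res$rho, 0.8)
  # t-approximation p-value
  tstat <- 0.8 * sqrt(3 / (1 - 0.64))
  expect_equal(res$p_value, 2 * pt(-tstat, 3))
})

test_that("constant input yields a missing rho with a tie diagnostic", {
  expect_warning(res <- spearman_cor(rep(1, 5), 1:5), "constant")
  expect_true(is.na(res$rho))
})

test_that("rank and folded-ECDF computations agree with a brute-force oracle", {
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    x <- sample(rnorm(n %/% 2 + 1), n, replace = TRUE)  # force some ties
    y <- rnorm(n)
    # O(n^2) average ranks
    brute_rank <- function(v) vapply(seq_along(v), function(i)
      sum(v < v[i]) + (sum(v == v[i]) + 1) / 2, numeric(1))
    rho_oracle <- cor(brute_rank(x), brute_rank(y))
    expect_equal(spearman_cor(x, y)$rho, rho_oracle, tolerance = 1e-12)
    # O(n^2) folded ECDF
    d <- sort(y)
    p_oracle <- vapply(d, function(v) mean(d <= v), numeric(1))
    mp <- mountain_plot(y)
    expect_equal(mp$curve$ecdf, p_oracle, tolerance = 1e-12)
    expect_equal(mp$curve$folded, ifelse(p_oracle <= 0.5, p_oracle, 1 - p_oracle))
  }
})

test_that("identical measurements give zero bias, collapsed limits and zero slope", {
  x <- c(1, 2, 3, 4, 5, 6)
  ba <- bland_altman(x, x)
  expect_equal(ba$bias, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(0, 0))
  expect_equal(ba$slope, 0)
  expect_true(ba$degenerate)
})

test_that("a pure offset is reported as bias with zero slope", {
  set.seed(4)
  x <- rnorm(40)
  exact <- bland_altman(x, x + 2)  # zero-variance differences collapse
  expect_equal(exact$bias, 2)
  expect_equal(exact$slope, 0)
  expect_true(exact$degenerate)
  noisy <- bland_altman(x, x + 2 + rnorm(40, 0, 0.1))
  expect_equal(noisy$bias, 2, tolerance = 0.1)
  expect_equal(noisy$slope, 0, tolerance = 0.1)
  expect_lt(noisy$t_p, 1e-10)  # sd << bias * sqrt(n) / t_crit: bias detected
})

test_that("limits of agreement cover ~95% of normal differences at n = 10000", {
  set.seed(11)
  d <- rnorm(10000)
  ba <- bland_altman(rep(0, 10000), d)
  expect_lt(abs(ba$loa_low + 1.96), 0.05)
  expect_lt(abs(ba$loa_high - 1.96), 0.05)
  coverage <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_lt(abs(coverage - 0.95), 0.01)
  expect_gt(ba$normality_p, 0.05)
})

test_that("negating the differences mirrors bias and limits", {
  set.seed(5)
  x <- rnorm(30); y <- x + rnorm(30, 0.5, 0.3)
  ba1 <- bland_altman(x, y)
  ba2 <- bland_altman(y, x)
  expect_equal(ba2$bias, -ba1$bias)
  expect_equal(ba2$loa_low, -ba1$loa_high)
  expect_equal(ba2$loa_high, -ba1$loa_low)
})

test_that("the omnibus normality test separates normal from heavy-tailed data", {
  set.seed(6)
  expect_gt(dagostino_pearson(rnorm(200))$p_value, 0.01)
  expect_lt(dagostino_pearson(rt(200, df = 2))$p_value, 0.01)
})

test_that("the mountain curve peaks at 0.5 at the median", {
  mp <- mountain_plot(c(1, 2, 3, 4))
  expect_equal(mp$curve$folded, c(0.25, 0.5, 0.25, 0))
  set.seed(2)
  d <- rnorm(100)  # even n: the 0.5 fold is attained exactly
  mp2 <- mountain_plot(d)
  expect_equal(max(mp2$curve$folded), 0.5)
  expect_equal(mp2$curve$diff[which.max(mp2$curve$folded)],
               sort(d)[50])
  # symmetric data: median zero, folded values match the direct evaluation
  ds <- c(-3, -2, -1, 1, 2, 3)
  mps <- mountain_plot(ds)
  expect_equal(mps$median, 0)
  expect_equal(mps$curve$folded, c(1, 2, 3, 2, 1, 0) / 6)
})

test_that("an agreement report of a table against itself is perfect", {
  set.seed(8)
  tbl <- tibble::tibble(prism = 1:12, `BV/TV` = runif(12, 10, 40),
                        `Tb.Th` = runif(12, 50, 120))
  rep_ <- build_agreement_report(tbl, tbl, parameters = c("BV/TV", "Tb.Th"))
  expect_equal(nrow(rep_$table), 2L)
  expect_true(all(rep_$table$rho == 1))
  expect_true(all(rep_$table$bias == 0))
})

test_that("unmatched prism ids and missing parameters are rejected by name", {
  a <- tibble::tibble(prism = 1:5, `BV/TV` = runif(5))
  b <- tibble::tibble(prism = 2:6, `BV/TV` = runif(5))
  expect_error(build_agreement_report(a, b), "unmatched prism ids: 1, 6")
  b2 <- tibble::tibble(prism = 1:5, other = runif(5))
  expect_error(build_agreement_report(a, b2, parameters = "BV/TV"),
               "not present")
})

test_that("requesting the standard five parameters yields five rows", {
  set.seed(10)
  cols <- c("BV/TV", "BS/TV", "Tb.Pf", "Tb.Th", "Tb.Sp")
  mk <- function() {
    tb <- tibble::tibble(prism = 1:10)
    for (cl in cols) tb[[cl]] <- runif(10)
    tb
  }
  rep_ <- build_agreement_report(mk(), mk())
  expect_equal(rep_$table$parameter, cols)
  expect_equal(nrow(rep_$table), 5L)
})
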