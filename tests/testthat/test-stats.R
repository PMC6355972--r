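# ALP fractions, Spearman trends, volume-response fits, group tests.

test_that("ALP-positive fraction: exact counts, binomial recovery, guards", {
  all_pos <- data.frame(alp_positive = rep(1, 12))
  f <- alpPositiveFraction(all_pos)
  expect_equal(f$percent, 100)

  set.seed(16)
  sim <- data.frame(alp_positive = rbinom(200, 1, 0.3))
  f2 <- alpPositiveFraction(sim)
  expect_gte(30, f2$ci_low)
  expect_lte(30, f2$ci_high)

  intens <- c(1, 2, 3, 10)
  expect_equal(alpPositiveFraction(intens, cutoff = 5)$percent, 25)
  expect_equal(alpPositiveFraction(intens, cutoff = 99)$percent, 0)
  expect_error(alpPositiveFraction(data.frame(alp_positive = integer())),
               "zero cells")
  expect_error(alpPositiveFraction(intens), "cutoff")
})

test_that("Spearman: exact monotone cases and mid-rank ties", {
  expect_equal(spearmanTrend(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearmanTrend(1:8, rev(1:8))$rho, -1)
  x <- c(1, 2, 2, 3, 5, 5, 7)
  y <- c(2, 1, 4, 4, 6, 8, 9)
  expect_equal(spearmanTrend(x, y)$rho,
               unname(cor.test(x, y, method = "spearman",
                               exact = FALSE)$estimate))
})

test_that("small-sample p matches the full 720-permutation enumeration", {
  set.seed(33)
  for (i in 1:3) {
    x <- rnorm(6); y <- rnorm(6)
    got <- spearmanTrend(x, y)
    expect_identical(got$method, "exact permutation")
    expect_equal(got$p, spearmanPermExhaustive(x, y), tolerance = 1e-12)
  }
  # large-sample branch agrees with the textbook t approximation
  set.seed(34)
  x <- rnorm(40); y <- x + rnorm(40)
  got <- spearmanTrend(x, y)
  tt <- got$rho * sqrt(38 / (1 - got$rho^2))
  expect_equal(got$p, 2 * pt(-abs(tt), 38), tolerance = 1e-12)
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(35)
  x <- runif(25, 1, 100); y <- runif(25, 1, 100)
  base <- spearmanTrend(x, y)
  expect_equal(spearmanTrend(log(x), y)$rho, base$rho)
  expect_equal(spearmanTrend(x, y^3)$rho, base$rho)
  expect_equal(spearmanTrend(exp(x / 50), sqrt(y))$p, base$p)
})

test_that("linear fit recovers an exact line; constant response has slope 0", {
  v <- seq(100, 5000, length.out = 40)
  fit <- fitVolumeResponse(v, 3 + 0.01 * v, "linear")
  expect_equal(unname(fit$coefficients["intercept"]), 3, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients["slope"]), 0.01, tolerance = 1e-12)
  expect_equal(fit$predict(2000), 23, tolerance = 1e-9)

  flat <- fitVolumeResponse(v, rep(40, 40), "linear")
  expect_equal(unname(flat$coefficients["slope"]), 0, tolerance = 1e-12)
})

test_that("saturating fit recovers generator parameters within 10%", {
  set.seed(44)
  v <- runif(100, 200, 8000)
  r <- 60 * v / (2000 + v)
  r <- r + rnorm(100, sd = 0.05 * r)
  fit <- fitVolumeResponse(v, r, "saturating")
  expect_lt(abs(fit$coefficients[["a"]] / 60 - 1), 0.10)
  expect_lt(abs(fit$coefficients[["k"]] / 2000 - 1), 0.10)
  # evaluator reproduces the fitted curve
  expect_equal(fit$predict(1500),
               fit$coefficients[["a"]] * 1500 / (fit$coefficients[["k"]] + 1500),
               tolerance = 1e-12)
})

test_that("ALP-fraction estimator is unbiased over generator replicates", {
  ests <- vapply(1:30, function(s) {
    tab <- makePopulationTable(30, linkA = 40, linkK = 0, seed = s)$table
    alpPositiveFraction(tab)$percent
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 40), 3 * se + 0.5)
})

test_that("group comparisons behave on null, shifted and degenerate input", {
  set.seed(55)
  null_tab <- data.frame(g = rep(c("a", "b", "c"), each = 30),
                         v = rnorm(90))
  res <- groupCompare(null_tab, "v", "g", "anova")
  expect_gt(res$p, 0.01)
  expect_true(is.matrix(res$pairwise))

  shift <- data.frame(g = rep(c("a", "b"), each = 30),
                      v = c(rnorm(30), rnorm(30) + 5))
  expect_lt(groupCompare(shift, "v", "g", "t")$p, 1e-3)
  expect_lt(groupCompare(shift, "v", "g", "anova")$p, 1e-3)

  one <- data.frame(g = rep("a", 10), v = rnorm(10))
  expect_error(groupCompare(one, "v", "g", "anova"), "at least 2")
  expect_error(groupCompare(one, "v", "g", "t"), "exactly 2")
})
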