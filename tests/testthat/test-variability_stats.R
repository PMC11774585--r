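test_that("coefficient of variation matches its definition and scale-invariance", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(2, 4, 6)), 0.5) # sd 2, mean 4
  expect_equal(coefficient_of_variation(c(2, 4, 6) * 10), 0.5)
  set.seed(9)
  x <- rlnorm(20)
  for (f in c(0.1, 3, 1000))
    expect_equal(coefficient_of_variation(f * x),
                 coefficient_of_variation(x))
  expect_error(coefficient_of_variation(3), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("permutation CoV test: null behavior, exact enumeration, determinism", {
  x <- c(1, 2, 3, 4, 5)
  r <- permutation_cov_test(x, x, n_permutations = 500, sided = "two",
                            seed = 1)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  # 2x2 groups: exhaustive option equals manual enumeration of all 6 splits
  a <- c(1, 2)
  b <- c(3, 7)
  an <- a / mean(a)
  bn <- b / mean(b)
  pool <- c(an, bn)
  stats <- apply(combn(4, 2), 2, function(ia) {
    ga <- pool[ia]
    gb <- pool[-ia]
    sd(gb) / mean(gb) - sd(ga) / mean(ga)
  })
  obs <- sd(bn) / mean(bn) - sd(an) / mean(an)
  r2 <- permutation_cov_test(a, b, sided = "one", exhaustive = TRUE)
  expect_equal(r2$p.value, mean(stats >= obs - 1e-12))
  expect_equal(r2$n_permutations, 6L)
  # determinism: identical seed gives bit-identical p
  set.seed(77)
  g1 <- rlnorm(10)
  g2 <- rlnorm(12, sdlog = 1.5)
  p1 <- permutation_cov_test(g1, g2, 300, seed = 42)$p.value
  p2 <- permutation_cov_test(g1, g2, 300, seed = 42)$p.value
  expect_identical(p1, p2)
  # degenerate pooled values
  expect_warning(pd <- permutation_cov_test(c(1, 1), c(2, 2), 100),
                 "degenerate")
  expect_equal(pd$p.value, 1)
})

test_that("normalization makes the test compare relative spread only", {
  # same shape, different scale: statistic is unaffected by the scale
  set.seed(5)
  a <- rlnorm(15)
  b <- a * 100
  r <- permutation_cov_test(a, b, n_permutations = 200, sided = "two",
                            seed = 3)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
})

test_that("kappa ratio follows its formula and symmetry", {
  expect_equal(kappa_ratio(1, 2, 1, 2), 1)
  expect_equal(kappa_ratio(1, 2, 2, 2), 0.5)
  k <- kappa_ratio(0.3, 1.2, 0.4, 0.9)
  expect_equal(kappa_ratio(0.4, 0.9, 0.3, 1.2), 1 / k)
  expect_error(kappa_ratio(0, 1, 1, 1), "positive")
})

test_that("Wilcoxon on log kappa: exact p-values and zero handling", {
  # 11 distinct ratios all below 1: most extreme statistic
  ks <- seq(0.5, 0.9, length.out = 11)
  r <- wilcoxon_log_kappa(ks)
  expect_equal(r$p.value, 2 / 2^11)
  expect_equal(r$median_kappa, median(ks))
  # log-symmetric ratios: centered statistic, p = 1
  expect_equal(wilcoxon_log_kappa(c(0.5, 2))$p.value, 1)
  # kappa = 1 entries are dropped before ranking
  r3 <- wilcoxon_log_kappa(c(0.5, 0.6, 1, 0.7))
  expect_equal(r3$n_used, 3L)
  expect_equal(r3$p.value, wilcoxon_log_kappa(c(0.5, 0.6, 0.7))$p.value)
  expect_equal(wilcoxon_log_kappa(c(1, 1, 1))$p.value, 1)
})

test_that("Wilcoxon exact path agrees with sign-enumeration oracle up to n = 10", {
  # brute-force oracle: enumerate all 2^n sign assignments of the ranked
  # absolute log ratios
  oracle <- function(ks) {
    x <- log(ks)
    rk <- rank(abs(x))
    W <- sum(rk[x > 0])
    ws <- 0
    for (r in rk) ws <- c(ws, ws + r)
    min(1, 2 * min(mean(ws <= W + 1e-9), mean(ws >= W - 1e-9)))
  }
  set.seed(123)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    ks <- exp(rnorm(n, -0.2, 0.5))
    expect_equal(wilcoxon_log_kappa(ks)$p.value, oracle(ks),
                 tolerance = 1e-12)
  }
})

test_that("correlation permutation test: perfect correlation and exact enumeration", {
  m <- c(1, 2, 3, 4, 5)
  r <- correlation_permutation_test(m, 2 * m, n_permutations = 999,
                                    seed = 6)
  expect_equal(r$correlation, 1)
  # only the identity and the full reversal reach |r| = 1 (two-sided), so
  # p concentrates near its exhaustive value 2/5!
  expect_lt(r$p.value, 0.04)
  re5 <- correlation_permutation_test(m, 2 * m, exhaustive = TRUE)
  expect_equal(re5$p.value, 2 / factorial(5))
  # n = 3 exhaustive: matches direct enumeration over all 6 permutations
  x <- c(1, 2, 4)
  y <- c(0.3, 0.1, 0.5)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  rs <- vapply(perms, function(p) cor(x, y[p]), numeric(1))
  re <- correlation_permutation_test(x, y, exhaustive = TRUE)
  expect_equal(re$p.value,
               mean(abs(rs) >= abs(cor(x, y)) - 1e-12))
  expect_error(correlation_permutation_test(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")
})

test_that("stochastic tests are reproducible bit-for-bit given a seed", {
  set.seed(1000)
  m <- rlnorm(8)
  v <- rlnorm(8)
  r1 <- correlation_permutation_test(m, v, 500, seed = 9)
  r2 <- correlation_permutation_test(m, v, 500, seed = 9)
  expect_identical(r1, r2)
  # and the caller's RNG stream is untouched
  set.seed(55)
  before <- rnorm(1)
  set.seed(55)
  invisible(permutation_cov_test(m, v, 100, seed = 3))
  expect_identical(rnorm(1), before)
})
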