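# Descriptives, rank correlations, paired tests, composite, power analysis.

test_that("descriptives match hand-computed values and conventions", {
  row <- descriptives(c(1, 2, 3, 4, 5))
  expect_equal(row$median, 3)
  expect_equal(row$sd, 1.5811, tolerance = 1e-4)
  expect_equal(row$skewness, 0)
  sym <- descriptives(c(-3, -1, 0, 1, 3))
  expect_equal(sym$skewness, 0)
  const <- descriptives(rep(2, 10))
  expect_equal(const$sd, 0)
  expect_true(is.na(const$skewness) && is.na(const$kurtosis))
})

test_that("Spearman's rho matches the classical formula and cor.test", {
  res <- spearman(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(res$rho, 0.8)          # 1 - 6*4/(5*24)
  expect_equal(spearman(1:10, 1:10)$rho, 1)
  expect_equal(spearman(1:10, 10:1)$rho, -1)
  # tie-aware agreement with rank-then-Pearson on random tied data
  set.seed(20)
  for (i in 1:100) {
    n <- sample(8:40, 1)
    x <- sample(1:6, n, replace = TRUE)   # heavy ties
    y <- x + sample(0:3, n, replace = TRUE)
    res <- spearman(x, y)
    oracle <- cor(rank(x), rank(y))
    expect_equal(res$rho, oracle, tolerance = 1e-12)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(res$rho, unname(ct$estimate), tolerance = 1e-12)
  }
  expect_true(is.na(spearman(rep(1, 10), 1:10)$rho))  # zero rank variance
})

test_that("partial Spearman reduces to zero-order and removes a shared driver", {
  set.seed(21)
  x <- rnorm(50); y <- rnorm(50)
  plain <- spearman(x, y)
  reduced <- partial_spearman(x, y, NULL)
  expect_equal(plain$rho, reduced$rho)
  expect_equal(plain$p, reduced$p)
  # x and y driven by z only: partialling z leaves ~0 at n = 2000
  n <- 2000
  z <- rnorm(n)
  x2 <- z + rnorm(n); y2 <- z + rnorm(n)
  ctrl <- partial_spearman(x2, y2, data.frame(z = z))
  expect_lt(abs(ctrl$rho), 0.08)
  raw <- spearman(x2, y2)
  expect_gt(raw$rho, 0.4)
})

test_that("partial Spearman agrees with the inverse-correlation-matrix oracle", {
  set.seed(22)
  for (i in 1:20) {
    n <- 60
    M <- matrix(rnorm(n * 5), n, 5) %*% chol(0.4 + 0.6 * diag(5))
    ranked <- apply(M, 2, rank)
    R <- cor(ranked)
    P <- solve(R)
    oracle <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
    res <- partial_spearman(M[, 1], M[, 2],
                            as.data.frame(M[, 3:5]))
    expect_equal(res$rho, oracle, tolerance = 1e-10)
  }
})

test_that("paired t matches the hand-computed textbook value", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 2, 5, 4, 8)
  res <- paired_t(a, b)
  # d = a - b = (-1, 0, -2, 0, -3); mean -1.2, sd sqrt(1.7)
  expect_equal(res$t, -1.2 / sqrt(1.7 / 5), tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(-abs(res$t), 4), tolerance = 1e-12)
  same <- paired_t(a, a + 0)
  expect_true(same$degenerate)
  shifted <- paired_t(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_true(shifted$degenerate)        # constant difference, variance 0
})

test_that("the reading composite has mean zero and the expected spread", {
  set.seed(23)
  f <- sample(0:3, 400, replace = TRUE)
  d <- sample(0:3, 400, replace = TRUE)
  comp <- reading_composite(f, d)
  expect_equal(mean(comp), 0, tolerance = 1e-12)
  # independent items: Var(mean of two independent z-scores) = 1/2
  expect_equal(sd(comp), sqrt(0.5), tolerance = 0.1)
  # perfectly correlated items: composite is a single z-score
  comp2 <- reading_composite(f, f)
  expect_equal(sd(comp2), 1, tolerance = 1e-12)
  # one missing item falls back to the observed one, flagged
  f3 <- c(0, 1, 2, 3); d3 <- c(3, NA, 1, 0)
  comp3 <- reading_composite(f3, d3)
  expect_false(anyNA(comp3))
  expect_identical(attr(comp3, "partial"), c(FALSE, TRUE, FALSE, FALSE))
  expect_error(reading_composite(c(0, 5), c(1, 1)), "0-3")
})

test_that("the CDI 90% answering rule uses the 81-item threshold", {
  make_items <- function(n_answered) c(rep(1, n_answered),
                                       rep(NA, 90 - n_answered))
  expect_true(cdi_inclusion(make_items(81)))
  expect_false(cdi_inclusion(make_items(80)))
  expect_true(cdi_inclusion(make_items(90)))
})

test_that("Fisher-z sensitivity matches its closed form and behaves in limits", {
  for (n in c(30, 70, 150)) {
    closed <- tanh((qnorm(0.975) + qnorm(0.80)) / sqrt(n - 3))
    expect_equal(min_detectable_r(n, 0.05, 0.80, 2, "fisher-z"), closed,
                 tolerance = 1e-4)
  }
  # as power -> alpha the detectable correlation vanishes
  expect_lt(min_detectable_r(70, 0.05, 0.051, 2, "fisher-z"), 0.02)
  # exact method: power at the root is the target, and the null rejection
  # rate equals alpha
  r <- min_detectable_r(70, 0.05, 0.80, 2, "exact")
  expect_equal(correlation_power(r, 70, 0.05, 2, "exact"), 0.80,
               tolerance = 1e-5)
  expect_equal(correlation_power(1e-9, 70, 0.05, 2, "exact"), 0.05,
               tolerance = 1e-6)
  # exact and Fisher-z agree closely at moderate n
  expect_lt(abs(r - min_detectable_r(70, 0.05, 0.80, 2, "fisher-z")), 0.01)
})

test_that("exact correlation power matches Monte Carlo simulation", {
  set.seed(24)
  n <- 40; rho <- 0.4
  mc <- mean(replicate(3000, {
    x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    r <- cor(x, y)
    abs(r * sqrt((n - 2) / (1 - r^2))) > qt(0.975, n - 2)
  }))
  expect_equal(correlation_power(rho, n, 0.05, 2, "exact"), mc,
               tolerance = 0.035)
})

test_that("correlation matrices are symmetric with unit diagonal", {
  set.seed(25)
  tab <- as.data.frame(matrix(rnorm(50 * 4), 50, 4))
  names(tab) <- c("a", "b", "c", "z")
  rep0 <- correlation_report(tab, c("a", "b", "c"))
  expect_equal(rep0$rho, t(rep0$rho))
  expect_equal(unname(diag(rep0$rho)), rep(1, 3))
  expect_true(all(abs(rep0$rho) <= 1))
  repp <- correlation_report(tab, c("a", "b", "c"), covariates = "z")
  expect_equal(repp$rho, t(repp$rho))
  expect_identical(repp$method, "partial")
  # empty covariate set equals zero-order
  repe <- correlation_report(tab, c("a", "b", "c"), covariates = NULL)
  expect_equal(repe$rho, rep0$rho)
})
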