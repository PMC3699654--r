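# Rescaled KDEs, bootstrap medians, Mann-Whitney U, Deming regression and
# logistic growth fits.

test_that("rescaled KDE has unit maximum and near-unit raw area", {
  set.seed(41)
  x <- rnorm(400, 10, 2)
  k <- rescaled_kde(x)
  expect_equal(max(k$height), 1, tolerance = 1e-9)
  expect_true(all(k$height >= 0))
  raw <- k$height * k$max_density
  area <- sum(diff(k$grid) * (raw[-1] + raw[-length(raw)]) / 2)
  expect_lt(abs(area - 1), 0.01)
  # rescaling is idempotent
  expect_equal(k$height / max(k$height), k$height)
  expect_error(rescaled_kde(rep(3, 10)), "distinct")
})

test_that("a mirrored bimodal sample gives two equal peaks at height one", {
  set.seed(42)
  half <- rnorm(500, 3, 0.4)
  x <- c(half, -half)   # exactly symmetric about 0
  k <- rescaled_kde(x)
  h_at <- function(v) k$height[which.min(abs(k$grid - v))]
  expect_gt(h_at(3), 0.95)
  expect_gt(h_at(-3), 0.95)
  expect_lt(h_at(0), 0.5)
  expect_equal(k$bandwidth_rule, "scott")
})

test_that("bootstrap SE of the median matches the asymptotic rate", {
  expect_equal(median_summary(c(1, 2, 3))$median, 2)
  expect_equal(median_summary(rep(7, 20))$se, 0)
  set.seed(43)
  x <- rnorm(500)
  ms <- median_summary(x, n_boot = 1000, seed = 7)
  asym <- 1.2533 / sqrt(500)
  expect_lt(abs(ms$se - asym) / asym, 0.15)
  expect_error(median_summary(numeric(0)), "empty")
  # seeded: identical calls agree
  expect_identical(median_summary(x, seed = 7)$se,
                   median_summary(x, seed = 7)$se)
})

test_that("Mann-Whitney exact enumeration matches hand-counted cases", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 1 / 3)
  expect_equal(r$method, "exact")
  ident <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_gte(ident$p_value, 0.99)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact and wilcox.test agree; normal approximation is close
           at n = 8", {
  set.seed(44)
  for (i in 1:5) {
    a <- rnorm(8); b <- rnorm(8, 0.5)
    ex <- mann_whitney_u(a, b)
    # independent oracle: exact distribution from wilcox.test
    wt <- wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(ex$method, "exact")
    expect_equal(ex$p_value, wt$p.value, tolerance = 1e-10)
    ap <- mann_whitney_u(a, b, exact_max = 0)
    expect_equal(ap$method, "normal")
    expect_lt(abs(ap$p_value - ex$p_value), 0.02)
  }
})

test_that("Mann-Whitney p is invariant under common monotone transforms", {
  set.seed(45)
  a <- rlnorm(6); b <- rlnorm(7, 0.4)
  base <- mann_whitney_u(a, b)
  for (f in list(log, sqrt, function(z) 5 * z + 2)) {
    tr <- mann_whitney_u(f(a), f(b))
    expect_equal(tr$p_value, base$p_value)
  }
})

test_that("Deming regression: exact line, brute-force oracle, symmetry", {
  x <- c(1, 2, 3, 4)
  d <- deming_fit(x, 2 * x + 1)
  expect_equal(d$slope, 2, tolerance = 1e-12)
  expect_equal(d$intercept, 1, tolerance = 1e-12)

  set.seed(46)
  xx <- rnorm(10, 5, 2); yy <- 1.4 * xx + rnorm(10, 0, 0.8)
  for (ratio in c(1, 2.5)) {
    fit <- deming_fit(xx, yy, variance_ratio = ratio)
    # brute force: minimize the profiled weighted orthogonal residual sum
    obj <- function(p) sum((yy - p[1] - p[2] * xx)^2 / (ratio + p[2]^2))
    opt <- optim(c(fit$intercept, fit$slope) + 0.3, obj,
                 method = "BFGS", control = list(reltol = 1e-14))
    expect_lt(abs(fit$slope - opt$par[2]), 1e-4)
    expect_lt(abs(fit$intercept - opt$par[1]), 1e-4)
    expect_lte(obj(c(fit$intercept, fit$slope)), opt$value + 1e-10)
  }
  # orthogonal regression: swapping axes inverts the slope
  sw <- deming_fit(yy, xx, variance_ratio = 1)
  expect_equal(sw$slope, 1 / deming_fit(xx, yy)$slope, tolerance = 1e-10)
  expect_error(deming_fit(rep(1, 5), rep(2, 5)), "degenerate")
  expect_error(deming_fit(1:5, 2:6, variance_ratio = 0), "variance_ratio")
})

test_that("Deming approaches OLS when x errors vanish", {
  set.seed(47)
  x <- rnorm(30, 10, 3); y <- 2 + 0.7 * x + rnorm(30, 0, 0.5)
  ols <- unname(coef(lm(y ~ x))[2])
  dem <- deming_fit(x, y, variance_ratio = 1e8)$slope
  expect_equal(dem, ols, tolerance = 1e-4)
})

test_that("logistic growth fit recovers known parameters", {
  tt <- seq(0, 11, length.out = 12)
  od <- 3.3 / (1 + exp(-1.0 * (tt - 4)))
  fit <- logistic_growth_fit(tt, od)
  expect_equal(fit$carrying_capacity, 3.3, tolerance = 1e-6)
  expect_equal(fit$rate, 1.0, tolerance = 1e-6)
  expect_equal(fit$midpoint, 4, tolerance = 1e-6)
  set.seed(48)
  noisy <- od * (1 + rnorm(12, 0, 0.01))
  nf <- logistic_growth_fit(tt, noisy)
  expect_lt(abs(nf$carrying_capacity - 3.3) / 3.3, 0.05)
  # decreasing series: flagged (negative rate) or reported non-convergence
  dec <- 3.3 / (1 + exp(0.8 * (tt - 4)))
  outcome <- tryCatch(logistic_growth_fit(tt, dec),
                      warning = function(w) "flagged",
                      error = function(e) "flagged")
  expect_identical(outcome, "flagged")
  expect_error(logistic_growth_fit(1:3, c(1, 2, 3)), "at least 4")
})

test_that("batch_summary reproduces per-group median_summary rows", {
  set.seed(49)
  v <- c(rnorm(40, 1.4, 0.01), rnorm(60, 1.45, 0.01))
  g <- rep(c("a", "b"), c(40, 60))
  tab <- batch_summary(v, g, n_boot = 200, seed = 5)
  expect_equal(tab$group, c("a", "b"))
  expect_equal(tab$n, c(40L, 60L))
  ma <- median_summary(v[g == "a"], n_boot = 200, seed = 5)
  expect_equal(tab$median[1], ma$median)
  expect_equal(tab$se[1], ma$se)
  # technical replicates of identical data give identical rows
  rep2 <- batch_summary(c(v[g == "a"], v[g == "a"]),
                        rep(c("r1", "r2"), each = 40),
                        n_boot = 200, seed = 5)
  expect_equal(rep2$median[1], rep2$median[2])
  expect_equal(rep2$se[1], rep2$se[2])
  # validity counting
  tv <- batch_summary(c(1, 2, 3, 100), rep("g", 4),
                      valid = c(TRUE, TRUE, TRUE, FALSE),
                      n_boot = 50, seed = 1)
  expect_equal(tv$n_valid, 3L)
  expect_equal(tv$median, 2)
})
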