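test_that("paired differences follow the stated conventions", {
  expect_equal(percent_differences(c(50, 100), c(55, 90)), c(10, -10))
  expect_equal(percent_differences(c(60), c(84)), 40)
  expect_equal(percent_differences(c(30, 60), c(30, 60)), c(0, 0))
  expect_equal(percent_differences(60, 84, scale = "log"), 100 * log(1.4))
  expect_error(percent_differences(c(1, 2), 1), "equal length")
  expect_error(percent_differences(c(0, 2), c(1, 2)), "positive")
})

test_that("ccc matches the moment formula and its exact special cases", {
  x <- c(3, 1, 4, 1.5)
  expect_equal(ccc(x, x), 1)
  expect_equal(ccc(c(1, 2, 3, 4), c(2, 3, 4, 5)), 2 * 1.25 / 3.5)
  z <- c(-2, -1, 1, 2)
  expect_equal(ccc(z, -z), -1)
  expect_error(ccc(c(1, 1), c(1, 1)), "undefined")
})

test_that("ccc is scale-invariant, not shift-invariant, and bounded by r", {
  set.seed(5)
  x <- rnorm(40, 50, 10)
  y <- x + rnorm(40, 0, 5)
  expect_equal(ccc(3 * x, 3 * y), ccc(x, y))          # common rescaling
  expect_false(isTRUE(all.equal(ccc(x, y + 10), ccc(x, y))))  # shifting one
  expect_lte(abs(ccc(x, y)), abs(cor(x, y)))
})

test_that("empirical TDI is the stated order statistic", {
  expect_equal(tdi_empirical(rep(0, 7)), 0)
  expect_equal(tdi_empirical(1:10, p = 0.9), 9)
  expect_equal(tdi_empirical(c(-3, 1, 2), p = 0.5), 2)  # ceiling(1.5) = 2nd
  set.seed(8)
  d <- rnorm(1e5, 0, 10)
  expect_equal(tdi_empirical(d, 0.9), 16.449, tolerance = 0.01)
  # nondecreasing in p
  ps <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(sapply(ps, function(p) tdi_empirical(d, p))) >= 0))
  expect_error(tdi_empirical(numeric(0)), "empty")
})

test_that("parametric TDI reduces to the normal-quantile closed forms", {
  expect_equal(tdi_parametric(0, 10, 0.90), 10 * qnorm(0.95))
  expect_equal(tdi_parametric(0, 10, 0.50), 10 * qnorm(0.75), tolerance = 1e-6)
  # small-sd limit approaches |mean| from above
  expect_equal(tdi_parametric(7, 0.05, 0.90), 7, tolerance = 0.01)
  expect_gt(tdi_parametric(7, 0.05, 0.90), 7)
  expect_error(tdi_parametric(0, 0), "positive")
})

test_that("parametric and empirical TDI agree on large Normal samples", {
  set.seed(12)
  d <- rnorm(2e4, 3, 12)
  emp <- tdi_empirical(d, 0.9)
  par <- tdi_parametric(mean(d), sd(d), 0.9)
  expect_lt(abs(emp - par) / par, 0.02)
})

test_that("coverage probability counts pairs inside the boundary", {
  expect_equal(coverage_probability(rep(0, 5), 10), 1)
  expect_equal(coverage_probability(c(5, 15), 10), 0.5)
  expect_equal(coverage_parametric(0, 10, 10 * qnorm(0.95)), 0.9)
  # nondecreasing in kappa0
  set.seed(3)
  d <- rnorm(500, 0, 15)
  ks <- seq(1, 50, by = 1)
  expect_true(all(diff(sapply(ks, function(k) coverage_probability(d, k))) >= 0))
})

test_that("TDI and coverage are dual, exactly when p*n is an integer", {
  set.seed(44)
  for (n in c(10, 50, 200)) {
    d <- rnorm(n, 0, 20)
    expect_equal(coverage_probability(d, tdi_empirical(d, 0.9)), 0.9)
  }
  for (n in c(13, 57, 201)) {
    d <- rnorm(n, 0, 20)
    expect_gte(coverage_probability(d, tdi_empirical(d, 0.9)), 0.9)
  }
})

test_that("the symmetric relative error band is exact", {
  expect_identical(unname(relative_error_band(60, 30)), c(42, 78))
  expect_equal(relative_error_band(100, 10), c(lower = 90, upper = 110))
})

test_that("bootstrap bounds are deterministic and match a loop oracle", {
  set.seed(99)
  m <- rnorm(50, 70, 25)
  e <- m * exp(rnorm(50, 0, 0.2))
  pairs <- cbind(m, e)
  stat <- function(d) ccc(d[, 1], d[, 2])
  b1 <- bootstrap_bound(stat, pairs, B = 400, seed = 7)
  b2 <- bootstrap_bound(stat, pairs, B = 400, seed = 7)
  expect_identical(b1, b2)

  # independent explicit-loop oracle sharing only the RNG stream
  set.seed(7)
  reps <- numeric(400)
  for (b in 1:400) {
    idx <- sample.int(50, 50, replace = TRUE)
    reps[b] <- ccc_oracle(m[idx], e[idx])
  }
  expect_equal(b1$bound, quantile7_oracle(reps, 0.05), tolerance = 1e-12)
  expect_equal(b1$estimate, ccc_oracle(m, e), tolerance = 1e-12)
})

test_that("degenerate and undersized bootstrap inputs behave as specified", {
  d <- rep(12, 30)
  b <- bootstrap_bound(function(x) tdi_empirical(x, 0.9), d, B = 200,
                       seed = 1, direction = "upper")
  expect_equal(b$bound, b$estimate)
  expect_error(bootstrap_bound(mean, 1:4, seed = 1), "fewer than 5")
  expect_error(bootstrap_bound(mean, 1:30, B = 50, seed = 1), "B must be")
})

test_that("agreement() reports perfect concordance for identical series", {
  m <- c(35, 50, 62, 71, 88, 95, 101, 120)
  a <- agreement(m, m, seed = 5, B = 150)
  expect_equal(a$ccc, 1)
  expect_equal(a$tdi, 0)
  expect_equal(a$cp, 100)
  expect_equal(a$ccc_bound, 1)
  expect_equal(a$tdi_bound, 0)
  expect_equal(a$cp_bound, 100)
})

test_that("log-scale TDI back-transforms to the lognormal closed form", {
  set.seed(61)
  m <- runif(4000, 30, 110)
  e <- m * exp(rnorm(4000, 0, 0.25))
  a <- agreement(m, e, scale = "log")
  expect_equal(a$tdi, 100 * (exp(qnorm(0.95) * 0.25) - 1), tolerance = 0.05)
  # and cp matches the normal-CDF prediction at kappa0 = 10%
  expect_equal(a$cp, 100 * (2 * pnorm(log(1.1) / 0.25) - 1), tolerance = 0.06)
})

test_that("the agreement table runs all equations and flags failures", {
  co <- generate_cohort(60, seed = 21)
  tab <- agreement_table(co, seed = 13, B = 120)
  expect_equal(nrow(tab), length(formula_ids()))
  expect_true(all(tab$status == "ok"))
  expect_true(all(is.finite(tab$ccc_bound)))
  expect_true(all(tab$ccc_bound <= tab$ccc))
  expect_true(all(tab$tdi_bound >= tab$tdi))
  expect_true(all(tab$cp_bound <= tab$cp))
  # cohort without cystatin: those rows are flagged, the rest still run
  tab2 <- agreement_table(co[, setdiff(names(co), "cysc")],
                          seed = 13, B = 120)
  cy <- formula_registry()$basis %in% c("cystatin", "both")
  expect_true(all(grepl("skipped", tab2$status[cy])))
  expect_true(all(tab2$status[!cy] == "ok"))
})
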