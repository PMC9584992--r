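test_that("KDIGO stages follow the band boundaries", {
  expect_equal(kdigo_stage(c(95, 90, 89.9, 60, 59.9, 45, 44.9, 30, 29.99, 15, 14.9, 0)),
               c("G1", "G1", "G2", "G2", "G3a", "G3a", "G3b", "G3b",
                 "G4", "G4", "G5", "G5"))
  expect_error(kdigo_stage(-1), "non-negative")
})

test_that("stage bands partition the GFR axis", {
  set.seed(2)
  g <- runif(500, 0, 150)
  st <- kdigo_stage(g)
  expect_false(anyNA(st))
  manual <- ifelse(g >= 90, "G1", ifelse(g >= 60, "G2",
            ifelse(g >= 45, "G3a", ifelse(g >= 30, "G3b",
            ifelse(g >= 15, "G4", "G5")))))
  expect_equal(st, manual)
})

test_that("strata distribution uses the documented boundary convention", {
  expect_equal(unname(strata_distribution(c(95, 70, 40, 20))),
               rep(0.25, 4))
  expect_equal(unname(strata_distribution(rep(100, 5))), c(1, 0, 0, 0))
  # 90 belongs to 60-90 (closed); 60 belongs to 60-90; 30 to 30-60
  expect_equal(unname(strata_distribution(c(90, 60, 30))), c(0, 2 / 3, 1 / 3, 0))
  s <- strata_distribution(runif(100, 5, 130))
  expect_equal(sum(s), 1)
  expect_error(strata_distribution(numeric(0)), "empty")
})

test_that("threshold misclassification reproduces the reference panel counts", {
  rc <- reference_cases()
  expect_equal(nrow(rc), 14)
  # frozen by direct counting of the printed panel: 5 cases have mGFR < 30
  expected_over <- c(amdrd = 1, ckdepi_cr = 1, ckdepi_cy = 0, ckdepi_crcy = 0)
  expected_under <- c(amdrd = 0, ckdepi_cr = 0, ckdepi_cy = 1, ckdepi_crcy = 0)
  for (col in names(expected_over)) {
    r <- threshold_misclassification(rc$mgfr, rc[[col]])
    expect_equal(r$n_below, 5, label = col)
    expect_equal(r$n_below_est_above, unname(expected_over[col]), label = col)
    expect_equal(r$n_in_band, 1, label = col)
    expect_equal(r$n_band_est_below, unname(expected_under[col]), label = col)
  }
})

test_that("perfect estimation yields zero misclassification", {
  m <- c(10, 25, 29.9, 30, 35, 40, 55, 80)
  r <- threshold_misclassification(m, m)
  expect_equal(r$n_below_est_above, 0)
  expect_equal(r$n_band_est_below, 0)
  expect_error(threshold_misclassification(m, m[-1]), "equal length")
})

test_that("near-identical estimates only misclassify exact-threshold pairs", {
  m <- c(29.999, 30, 30.001, 35, 40)
  eps <- 1e-9
  r_up <- threshold_misclassification(m, m * (1 + eps))
  # only the pair sitting just under the cut-off can cross upward
  expect_equal(r_up$n_below_est_above, 0)
  r_dn <- threshold_misclassification(m, m * (1 - eps))
  # the pair exactly at 30 drops below under any downward perturbation
  expect_equal(r_dn$n_band_est_below, 1)
})

test_that("error bands are an exhaustive left-closed partition", {
  expect_equal(unname(error_band_distribution(c(5, 15, 25, 35))), rep(0.25, 4))
  expect_equal(unname(error_band_distribution(rep(0, 4))), c(1, 0, 0, 0))
  expect_equal(unname(error_band_distribution(c(10, 20, 30))), c(0, 1 / 3, 1 / 3, 1 / 3))
  set.seed(9)
  d <- rnorm(2000, 0, 25)
  expect_equal(sum(error_band_distribution(d)), 1, tolerance = 1e-9)
})

test_that("error-band fractions match the normal-CDF oracle at scale", {
  set.seed(14)
  d <- rnorm(1e5, 0, 20)
  f <- error_band_distribution(d)
  expect_equal(unname(f["<10%"]), 2 * pnorm(0.5) - 1, tolerance = 0.01)
  expect_equal(unname(f[">30%"]), 2 * pnorm(-1.5), tolerance = 0.01)
})

test_that("tolvaptan flags encode the three published rules", {
  f <- tolvaptan_flags(c(40, 50, 58), c(25, 50, 70))
  expect_equal(f$below_cutoff_30, c(TRUE, FALSE, FALSE))
  expect_equal(f$reimbursable_45, c(FALSE, TRUE, TRUE))
  expect_equal(f$not_recommended_55_60_gfr60, c(FALSE, FALSE, TRUE))
  expect_error(tolvaptan_flags(16, 50), "adults")
})

test_that("per-formula misclassification table runs on a synthetic cohort", {
  co <- generate_cohort(150, seed = 33)
  tab <- misclassification_table(co)
  expect_equal(nrow(tab), length(formula_ids()))
  expect_true(all(tab$n_below <= tab$n))
  expect_true(all(tab$n_below_est_above <= tab$n_below))
  expect_true(all(tab$n_band_est_below <= tab$n_in_band))
})
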