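test_that("worked examples of individual equations evaluate as published", {
  cg <- data.frame(age = 40, sex = "male", weight = 72, height = 175, scr = 1.0)
  expect_equal(compute_egfr("Cockcroft-Gault", cg), 100)

  epi <- data.frame(age = 50, sex = "female", weight = 60, height = 160, scr = 0.8)
  expect_equal(compute_egfr("CKD-EPI-cr", epi, indexed = TRUE), 86, tolerance = 0.01)

  md <- data.frame(age = 60, sex = "male", weight = 85, height = 180, scr = 1.5)
  expect_equal(compute_egfr("aMDRD", md, indexed = TRUE), 47.7, tolerance = 0.002)
})

test_that("Du Bois BSA matches hand evaluation and is a power law", {
  expect_equal(du_bois_bsa(70, 180), 1.886, tolerance = 5e-4)
  expect_equal(du_bois_bsa(60, 160), 1.622, tolerance = 5e-4)
  # scaling weight by 2^(1/0.425) doubles BSA exactly
  expect_equal(du_bois_bsa(70 * 2^(1 / 0.425), 180), 2 * du_bois_bsa(70, 180))
  expect_error(du_bois_bsa(0, 170), "positive")
})

test_that("BSA un-adjustment is exact and inverts indexing", {
  expect_equal(unadjust_bsa(60, 1.73), 60)
  expect_equal(unadjust_bsa(60, 2.076), 72)
  expect_equal(unadjust_bsa(100, 1.384), 80)
  for (bsa in c(1.4, 1.73, 2.2)) {
    expect_equal(unadjust_bsa(adjust_bsa(87.3, bsa), bsa), 87.3)
  }
  expect_error(unadjust_bsa(60, 0), "positive")
})

test_that("ellipsoid TKV handles single and paired kidneys", {
  expect_equal(ellipsoid_tkv(0, 0, 0), 0)
  expect_equal(ellipsoid_tkv(2, 2, 2), pi / 6 * 8)
  expect_equal(ellipsoid_tkv(12, 6, 5), pi / 6 * 360, tolerance = 1e-10)
  expect_equal(ellipsoid_tkv(10, 5, 4, 11, 5.5, 4.5),
               pi / 6 * (200 + 272.25))
  expect_error(ellipsoid_tkv(-1, 2, 2), "non-negative")
})

test_that("all registered equations match the frozen hand-derived oracle", {
  expect_true(length(formula_ids()) >= 12)
  orc <- read.csv(test_path("fixtures", "egfr_panel_oracle.csv"),
                  check.names = FALSE)
  pan <- panel_patients()
  for (fid in names(orc)[-1]) {
    expect_equal(compute_egfr(fid, pan), orc[[fid]], tolerance = 0.1 / 50,
                 label = paste("absolute eGFR for", fid))
  }
})

test_that("output is strictly decreasing in the marker over 0.3-10", {
  base <- panel_patients()[2, ]
  grid <- seq(0.3, 10, length.out = 60)
  reg <- formula_registry()
  for (i in seq_len(nrow(reg))) {
    fid <- reg$formula_id[i]
    d <- base[rep(1, length(grid)), ]
    if (reg$basis[i] %in% c("creatinine", "both")) {
      d$scr <- grid
      v <- compute_egfr(fid, d)
      expect_true(all(diff(v) < 0), label = paste(fid, "decreasing in scr"))
    }
    if (reg$basis[i] %in% c("cystatin", "both")) {
      d <- base[rep(1, length(grid)), ]
      d$cysc <- grid
      v <- compute_egfr(fid, d)
      expect_true(all(diff(v) < 0), label = paste(fid, "decreasing in cysc"))
    }
  }
})

test_that("race coefficient applies only when the flag is explicitly set", {
  pt <- data.frame(age = 50, sex = "male", weight = 80, height = 178, scr = 1.2)
  v0 <- compute_egfr("aMDRD", pt, indexed = TRUE)
  pt$black <- TRUE
  expect_equal(compute_egfr("aMDRD", pt, indexed = TRUE), v0 * 1.212)
})

test_that("unknown ids, missing markers and bad values are rejected", {
  pt <- panel_patients()
  expect_error(compute_egfr("no-such-equation", pt), "unknown formula_id")
  expect_error(compute_egfr("CKD-EPI-cy", pt[, setdiff(names(pt), "cysc")]),
               "cysc")
  bad <- pt
  bad$scr[2] <- -1
  expect_error(compute_egfr("aMDRD", bad), "non-positive")
})

test_that("the registry accepts plug-in equations", {
  reg_env <- asNamespace("gfragree")$.registry
  on.exit(reg_env$specs[["test-linear"]] <- NULL)
  register_formula("test-linear", "creatinine", FALSE,
                   function(d) 100 / d$scr, requires = "scr")
  expect_true("test-linear" %in% formula_ids())
  expect_equal(compute_egfr("test-linear", data.frame(scr = 2)), 50)
  reg <- formula_registry()
  expect_true(!anyDuplicated(reg$formula_id))
})

test_that("the eGFR matrix quarantines equations it cannot run", {
  pt <- panel_patients()
  m <- egfr_matrix(pt[, setdiff(names(pt), "cysc")])
  expect_true(all(is.na(m[["CKD-EPI-cy"]])))
  expect_true(all(is.finite(m[["aMDRD"]])))
  expect_true("CKD-EPI-cy" %in% names(attr(m, "skipped")))
})
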