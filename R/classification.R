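## CKD staging, GFR-threshold misclassification and error-band summaries.
##
## The misclassification questions mirror treatment decision-making in
## ADPKD: tolvaptan is withheld below 30 ml/min, so an estimate landing on
## the wrong side of that cut-off changes management.

#' KDIGO GFR stage
#'
#' @param gfr GFR in ml/min (non-negative, vectorised).
#' @return Character vector of stages: G1 (>= 90), G2 (60-89), G3a (45-59),
#'   G3b (30-44), G4 (15-29), G5 (< 15).
#' @examples
#' kdigo_stage(c(95, 30, 29.99, 0))
#' @export
kdigo_stage <- function(gfr) {
  if (any(!is.finite(gfr)) || any(gfr < 0)) stop("gfr must be non-negative")
  as.character(cut(gfr, breaks = c(0, 15, 30, 45, 60, 90, Inf),
                   labels = c("G5", "G4", "G3b", "G3a", "G2", "G1"),
                   right = FALSE, include.lowest = TRUE))
}

#' GFR strata distribution of a cohort
#'
#' Fractions of subjects with GFR above 90, 60-90, 30-60 and below 30
#' ml/min. Boundary convention: `> 90` strict, `[60, 90]` closed,
#' `[30, 60)`, `< 30`, so the four strata partition the positive axis.
#'
#' @param mgfr Measured GFR values, ml/min.
#' @return Named numeric vector of four fractions summing to 1.
#' @export
strata_distribution <- function(mgfr) {
  if (length(mgfr) < 1) stop("empty input")
  c(">90" = mean(mgfr > 90),
    "60-90" = mean(mgfr >= 60 & mgfr <= 90),
    "30-60" = mean(mgfr >= 30 & mgfr < 60),
    "<30" = mean(mgfr < 30))
}

#' Misclassification around a GFR treatment threshold
#'
#' Two clinically directed counts: among subjects whose measured GFR is
#' below `threshold`, how many does the estimate place at or above it
#' (treatment incorrectly allowed); and among subjects with measured GFR
#' inside `band` (default the closed interval 30-40 ml/min), how many does
#' the estimate place below `threshold` (treatment incorrectly denied).
#'
#' @param mgfr,egfr Aligned measured and estimated GFR, ml/min.
#' @param threshold Decision cut-off, default 30 ml/min.
#' @param band Measured-GFR band `c(lo, hi)` for the undercall count,
#'   default `c(30, 40)`, both ends included.
#' @return List of class `"misclassification_report"`: threshold, band,
#'   `n`, `n_below`, `n_below_est_above` (+ `pct_below_est_above`),
#'   `n_in_band`, `n_band_est_below` (+ `pct_band_est_below`).
#' @export
threshold_misclassification <- function(mgfr, egfr, threshold = 30,
                                        band = c(30, 40)) {
  if (length(mgfr) != length(egfr)) stop("mgfr and egfr must have equal length")
  below <- mgfr < threshold
  in_band <- mgfr >= band[1] & mgfr <= band[2]
  n_below <- sum(below)
  n_over <- sum(below & egfr >= threshold)
  n_band <- sum(in_band)
  n_under <- sum(in_band & egfr < threshold)
  structure(list(
    threshold = threshold, band = band, n = length(mgfr),
    n_below = n_below, n_below_est_above = n_over,
    pct_below_est_above = if (n_below > 0) 100 * n_over / n_below else NA_real_,
    n_in_band = n_band, n_band_est_below = n_under,
    pct_band_est_below = if (n_band > 0) 100 * n_under / n_band else NA_real_
  ), class = "misclassification_report")
}

#' @export
print.misclassification_report <- function(x, ...) {
  cat(sprintf("GFR threshold misclassification (cut-off %g ml/min, n = %d)\n",
              x$threshold, x$n))
  cat(sprintf("  mGFR < %g: %d, of which estimated >= %g: %d (%s%%)\n",
              x$threshold, x$n_below, x$threshold, x$n_below_est_above,
              formatC(x$pct_below_est_above, format = "f", digits = 1)))
  cat(sprintf("  mGFR in [%g, %g]: %d, of which estimated < %g: %d (%s%%)\n",
              x$band[1], x$band[2], x$n_in_band, x$threshold,
              x$n_band_est_below,
              formatC(x$pct_band_est_below, format = "f", digits = 1)))
  invisible(x)
}

#' Per-formula misclassification breakdown
#'
#' @param cohort data.frame with `mgfr` and the marker columns.
#' @param ids Equation ids, default all registered.
#' @inheritParams threshold_misclassification
#' @return data.frame with one row per equation: the counts and
#'   percentages of [threshold_misclassification()], plus `status`.
#' @export
misclassification_table <- function(cohort, ids = formula_ids(),
                                    threshold = 30, band = c(30, 40)) {
  cohort <- as.data.frame(cohort)
  rows <- lapply(ids, function(fid) {
    base <- data.frame(formula_id = fid, threshold = threshold,
                       band_lo = band[1], band_hi = band[2],
                       n = nrow(cohort), n_below = NA_integer_,
                       n_below_est_above = NA_integer_,
                       pct_below_est_above = NA_real_,
                       n_in_band = NA_integer_,
                       n_band_est_below = NA_integer_,
                       pct_band_est_below = NA_real_,
                       status = "ok", stringsAsFactors = FALSE)
    tryCatch({
      egfr <- compute_egfr(fid, cohort)
      r <- threshold_misclassification(cohort$mgfr, egfr,
                                       threshold = threshold, band = band)
      base$n_below <- r$n_below
      base$n_below_est_above <- r$n_below_est_above
      base$pct_below_est_above <- r$pct_below_est_above
      base$n_in_band <- r$n_in_band
      base$n_band_est_below <- r$n_band_est_below
      base$pct_band_est_below <- r$pct_band_est_below
      base
    }, error = function(e) {
      base$status <- paste("skipped:", conditionMessage(e))
      base
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Distribution of absolute estimation errors across bands
#'
#' Partitions absolute percent differences into the bands `[0, 10)`,
#' `[10, 20)`, `[20, 30)` and `[30, Inf)` (left-closed).
#'
#' @param d_pct Percent differences (see [percent_differences()]).
#' @return Named fractions summing to 1.
#' @examples
#' error_band_distribution(c(5, 15, 25, 35))
#' @export
error_band_distribution <- function(d_pct) {
  if (length(d_pct) < 1) stop("empty input")
  a <- abs(d_pct)
  c("<10%" = mean(a < 10),
    "10-20%" = mean(a >= 10 & a < 20),
    "20-30%" = mean(a >= 20 & a < 30),
    ">30%" = mean(a >= 30))
}

#' Tolvaptan eligibility flags from age and GFR
#'
#' Informational flags mirroring published prescribing rules, not clinical
#' advice: GFR below the 30 ml/min cut-off where treatment is avoided;
#' GFR above the 45 ml/min reimbursement support level; and the
#' not-recommended window for subjects aged 55-60 with GFR above 60
#' ml/min. All thresholds are configurable.
#'
#' @param age Age in years (>= 18).
#' @param gfr GFR in ml/min.
#' @param avoid_below GFR cut-off to avoid treatment, default 30.
#' @param reimburse_above GFR level supporting reimbursement, default 45.
#' @param age_window Age band for the not-recommended rule, default
#'   `c(55, 60)`.
#' @param gfr_above_in_window GFR bound in that band, default 60.
#' @return data.frame of logicals: `below_cutoff_30`, `reimbursable_45`,
#'   `not_recommended_55_60_gfr60`.
#' @export
tolvaptan_flags <- function(age, gfr, avoid_below = 30, reimburse_above = 45,
                            age_window = c(55, 60), gfr_above_in_window = 60) {
  if (any(age < 18)) stop("flags are defined for adults (age >= 18)")
  if (any(gfr < 0)) stop("gfr must be non-negative")
  data.frame(
    below_cutoff_30 = gfr < avoid_below,
    reimbursable_45 = gfr > reimburse_above,
    not_recommended_55_60_gfr60 =
      age >= age_window[1] & age <= age_window[2] & gfr > gfr_above_in_window
  )
}

#' Published 14-case reference panel
#'
#' A small published panel of ADPKD patients with measured GFR and four
#' equation estimates (aMDRD, CKD-EPI creatinine, cystatin and combined),
#' arranged in pairs of similar measured GFR from 16 to 95 ml/min. Used as
#' a fixed fixture for threshold-misclassification counting.
#'
#' @return data.frame: `case`, `mgfr`, `amdrd`, `ckdepi_cr`, `ckdepi_cy`,
#'   `ckdepi_crcy` (all ml/min).
#' @export
reference_cases <- function() {
  path <- system.file("extdata", "adpkd_reference_cases.csv",
                      package = "gfragree", mustWork = TRUE)
  utils::read.csv(path)
}
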