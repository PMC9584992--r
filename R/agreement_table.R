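#' Agreement table: every equation against measured GFR
#'
#' Runs each registered (or requested) eGFR equation over the cohort,
#' converts indexed outputs to absolute ml/min, and summarises agreement
#' with measured GFR as one row per equation: CCC with a conservative lower
#' bound, empirical TDI (% of mGFR) with an upper bound, and coverage
#' probability at `kappa0` with a lower bound. Display follows the usual
#' reporting convention: CCC to 2 decimals, TDI and cp to whole percent.
#' Equations that cannot run on the cohort (e.g. a missing marker column)
#' are flagged in the `status` column, never aborted on.
#'
#' @param cohort data.frame with `mgfr` (ml/min) plus the marker and
#'   covariate columns the equations require.
#' @param ids Equation ids, default all registered.
#' @inheritParams agreement
#' @param round Apply the display rounding (default `TRUE`); `FALSE` keeps
#'   full precision.
#' @return data.frame: `formula_id`, `basis`, `n`, `ccc`, `ccc_bound`,
#'   `tdi`, `tdi_bound`, `cp`, `cp_bound`, `status`.
#' @export
agreement_table <- function(cohort, ids = formula_ids(), kappa0 = 10,
                            p = 0.90, scale = c("log", "percent"),
                            B = 2000, seed = NULL, round = TRUE) {
  scale <- match.arg(scale)
  cohort <- as.data.frame(cohort)
  if (!"mgfr" %in% names(cohort)) stop("cohort lacks an mgfr column")
  if (any(!is.finite(cohort$mgfr)) || any(cohort$mgfr <= 0)) {
    stop("mgfr must be finite and positive")
  }
  reg <- formula_registry()
  rows <- lapply(seq_along(ids), function(i) {
    fid <- ids[i]
    basis <- reg$basis[match(fid, reg$formula_id)]
    blank <- data.frame(
      formula_id = fid, basis = ifelse(is.na(basis), "?", basis),
      n = nrow(cohort), ccc = NA_real_, ccc_bound = NA_real_,
      tdi = NA_real_, tdi_bound = NA_real_,
      cp = NA_real_, cp_bound = NA_real_, status = "ok",
      stringsAsFactors = FALSE
    )
    tryCatch({
      egfr <- compute_egfr(fid, cohort)
      # per-formula seed offset keeps bootstrap draws independent across rows
      a <- agreement(cohort$mgfr, egfr, kappa0 = kappa0, p = p,
                     scale = scale, B = B,
                     seed = if (is.null(seed)) NULL else seed + i)
      blank$ccc <- a$ccc; blank$ccc_bound <- a$ccc_bound
      blank$tdi <- a$tdi; blank$tdi_bound <- a$tdi_bound
      blank$cp <- a$cp; blank$cp_bound <- a$cp_bound
      blank
    }, error = function(e) {
      blank$status <- paste("skipped:", conditionMessage(e))
      blank
    })
  })
  out <- do.call(rbind, rows)
  if (round) {
    out$ccc <- round(out$ccc, 2)
    out$ccc_bound <- round(out$ccc_bound, 2)
    for (col in c("tdi", "tdi_bound", "cp", "cp_bound")) {
      out[[col]] <- round(out[[col]])
    }
  }
  rownames(out) <- NULL
  out
}
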