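## End-to-end orchestration: cohort (synthetic or user-supplied) -> eGFR
## matrix -> agreement table -> misclassification and error-band reports,
## all written under one output directory with a manifest. Reruns with the
## same config are bit-identical: every stochastic stage is seeded from the
## single config seed and floats are serialised at 6 significant digits.

#' Pipeline run configuration
#'
#' @param seed Integer seed; mandatory, drives every stochastic stage.
#' @param cohort Cohort data.frame, path to a cohort CSV, or `NULL` to
#'   generate a synthetic cohort from `params`.
#' @param params [cohort_params()] for the synthetic cohort (ignored when
#'   `cohort` is supplied).
#' @param n Synthetic cohort size, default 1000.
#' @param ids Equation ids to run, default all registered.
#' @param kappa0,p,scale,B Agreement settings (see [agreement()]).
#' @param threshold,band Misclassification settings (see
#'   [threshold_misclassification()]).
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(seed, cohort = NULL, params = cohort_params(),
                       n = 1000, ids = formula_ids(), kappa0 = 10, p = 0.90,
                       scale = "log", B = 2000, threshold = 30,
                       band = c(30, 40), out_dir = NULL) {
  if (missing(seed) || !is.numeric(seed)) stop("an explicit seed is required")
  structure(list(seed = as.integer(seed), cohort = cohort, params = params,
                 n = n, ids = ids, kappa0 = kappa0, p = p, scale = scale,
                 B = B, threshold = threshold, band = band,
                 out_dir = out_dir), class = "run_config")
}

#' Read and validate a cohort CSV
#'
#' Strict validation: required columns `id`, `age`, `sex`, `weight`,
#' `height`, `scr`, `mgfr` (decimal point, ml/min, mg/dL); optional
#' `cysc`, `tkv`, `black`. A missing `cysc` column is tolerated (cystatin
#' equations will be flagged as skipped downstream); duplicate ids and
#' non-numeric cells are hard errors naming the offender.
#'
#' @param path CSV file path.
#' @return Validated cohort data.frame.
#' @export
read_cohort_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "age", "sex", "weight", "height", "scr", "mgfr")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("cohort file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  dup <- x$id[duplicated(x$id)]
  if (length(dup) > 0) {
    stop("duplicate patient id(s): ", paste(unique(dup), collapse = ", "))
  }
  num_cols <- intersect(c("age", "weight", "height", "scr", "cysc",
                          "mgfr", "tkv"), names(x))
  for (col in num_cols) {
    if (!is.numeric(x[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(x[[col]]))) &
                     !is.na(x[[col]]))
      stop("non-numeric value in column '", col, "', row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  if (!all(x$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }
  if (any(x$age < 18)) stop("cohort includes subjects under 18")
  for (col in c("weight", "height", "scr")) {
    if (any(!is.finite(x[[col]]) | x[[col]] <= 0)) {
      stop("column '", col, "' must be finite and positive")
    }
  }
  if ("cysc" %in% names(x) && any(!is.na(x$cysc) & x$cysc <= 0)) {
    stop("column 'cysc' must be positive where present")
  }
  if (any(!is.finite(x$mgfr) | x$mgfr < 0)) {
    stop("column 'mgfr' must be finite and non-negative")
  }
  if (!"black" %in% names(x)) x$black <- FALSE
  x
}

#' @rdname read_cohort_csv
#' @param cohort Cohort data.frame to write.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt_num_cols <- function(df, digits = 6) {
  for (col in names(df)) {
    if (is.numeric(df[[col]])) df[[col]] <- signif(df[[col]], digits)
  }
  df
}

write_table_csv <- function(df, path, digits = 6) {
  utils::write.csv(fmt_num_cols(df, digits), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Run the full agreement analysis
#'
#' Stages: (1) obtain the cohort (synthetic, data.frame, or CSV path);
#' (2) evaluate every requested eGFR equation into an absolute-scale
#' matrix; (3) agreement table (Table-1 shape) with bootstrap bounds;
#' (4) per-formula misclassification report at the treatment threshold;
#' (5) per-formula error-band distribution; (6) long-format scatter data
#' (mGFR vs eGFR per equation). When `config$out_dir` is set, each stage's
#' table is written there (CSV, floats at 6 significant digits; the
#' misclassification report and run manifest as JSON); reruns with the
#' same config produce byte-identical artifacts.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage log lines.
#' @return List (invisibly when writing): `cohort`, `egfr`,
#'   `agreement`, `misclassification`, `error_bands`, `scatter`,
#'   `manifest`, `paths`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  cohort <- config$cohort
  if (is.null(cohort)) {
    cohort <- generate_cohort(config$n, seed = config$seed,
                              params = config$params)
    say("stage synth: generated %d synthetic subjects (seed %d)",
        nrow(cohort), config$seed)
  } else if (is.character(cohort)) {
    cohort <- read_cohort_csv(cohort)
    say("stage read: %d subjects from %s", nrow(cohort), config$cohort)
  }

  egfr <- egfr_matrix(cohort, ids = config$ids)
  n_skip <- length(attr(egfr, "skipped"))
  say("stage egfr: %d equations on %d subjects (%d skipped)",
      length(config$ids), nrow(cohort), n_skip)

  agree <- agreement_table(cohort, ids = config$ids, kappa0 = config$kappa0,
                           p = config$p, scale = config$scale, B = config$B,
                           seed = config$seed)
  say("stage agree: %d rows, B = %d", nrow(agree), config$B)

  misclass <- misclassification_table(cohort, ids = config$ids,
                                      threshold = config$threshold,
                                      band = config$band)
  say("stage classify: threshold %g ml/min, band [%g, %g]",
      config$threshold, config$band[1], config$band[2])

  bands <- do.call(rbind, lapply(config$ids, function(fid) {
    e <- egfr[[fid]]
    if (all(is.na(e))) return(NULL)
    f <- error_band_distribution(percent_differences(cohort$mgfr, e))
    data.frame(formula_id = fid, band = names(f), fraction = unname(f))
  }))
  rownames(bands) <- NULL

  scatter <- do.call(rbind, lapply(config$ids, function(fid) {
    e <- egfr[[fid]]
    if (all(is.na(e))) return(NULL)
    data.frame(formula_id = fid, id = cohort$id, mgfr = cohort$mgfr, egfr = e)
  }))
  rownames(scatter) <- NULL

  manifest <- list(
    package = "gfragree",
    version = as.character(utils::packageVersion("gfragree")),
    seed = config$seed,
    n = nrow(cohort),
    formulas = config$ids,
    kappa0 = config$kappa0, p = config$p, scale = config$scale,
    B = config$B, threshold = config$threshold, band = config$band,
    synthetic = is.null(config$cohort)
  )

  paths <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      cohort = file.path(config$out_dir, "cohort.csv"),
      egfr = file.path(config$out_dir, "egfr_matrix.csv"),
      agreement = file.path(config$out_dir, "agreement_table.csv"),
      misclassification = file.path(config$out_dir, "misclassification.json"),
      error_bands = file.path(config$out_dir, "error_bands.csv"),
      scatter = file.path(config$out_dir, "scatter_mgfr_egfr.csv"),
      manifest = file.path(config$out_dir, "manifest.json")
    )
    write_table_csv(cohort, paths$cohort)
    write_table_csv(egfr, paths$egfr)
    write_table_csv(agree, paths$agreement)
    jsonlite::write_json(fmt_num_cols(misclass), paths$misclassification,
                         auto_unbox = FALSE, digits = NA, pretty = TRUE)
    write_table_csv(bands, paths$error_bands)
    write_table_csv(scatter, paths$scatter)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    say("stage write: %d artifacts in %s", length(paths), config$out_dir)
  }

  out <- list(cohort = cohort, egfr = egfr, agreement = agree,
              misclassification = misclass, error_bands = bands,
              scatter = scatter, manifest = manifest, paths = paths)
  if (is.null(config$out_dir)) out else invisible(out)
}
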