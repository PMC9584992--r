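## Plug-in registry of eGFR equations.
##
## Each entry couples a vectorised evaluator (data.frame of patients ->
## numeric, on the scale the equation was published: ml/min/1.73 m2 when
## indexed_output, ml/min otherwise) with the metadata needed to run it
## inside the pipeline: which serum marker(s) it needs and which covariate
## columns it reads.

.registry <- new.env(parent = emptyenv())
.registry$specs <- list()

#' Register an eGFR equation
#'
#' Adds (or replaces) an equation in the package registry. The bundled
#' equations are registered on load; user-supplied equations can be added
#' the same way and then participate in every pipeline stage.
#'
#' @param formula_id Unique short label, e.g. `"CKD-EPI-cr"`.
#' @param basis One of `"creatinine"`, `"cystatin"`, `"both"`.
#' @param indexed_output `TRUE` if the published equation returns
#'   ml/min/1.73 m2 (it will be converted to absolute ml/min by default).
#' @param fun Evaluator: `function(patients)` taking a data.frame and
#'   returning one value per row, vectorised, on the published scale.
#' @param requires Character vector of patient columns the evaluator reads.
#' @param citation Free-text citation of the original publication.
#' @return `formula_id`, invisibly.
#' @export
register_formula <- function(formula_id, basis, indexed_output, fun,
                             requires, citation = "") {
  stopifnot(is.character(formula_id), length(formula_id) == 1L, nzchar(formula_id))
  basis <- match.arg(basis, c("creatinine", "cystatin", "both"))
  stopifnot(is.function(fun), is.logical(indexed_output))
  .registry$specs[[formula_id]] <- list(
    formula_id = formula_id, basis = basis,
    indexed_output = indexed_output, fun = fun,
    requires = requires, citation = citation
  )
  invisible(formula_id)
}

#' @rdname formula_registry
#' @export
formula_ids <- function() names(.registry$specs)

#' Enumerate registered eGFR equations
#'
#' @param formula_id Optional single id; if given, return that entry's
#'   metadata as a list (including the evaluator).
#' @return `formula_registry()` returns a data.frame with one row per
#'   registered equation (id, marker basis, whether the published output is
#'   BSA-indexed, citation); `formula_ids()` the ids alone.
#' @export
formula_registry <- function(formula_id = NULL) {
  if (!is.null(formula_id)) {
    spec <- .registry$specs[[formula_id]]
    if (is.null(spec)) stop("unknown formula_id: ", formula_id)
    return(spec)
  }
  specs <- .registry$specs
  data.frame(
    formula_id = vapply(specs, `[[`, "", "formula_id"),
    basis = vapply(specs, `[[`, "", "basis"),
    indexed_output = vapply(specs, `[[`, TRUE, "indexed_output"),
    citation = vapply(specs, `[[`, "", "citation"),
    row.names = NULL
  )
}

#' Serialise / restore the formula registry
#'
#' Writes the registry metadata (not the evaluator code) as JSON, the
#' interchange format for recording which equation set an analysis used.
#'
#' @param path File path for the JSON registry listing.
#' @return The path, invisibly.
#' @export
write_registry_json <- function(path) {
  jsonlite::write_json(formula_registry(), path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

.required_markers <- c(creatinine = "scr", cystatin = "cysc")

validate_patients <- function(patients, spec, need_bsa) {
  patients <- as.data.frame(patients)
  need <- unique(c(spec$requires, if (need_bsa) c("weight", "height")))
  missing_cols <- setdiff(need, names(patients))
  if (length(missing_cols) > 0) {
    stop("patients lack column(s) required by ", spec$formula_id, ": ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in intersect(need, c("scr", "cysc", "weight", "height", "age"))) {
    v <- patients[[col]]
    if (any(!is.finite(v)) || any(v <= 0)) {
      stop("non-positive or missing values in required column '", col,
           "' for ", spec$formula_id)
    }
  }
  if ("sex" %in% need && !all(patients$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }
  if (!"black" %in% names(patients)) patients$black <- FALSE
  patients
}

#' Evaluate a registered eGFR equation on patients
#'
#' Evaluates the published equation for each patient row. Equations whose
#' published output is indexed to 1.73 m2 BSA are converted to absolute
#' ml/min by default, multiplying by the patient's Du Bois BSA over 1.73
#' (`indexed = TRUE` returns the raw published value instead). All
#' downstream comparisons against measured GFR use the absolute scale.
#'
#' @param formula_id A registered equation id (see [formula_ids()]).
#' @param patients data.frame with the columns the equation requires
#'   (`scr` mg/dL, `cysc` mg/L, `age` years, `sex` "male"/"female",
#'   `weight` kg, `height` cm; optional logical `black`, default `FALSE`).
#' @param indexed If `TRUE`, return the equation's raw published value
#'   (ml/min/1.73 m2 for indexed equations) without BSA conversion.
#' @return Numeric vector of eGFR values, one per patient row.
#' @examples
#' pt <- data.frame(age = 40, sex = "male", weight = 72, height = 175,
#'                  scr = 1.0, cysc = 0.9)
#' compute_egfr("Cockcroft-Gault", pt) # 100 ml/min
#' @export
compute_egfr <- function(formula_id, patients, indexed = FALSE) {
  spec <- formula_registry(formula_id)
  need_bsa <- spec$indexed_output && !indexed
  patients <- validate_patients(patients, spec, need_bsa)
  val <- spec$fun(patients)
  if (need_bsa) {
    val <- unadjust_bsa(val, du_bois_bsa(patients$weight, patients$height))
  }
  val
}

#' Evaluate many equations into an eGFR matrix
#'
#' @param patients Cohort data.frame (see [compute_egfr()]).
#' @param ids Equation ids, default all registered.
#' @param indexed Passed to [compute_egfr()].
#' @return data.frame: patient `id` column (if present) plus one numeric
#'   column per equation; equations that cannot run on this cohort (e.g.
#'   missing marker column) yield an all-`NA` column with a
#'   `"skipped"` attribute recording the reason.
#' @export
egfr_matrix <- function(patients, ids = formula_ids(), indexed = FALSE) {
  patients <- as.data.frame(patients)
  out <- if ("id" %in% names(patients)) {
    data.frame(id = patients$id)
  } else {
    data.frame(row = seq_len(nrow(patients)))
  }
  skipped <- character(0)
  for (fid in ids) {
    val <- tryCatch(compute_egfr(fid, patients, indexed = indexed),
                    error = function(e) {
                      skipped[[fid]] <<- conditionMessage(e)
                      rep(NA_real_, nrow(patients))
                    })
    out[[fid]] <- val
  }
  attr(out, "skipped") <- skipped
  out
}
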