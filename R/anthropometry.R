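#' Du Bois body surface area
#'
#' Computes body surface area (BSA) from weight and height with the
#' Du Bois & Du Bois power formula, the convention used to index (and
#' un-index) GFR to 1.73 m2.
#'
#' @param weight Body weight in kg (vectorised).
#' @param height Standing height in cm (vectorised).
#' @return BSA in m2.
#' @examples
#' du_bois_bsa(70, 180)
#' @export
du_bois_bsa <- function(weight, height) {
  if (any(!is.finite(weight)) || any(!is.finite(height)) ||
      any(weight <= 0) || any(height <= 0)) {
    stop("weight and height must be finite and positive")
  }
  0.007184 * weight^0.425 * height^0.725
}

#' Convert BSA-indexed GFR to absolute GFR
#'
#' Published eGFR equations often return ml/min/1.73 m2. All comparisons in
#' this package are made on the absolute (un-indexed) scale, so indexed
#' values are converted back via `gfr_absolute = gfr_indexed * bsa / 1.73`.
#' `adjust_bsa()` is the exact inverse (absolute -> indexed).
#'
#' @param egfr_indexed GFR in ml/min/1.73 m2.
#' @param bsa Body surface area in m2 (see [du_bois_bsa()]).
#' @return GFR in ml/min.
#' @examples
#' unadjust_bsa(60, 2.076) # 72 ml/min
#' @export
unadjust_bsa <- function(egfr_indexed, bsa) {
  if (any(!is.finite(bsa)) || any(bsa <= 0)) stop("bsa must be positive")
  egfr_indexed * bsa / 1.73
}

#' @rdname unadjust_bsa
#' @param egfr_absolute GFR in ml/min.
#' @export
adjust_bsa <- function(egfr_absolute, bsa) {
  if (any(!is.finite(bsa)) || any(bsa <= 0)) stop("bsa must be positive")
  egfr_absolute * 1.73 / bsa
}

#' Total kidney volume by the ellipsoid method
#'
#' Per-kidney volume is pi/6 * length * width * depth (cm3 = ml), the
#' ellipsoid approximation used for ultrasound and MRI measurements of
#' polycystic kidneys; total kidney volume (TKV) is the sum over both
#' kidneys.
#'
#' @param l_length,l_width,l_depth Largest diameters of the left kidney, cm.
#' @param r_length,r_width,r_depth Largest diameters of the right kidney, cm
#'   (default 0, i.e. a single kidney).
#' @return Total volume in ml.
#' @examples
#' ellipsoid_tkv(12, 6, 5) # single kidney, ~188.5 ml
#' @export
ellipsoid_tkv <- function(l_length, l_width, l_depth,
                          r_length = 0, r_width = 0, r_depth = 0) {
  dims <- c(l_length, l_width, l_depth, r_length, r_width, r_depth)
  if (any(!is.finite(dims)) || any(dims < 0)) {
    stop("kidney diameters must be non-negative")
  }
  pi / 6 * l_length * l_width * l_depth +
    pi / 6 * r_length * r_width * r_depth
}
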