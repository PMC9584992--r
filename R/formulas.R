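## The bundled eGFR equations, as originally published.
##
## Conventions: serum creatinine (scr) in mg/dL, IDMS-traceable; cystatin-C
## (cysc) in mg/L; age in years. Equations published per 1.73 m2 are marked
## indexed_output = TRUE and converted to absolute ml/min by compute_egfr().
## Race terms are applied only when a patient's `black` flag is explicitly
## TRUE (default FALSE). Sex terms follow each original publication; no
## harmonisation across equations.

MG_PER_DL_TO_UMOL_PER_L <- 88.42

fml_amdrd <- function(d) {
  175 * d$scr^-1.154 * d$age^-0.203 *
    ifelse(d$sex == "female", 0.742, 1) *
    ifelse(d$black, 1.212, 1)
}

fml_ckdepi_cr <- function(d) {
  kappa <- ifelse(d$sex == "female", 0.7, 0.9)
  alpha <- ifelse(d$sex == "female", -0.329, -0.411)
  141 * pmin(d$scr / kappa, 1)^alpha * pmax(d$scr / kappa, 1)^-1.209 *
    0.993^d$age *
    ifelse(d$sex == "female", 1.018, 1) *
    ifelse(d$black, 1.159, 1)
}

fml_ckdepi_cy <- function(d) {
  133 * pmin(d$cysc / 0.8, 1)^-0.499 * pmax(d$cysc / 0.8, 1)^-1.328 *
    0.996^d$age * ifelse(d$sex == "female", 0.932, 1)
}

fml_ckdepi_cr_cy <- function(d) {
  kappa <- ifelse(d$sex == "female", 0.7, 0.9)
  alpha <- ifelse(d$sex == "female", -0.248, -0.207)
  135 * pmin(d$scr / kappa, 1)^alpha * pmax(d$scr / kappa, 1)^-0.601 *
    pmin(d$cysc / 0.8, 1)^-0.375 * pmax(d$cysc / 0.8, 1)^-0.711 *
    0.995^d$age *
    ifelse(d$sex == "female", 0.969, 1) *
    ifelse(d$black, 1.08, 1)
}

fml_cockcroft_gault <- function(d) {
  (140 - d$age) * d$weight / (72 * d$scr) *
    ifelse(d$sex == "female", 0.85, 1)
}

# Full-age-spectrum equations: Q is the sex- (or age-) specific median of
# the marker in healthy subjects; the age decline applies past age 40.
fas_age_factor <- function(age) ifelse(age > 40, 0.988^(age - 40), 1)

fml_fas_cr <- function(d) {
  q_cr <- ifelse(d$sex == "female", 0.70, 0.90)
  107.3 / (d$scr / q_cr) * fas_age_factor(d$age)
}

fml_fas_cy <- function(d) {
  q_cy <- ifelse(d$age >= 70, 0.95, 0.82)
  107.3 / (d$cysc / q_cy) * fas_age_factor(d$age)
}

fml_fas_cr_cy <- function(d) {
  q_cr <- ifelse(d$sex == "female", 0.70, 0.90)
  q_cy <- ifelse(d$age >= 70, 0.95, 0.82)
  107.3 / (0.5 * d$scr / q_cr + 0.5 * d$cysc / q_cy) * fas_age_factor(d$age)
}

# Revised Lund-Malmo; published with creatinine in umol/L.
fml_lund_malmo_rev <- function(d) {
  scr_um <- d$scr * MG_PER_DL_TO_UMOL_PER_L
  x <- ifelse(d$sex == "female",
              ifelse(scr_um < 150,
                     2.50 + 0.0121 * (150 - scr_um),
                     2.50 - 0.926 * log(scr_um / 150)),
              ifelse(scr_um < 180,
                     2.56 + 0.00968 * (180 - scr_um),
                     2.56 - 0.926 * log(scr_um / 180)))
  exp(x - 0.0158 * d$age + 0.438 * log(d$age))
}

fml_capa <- function(d) {
  130 * d$cysc^-1.069 * d$age^-0.117 - 7
}

fml_hoek <- function(d) {
  -4.32 + 80.35 / d$cysc
}

fml_larsson <- function(d) {
  77.24 * d$cysc^-1.2623
}

register_builtin_formulas <- function() {
  cr <- c("scr", "age", "sex")
  cy <- c("cysc")
  register_formula("aMDRD", "creatinine", TRUE, fml_amdrd, cr,
    "Levey et al. 2006 (IDMS-traceable abbreviated MDRD)")
  register_formula("CKD-EPI-cr", "creatinine", TRUE, fml_ckdepi_cr, cr,
    "Levey et al. 2009 (CKD-EPI creatinine)")
  register_formula("CKD-EPI-cy", "cystatin", TRUE, fml_ckdepi_cy,
    c("cysc", "age", "sex"),
    "Inker et al. 2012 (CKD-EPI cystatin C)")
  register_formula("CKD-EPI-cr-cy", "both", TRUE, fml_ckdepi_cr_cy,
    c("scr", "cysc", "age", "sex"),
    "Inker et al. 2012 (CKD-EPI creatinine-cystatin C)")
  register_formula("Cockcroft-Gault", "creatinine", FALSE,
    fml_cockcroft_gault, c("scr", "age", "sex", "weight"),
    "Cockcroft & Gault 1976 (creatinine clearance)")
  register_formula("FAS-cr", "creatinine", TRUE, fml_fas_cr, cr,
    "Pottel et al. 2016 (full age spectrum, creatinine)")
  register_formula("FAS-cy", "cystatin", TRUE, fml_fas_cy, c("cysc", "age"),
    "Pottel et al. 2017 (full age spectrum, cystatin C)")
  register_formula("FAS-cr-cy", "both", TRUE, fml_fas_cr_cy,
    c("scr", "cysc", "age", "sex"),
    "Pottel et al. 2017 (full age spectrum, combined)")
  register_formula("Lund-Malmo (Rv)", "creatinine", TRUE,
    fml_lund_malmo_rev, cr,
    "Bjork et al. 2011 (revised Lund-Malmo)")
  register_formula("Grubb-2014 (CAPA)", "cystatin", TRUE, fml_capa,
    c("cysc", "age"),
    "Grubb et al. 2014 (CAPA)")
  register_formula("Hoek", "cystatin", TRUE, fml_hoek, cy,
    "Hoek et al. 2003")
  register_formula("Larsson", "cystatin", FALSE, fml_larsson, cy,
    "Larsson et al. 2004 (predicts absolute iohexol clearance)")
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_formulas()
}
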