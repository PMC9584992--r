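## Agreement statistics for continuous method comparison: Lin's concordance
## correlation coefficient (CCC), the total deviation index (TDI) and the
## coverage probability (cp), with pair-resampling bootstrap bounds.
##
## Differences between an estimate and its reference can be expressed on
## two scales. "percent" is the plain percent-of-reference difference
## 100*(est - ref)/ref. "log" is 100*ln(est/ref), the proportional-error
## convention: a TDI computed on the log scale is back-transformed to a
## percent boundary via 100*(exp(tdi_log/100) - 1), and a percent tolerance
## kappa0 becomes 100*ln(1 + kappa0/100) on the log scale. The log scale is
## the package default for GFR agreement because marker error is
## multiplicative.

#' Paired differences between measured and estimated GFR
#'
#' @param mgfr Reference (measured GFR) values, positive.
#' @param egfr Estimated values, aligned with `mgfr`.
#' @param scale `"percent"` for 100*(egfr - mgfr)/mgfr, `"log"` for
#'   100*ln(egfr/mgfr).
#' @return Numeric vector of differences (units: % of mGFR, or log-%).
#' @examples
#' percent_differences(c(50, 100), c(55, 90)) # +10, -10
#' @export
percent_differences <- function(mgfr, egfr, scale = c("percent", "log")) {
  scale <- match.arg(scale)
  if (length(mgfr) != length(egfr)) stop("mgfr and egfr must have equal length")
  if (any(!is.finite(mgfr)) || any(mgfr <= 0)) {
    stop("mgfr values must be finite and positive")
  }
  if (scale == "percent") {
    100 * (egfr - mgfr) / mgfr
  } else {
    if (any(!is.finite(egfr)) || any(egfr <= 0)) {
      stop("log-scale differences need positive egfr values")
    }
    100 * log(egfr / mgfr)
  }
}

#' Lin's concordance correlation coefficient
#'
#' `ccc = 2*s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with moment
#' estimators (divisor n). Combines precision (Pearson correlation) with
#' accuracy (penalty for location/scale shift); the moment estimator ranges
#' over \[-1, 1\] even though near-perfect agreement keeps it near 1.
#'
#' @param x,y Paired measurements, n >= 2, finite.
#' @return CCC in \[-1, 1\].
#' @examples
#' ccc(1:4, 2:5) # 0.7143
#' @export
ccc <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 2) stop("x and y must be paired with n >= 2")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) stop("ccc undefined: both series constant with equal means")
  2 * sxy / denom
}

#' Empirical total deviation index
#'
#' The smallest boundary kappa such that at least `ceiling(p * n)` of the
#' absolute differences lie within kappa: the `ceiling(p*n)`-th order
#' statistic of `abs(d)`. No interpolation; with ties the smallest
#' qualifying order statistic wins.
#'
#' @param d Differences (any scale).
#' @param p Target coverage proportion, default 0.90.
#' @return The boundary, in the units of `d`.
#' @examples
#' tdi_empirical(1:10) # 9
#' @export
tdi_empirical <- function(d, p = 0.90) {
  n <- length(d)
  if (n < 1) stop("empty difference series")
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  sort(abs(d))[ceiling(p * n)]
}

#' Parametric total deviation index
#'
#' Under d ~ Normal(mean_d, sd_d), the p-th quantile of `abs(d)` is
#' `sd_d * sqrt(q)` with q the p-quantile of the noncentral chi-square with
#' 1 df and noncentrality `(mean_d / sd_d)^2`. Reduces to
#' `sd_d * z_{(1+p)/2}` when `mean_d = 0`.
#'
#' @param mean_d,sd_d Mean and SD of the differences (`sd_d > 0`).
#' @param p Target coverage proportion, default 0.90.
#' @return The boundary, in the units of the differences.
#' @examples
#' tdi_parametric(0, 10) # 16.449
#' @export
tdi_parametric <- function(mean_d, sd_d, p = 0.90) {
  if (!is.finite(sd_d) || sd_d <= 0) stop("sd_d must be positive")
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  sd_d * sqrt(stats::qchisq(p, df = 1, ncp = (mean_d / sd_d)^2))
}

#' Coverage probability of a tolerance boundary
#'
#' Empirical: the fraction of differences with `abs(d) <= kappa0`. The
#' parametric variant ([coverage_parametric()]) is
#' `pnorm((kappa0 - mu)/sigma) - pnorm((-kappa0 - mu)/sigma)`.
#'
#' @param d Differences (any scale).
#' @param kappa0 Allowed boundary, same units as `d`; default 10.
#' @return Proportion in \[0, 1\].
#' @examples
#' coverage_probability(c(5, 15)) # 0.5
#' @export
coverage_probability <- function(d, kappa0 = 10) {
  if (length(d) < 1) stop("empty difference series")
  if (kappa0 <= 0) stop("kappa0 must be positive")
  mean(abs(d) <= kappa0)
}

#' @rdname coverage_probability
#' @param mean_d,sd_d Normal parameters of the differences.
#' @export
coverage_parametric <- function(mean_d, sd_d, kappa0 = 10) {
  if (sd_d <= 0) stop("sd_d must be positive")
  stats::pnorm((kappa0 - mean_d) / sd_d) -
    stats::pnorm((-kappa0 - mean_d) / sd_d)
}

#' Symmetric relative error band around a GFR value
#'
#' The interval an estimate may fall in when its error is within
#' +/- `pct` percent of the reference: `gfr * (1 -/+ pct/100)`.
#'
#' @param gfr Reference GFR, ml/min.
#' @param pct Half-width of the band in percent (default 30).
#' @return Named vector `c(lower, upper)`, ml/min.
#' @examples
#' relative_error_band(60, 30) # 42, 78
#' @export
relative_error_band <- function(gfr, pct = 30) {
  if (any(gfr < 0) || pct < 0) stop("gfr and pct must be non-negative")
  c(lower = gfr * (1 - pct / 100), upper = gfr * (1 + pct / 100))
}

#' Percentile bootstrap bound for an agreement statistic
#'
#' Resamples pairs (rows) with replacement and returns the point estimate
#' together with a conservative one-sided percentile bound: the lower
#' `1 - level` quantile for statistics where small is bad (CCC, cp), the
#' upper `level` quantile for statistics where large is bad (TDI).
#' Reproducible given `seed` and `B`.
#'
#' @param statistic `function(data)` returning a scalar; `data` is a vector
#'   or a data.frame/matrix of pairs (resampled row-wise).
#' @param data The full sample.
#' @param B Bootstrap replicates (>= 100), default 2000.
#' @param seed Integer seed (required).
#' @param level One-sided confidence level, default 0.95.
#' @param direction `"lower"` or `"upper"` bound.
#' @return List: `estimate`, `bound`, `B`, `level`, `direction`.
#' @export
bootstrap_bound <- function(statistic, data, B = 2000, seed,
                            level = 0.95, direction = c("lower", "upper")) {
  direction <- match.arg(direction)
  if (missing(seed)) stop("an explicit seed is required")
  if (B < 100) stop("B must be >= 100")
  n <- NROW(data)
  if (n < 5) stop("refusing to bootstrap fewer than 5 pairs")
  take <- if (is.null(dim(data))) {
    function(idx) data[idx]
  } else {
    function(idx) data[idx, , drop = FALSE]
  }
  est <- statistic(data)
  set.seed(seed)
  boot <- vapply(seq_len(B), function(b) {
    statistic(take(sample.int(n, n, replace = TRUE)))
  }, numeric(1))
  prob <- if (direction == "lower") 1 - level else level
  list(estimate = est,
       bound = unname(stats::quantile(boot, probs = prob, type = 7)),
       B = B, level = level, direction = direction)
}

# Shared-resample bootstrap of (ccc, tdi, cp) for one formula; one index
# draw per replicate so the three bounds come from the same resamples.
bootstrap_agreement <- function(mgfr, egfr, d, kappa_d, p, B, seed,
                                level = 0.95) {
  n <- length(mgfr)
  set.seed(seed)
  reps <- matrix(NA_real_, nrow = B, ncol = 3)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    reps[b, 1] <- ccc(mgfr[idx], egfr[idx])
    reps[b, 2] <- tdi_empirical(d[idx], p)
    reps[b, 3] <- coverage_probability(d[idx], kappa_d)
  }
  c(ccc_bound = unname(stats::quantile(reps[, 1], 1 - level, type = 7)),
    tdi_bound = unname(stats::quantile(reps[, 2], level, type = 7)),
    cp_bound = unname(stats::quantile(reps[, 3], 1 - level, type = 7)))
}

#' Agreement between measured and estimated GFR
#'
#' Computes CCC on the absolute values, the empirical TDI at coverage `p`,
#' and the coverage probability at tolerance `kappa0`, with conservative
#' one-sided bootstrap bounds (lower for CCC and cp, upper for TDI). TDI
#' and cp are evaluated on the difference `scale` (default log, the
#' proportional-error convention) and reported in percent units: a
#' log-scale TDI is back-transformed via `100*(exp(q/100) - 1)` and
#' `kappa0` is mapped onto the log scale, so reported numbers read as
#' "% of mGFR" either way.
#'
#' @inheritParams percent_differences
#' @param kappa0 Allowed difference in percent for cp, default 10.
#' @param p TDI coverage proportion, default 0.90.
#' @param B,seed,level Bootstrap settings (see [bootstrap_bound()]); `seed
#'   = NULL` skips the bootstrap and returns `NA` bounds.
#' @return List of class `"gfr_agreement"`: `n`, `ccc`, `ccc_bound`, `tdi`
#'   (%), `tdi_bound`, `cp` (% of pairs within `kappa0`), `cp_bound`,
#'   `kappa0`, `p`, `scale`.
#' @export
agreement <- function(mgfr, egfr, kappa0 = 10, p = 0.90,
                      scale = c("log", "percent"),
                      B = 2000, seed = NULL, level = 0.95) {
  scale <- match.arg(scale)
  d <- percent_differences(mgfr, egfr, scale = scale)
  kappa_d <- if (scale == "log") 100 * log(1 + kappa0 / 100) else kappa0
  back <- if (scale == "log") {
    function(q) 100 * (exp(q / 100) - 1)
  } else {
    identity
  }
  res <- list(
    n = length(mgfr),
    ccc = ccc(mgfr, egfr),
    tdi = back(tdi_empirical(d, p)),
    cp = 100 * coverage_probability(d, kappa_d),
    kappa0 = kappa0, p = p, scale = scale,
    ccc_bound = NA_real_, tdi_bound = NA_real_, cp_bound = NA_real_
  )
  if (!is.null(seed)) {
    bb <- bootstrap_agreement(mgfr, egfr, d, kappa_d, p, B, seed, level)
    res$ccc_bound <- bb[["ccc_bound"]]
    res$tdi_bound <- back(bb[["tdi_bound"]])
    res$cp_bound <- 100 * bb[["cp_bound"]]
  }
  class(res) <- "gfr_agreement"
  res
}

#' @export
print.gfr_agreement <- function(x, ...) {
  cat(sprintf(
    "GFR agreement (n = %d, %s scale)\n  CCC %.2f (%.2f)  TDI(%.2f) %.0f%% (%.0f)  cp(+/-%g%%) %.0f (%.0f)\n",
    x$n, x$scale, x$ccc, x$ccc_bound, x$p, x$tdi, x$tdi_bound,
    x$kappa0, x$cp, x$cp_bound))
  invisible(x)
}
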