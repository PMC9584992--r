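# Shared fixtures, built in code.

# Fixed 5-patient panel matching the frozen hand-derived oracle file.
panel_patients <- function() {
  data.frame(
    id = c("A", "B", "C", "D", "E"),
    age = c(40, 50, 60, 30, 72),
    sex = c("male", "female", "male", "female", "male"),
    weight = c(72, 60, 85, 55, 78),
    height = c(175, 160, 180, 165, 170),
    scr = c(1.0, 0.8, 1.5, 0.6, 2.8),
    cysc = c(0.9, 1.1, 1.4, 0.7, 2.2),
    stringsAsFactors = FALSE
  )
}

# Two-compartment iohexol curve (mg/L) with known true clearance.
# Volumes in ml, clearances in ml/min; plausible adult iohexol kinetics.
biexp_curve <- function(dose, cl, t, v1 = 6000, v2 = 9000, q = 200) {
  k10 <- cl / v1; k12 <- q / v1; k21 <- q / v2
  s <- k10 + k12 + k21; pr <- k10 * k21
  alpha <- (s + sqrt(s^2 - 4 * pr)) / 2
  beta <- (s - sqrt(s^2 - 4 * pr)) / 2
  a <- dose / (v1 / 1000) * (alpha - k21) / (alpha - beta)
  b <- dose / (v1 / 1000) * (k21 - beta) / (alpha - beta)
  list(conc = a * exp(-alpha * t) + b * exp(-beta * t),
       a = a, b = b, alpha = alpha, beta = beta,
       auc = a / alpha + b / beta)
}

# Moment-formula CCC written independently of the package (sums, not cov).
ccc_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# Manual type-7 quantile (independent of stats::quantile internals).
quantile7_oracle <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}
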