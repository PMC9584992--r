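---
title: "Measuring the error of estimated GFR: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the error of estimated GFR: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfragree)
```

## The problem

In autosomal dominant polycystic kidney disease (ADPKD), treatment
decisions hinge on kidney function: tolvaptan is avoided below a GFR of
30 ml/min, some payers tie reimbursement to 45 ml/min, and treatment is
not recommended for subjects aged 55--60 with GFR above 60 ml/min. In
routine care GFR is *estimated* from serum creatinine and/or cystatin-C by
published equations (eGFR), while the reference standard *measures* it as
the plasma clearance of an injected tracer, here iohexol (mGFR). This
package quantifies how far eGFR strays from mGFR in an ADPKD-like
population and what that error does to threshold-based decisions.

Since patient-level data from such studies are not deposited, the package
pairs the analysis code with a seeded synthetic-cohort generator that
reproduces the *statistical structure* of a multicentre adult ADPKD cohort.
Every stage -- tracer kinetics, equation evaluation, agreement statistics,
threshold misclassification -- runs end-to-end on generated data and is
tested against closed forms and independent oracles.

## Measured GFR: iohexol plasma clearance

Late-phase iohexol concentrations decay mono-exponentially. We fit
$\ln C(t) = \ln C_0 - kt$ by ordinary least squares, form the
slope-intercept clearance

$$\mathrm{CL}_1 = \frac{\text{dose} \cdot k}{C_0},$$

(dose over the area under the extrapolated single exponential), and correct
for the distribution phase that slope-intercept methods miss with the
one-pool quadratic

$$\mathrm{CL} = 0.990778\,\mathrm{CL}_1 - 0.001218\,\mathrm{CL}_1^2 .$$

The coefficients are the widely used adult constants; the study this
package models did not print its clearance equations, so these are a
documented convention of the package, swappable via the `coef` argument.
The correction is monotone on $[0, 406]$ ml/min, bounded above by the
identity, and exactly invertible below $\mathrm{CL} \approx 201$ ml/min --
the inversion is what the curve simulator uses so that a noise-free curve
round-trips to the subject's true mGFR (verified to $< 0.5$ ml/min, in
practice to $10^{-13}$).

On synthetic two-compartment curves with plausible adult iohexol kinetics
(central volume 6 L, peripheral 9 L, intercompartmental clearance 200
ml/min; numerical AUC integration as the oracle), sampling at 120--300 min
recovers true clearance within 5% across 20--120 ml/min. Fits with
log-linear $R^2 < 0.97$ are QC-flagged, a reproducibility gate rather than
a hard failure; subjects whose noisy curves do not decay at all (possible
at very low GFR on a 120--240 min schedule) are returned as `NA` and
flagged.

## Estimated GFR: the equation library

Twelve equations are built in -- aMDRD, CKD-EPI (creatinine, cystatin,
combined), Cockcroft-Gault, FAS (three variants), revised Lund-Malmö,
CAPA, Hoek and Larsson -- each transcribed from its original publication
and checked, on a fixed 5-patient panel, against an independently written
oracle to better than 0.1 ml/min. The registry is a plug-in: any
`function(patients) -> eGFR` can be registered and then participates in
every pipeline stage. Units are fixed (creatinine mg/dL IDMS-traceable,
cystatin-C mg/L); there is no auto-detection.

All comparisons use **absolute** ml/min. Equations published per 1.73 m²
are un-indexed with the patient's Du Bois body surface area,
$\text{GFR} = \text{GFR}_{1.73} \cdot \text{BSA}/1.73$, because indexing
distorts agreement in adults far from the reference body size. Race terms
are applied only when a record's `black` flag is explicitly `TRUE`
(default `FALSE`; the emulated cohort is Spanish and the study never
mentions race adjustment).

## Agreement statistics

Three complementary statistics summarise agreement between $x = $ mGFR and
$y = $ eGFR:

* **CCC** (Lin's concordance correlation coefficient),
  $\rho_c = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)$ with
  divisor-$n$ moments. It multiplies precision (Pearson $r$) by an accuracy
  penalty, so $|\rho_c| \le |r|$; it is invariant to rescaling both series
  but not to shifting one of them. The moment estimator's mathematical
  range is $[-1, 1]$, although for these data it lives near the top of
  $[0, 1]$.
* **TDI** (total deviation index) at coverage $p = 0.90$: the boundary
  containing 90% of absolute differences. The empirical estimator is the
  $\lceil pn \rceil$-th order statistic of $|d|$ (no interpolation;
  smallest qualifying value under ties). The parametric version is
  $\sigma_d \sqrt{\chi^2_{1,(\mu_d/\sigma_d)^2}(p)}$, reducing to
  $\sigma_d z_{0.95} = 1.645\,\sigma_d$ for centred differences.
* **cp** (coverage probability) at tolerance $\kappa_0 = 10\%$: the
  fraction of pairs within $\pm\kappa_0$, the dual of the TDI. When $pn$ is
  an integer, coverage evaluated at the empirical TDI equals $p$ exactly --
  asserted as an identity in the tests.

### The difference scale

Marker error is multiplicative, so the package computes differences on the
**log scale** by default, $d = 100 \ln(\mathrm{eGFR}/\mathrm{mGFR})$, and
back-transforms boundaries to percent for reporting:
$\mathrm{TDI}_\% = 100(e^{\mathrm{TDI}_{\log}/100} - 1)$, and $\kappa_0$
maps to $100\ln(1 + \kappa_0/100)$. Under this convention a lognormal
error of scale $\sigma$ has the closed-form TDI
$100(e^{1.645\sigma} - 1)$, which is both the calibration target of the
synthetic cohort and the oracle of the parameter-recovery tests. It also
reproduces, almost exactly, the published pairing of TDI and cp values in
this population (a TDI of 42% predicts cp $= 2\Phi(\ln 1.1 / 0.213) - 1
\approx 34\%$). The plain percent-of-reference scale
$100(y - x)/x$ is available via `scale = "percent"`; its 0.90 quantile for
the same lognormal error is noticeably smaller (about 41% at
$\sigma = 0.25$ versus 51%) because the ratio distribution is
right-skewed, which is why the scale choice is stated explicitly
everywhere it matters. CCC is always computed on the raw absolute values.

### Uncertainty

Bounds are conservative one-sided 95% percentile bootstrap limits over
resampled *pairs* (B = 2000 by default, explicit seed mandatory): lower
bounds for CCC and cp (where small is bad), upper for TDI (where large is
bad). The three statistics share each replicate's resample so the bounds
are internally consistent. The study's published parenthetical bounds were
produced by a different (unstated) interval method; these bootstrap bounds
follow the same direction convention but are not claimed to reproduce
those numbers.

## Threshold misclassification

Around the 30 ml/min cut-off two counts matter: subjects measured below 30
whose estimate is $\ge 30$ (treatment incorrectly allowed) and subjects
measured in the closed band 30--40 whose estimate is $< 30$ (treatment
incorrectly denied). Both thresholds and the band are configurable.
Absolute errors are also binned into $<10$, 10--20, 20--30 and $>30\%$ of
mGFR (left-closed bins). GFR strata use $>90$ strict, $[60, 90]$ closed,
$[30, 60)$, $<30$ -- the published "between 60 and 90" phrasing is
ambiguous at the boundaries, and this convention makes the four strata a
clean partition. A bundled 14-case published reference panel with known
per-equation counts anchors the counting logic as a frozen fixture.

## The synthetic cohort: what it does and does not emulate

`generate_cohort()` draws mGFR stratum-wise -- proportions
0.32/0.30/0.24/0.14 across $>90$, 60--90, 30--60, $<30$ ml/min, uniform
within per-stratum ranges (90--122, 60--90, 30--60, 10--30) chosen so the
pooled median is $\approx 71$ and IQR $\approx 44$--97 ml/min -- then age
(45 ± 14 y truncated at 18), sex (half male), and sex-specific height and
weight. Serum markers are produced by **inverting an anchor equation**:
creatinine is the value at which aMDRD (absolute scale) returns
$\mathrm{mGFR} \cdot e^{\varepsilon_{cr}}$, found by vectorised bisection
on [0.2, 15] mg/dL to $10^{-8}$; cystatin-C likewise via CKD-EPI-cy. The
error pair $(\varepsilon_{cr}, \varepsilon_{cys})$ is bivariate normal
with $\sigma_{cr} = 0.20$, $\sigma_{cys} = 0.22$, $\rho = 0.3$ -- a
calibration (not an estimate) placing equation TDIs in the 35--60% range
reported for this population. Total kidney volume is lognormal (median
$\approx 1008$ ml, log-SD 0.8, matching the ultrasound median and
approximating its IQR) and observed for 68% of subjects.

Anchor inversion has two consequences worth naming. First, at
$\sigma = 0$ the anchor equations reproduce mGFR *exactly* -- the
noiseless pipeline identity used in tests -- while non-anchor equations
still differ through their different age/sex/weight dependence, which is
precisely the formula-dependent disagreement the analysis is about.
Second, the anchor's TDI has the lognormal closed form above, giving a
parameter-recovery test with a known answer
($\sigma \in \{0.1, 0.2, 0.3\}$ at $n = 5000$ recovers it within 2
percentage points, monotonically).

What the generator does **not** emulate: non-GFR determinants of the
markers (muscle mass, inflammation, thyroid state), within-subject
biological drift, assay recalibration differences between centres, and any
longitudinal structure. Passing tests therefore demonstrate that the
*statistical machinery* is correct and that the qualitative conclusion
(large, equation-dependent error with material threshold
misclassification) follows from proportional marker error of realistic
size -- they do not re-estimate the published effect sizes from real
patients.

## Numerical and design choices

* Bisection rather than analytic inversion of the anchors keeps the
  generator correct for any registered monotone equation; infeasible noise
  draws (target eGFR unreachable for any marker value in range) are
  redrawn and counted, not silently clamped.
* Curve simulation chooses the one-compartment $k$ and $C_0$ through the
  *inverse* of the one-pool correction so that the measurement pipeline is
  exercised end-to-end; the iohexol distribution volume is 250 ml/kg body
  weight, and the default sampling schedule is 120/150/180/240 min.
* Order statistics use the ceiling convention with no interpolation; the
  bootstrap uses `stats::quantile` type 7 on the replicate vector.
* All pipeline artifacts serialise floats at 6 significant digits, and a
  rerun with the same config is byte-identical; the manifest records seed,
  sample size and every analysis setting.
* Problem sizes in the test-suite and acceptance runs (cohorts of
  60--5000, B of 120--2000) were chosen as the smallest sizes at which the
  Monte-Carlo tolerances above are meaningful.

## Known limitations

The equation library implements the twelve named equations, not the full
historical catalogue of 61; the registry exists so the remainder can be
added. The one-pool correction is an adult convention -- paediatric or
extreme-body-size use would need different constants. The bootstrap bounds
are percentile-method and one-sided by design; they are not BCa intervals.
And the cohort generator's realism is exactly the lognormal error model
described above -- conclusions about any *specific* equation's bias in real
patients should come from measured data, which is rather the point of the
analysis.
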