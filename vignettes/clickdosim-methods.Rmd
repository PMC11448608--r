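---
title: "Methods: preclinical dosimetry and pretargeting pharmacokinetics with clickdosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preclinical dosimetry and pretargeting pharmacokinetics with clickdosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clickdosim)
```

## The problem

Single-domain antibodies (sdAbs) are attractive vectors for targeted
radionuclide therapy: they clear quickly from blood and penetrate tumors
well. The price of that rapid renal clearance is kidney retention of the
radiolabel, which makes the kidney the dose-limiting organ. Pretargeting
splits dosing in two steps — an unlabelled TCO-functionalised vector first,
then, after a lag, a small, fast-clearing tetrazine radioligand that clicks
onto the vector in vivo — so that most of the activity never rides on the
slowly-excreted vector through the kidney.

`clickdosim` implements the quantitative chain used to evaluate such
designs in mice: per-animal biodistribution tables (%IA/g) are reduced to
per-organ time–activity curves (TACs), integrated into cumulated activity,
converted to organ mean absorbed dose (MAD) for ^177^Lu, and compared via
therapeutic indices, fold-changes, ANOVA and survival analysis. A
compartmental simulator generates synthetic one-step and two-step cohorts
with the statistical structure this analysis assumes, enabling end-to-end
testing, lag-time/injected-mass sweeps and parameter recovery studies.

## From biodistribution to cumulated activity

The unit of observation is one animal, sacrificed at one time point: a
cross-sectional design. `build_tac()` reduces a cohort × organ to per-time
means and sample SDs. Because each time point is a different group of
animals, per-time means are independent; every SD propagation downstream
relies on this design fact and deliberately ignores between-time
covariance.

Dosimetry integrates *physical* activity — what actually decays in the
tissue. Biodistribution tables are often decay-corrected to injection
time, but published tables rarely say so; the `decay_corrected` flag
therefore travels with every study and curve, `apply_physical_decay()`
converts (multiplying by $e^{-\lambda_{phys} t}$, idempotent with a
warning), and `integrate_tac()` refuses decay-corrected input rather than
silently overestimating decays.

Cumulated activity $\tilde a$ (%IA/g·h) is computed as

$$\tilde a = \underbrace{\text{leading segment}}_{[0, t_1]}
  + \underbrace{\text{trapezoid}}_{[t_1, t_n]}
  + \underbrace{\text{tail}}_{[t_n, \infty)}$$

* **Leading segment** (`t0`): sampling rarely includes $t = 0$ and
  published integrations do not state their leading-edge treatment, so it
  is explicit and configurable: `"rise"` (linear from 0 at injection to
  the first sample — the default, appropriate for one-step vectors whose
  uptake begins at injection), `"plateau"` (first sample held back to
  $t=0$), or `"none"`.
* **Tail**: the default is a terminal mono-exponential fitted by
  log-linear regression on the last $k \ge 2$ points, contributing
  $A_n/\lambda_{term}$. The fitted rate is constrained to be at least
  $\lambda_{phys}$ — biological retention cannot make physical activity
  outlive bare decay — and violations (common when the last two noisy
  points happen to rise) fall back to the physical-decay-only tail
  $A_n/\lambda_{phys}$ with a warning. A truncated (`"none"`) option
  supports window-matched comparisons. These choices give the ordering
  truncated ≤ terminal-exponential ≤ physical-decay tail.
* **SD**: the integral is a fixed linear combination $\sum_i w_i A_i$ of
  the per-time means, so the delta method gives
  $sd = \sqrt{\sum_i w_i^2 sd_i^2}$. The fitted terminal rate is treated
  as fixed in this propagation (its sampling variability is not modelled).

Every result row records the integration method and window, so values
integrated to the last sample are never silently compared against values
extrapolated to infinity.

## From cumulated activity to dose

Under the local-deposition model each decay deposits its mean energy
$\Delta$ locally, scaled by an absorbed fraction $\varphi$:

$$\mathrm{MAD}\ [\mathrm{cGy/MBq}] = \tilde a \cdot 10^{-2} \cdot 3600
  \cdot 10^{6} \cdot \Delta_J \cdot 10^{3} \cdot 10^{2} \cdot \varphi$$

reading left to right: fraction per gram, s/h, decays/s per MBq, J per
decay, g/kg, cGy/Gy. The packaged ^177^Lu entry uses a half-life of
6.647 d and $\Delta$ = 147.9 keV of locally deposited (electron) energy
per decay with $\varphi = 1$; both are named configuration constants, not
literals in computation code, because published mouse dosimetry is
usually based on Monte-Carlo S-value tables that are not generally
available. At these defaults the coefficient is ≈ 0.0853 cGy/MBq per
1 %IA/g·h; reconstructions of published organ MADs with this stand-in
land within about ±10% of S-value-based tables, which is the accuracy
claimed for it. Photon cross-dose is ignored on this path — at
mouse-organ scale the ^177^Lu dose is electron-dominated — and
`svalue_dose()` provides the full MIRD
$D_{target} = \sum_{source} \tilde A_{source} \cdot S(target \leftarrow
source)$ path when a table is available (a diagonal S-matrix reproduces
local deposition exactly, which is tested).

Therapeutic index is tumor MAD over organ MAD. Reported TIs follow the
dosimetry-table convention — two decimals below 10, whole numbers above —
with the raw ratio always retained alongside.

## The comparison layer

* `fold_change()` always reports larger/smaller with the direction
  recorded, rounding headline values to integers at ≥ 2-fold and one
  decimal below.
* `ratio_with_uncertainty()` propagates SDs by the first-order delta
  method assuming independence. This operates on cohort-level AUC
  mean ± SD because per-animal AUCs do not exist in cross-sectional
  sacrifice designs; it reproduces published tumor-to-kidney ratios and
  their quoted uncertainties, so it is adopted as the package's stated
  convention.
* `anova_multi()` computes Dunnett many-to-one adjusted p-values
  numerically from the multivariate-t distribution (via
  `mvtnorm::pmvt`, absolute error 1e-5) rather than table lookup, with
  the standard correlation structure
  $\rho_{jk} = \sqrt{n_j n_k / ((n_j+n_0)(n_k+n_0))}$; Šídák all-pairs
  adjustment is $1-(1-p)^m$. Fully degenerate inputs (zero within-group
  variance everywhere) are flagged as exact separation rather than
  producing NaN. Published two-way designs are handled by the optional
  second crossed factor with interaction; repeated-measures structures
  are out of scope.
* `km_fit()`/`logrank()` wrap the survival package's product-limit
  estimator and Mantel–Cox test behind the package's tidy interface. The
  median convention is the smallest time with $S(t) \le 0.5$ (undefined
  when the curve never reaches 0.5), matching common KM software; both
  are verified in tests against hand-computed product-limit and
  O−E/V tables.

## The pretargeting simulator

The simulator is this package's own mechanistic construction — published
pretargeting optimisations are empirical, and no rate constants are
imputed to any publication. Amounts are nmol; bimolecular rates are
1/(nmol·h).

**One-step model** (directly labelled vector): blood vector $V_b$ clears
renally at $k_{ren}$ with fraction $f_{kid}$ retained in kidney (released
at $k_{kidrel}$) and binds a saturable tumor compartment
($k_{on}$, $B_{max}$, $k_{off}$).

**Two-step model**: during the lag the unlabelled TCO-vector follows the
same dynamics with the bound pool split into reactive surface ($S$) and
internalized ($I$) fractions — receptor-mediated internalization leaves
TCO unreactive — while all TCO deactivates as
$\rho(t) = e^{-k_{deact} t}$ from vector injection. After radioligand
injection, free ligand clears renally fast ($k_{Lren}$, small retained
fraction $f_{Lkid}$) while clicking onto reactive TCO in blood and on the
tumor surface at $k_{click}$. The clicked blood complex behaves like
labelled vector: it can still bind tumor and it clears renally with the
vector's high kidney retention — this is precisely the mechanism that
penalises short lag times. Radioactivity tracks ligand-bearing species
only. In the limit of zero lag, stable TCO and very fast click, the
two-step solution collapses onto the one-step model, which is tested.

Output converts compartment amounts to %IA/g via nominal organ masses
(kidney 0.3 g, tumor 0.15 g, blood 1.5 g — stated assumptions for a
20–25 g mouse), applies physical decay, and adds per-animal multiplicative
lognormal noise (mean-preserving, CV 0.15 by default, matching typical
between-animal scatter in biodistribution cohorts) under a cross-sectional
design with fresh animals per time point.

**Calibration.** The default rates are a one-time calibration of this
package, chosen so the simulator reproduces three qualitative behaviours
of sdAb pretargeting and then frozen: (i) kidney cumulated activity falls
at least 5-fold between a 0.5 h and an 8 h lag; (ii) the two-step tumor
AUC is ≈ 0.6× the one-step arm (clicking cannot reach internalized or
deactivated TCO); (iii) the tumor-to-kidney AUC ratio over lags
{0.5, 2, 8, 24} h peaks at 8 h — short lags lose on blood-click kidney
uptake, long lags lose on TCO deactivation. The defaults are
`k_ren` 1.0/h, `f_kid` 0.5, `k_kid_rel` 0.01/h, `k_on` 0.1/(nmol·h),
`B_max` 1.5 nmol, `k_off` 0.02/h, `k_int` 0.2/h, `k_deact` 0.15/h,
`k_click` 2/(nmol·h), `k_Lren` 2/h, `f_Lkid` 0.01, vector 16 nmol
(200 µg of a ~12.5 kDa conjugate), ligand 2 nmol, lag 8 h. They are
calibration constants of this artifact, not estimates of any real system.

**What the simulator does and does not emulate.** It reproduces the
cross-sectional design, positive multiplicative scatter, saturable tumor
binding and the lag/mass trade-offs. It does not model whole-body
physiology (no PBPK), non-renal clearance routes, radiocatabolite
recirculation, immunogenicity, dynamic target expression, or
tumor-growth/dose coupling. Passing tests on simulated cohorts therefore
validate the pipeline's arithmetic and statistical behaviour under the
stated assumptions, not the biology of any particular real study.

## Parameter fitting

`fit_params()` does least-squares on log activities (multiplicative noise
makes log residuals approximately homoscedastic) over the per-time organ
means of a one-step study. Rates and `B_max` are fitted on the log scale,
fractions on the logit scale, so every iterate respects bounds.
Optimisation is Nelder–Mead from 5 seeded Latin-hypercube starts plus the
baseline values (short exploratory runs, then a full polish of the best),
with the one-step right-hand side compiled in C for speed. The documented
identifiable subset from one-step data is {`k_ren`, `k_off`, `f_kid`}
(plus `k_kid_rel` with late sampling); requesting two-step parameters
from one-step data is an explicit error naming the missing design
requirement (two-step studies at ≥ 2 lag times). A fit with RMS
log-residual above 0.5 — predictions off by ~65% on average — is flagged
`poor_fit` with a warning, so mislabelled inputs can never fit silently.

## Numerical choices

* ODE integration: `deSolve::lsoda` at rtol 1e-8 / atol 1e-12 for
  simulation output (reproducibility across platforms); the fitting hot
  path uses the compiled RHS with fixed-order Adams at rtol 1e-6, whose
  error is far below the noise level being fitted. Solver undershoot of
  empty compartments (~atol) is clamped to zero at output.
* Terminal-rate constraint uses a 1e-9 relative slack so a rate equal to
  $\lambda_{phys}$ up to regression round-off is not a spurious fallback.
* All randomness (noise, sweeps, fitting starts, fixtures) is seeded;
  sweep cells derive per-cell seeds from one master seed, so results are
  bit-reproducible on one platform.
* Test and acceptance problem sizes are the package's own choices:
  property checks use 5–40-point curves against a 1e4-subinterval
  quadrature oracle; the log-rank null calibration uses 2,000 two-arm
  replicates (n = 10/arm); parameter recovery uses 100 seeded cohorts
  (CV 0.15, 5 animals/time, 3 time points); the calibrated lag sweep
  averages 10 replicate cohorts per lag.

## Known limitations

* The local-deposition dose model is a deliberate stand-in accurate to
  ~±10% against published S-value-based mouse tables; absolute MADs
  should use `svalue_dose()` with a real table when available.
* Delta-method ratio SDs are first-order and assume independence of the
  two AUC estimates.
* The KM median is undefined (NA) under heavy censoring; log-rank is
  refused with zero events.
* The simulator's click chemistry is reduced to a single deactivation
  clock and a single reactive-surface pool; multi-TCO valency and spacer
  effects are not modelled.
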