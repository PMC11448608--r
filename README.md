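# clickdosim

Preclinical radiopharmaceutical dosimetry and pretargeting
pharmacokinetics, tidyverse-style.

Single-domain antibodies (sdAbs) clear renally, and the retained
radiolabel makes the kidney the dose-limiting organ of sdAb-based
targeted radionuclide therapy. Click-chemistry pretargeting — inject an
unlabelled TCO-functionalised vector first, then a fast-clearing
tetrazine radioligand after a lag time — decouples targeting from
radioactivity transport and can raise the kidney therapeutic index
severalfold. `clickdosim` is for researchers evaluating such designs in
mice: it implements the full quantitative chain from biodistribution
tables to organ doses and statistical comparisons, plus a compartmental
simulator of one-step and two-step kinetics for study design and
end-to-end validation.

The chain:

1. **Time–activity curves** — per-animal %IA/g tables (cross-sectional
   sacrifice design) reduced to per-organ mean ± SD curves
   (`read_biodist()`, `build_tac()`).
2. **Cumulated activity** — ã (%IA/g·h) by trapezoid integration with a
   configurable leading-edge convention and tail model (terminal
   mono-exponential with rate constrained ≥ λ_phys, physical-decay-only,
   or truncated), with delta-method SD propagation
   (`apply_physical_decay()`, `integrate_tac()`, `auc_table()`).
3. **Absorbed dose** — organ mean absorbed dose (MAD, cGy/MBq) by local
   energy deposition, MAD = ã · 10⁻² · 3600 · 10⁶ · Δ_J · 10³ · 10² · φ
   (≈ 0.0853 cGy/MBq per %IA/g·h for ¹⁷⁷Lu at Δ = 147.9 keV, φ = 1), or
   by MIRD S-values, D_target = Σ_source Ã_source · S(target ← source)
   (`local_deposition_dose()`, `svalue_dose()`).
4. **Therapeutic index** — TI = MAD_tumor / MAD_organ
   (`therapeutic_index()`).
5. **Comparison layer** — fold-changes, delta-method ratio ± SD, ANOVA
   with Dunnett (numerical multivariate-t) or Šídák adjustment,
   Kaplan–Meier medians and Mantel–Cox log-rank (`fold_change()`,
   `ratio_with_uncertainty()`, `anova_multi()`, `km_fit()`, `logrank()`).
6. **Simulator** — compartmental ODE models of one-step and two-step
   (pretargeting) kinetics with seeded lognormal between-animal noise,
   lag/mass sweeps and least-squares parameter recovery
   (`simulate_conventional()`, `simulate_pretargeting()`,
   `sweep_pretargeting()`, `fit_params()`).

All user-facing functions take data frames and return tibbles; fitted
objects have broom-style `tidy()`/`glance()` methods and result types
have `autoplot()` methods.

## Worked example

Therapeutic indices from an organ-dose table (two-step arm of a mouse
dosimetry study):

```r
library(clickdosim)
mads <- data.frame(organ = c("blood", "kidney", "tumor"),
                   mad_cGy_per_MBq = c(0.55, 15.64, 37.54))
therapeutic_index(mads, arm = "pretargeting_8h")
#> # A tibble: 3 × 6
#>   arm             organ  mad_cGy_per_MBq ti_raw    ti ti_defined
#>   <chr>           <chr>            <dbl>  <dbl> <dbl> <lgl>
#> 1 pretargeting_8h blood             0.55  68.3   68   TRUE
#> 2 pretargeting_8h kidney           15.6    2.40   2.4 TRUE
#> 3 pretargeting_8h tumor            37.5   NA     NA   FALSE
```

The kidney TI of 2.40 says the tumor absorbs 2.4× the kidney dose per
MBq injected; blood, at TI 68, is far from dose-limiting. Headline
comparisons from cumulated activities (here kidney, healthy mice,
pretargeting vs one-step):

```r
fold_change(260.4, 11.2)
#> # A tibble: 1 × 5
#>       a     b   raw  fold direction
#>   <dbl> <dbl> <dbl> <dbl> <chr>
#> 1  260.  11.2  23.2    23 increase

ratio_with_uncertainty(404, 41, 197, 31)   # tumor-to-kidney AUC ratio
#> # A tibble: 1 × 6
#>   ratio    sd mean_a  sd_a mean_b  sd_b
#>   <dbl> <dbl>  <dbl> <dbl>  <dbl> <dbl>
#> 1  2.05 0.384    404    41    197    31
```

A simulated two-step cohort through the dose chain:

```r
st <- simulate_pretargeting(noise = noise_model(cv = 0.15, seed = 7))
build_tac(st, "pretarget_lag8h", "kidney")
#> # A tibble: 5 × 5
#>   organ  time_h mean_pct_ia_per_g sd_pct_ia_per_g     n
#>   <chr>   <dbl>             <dbl>           <dbl> <int>
#> 1 kidney      1              2.99           0.200     3
#> 2 kidney      4              3.47           0.356     3
#> 3 kidney     24              5.07           0.411     3
#> 4 kidney     48              4.26           0.159     3
#> 5 kidney     72              3.55           0.292     3

aucs <- auc_table(st, organs = c("kidney", "tumor"))
local_deposition_dose(aucs)
#> # A tibble: 2 × 5
#>   cohort          organ  mad_cGy_per_MBq sd_cGy_per_MBq method
#>   <chr>           <chr>            <dbl>          <dbl> <chr>
#> 1 pretarget_lag8h kidney            65.6           3.68 local
#> 2 pretarget_lag8h tumor            121.            9.68 local
```

`run_pipeline()` chains these stages from a YAML config (file input or
seeded simulation) into a deterministic CSV + text report bundle, and
`make_fixtures()` writes the small worked-example input tables.

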