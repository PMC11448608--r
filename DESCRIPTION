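Package: clickdosim
Title: Preclinical Dosimetry and Pharmacokinetic Simulation for
    Pretargeted Radioligand Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for preclinical radiopharmaceutical
    dosimetry: per-animal biodistribution tables (%IA/g) are turned into
    per-organ time-activity curves, time-integrated (cumulated) activity with
    configurable tail extrapolation, organ mean absorbed dose for 177Lu via
    local energy deposition or user-supplied S-value tables, and therapeutic
    indices.  A comparison layer provides fold-changes, delta-method ratio
    uncertainties, one- and two-factor ANOVA with Dunnett or Sidak adjustment,
    and Kaplan-Meier/log-rank survival summaries.  A compartmental
    pharmacokinetic simulator generates synthetic cross-sectional
    biodistribution cohorts for one-step (directly labelled single-domain
    antibody) and two-step (TCO-tetrazine click pretargeting) dosing, with
    lag-time and injected-mass sweeps and least-squares parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    deSolve,
    mvtnorm,
    lhs,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    multcomp,
    jsonlite,
    knitr
Config/testthat/edition: 3
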