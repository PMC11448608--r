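#' Build a per-organ time-activity curve
#'
#' Aggregates the per-animal measurements of one cohort x organ into a
#' time-activity curve (TAC): per-time mean, sample SD and animal count, with
#' times sorted ascending. SD is `NA` where a time point has a single animal.
#'
#' @param study A [biodist_study()].
#' @param cohort Cohort identifier present in the study.
#' @param organ Canonical organ label (normalized before lookup).
#' @return A `tac` tibble with columns `organ`, `time_h`,
#'   `mean_pct_ia_per_g`, `sd_pct_ia_per_g`, `n`; attributes carry the
#'   cohort, the radionuclide and the `decay_corrected` flag.
#' @export
#' @examples
#' st <- biodist_study(data.frame(
#'   cohort_id = "a", organ = "kidney", time_h = rep(c(1, 24), each = 3),
#'   animal_id = rep(1:3, 2), pct_ia_per_g = c(10, 12, 14, 5, 6, 7)
#' ))
#' build_tac(st, "a", "kidney")
build_tac <- function(study, cohort, organ) {
  organ <- normalize_organ(organ)
  df <- as_tibble(as.data.frame(study))
  sel <- df[df$cohort_id == cohort & df$organ == organ, , drop = FALSE]
  if (nrow(sel) == 0) {
    stop("no measurements for cohort '", cohort, "', organ '", organ, "'.",
         call. = FALSE)
  }
  out <- sel |>
    group_by(.data$time_h) |>
    summarise(
      mean_pct_ia_per_g = mean(.data$pct_ia_per_g),
      sd_pct_ia_per_g = if (n() >= 2) stats::sd(.data$pct_ia_per_g)
                        else NA_real_,
      n = n(),
      .groups = "drop"
    ) |>
    arrange(.data$time_h) |>
    mutate(organ = organ, .before = 1)
  new_tac(out, cohort = cohort,
          radionuclide = attr(study, "radionuclide"),
          decay_corrected = attr(study, "decay_corrected"))
}

new_tac <- function(df, cohort, radionuclide, decay_corrected) {
  structure(as_tibble(df),
            cohort = cohort,
            radionuclide = radionuclide,
            decay_corrected = decay_corrected,
            class = c("tac", class(as_tibble(df))))
}

#' Construct a time-activity curve directly
#'
#' Low-level constructor for a TAC from vectors, mainly for tests and for
#' integrating published mean +/- SD curves without a full study object.
#'
#' @param organ Organ label.
#' @param time_h Strictly increasing times in hours.
#' @param mean_pct_ia_per_g Per-time mean activities (%IA/g).
#' @param sd_pct_ia_per_g Per-time SDs (default `NA`).
#' @param n Animal counts per time (default 1).
#' @param cohort Cohort label.
#' @param decay_corrected Logical flag (default `TRUE`).
#' @return A `tac` tibble.
#' @export
tac <- function(organ, time_h, mean_pct_ia_per_g,
                sd_pct_ia_per_g = NA_real_, n = 1L,
                cohort = "cohort", decay_corrected = TRUE) {
  if (any(diff(time_h) <= 0)) {
    stop("`time_h` must be strictly increasing.", call. = FALSE)
  }
  df <- tibble(
    organ = normalize_organ(organ),
    time_h = as.numeric(time_h),
    mean_pct_ia_per_g = as.numeric(mean_pct_ia_per_g),
    sd_pct_ia_per_g = as.numeric(sd_pct_ia_per_g),
    n = as.integer(n)
  )
  new_tac(df, cohort = cohort, radionuclide = lu177(),
          decay_corrected = decay_corrected)
}

#' Convert a decay-corrected TAC to the physical-activity scale
#'
#' Dosimetry integrates physical (uncorrected) activity: what is actually
#' decaying in the tissue. Biodistribution data are often decay-corrected to
#' injection time; this multiplies each mean and SD by
#' \eqn{e^{-\lambda_{phys} t}} and flips the `decay_corrected` flag. Applying
#' it to an already-physical curve is a warning no-op, so the operation is
#' idempotent.
#'
#' @param tac A `tac` tibble.
#' @param nuclide A [radionuclide()]; defaults to the TAC's own.
#' @return The physical-scale `tac`.
#' @export
apply_physical_decay <- function(tac, nuclide = NULL) {
  stopifnot(inherits(tac, "tac"))
  if (!isTRUE(attr(tac, "decay_corrected"))) {
    warning("TAC is already on the physical-activity scale; returning as-is.",
            call. = FALSE)
    return(tac)
  }
  nuclide <- nuclide %||% attr(tac, "radionuclide")
  stopifnot(is_radionuclide(nuclide))
  fac <- exp(-nuclide$lambda_per_h * tac$time_h)
  out <- tac
  out$mean_pct_ia_per_g <- tac$mean_pct_ia_per_g * fac
  out$sd_pct_ia_per_g <- tac$sd_pct_ia_per_g * fac
  attr(out, "decay_corrected") <- FALSE
  attr(out, "radionuclide") <- nuclide
  out
}

#' Time-integrated (cumulated) activity of a TAC
#'
#' Computes the cumulated activity \eqn{\tilde a} in %IA/g.h: the trapezoid
#' integral over the sampled window, plus a leading segment back to t = 0 and
#' an optional extrapolated tail beyond the last sample.
#'
#' The curve must already be on the physical-activity scale (run
#' [apply_physical_decay()] first); integrating a decay-corrected curve would
#' overstate the number of decays, so it is an error.
#'
#' Leading segment (`t0`): biodistribution sampling rarely includes t = 0,
#' and published integrations do not state their leading-edge treatment, so
#' it is configurable. `"rise"` (default) assumes activity grows linearly
#' from 0 at injection to the first sample, appropriate for one-step vectors
#' whose uptake starts at injection; `"plateau"` holds the first sample back
#' to t = 0; `"none"` starts the window at the first sample.
#'
#' Tail models:
#' * `"terminal_exp"` (default): mono-exponential fitted by log-linear
#'   regression on the last `k` points, contributing
#'   \eqn{A_{last}/\lambda_{term}}. The fitted rate is constrained to be at
#'   least the physical decay constant — biological clearance cannot make
#'   physical activity outlive bare decay — and violations fall back to
#'   `"physical"` with a warning.
#' * `"physical"`: decay-only tail \eqn{A_{last}/\lambda_{phys}} (the tissue
#'   retains everything beyond the last sample).
#' * `"none"`: truncate at the last sample.
#'
#' SD is propagated by the delta method over the integration weights,
#' treating per-time means as independent — exact for cross-sectional
#' designs where each time point is a different group of animals. The fitted
#' terminal rate is treated as fixed in the propagation.
#'
#' @param tac A `tac` on the physical-activity scale.
#' @param nuclide A [radionuclide()]; defaults to the TAC's own.
#' @param tail `"terminal_exp"`, `"physical"` or `"none"`.
#' @param t0 `"rise"`, `"plateau"` or `"none"`.
#' @param k Number of terminal points for the exponential fit (>= 2).
#' @return A one-row `cumact` tibble: `organ`, `value`, `sd`, `method`,
#'   `tail`, `t0`, `window_start`, `window_end` (Inf for extrapolated
#'   tails), `cohort`.
#' @export
integrate_tac <- function(tac, nuclide = NULL,
                          tail = c("terminal_exp", "physical", "none"),
                          t0 = c("rise", "plateau", "none"), k = 2L) {
  stopifnot(inherits(tac, "tac"))
  tail <- match.arg(tail)
  t0 <- match.arg(t0)
  if (isTRUE(attr(tac, "decay_corrected"))) {
    stop("TAC is decay-corrected; run apply_physical_decay() before ",
         "integrating.", call. = FALSE)
  }
  nuclide <- nuclide %||% attr(tac, "radionuclide")
  stopifnot(is_radionuclide(nuclide))
  tt <- tac$time_h
  aa <- tac$mean_pct_ia_per_g
  ss <- ifelse(is.na(tac$sd_pct_ia_per_g), 0, tac$sd_pct_ia_per_g)
  m <- length(tt)
  if (m < 2) {
    stop("at least 2 time points are required for integration.",
         call. = FALSE)
  }

  # delta-method weights: value = sum(w * A); start from trapezoid weights
  w <- numeric(m)
  dt <- diff(tt)
  w[1] <- dt[1] / 2
  w[m] <- dt[m - 1] / 2
  if (m > 2) w[2:(m - 1)] <- (tt[3:m] - tt[1:(m - 2)]) / 2

  if (tt[1] > 0) {
    w[1] <- w[1] + switch(t0, rise = tt[1] / 2, plateau = tt[1], none = 0)
  }

  tail_used <- tail
  lambda_term <- NA_real_
  if (tail == "terminal_exp") {
    if (k < 2) stop("`k` must be >= 2 for the terminal fit.", call. = FALSE)
    kk <- min(k, m)
    idx <- (m - kk + 1):m
    if (any(aa[idx] <= 0)) {
      tail_used <- "physical"
      if (aa[m] > 0) {
        warning("non-positive terminal activity; falling back to the ",
                "physical-decay tail.", call. = FALSE)
      }
    } else {
      fit <- stats::lm(log(aa[idx]) ~ tt[idx])
      lambda_term <- -unname(stats::coef(fit)[2])
      # tiny relative slack so a terminal rate equal to lambda_phys up to
      # regression round-off does not trigger the fallback
      if (!is.finite(lambda_term) ||
          lambda_term < nuclide$lambda_per_h * (1 - 1e-9)) {
        warning(sprintf(
          "fitted terminal rate (%.4g /h) is below the physical decay constant (%.4g /h); falling back to the physical-decay tail.",
          lambda_term, nuclide$lambda_per_h), call. = FALSE)
        tail_used <- "physical"
        lambda_term <- NA_real_
      }
    }
  }
  tail_rate <- switch(tail_used,
    terminal_exp = lambda_term,
    physical = nuclide$lambda_per_h,
    none = NA_real_
  )
  if (tail_used != "none" && aa[m] > 0) {
    w[m] <- w[m] + 1 / tail_rate
  }

  value <- sum(w * aa)
  sd <- sqrt(sum((w * ss)^2))
  tibble(
    organ = tac$organ[1],
    value = value,
    sd = sd,
    method = paste0("trapezoid+", t0, "_t0+", tail_used, "_tail"),
    tail = tail_used,
    t0 = t0,
    window_start = if (t0 == "none") tt[1] else 0,
    window_end = if (tail_used == "none") tt[m] else Inf,
    cohort = attr(tac, "cohort") %||% NA_character_
  ) |>
    structure(class = c("cumact", class(tibble())))
}

#' Cumulated-activity table for a whole study
#'
#' Runs [build_tac()], [apply_physical_decay()] (if the study is
#' decay-corrected) and [integrate_tac()] for every cohort x organ
#' combination under one shared integration configuration.
#'
#' @param study A [biodist_study()].
#' @param organs Organ labels to integrate; default all organs present.
#' @param cohorts Cohorts to include; default all.
#' @inheritParams integrate_tac
#' @return A `cumact` tibble, one row per cohort x organ.
#' @export
auc_table <- function(study, organs = NULL, cohorts = NULL,
                      tail = c("terminal_exp", "physical", "none"),
                      t0 = c("rise", "plateau", "none"), k = 2L) {
  tail <- match.arg(tail)
  t0 <- match.arg(t0)
  df <- as_tibble(as.data.frame(study))
  organs <- normalize_organ(organs %||% unique(df$organ))
  cohorts <- cohorts %||% unique(df$cohort_id)
  grid <- tidyr::expand_grid(cohort = cohorts, organ = organs)
  rows <- purrr::pmap(grid, function(cohort, organ) {
    curve <- build_tac(study, cohort, organ)
    if (isTRUE(attr(curve, "decay_corrected"))) {
      curve <- apply_physical_decay(curve)
    }
    integrate_tac(curve, tail = tail, t0 = t0, k = k)
  })
  structure(bind_rows(rows), class = c("cumact", class(tibble())))
}
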