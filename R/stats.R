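#' Fold change between two positive quantities
#'
#' The fold is always larger/smaller, with the direction recorded relative
#' to the argument order. The headline value follows the usual reporting
#' convention: rounded to the nearest integer at 2-fold and above, one
#' decimal below (so 23.25 reports as 23-fold and 1.599 as 1.6-fold).
#'
#' @param a,b Positive scalars.
#' @return A one-row tibble: `a`, `b`, `raw` (larger/smaller), `fold`
#'   (headline value), `direction` (`"increase"` if `a > b`, `"decrease"`
#'   if `a < b`, `"equal"`).
#' @export
#' @examples
#' fold_change(260.4, 11.2) # 23-fold decrease (b vs a ordering recorded)
fold_change <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1 || length(b) != 1 ||
      !is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) {
    stop("`a` and `b` must be single positive numbers.", call. = FALSE)
  }
  raw <- max(a, b) / min(a, b)
  tibble(
    a = a, b = b, raw = raw,
    fold = if (raw >= 2) round(raw) else round(raw, 1),
    direction = if (a > b) "increase" else if (a < b) "decrease" else "equal"
  )
}

#' Ratio of two means with delta-method uncertainty
#'
#' First-order (delta-method) SD of a ratio of independent means:
#' \deqn{sd = \frac{\bar a}{\bar b}\sqrt{(sd_a/\bar a)^2 + (sd_b/\bar b)^2}}
#' This is the propagation appropriate for cohort-level AUC mean +/- SD,
#' where per-animal AUCs do not exist (cross-sectional sacrifice designs).
#'
#' @param mean_a,sd_a Numerator mean (positive) and SD (>= 0).
#' @param mean_b,sd_b Denominator mean (positive) and SD (>= 0).
#' @return A one-row tibble: `ratio`, `sd`, plus the four inputs.
#' @export
#' @examples
#' ratio_with_uncertainty(404, 41, 197, 31) # tumor-to-kidney 2.05 +/- 0.38
ratio_with_uncertainty <- function(mean_a, sd_a, mean_b, sd_b) {
  vals <- c(mean_a, sd_a, mean_b, sd_b)
  if (!all(is.finite(vals)) || mean_a <= 0 || mean_b <= 0 ||
      sd_a < 0 || sd_b < 0) {
    stop("means must be positive and SDs non-negative.", call. = FALSE)
  }
  r <- mean_a / mean_b
  tibble(
    ratio = r,
    sd = r * sqrt((sd_a / mean_a)^2 + (sd_b / mean_b)^2),
    mean_a = mean_a, sd_a = sd_a, mean_b = mean_b, sd_b = sd_b
  )
}

#' ANOVA with many-to-one (Dunnett) or Sidak-adjusted comparisons
#'
#' Fits a fixed-effects ANOVA and returns adjusted p-values per comparison.
#' With one factor, `adjust = "dunnett"` compares every group against the
#' control using the many-to-one multivariate-t distribution (critical
#' values computed numerically via [mvtnorm::pmvt()], not table lookup);
#' `adjust = "sidak"` compares all pairs with the Sidak correction
#' \eqn{p_{adj} = 1 - (1 - p)^m}. With a second crossed factor (`block`),
#' the model is `value ~ group * block` and comparisons use the pooled
#' residual variance.
#'
#' If every group has zero within-group variance the design is degenerate
#' (exact separation): F is infinite or undefined and the result is flagged
#' via `degenerate = TRUE`; when all samples are furthermore identical, all
#' adjusted p-values are 1.
#'
#' @param data Data frame with a numeric response and grouping column(s).
#' @param value,group Column names (strings) of response and primary factor.
#' @param block Optional column name of a second crossed factor.
#' @param adjust `"dunnett"` or `"sidak"`.
#' @param control Control-group label (required for Dunnett).
#' @return An `anova_compare` object; use [tidy()] for per-comparison rows
#'   and [glance()] for the F test.
#' @export
anova_multi <- function(data, value = "value", group = "group",
                        block = NULL, adjust = c("dunnett", "sidak"),
                        control = NULL) {
  adjust <- match.arg(adjust)
  data <- as.data.frame(data)
  y <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop("need at least 2 groups.", call. = FALSE)
  if (any(table(g) < 2)) stop("every group needs n >= 2.", call. = FALSE)

  if (is.null(block)) {
    fit <- stats::aov(y ~ g)
  } else {
    b <- factor(data[[block]])
    fit <- stats::aov(y ~ g * b)
  }
  atab <- stats::anova(fit)
  mse <- atab["Residuals", "Mean Sq"]
  df_res <- atab["Residuals", "Df"]
  degenerate <- !is.finite(mse) || mse <= .Machine$double.eps * mean(y^2 + 1)

  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  lev <- levels(g)

  if (adjust == "dunnett") {
    if (is.null(control)) {
      stop("Dunnett adjustment needs a `control` group label.", call. = FALSE)
    }
    if (!control %in% lev) {
      stop("control group '", control, "' not found.", call. = FALSE)
    }
    trt <- setdiff(lev, control)
    comp <- tibble(
      comparison = paste(trt, "-", control),
      estimate = unname(means[trt] - means[control])
    )
    if (degenerate) {
      comp$statistic <- ifelse(comp$estimate == 0, 0, Inf)
      comp$p_adj <- ifelse(comp$estimate == 0, 1, 0)
    } else {
      se <- sqrt(mse * (1 / ns[trt] + 1 / ns[control]))
      tstat <- comp$estimate / unname(se)
      # many-to-one correlation structure of the comparison t statistics
      lam <- sqrt(ns[trt] / (ns[trt] + ns[control]))
      R <- outer(lam, lam)
      diag(R) <- 1
      comp$statistic <- tstat
      comp$p_adj <- vapply(abs(tstat), function(t0) {
        1 - mvtnorm::pmvt(lower = rep(-t0, length(trt)),
                          upper = rep(t0, length(trt)),
                          df = as.integer(df_res), corr = R,
                          algorithm = mvtnorm::GenzBretz(abseps = 1e-5))[1]
      }, numeric(1))
    }
  } else {
    pairs <- utils::combn(lev, 2)
    m <- ncol(pairs)
    comp <- tibble(
      comparison = paste(pairs[2, ], "-", pairs[1, ]),
      estimate = unname(means[pairs[2, ]] - means[pairs[1, ]])
    )
    if (degenerate) {
      comp$statistic <- ifelse(comp$estimate == 0, 0, Inf)
      comp$p_adj <- ifelse(comp$estimate == 0, 1, 0)
    } else {
      se <- sqrt(mse * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
      comp$statistic <- comp$estimate / unname(se)
      p_raw <- 2 * stats::pt(abs(comp$statistic), df_res, lower.tail = FALSE)
      comp$p_adj <- 1 - (1 - p_raw)^m
    }
    comp$p_adj <- pmin(comp$p_adj, 1)
  }

  structure(
    list(
      comparisons = comp,
      anova_table = atab,
      f_statistic = atab[1, "F value"],
      p_value = atab[1, "Pr(>F)"],
      df = c(atab[1, "Df"], df_res),
      adjust = adjust,
      control = control,
      degenerate = degenerate
    ),
    class = "anova_compare"
  )
}

#' @export
print.anova_compare <- function(x, ...) {
  cat(sprintf("<anova_compare> %s adjustment | F = %.4g, p = %.4g%s\n",
              x$adjust, x$f_statistic, x$p_value,
              if (x$degenerate) " | DEGENERATE (zero within-group variance)"
              else ""))
  print(x$comparisons)
  invisible(x)
}

#' @export
tidy.anova_compare <- function(x, ...) x$comparisons

#' @export
glance.anova_compare <- function(x, ...) {
  tibble(
    f_statistic = x$f_statistic, p_value = x$p_value,
    df_between = x$df[1], df_resid = x$df[2],
    adjust = x$adjust, degenerate = x$degenerate
  )
}

#' Kaplan-Meier curve for one group
#'
#' Product-limit estimator with right censoring (via
#' [survival::survfit()]). The median is the smallest time with
#' \eqn{S(t) \le 0.5}, `NA` when the curve never reaches 0.5 (e.g. heavy
#' censoring).
#'
#' @param records Data frame with columns `time_d` and `event` (and
#'   optionally `group`, ignored here — see [logrank()] for two-arm tests).
#' @return A `km_curve` object; [tidy()] gives the step curve (time,
#'   n_risk, n_event, survival), [glance()] the median and counts.
#' @export
km_fit <- function(records) {
  records <- validate_km_input(records)
  fit <- survival::survfit(
    survival::Surv(time_d, event) ~ 1,
    data = records, conf.type = "none"
  )
  curve <- tibble(
    time_d = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv
  )
  at_or_below <- curve$time_d[curve$survival <= 0.5 + 1e-12]
  structure(
    list(
      curve = curve,
      median_d = if (length(at_or_below)) min(at_or_below) else NA_real_,
      n = nrow(records),
      events = sum(records$event)
    ),
    class = "km_curve"
  )
}

validate_km_input <- function(records) {
  records <- as_tibble(records)
  stopifnot(all(c("time_d", "event") %in% names(records)))
  if (nrow(records) < 1) stop("need at least one record.", call. = FALSE)
  if (!all(records$event %in% c(0, 1))) {
    stop("event must be 0 or 1.", call. = FALSE)
  }
  records
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, events = %d, median = %s d\n",
              x$n, x$events,
              if (is.na(x$median_d)) "undefined" else format(x$median_d)))
  invisible(x)
}

#' @export
tidy.km_curve <- function(x, ...) x$curve

#' @export
glance.km_curve <- function(x, ...) {
  tibble(n = x$n, events = x$events, median_d = x$median_d)
}

#' Kaplan-Meier curves per group
#'
#' @param records Data frame with columns `group`, `time_d`, `event`.
#' @return Tibble of per-group medians and counts, with the per-group
#'   `km_curve` objects in a list column.
#' @export
km_by_group <- function(records) {
  records <- validate_survival(records)
  records |>
    group_by(.data$group) |>
    tidyr::nest() |>
    ungroup() |>
    mutate(
      fit = purrr::map(.data$data, km_fit),
      n = purrr::map_int(.data$fit, "n"),
      events = purrr::map_int(.data$fit, \(f) as.integer(f$events)),
      median_d = purrr::map_dbl(.data$fit, "median_d")
    ) |>
    select("group", "n", "events", "median_d", "fit")
}

#' Log-rank (Mantel-Cox) test between two groups
#'
#' Standard O-E log-rank statistic on 1 df (via [survival::survdiff()]).
#' With zero observed events the statistic is undefined and an error names
#' the condition.
#'
#' @param records Data frame with columns `group`, `time_d`, `event`
#'   containing exactly two groups (or use `groups` to pick two).
#' @param groups Optional character pair selecting two groups.
#' @return One-row tibble: `group_a`, `group_b`, `chisq`, `df`, `p_value`.
#' @export
logrank <- function(records, groups = NULL) {
  records <- validate_survival(records)
  if (!is.null(groups)) {
    stopifnot(length(groups) == 2)
    records <- records[records$group %in% groups, , drop = FALSE]
  }
  lev <- unique(records$group)
  if (length(lev) != 2) {
    stop("log-rank needs exactly two groups (use `groups = c(a, b)`).",
         call. = FALSE)
  }
  if (sum(records$event) == 0) {
    stop("log-rank is undefined with zero events.", call. = FALSE)
  }
  sd <- survival::survdiff(
    survival::Surv(time_d, event) ~ group, data = records
  )
  tibble(
    group_a = lev[1], group_b = lev[2],
    chisq = sd$chisq, df = 1L,
    p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  )
}
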