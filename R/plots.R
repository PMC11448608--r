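#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point
#'   geom_errorbar geom_step geom_col labs theme_minimal scale_y_log10
NULL

#' Plot a time-activity curve
#'
#' Mean +/- SD activity versus time for one organ.
#'
#' @param object A `tac` tibble from [build_tac()] or [tac()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tac <- function(object, ...) {
  ggplot(object, aes(x = .data$time_h, y = .data$mean_pct_ia_per_g)) +
    geom_errorbar(aes(
      ymin = .data$mean_pct_ia_per_g - dplyr::coalesce(.data$sd_pct_ia_per_g, 0),
      ymax = .data$mean_pct_ia_per_g + dplyr::coalesce(.data$sd_pct_ia_per_g, 0)
    ), width = 0.5) +
    geom_line() +
    geom_point() +
    labs(
      x = "Time (h)", y = "%IA/g",
      title = sprintf("%s — %s (%s)", attr(object, "cohort"),
                      object$organ[1],
                      if (isTRUE(attr(object, "decay_corrected")))
                        "decay-corrected" else "physical activity")
    ) +
    theme_minimal()
}

#' Plot cumulated-activity results
#'
#' Bar chart of cumulated activity per cohort and organ with SD whiskers.
#'
#' @param object A `cumact` tibble from [auc_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cumact <- function(object, ...) {
  ggplot(object, aes(x = .data$organ, y = .data$value,
                     fill = .data$cohort)) +
    geom_col(position = "dodge") +
    geom_errorbar(aes(ymin = .data$value - .data$sd,
                      ymax = .data$value + .data$sd),
                  position = ggplot2::position_dodge(width = 0.9),
                  width = 0.2) +
    labs(x = NULL, y = "Cumulated activity (%IA/g·h)", fill = "Cohort") +
    theme_minimal()
}

#' Plot a Kaplan-Meier curve
#'
#' Step plot of the product-limit survival estimate, starting at S(0) = 1.
#'
#' @param object A `km_curve` from [km_fit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- tidy(object)
  df <- bind_rows(tibble(time_d = 0, n_risk = object$n, n_event = 0L,
                         n_censor = 0L, survival = 1), df)
  ggplot(df, aes(x = .data$time_d, y = .data$survival)) +
    geom_step() +
    labs(x = "Time (d)", y = "Survival probability") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    theme_minimal()
}

#' Plot a lag-time sweep
#'
#' Kidney and tumor cumulated activity (log scale) and tumor-to-kidney
#' ratio as a function of lag time.
#'
#' @param sweep Output of [sweep_pretargeting()] (one `vector_nmol`).
#' @return A ggplot object.
#' @export
plot_lag_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(
    sweep[c("lag_h", "kidney_auc", "tumor_auc")],
    -"lag_h", names_to = "organ", values_to = "auc"
  )
  ggplot(long, aes(x = .data$lag_h, y = .data$auc, colour = .data$organ)) +
    geom_line() + geom_point() +
    scale_y_log10() +
    labs(x = "Lag time (h)", y = "Cumulated activity (%IA/g·h)",
         colour = NULL) +
    theme_minimal()
}
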