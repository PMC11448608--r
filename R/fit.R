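one_step_free <- c("k_ren", "f_kid", "k_kid_rel", "k_on", "k_off", "B_max")
two_step_only <- c("k_click", "k_deact", "k_Lren", "f_Lkid", "lag_h")

default_fit_bounds <- list(
  k_ren = c(0.01, 20), f_kid = c(0.001, 0.999), k_kid_rel = c(1e-5, 2),
  k_on = c(1e-4, 10), k_off = c(1e-5, 2), B_max = c(0.01, 100)
)

# rates and B_max fit on log scale, fractions on logit scale
to_unconstrained <- function(v, nm) {
  is_frac <- nm %in% c("f_kid", "f_Lkid")
  out <- numeric(length(v))
  out[is_frac] <- stats::qlogis(v[is_frac])
  out[!is_frac] <- log(v[!is_frac])
  stats::setNames(out, nm)
}
from_unconstrained <- function(u, nm) {
  is_frac <- nm %in% c("f_kid", "f_Lkid")
  out <- numeric(length(u))
  out[is_frac] <- stats::plogis(u[is_frac])
  out[!is_frac] <- exp(u[!is_frac])
  stats::setNames(out, nm)
}

#' Fit one-step model parameters to a biodistribution study
#'
#' Least-squares fit of a subset of the one-step compartmental parameters
#' to the per-time organ means of a study, on the log-activity scale
#' (multiplicative noise makes log residuals homoscedastic). Rates and
#' `B_max` are fitted on the log scale and fractions on the logit scale, so
#' every start respects the bounds; optimisation is Nelder-Mead from
#' `n_starts` seeded Latin-hypercube starts plus the baseline parameter
#' values, keeping the best optimum.
#'
#' Identifiability: from one-step data the documented recoverable subset is
#' `{k_ren, k_off, f_kid}` (plus `k_kid_rel` with late sampling). The
#' two-step parameters (`k_click`, `k_deact`, ...) require two-step studies
#' at two or more lag times and are rejected with an explicit error.
#'
#' @param study A one-step [biodist_study()] with >= 3 time points,
#'   physical-activity scale, containing some of the organs blood, tumor,
#'   kidney.
#' @param free Character vector of parameter names to fit.
#' @param bounds Named list of `c(lower, upper)` overriding the defaults.
#' @param params Baseline [pretarget_params()] supplying fixed values.
#' @param n_starts Number of Latin-hypercube starts (>= 1; 5 by default).
#' @param seed Integer seed for the start design.
#' @param organ_masses Named masses (g) used in the %IA/g conversion.
#' @param nuclide A [radionuclide()] for the decay term.
#' @param compute_se Compute approximate standard errors from a
#'   finite-difference Hessian (default `TRUE`; disable in large
#'   simulation studies where only point estimates are needed).
#' @return A `pk_fit` object; [tidy()] gives estimates with approximate
#'   SEs, [glance()] the fit summary including an `rms_log` residual scale
#'   and a `poor_fit` flag.
#' @export
fit_params <- function(study, free = c("k_ren", "f_kid"),
                       bounds = list(), params = pretarget_params(),
                       n_starts = 5, seed = 1L,
                       organ_masses = default_organ_masses,
                       nuclide = NULL, compute_se = TRUE) {
  bad <- intersect(free, two_step_only)
  if (length(bad) > 0) {
    stop("parameter(s) ", paste(bad, collapse = ", "),
         " are not identifiable from a one-step study; they require ",
         "two-step (pretargeting) designs at >= 2 lag times.", call. = FALSE)
  }
  unknown <- setdiff(free, one_step_free)
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  nuclide <- nuclide %||% attr(study, "radionuclide") %||% lu177()
  if (isTRUE(attr(study, "decay_corrected"))) {
    stop("fit expects physical-activity data (decay_corrected = FALSE).",
         call. = FALSE)
  }

  df <- as_tibble(as.data.frame(study))
  df <- df[df$organ %in% c("blood", "tumor", "kidney"), , drop = FALSE]
  if (nrow(df) == 0) {
    stop("study contains none of the model organs (blood, tumor, kidney).",
         call. = FALSE)
  }
  obs <- df |>
    filter(.data$time_h > 0) |>
    group_by(.data$organ, .data$time_h) |>
    summarise(obs = mean(.data$pct_ia_per_g), .groups = "drop")
  if (length(unique(obs$time_h)) < 3) {
    stop("need >= 3 time points to fit.", call. = FALSE)
  }
  times <- sort(unique(obs$time_h))

  bnds <- utils::modifyList(default_fit_bounds, bounds)
  lo <- to_unconstrained(vapply(bnds[free], `[`, numeric(1), 1), free)
  hi <- to_unconstrained(vapply(bnds[free], `[`, numeric(1), 2), free)

  eps <- 1e-9
  # precomputed lookups for the hot loop
  organ_idx <- match(obs$organ, c("blood", "tumor", "kidney"))
  time_idx <- match(obs$time_h, times)
  conv_fac <- 100 / unname(organ_masses[obs$organ]) *
    exp(-nuclide$lambda_per_h * obs$time_h)
  log_obs <- log(obs$obs + eps)
  pv_base <- unlist(params[c("k_ren", "f_kid", "k_kid_rel", "k_on",
                             "B_max", "k_off", "vector_nmol")])
  free_pos <- match(free, names(pv_base))
  objective <- function(u) {
    pv <- pv_base
    pv[free_pos] <- from_unconstrained(u, free)
    sol <- tryCatch(suppressWarnings(solve_conventional_fast(pv, times)),
                    error = function(e) NULL)
    if (is.null(sol) || any(!is.finite(sol))) return(1e10)
    amount <- sol[cbind(time_idx, organ_idx)] # Vb, Tb, K columns 1:3
    pred <- pmax(amount, 0) / pv[7] * conv_fac
    sum((log_obs - log(pred + eps))^2)
  }

  set.seed(as.integer(seed))
  design <- lhs::randomLHS(max(1, n_starts), length(free))
  starts <- t(apply(design, 1, function(r) lo + r * (hi - lo)))
  base_u <- to_unconstrained(unlist(params[free]), free)
  starts <- rbind(starts, base_u)

  # staged multi-start: short exploratory runs from every start, then a
  # full polish of the best candidate
  runs <- purrr::map(seq_len(nrow(starts)), function(i) {
    u0 <- starts[i, ]
    opt <- if (length(free) == 1) {
      o <- stats::optimize(function(u) objective(u), c(lo, hi))
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      stats::optim(u0, objective, method = "Nelder-Mead",
                   control = list(maxit = 50, reltol = 1e-5))
    }
    tibble(start = i, objective = opt$value,
           convergence = opt$convergence,
           par = list(stats::setNames(from_unconstrained(opt$par, free),
                                      free)))
  }) |> bind_rows()

  best <- runs[which.min(runs$objective), ]
  if (length(free) > 1) {
    polish <- stats::optim(
      to_unconstrained(best$par[[1]], free), objective,
      method = "Nelder-Mead", control = list(maxit = 300, reltol = 1e-9)
    )
    best$objective <- polish$value
    best$convergence <- polish$convergence
    best$par <- list(stats::setNames(from_unconstrained(polish$par, free),
                                     free))
  }
  est <- best$par[[1]]
  n_obs <- nrow(obs)
  rms_log <- sqrt(best$objective / n_obs)

  # approximate SEs: central-difference Hessian on the unconstrained scale
  u_hat <- to_unconstrained(est, free)
  se_u <- rep(NA_real_, length(free))
  if (compute_se && length(free) >= 1 && rms_log > 0) {
    h <- 1e-4
    H <- matrix(NA_real_, length(free), length(free))
    f0 <- objective(u_hat)
    for (i in seq_along(free)) {
      for (j in seq_len(i)) {
        ei <- ej <- rep(0, length(free)); ei[i] <- h; ej[j] <- h
        H[i, j] <- H[j, i] <-
          (objective(u_hat + ei + ej) - objective(u_hat + ei - ej) -
           objective(u_hat - ei + ej) + objective(u_hat - ei - ej)) /
          (4 * h^2)
      }
    }
    sigma2 <- f0 / max(n_obs - length(free), 1)
    cov_u <- tryCatch(2 * sigma2 * solve(H), error = function(e) NULL)
    if (!is.null(cov_u) && all(diag(cov_u) > 0)) se_u <- sqrt(diag(cov_u))
  }

  poor <- rms_log > 0.5
  if (poor) {
    warning(sprintf(
      "poor fit: RMS log-residual %.2f (> 0.5); check organ labels and model adequacy.",
      rms_log), call. = FALSE)
  }
  structure(
    list(
      estimate = est, se_unconstrained = stats::setNames(se_u, free),
      free = free, objective = best$objective, rms_log = rms_log,
      n_obs = n_obs, starts = runs, convergence = best$convergence,
      poor_fit = poor, fixed = params
    ),
    class = "pk_fit"
  )
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("<pk_fit> %d free parameter(s), RMS log-residual %.3f%s\n",
              length(x$free), x$rms_log,
              if (x$poor_fit) " [POOR FIT]" else ""))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.pk_fit <- function(x, ...) {
  # delta-method SEs back on the natural scale
  deriv <- ifelse(x$free %in% c("f_kid", "f_Lkid"),
                  x$estimate * (1 - x$estimate), x$estimate)
  tibble(
    term = x$free,
    estimate = unname(x$estimate),
    std_error = unname(abs(deriv) * x$se_unconstrained)
  )
}

#' @export
glance.pk_fit <- function(x, ...) {
  tibble(
    objective = x$objective, rms_log = x$rms_log, n_obs = x$n_obs,
    n_starts = nrow(x$starts), convergence = x$convergence,
    poor_fit = x$poor_fit
  )
}
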