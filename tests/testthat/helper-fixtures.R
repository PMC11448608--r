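# small in-code fixtures shared across test files

toy_measurements <- function(organs = c("kidney", "tumor"),
                             times = c(1, 24, 72), animals = 3) {
  grid <- expand.grid(organ = organs, time_h = times,
                      animal_id = paste0("m", seq_len(animals)),
                      stringsAsFactors = FALSE)
  grid$cohort_id <- "arm1"
  # deterministic positive values, distinct per row
  grid$pct_ia_per_g <- 10 + as.numeric(factor(grid$organ)) +
    grid$time_h / 10 + as.numeric(factor(grid$animal_id)) / 2
  grid[c("cohort_id", "organ", "time_h", "animal_id", "pct_ia_per_g")]
}

toy_study <- function(...) biodist_study(toy_measurements(...))

# exact exponential TAC sampled on a grid (physical scale)
exp_tac <- function(a0 = 100, lambda = 0.02, times = seq(0.5, 300, length.out = 30),
                    organ = "kidney") {
  tac(organ, times, a0 * exp(-lambda * times), decay_corrected = FALSE)
}

# brute-force quadrature of the piecewise-linear interpolant
trapz_oracle <- function(times, values, nsub = 1e4) {
  grid <- seq(min(times), max(times), length.out = nsub + 1)
  y <- stats::approx(times, values, xout = grid)$y
  sum((y[-1] + y[-length(y)]) / 2 * diff(grid))
}
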