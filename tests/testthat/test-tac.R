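test_that("build_tac computes per-time mean and sample SD, order-invariant", {
  m <- data.frame(
    cohort_id = "a", organ = "kidney", time_h = 1,
    animal_id = c("x", "y", "z"), pct_ia_per_g = c(10, 12, 14)
  )
  curve <- build_tac(biodist_study(m), "a", "kidney")
  expect_equal(curve$mean_pct_ia_per_g, 12)
  expect_equal(curve$sd_pct_ia_per_g, 2)
  expect_equal(curve$n, 3L)

  # single animal per time: SD absent, mean passes through
  m1 <- data.frame(cohort_id = "a", organ = "kidney", time_h = c(1, 24),
                   animal_id = "x", pct_ia_per_g = c(8, 3))
  c1 <- build_tac(biodist_study(m1), "a", "kidney")
  expect_true(all(is.na(c1$sd_pct_ia_per_g)))
  expect_equal(c1$mean_pct_ia_per_g, c(8, 3))

  # shuffling rows changes nothing
  m_all <- toy_measurements()
  shuffled <- m_all[rev(seq_len(nrow(m_all))), ]
  expect_equal(
    build_tac(biodist_study(shuffled), "arm1", "kidney"),
    build_tac(biodist_study(m_all), "arm1", "kidney")
  )

  expect_error(build_tac(toy_study(), "nope", "kidney"), "no measurements")
})

test_that("apply_physical_decay halves at one half-life and is a guarded no-op", {
  curve <- tac("kidney", c(0, lu177()$half_life_h), c(100, 100),
               decay_corrected = TRUE)
  phys <- apply_physical_decay(curve)
  expect_equal(phys$mean_pct_ia_per_g[1], 100) # t = 0 unchanged
  expect_equal(phys$mean_pct_ia_per_g[2], 50, tolerance = 1e-10)
  expect_false(attr(phys, "decay_corrected"))
  expect_warning(again <- apply_physical_decay(phys), "already")
  expect_equal(again, phys)
})

test_that("integration of an exact exponential recovers A0/lambda", {
  lam <- 0.02
  # >= 20 samples over 5 half-lives
  times <- seq(0.05, 5 * log(2) / lam, length.out = 40)
  curve <- tac("kidney", times, 100 * exp(-lam * times),
               decay_corrected = FALSE)
  res <- integrate_tac(curve, nuclide = radionuclide("x", log(2) / lam, 100),
                       tail = "terminal_exp", t0 = "rise")
  expect_lt(abs(res$value - 100 / lam) / (100 / lam), 0.01)

  # constant decay-corrected curve: after decay, physical tail and plateau
  # leading edge give a0 / lambda_phys
  nuc <- lu177()
  t2 <- seq(1, 400, length.out = 60)
  const <- tac("kidney", t2, rep(40, length(t2)), decay_corrected = TRUE)
  phys <- apply_physical_decay(const, nuc)
  r2 <- integrate_tac(phys, nuc, tail = "physical", t0 = "plateau")
  expect_lt(abs(r2$value - 40 / nuc$lambda_per_h) / (40 / nuc$lambda_per_h),
            0.01)
})

test_that("truncated trapezoid matches a fine-grained quadrature oracle", {
  set.seed(11)
  for (i in 1:5) {
    times <- sort(runif(5, 0.5, 80))
    vals <- runif(5, 1, 50)
    curve <- tac("tumor", times, vals, decay_corrected = FALSE)
    res <- integrate_tac(curve, tail = "none", t0 = "none")
    oracle <- trapz_oracle(times, vals)
    expect_lt(abs(res$value - oracle) / oracle, 1e-4)
    expect_equal(res$window_start, times[1])
    expect_equal(res$window_end, times[5])
  }
})

test_that("tail models are ordered and scale equivariance holds", {
  set.seed(21)
  times <- c(1, 4, 24, 48, 72)
  vals <- c(30, 25, 12, 7, 4) * exp(-0.01 * times) # decaying curve
  curve <- tac("kidney", times, vals, sd_pct_ia_per_g = vals * 0.1,
               n = 3L, decay_corrected = FALSE)
  v_none <- integrate_tac(curve, tail = "none")
  v_phys <- integrate_tac(curve, tail = "physical")
  v_term <- integrate_tac(curve, tail = "terminal_exp")
  # adding a tail never decreases; terminal rate >= lambda_phys caps the
  # terminal-exp tail at the physical-decay tail
  expect_lt(v_none$value, v_term$value)
  expect_lte(v_term$value, v_phys$value)

  # multiplying activities by c scales value and sd by c
  c10 <- tac("kidney", times, 10 * vals, sd_pct_ia_per_g = 10 * vals * 0.1,
             n = 3L, decay_corrected = FALSE)
  r10 <- integrate_tac(c10, tail = "terminal_exp")
  expect_equal(r10$value, 10 * v_term$value, tolerance = 1e-12)
  expect_equal(r10$sd, 10 * v_term$sd, tolerance = 1e-12)
})

test_that("rising terminal points fall back to the physical tail with warning", {
  curve <- tac("kidney", c(1, 24, 48), c(10, 5, 8), decay_corrected = FALSE)
  expect_warning(res <- integrate_tac(curve, tail = "terminal_exp"),
                 "falling back")
  expect_equal(res$tail, "physical")
})

test_that("integration rejects decay-corrected curves and short curves", {
  corr <- tac("kidney", c(1, 24), c(10, 5), decay_corrected = TRUE)
  expect_error(integrate_tac(corr), "apply_physical_decay")
  single <- tac("kidney", 1, 10, decay_corrected = FALSE)
  expect_error(integrate_tac(single), "2 time points")
})

test_that("auc_table covers cohorts x organs and handles zero organs", {
  m <- toy_measurements(organs = c("kidney", "tumor"), times = c(1, 24, 72))
  m2 <- m
  m2$cohort_id <- "arm2"
  m2$pct_ia_per_g[m2$organ == "tumor"] <- 0
  st <- biodist_study(rbind(m, m2), decay_corrected = FALSE)
  tab <- suppressWarnings(auc_table(st)) # rising toy curves -> tail fallback
  expect_equal(nrow(tab), 4)
  expect_equal(tab$value[tab$cohort == "arm2" & tab$organ == "tumor"], 0)
})

test_that("simulator kidney AUC matches the closed-form linear solution", {
  # with k_on = 0 the kidney compartment is a linear two-compartment chain:
  # K(t) = f k A0 / (kr - k) (e^{-k t} - e^{-kr t}) and the decayed integral
  # has a closed form
  p <- pretarget_params(k_on = 0, k_ren = 0.8, f_kid = 0.4, k_kid_rel = 0.05)
  nuc <- lu177()
  times <- seq(1, 72, length.out = 30)
  st <- simulate_conventional(p, nuc, times_h = times, n_per_time = 1,
                              noise = noise_model(cv = 0))
  res <- auc_table(st, organs = "kidney", t0 = "rise", tail = "terminal_exp")
  lam <- nuc$lambda_per_h
  scale <- 100 * p$f_kid * p$k_ren * p$vector_nmol /
    (p$k_kid_rel - p$k_ren) / p$vector_nmol / 0.3
  analytic <- scale * (1 / (p$k_ren + lam) - 1 / (p$k_kid_rel + lam))
  expect_lt(abs(res$value - analytic) / analytic, 0.05)
})
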