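test_that("fold changes reproduce the published headline values", {
  # kidney cumulated activity, healthy mice: 23-fold
  fc1 <- fold_change(260.4, 11.2)
  expect_equal(fc1$fold, 23)
  expect_equal(fc1$raw, 23.25, tolerance = 1e-3)
  expect_equal(fc1$direction, "increase")

  # kidney cumulated activity, xenografts: 8-fold
  fc2 <- fold_change(1615, 197)
  expect_equal(fc2$fold, 8)
  expect_equal(fc2$raw, 8.20, tolerance = 1e-3)

  # tumor MAD: 1.6-fold
  fc3 <- fold_change(60.03, 37.54)
  expect_equal(fc3$fold, 1.6)
  expect_equal(fc3$raw, 1.599, tolerance = 1e-3)

  expect_equal(fold_change(5, 5)$fold, 1)
  expect_equal(fold_change(5, 5)$direction, "equal")
  expect_error(fold_change(-1, 2), "positive")
})

test_that("delta-method ratios reproduce the published tumor-to-kidney values", {
  r1 <- ratio_with_uncertainty(404, 41, 197, 31)
  expect_equal(r1$ratio, 2.05, tolerance = 1e-2)
  expect_equal(r1$sd, 0.384, tolerance = 1e-2)
  expect_equal(round(r1$sd, 1), 0.4)

  r2 <- ratio_with_uncertainty(662, 60, 1615, 185)
  expect_equal(r2$ratio, 0.41, tolerance = 1e-2)
  expect_equal(r2$sd, 0.06, tolerance = 0.005)

  r0 <- ratio_with_uncertainty(7, 0, 7, 0)
  expect_equal(r0$ratio, 1)
  expect_equal(r0$sd, 0)
  expect_error(ratio_with_uncertainty(0, 1, 2, 1), "positive")
})

test_that("delta-method SD is scale-invariant in CV terms", {
  r <- ratio_with_uncertainty(404, 41, 197, 31)
  rc <- ratio_with_uncertainty(404 * 3.7, 41 * 3.7, 197 * 3.7, 31 * 3.7)
  expect_equal(rc$ratio, r$ratio, tolerance = 1e-12)
  expect_equal(rc$sd / rc$ratio, r$sd / r$ratio, tolerance = 1e-12)
})

test_that("degenerate and single-comparison ANOVA cases behave as specified", {
  # all groups identical samples: every adjusted p is 1
  d <- data.frame(value = rep(c(1, 2, 3), 3),
                  group = rep(c("a", "b", "c"), each = 3))
  res <- anova_multi(d, adjust = "sidak")
  expect_true(all(tidy(res)$p_adj == 1))

  # Sidak with m = 1 equals the unadjusted two-group p (t test, pooled var)
  d2 <- data.frame(value = c(1.1, 2.3, 0.8, 2.9, 3.4, 2.2),
                   group = rep(c("a", "b"), each = 3))
  res2 <- anova_multi(d2, adjust = "sidak")
  p_t <- t.test(value ~ group, data = d2, var.equal = TRUE)$p.value
  expect_equal(tidy(res2)$p_adj, p_t, tolerance = 1e-12)

  # degenerate: zero within-group variance everywhere, groups differ
  d3 <- data.frame(value = rep(c(1, 2), each = 3),
                   group = rep(c("a", "b"), each = 3))
  res3 <- suppressWarnings(anova_multi(d3, adjust = "sidak"))
  expect_true(res3$degenerate)
})

test_that("Dunnett adjustment agrees with the multivariate-t reference", {
  skip_if_not_installed("multcomp")
  set.seed(42)
  d <- data.frame(
    value = c(rnorm(8, 10), rnorm(8, 11), rnorm(8, 12.5), rnorm(6, 10.2)),
    group = factor(rep(c("ctrl", "t1", "t2", "t3"), c(8, 8, 8, 6)))
  )
  res <- anova_multi(d, adjust = "dunnett", control = "ctrl")
  fit <- stats::aov(value ~ group, data = d)
  ref <- summary(multcomp::glht(
    fit, linfct = multcomp::mcp(group = "Dunnett")
  ), test = multcomp::adjusted("single-step"))
  expect_equal(unname(tidy(res)$p_adj),
               unname(as.vector(ref$test$pvalues)), tolerance = 5e-4)
})

test_that("Dunnett-adjusted p agrees with a permutation max-|t| null", {
  set.seed(7)
  n <- 20
  d <- data.frame(
    value = c(rnorm(n, 0), rnorm(n, 0.6), rnorm(n, 0.2)),
    group = rep(c("ctrl", "t1", "t2"), each = n)
  )
  res <- anova_multi(d, adjust = "dunnett", control = "ctrl")
  obs_t <- abs(tidy(res)$statistic)

  # permutation reference: distribution of the max |t| over comparisons
  y <- d$value
  g <- d$group
  nperm <- 1e4
  maxt <- replicate(nperm, {
    gp <- sample(g)
    ms <- tapply(y, gp, mean)
    vs <- tapply(y, gp, var)
    ns <- tapply(y, gp, length)
    mse <- sum(vs * (ns - 1)) / sum(ns - 1)
    max(abs(ms[c("t1", "t2")] - ms["ctrl"]) /
          sqrt(mse * (1 / ns[c("t1", "t2")] + 1 / ns["ctrl"])))
  })
  p_perm <- vapply(obs_t, function(t0) mean(maxt >= t0), numeric(1))
  expect_lt(max(abs(tidy(res)$p_adj - p_perm)), 0.025)
})

test_that("KM estimator matches a hand-computed product-limit table", {
  # toy set: events at 2, 4 (x2), censored at 3, 5; n = 5
  rec <- data.frame(time_d = c(2, 3, 4, 4, 5), event = c(1, 0, 1, 1, 0))
  km <- km_fit(rec)
  tab <- tidy(km)
  # hand computation: S(2) = 4/5; at t = 4, 3 at risk, 2 events ->
  # S(4) = 4/5 * 1/3; censoring at 5 leaves the curve flat
  expect_equal(tab$survival[tab$time_d == 2], 4 / 5)
  expect_equal(tab$survival[tab$time_d == 4], 4 / 5 * 1 / 3,
               tolerance = 1e-12)
  expect_equal(km$median_d, 4)
})

test_that("KM equals the empirical survivor function without censoring", {
  set.seed(9)
  t_obs <- sort(sample(1:50, 12))
  rec <- data.frame(time_d = t_obs, event = 1)
  tab <- tidy(km_fit(rec))
  emp <- vapply(tab$time_d, function(t0) mean(t_obs > t0), numeric(1))
  expect_equal(tab$survival, emp, tolerance = 1e-12)

  # median convention: times 1..10, smallest t with S <= 0.5 is 5
  km10 <- km_fit(data.frame(time_d = 1:10, event = 1))
  expect_equal(km10$median_d, 5)
})

test_that("log-rank matches the hand-computed O-E/V statistic", {
  # 2x4 toy: group a events at 1, 3; group b events at 2, 4
  rec <- data.frame(group = c("a", "a", "b", "b"),
                    time_d = c(1, 3, 2, 4), event = 1)
  # hand computation over the four event times:
  # t=1: n=4 (2a), O_a=1, E_a=1/2, V=1/4; t=2: n=3 (1a), O_a=0, E_a=1/3,
  # V=2/9; t=3: n=2 (1a), O_a=1, E_a=1/2, V=1/4; t=4: only b remains,
  # E_a=0, V=0. Sum: O-E = 2 - 4/3 = 2/3; V = 1/4 + 2/9 + 1/4 = 13/18.
  chisq_hand <- (2 / 3)^2 / (13 / 18)
  lr <- logrank(rec)
  expect_equal(lr$chisq, chisq_hand, tolerance = 1e-10)

  # identical groups give statistic 0, p = 1
  same <- data.frame(group = rep(c("a", "b"), each = 4),
                     time_d = rep(c(2, 5, 7, 9), 2), event = 1)
  lr0 <- logrank(same)
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)

  # label swap leaves the statistic invariant
  swapped <- rec
  swapped$group <- ifelse(rec$group == "a", "b", "a")
  expect_equal(logrank(swapped)$chisq, lr$chisq, tolerance = 1e-12)

  # zero events is undefined
  none <- data.frame(group = rep(c("a", "b"), each = 2),
                     time_d = c(1, 2, 3, 4), event = 0)
  expect_error(logrank(none), "zero events")
})

test_that("group-level KM summary reports medians per group", {
  rec <- data.frame(
    group = rep(c("veh", "trt"), each = 6),
    time_d = c(60, 65, 70, 72, 75, 80, 70, 80, 84, 90, 95, 100),
    event = 1
  )
  km <- km_by_group(rec)
  expect_equal(nrow(km), 2)
  expect_equal(km$median_d[km$group == "veh"], 70)
  expect_equal(km$median_d[km$group == "trt"], 84)
})
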