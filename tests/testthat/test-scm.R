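test_that("cumulative hazard matches termwise integration of the hazard families", {
  scm <- fig2_scm(ell = 0.5)
  u0 <- 1.3; u1 <- 0.4
  for (t in c(0, 0.5, 2, 4)) {
    expect_equal(cumulative_hazard(scm, t, u0, u1, 1),
                 (0.5 + u1) * t + u0 * t^3 / 3, tolerance = 1e-14)
    # independent oracle: numeric quadrature of the instantaneous hazard
    if (t > 0)
      expect_equal(cumulative_hazard(scm, t, u0, u1, 1),
                   integrate(function(s) 0.5 + u0 * s^2 + u1, 0, t,
                             rel.tol = 1e-12)$value, tolerance = 1e-10)
  }
  scm20 <- fig2_scm(ell = 1, baseline = "scaled_quadratic")
  expect_equal(cumulative_hazard(scm20, 3, u0, -0.2, 1),
               (1 - 0.2) * 3 + u0 * 27 / 60, tolerance = 1e-14)
  sc <- case_study_scm()
  expect_equal(cumulative_hazard(sc, 2, 0.3, -0.1, 1), (0.1 + 0.3 - 0.1) * 2)
  # empty integral and null effect
  expect_equal(cumulative_hazard(scm, 0, u0, u1, 1), 0)
  expect_equal(cumulative_hazard(scm, 3, u0, 0, 1),
               cumulative_hazard(scm, 3, u0, 0, 0))
  expect_error(cumulative_hazard(scm, 1, u0, -2, 1), "negative")
})

test_that("model construction enforces hazard positivity over the latent support", {
  expect_error(additive_hazard_scm("quadratic", ell = 0.05,
                                   modifier = bhn_modifier(0.5, -0.1, 0.5, 0.4)),
               "positivity")
  expect_silent(additive_hazard_scm("quadratic", ell = 0.1,
                                    modifier = bhn_modifier(0.5, -0.1, 0.5, 0.4)))
  # constant family may absorb a negative modifier through the frailty floor
  expect_silent(additive_hazard_scm("constant", ell = 0,
                                    frailty = degenerate_frailty(0.5),
                                    modifier = degenerate_modifier(-0.4)))
})

test_that("sampled potential times invert the cumulative hazard exactly", {
  scm <- fig2_scm(tau = 0.5, ell = 0.5)
  po <- sample_potential_times(scm, 2000, seed = 21)
  e1 <- cumulative_hazard(scm, po$t1, po$u0, po$u1, 1)
  e0 <- cumulative_hazard(scm, po$t0, po$u0, po$u1, 0)
  # shared structural noise: both arms solve Lambda = e for the same e
  expect_lt(max(abs(e1 - e0)), 1e-10)
  # probability-integral transform: Lambda(T^a) is unit exponential
  po_big <- sample_potential_times(scm, 10000, seed = 22)
  expect_gt(ks.test(cumulative_hazard(scm, po_big$t0, po_big$u0, po_big$u1, 0),
                    "pexp")$p.value, 0.01)
})

test_that("constant-family inversion is the closed form e / rate", {
  scm <- additive_hazard_scm("constant", ell = 0.2,
                             frailty = degenerate_frailty(0.3),
                             modifier = degenerate_modifier(0))
  po <- sample_potential_times(scm, 10000, seed = 3)
  expect_equal(po$t0, po$t1, tolerance = 1e-12)
  expect_gt(ks.test(po$t0, "pexp", 0.5)$p.value, 0.01)
})

test_that("shared noise makes harmed individuals fail earlier under treatment", {
  scm <- additive_hazard_scm("quadratic", ell = 0,
                             modifier = bhn_modifier(0, 0, 0.5, 1))
  po <- sample_potential_times(scm, 5000, seed = 4)
  expect_true(all(po$u1 >= 0))
  expect_true(all(po$t1 <= po$t0 + 1e-12))
})

test_that("the marginal law of an arm's event time is coupling-invariant", {
  # re-simulate the treated arm with its own independent exponential noise;
  # the marginal of T^1 must agree in distribution with the shared-noise draw
  scm <- fig2_scm(tau = 0, ell = 0.5)
  po <- sample_potential_times(scm, 10000, seed = 15)
  set.seed(16)
  lat <- sample_joint(scm$frailty, scm$modifier, scm$copula, 10000)
  e <- rexp(10000)
  t1_indep <- smchd:::invert_cumhaz(0.5 + lat$u1, lat$u0 / 3, e)
  expect_gt(ks.test(po$t1, t1_indep)$p.value, 0.01)
})

test_that("randomized assignment is independent of the latents", {
  scm <- case_study_scm()
  data <- generate_rct(scm, 10000, seed = 8)
  expect_true(all(data$status == 1L))
  expect_lt(abs(mean(data$exposure) - 0.5), 3 * sqrt(0.25 / 10000))
  lat <- attr(data, "latents")
  u1_gap <- mean(lat$u1[data$exposure == 1]) - mean(lat$u1[data$exposure == 0])
  se <- sqrt(var(lat$u1) * (1 / sum(data$exposure) +
                              1 / sum(1 - data$exposure)))
  expect_lt(abs(u1_gap), 3 * se)
})

test_that("independent censoring truncates times and flags status", {
  scm <- case_study_scm()
  data <- generate_rct(scm, 2000, censoring = list(type = "uniform", max = 3),
                       seed = 12)
  expect_true(all(data$time <= 3 + 1e-12))
  expect_true(any(data$status == 0L) && any(data$status == 1L))
  lat <- attr(data, "latents")
  t_obs <- ifelse(data$exposure == 1, lat$t1, lat$t0)
  expect_true(all(data$time[data$status == 1] == t_obs[data$status == 1]))
  expect_error(generate_rct(scm, 10, censoring = list(type = "weibull")),
               "censoring")
})

test_that("Monte-Carlo marginal survival matches the exponential closed form", {
  scm <- additive_hazard_scm("constant", ell = 0,
                             frailty = degenerate_frailty(0.8),
                             modifier = degenerate_modifier(0))
  grid <- c(0, 0.5, 1, 2)
  surv <- marginal_survival(scm, grid, a = 0, n = 10000, seed = 17)
  expect_equal(surv$survival[1], 1)
  expect_true(all(diff(surv$survival) <= 0))
  tol <- 3 * sqrt(0.25 / 10000)
  expect_true(all(abs(surv$survival - exp(-0.8 * grid)) < tol + 1e-12))
  # an all-harm modifier shifts the treated survival curve down
  harm <- additive_hazard_scm("constant", ell = 0,
                              frailty = gamma_frailty(1, 0.5),
                              modifier = bhn_modifier(0, 0, 0.8, 0.6))
  s1 <- marginal_survival(harm, grid, a = 1, n = 10000, seed = 18)
  s0 <- marginal_survival(harm, grid, a = 0, n = 10000, seed = 18)
  expect_true(all(s1$survival <= s0$survival + tol))
})
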