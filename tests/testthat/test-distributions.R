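test_that("Laplace transforms match direct finite-support sums and text-book forms", {
  b <- bhn_modifier(0.3, -0.2, 0.5, 0.7)
  cs <- c(0, 0.1, 1, 2.5, 5)
  # independent oracle: expectation over the three support points
  oracle <- vapply(cs, function(c)
    sum(c(0.3, 0.5, 0.2) * exp(-c * c(-0.2, 0.7, 0))), numeric(1))
  expect_equal(laplace(b, cs), oracle, tolerance = 1e-14)
  # unit-exponential modifier: L(c) = 1/(1+c)
  sg <- shifted_gamma_modifier(1, 1, 0)
  expect_equal(laplace(sg, cs), 1 / (1 + cs), tolerance = 1e-14)
  expect_equal(laplace_deriv(sg, cs), -1 / (1 + cs)^2, tolerance = 1e-14)
  # normalization at c = 0 for every supported law
  for (law in list(b, sg, shifted_gamma_modifier(2, 0.5, 1),
                   degenerate_modifier(-0.3), gamma_frailty(1, 1),
                   degenerate_frailty(2)))
    expect_identical(laplace(law, 0), 1)
})

test_that("Laplace derivative agrees with a numerical derivative on c in [0, 5]", {
  h <- 1e-6
  grid <- seq(h, 5, length.out = 21)
  for (law in list(bhn_modifier(0.5, -0.1, 0.5, 0.4),
                   shifted_gamma_modifier(2, 0.5, 0.3),
                   degenerate_modifier(0.7))) {
    num <- (laplace(law, grid + h) - laplace(law, grid - h)) / (2 * h)
    expect_equal(laplace_deriv(law, grid), num, tolerance = 1e-6)
    # moment identity at c = 0
    expect_equal(laplace_deriv(law, 0), -law_mean(law), tolerance = 1e-12)
  }
})

test_that("divergent Laplace transforms raise domain errors", {
  expect_error(laplace(gamma_frailty(1, 1), -1), "diverges")
  expect_error(laplace(shifted_gamma_modifier(1, 2), -0.5), "diverges")
  expect_silent(laplace(bhn_modifier(0.5, -0.1, 0.5, 0.4), -3))
})

test_that("Kendall tau maps to the Gaussian correlation sin(pi tau / 2)", {
  expect_equal(kendall_to_gaussian_rho(0.5), sin(0.25 * pi))
  expect_equal(kendall_to_gaussian_rho(0), 0)
  expect_equal(kendall_to_gaussian_rho(1), 1)
  expect_equal(kendall_to_gaussian_rho(-1), -1)
  expect_error(kendall_to_gaussian_rho(1.2), "tau")
})

test_that("BHN parameter validation enforces sign and probability constraints", {
  expect_error(bhn_modifier(0.6, -0.1, 0.6, 0.4), "p1")
  expect_error(bhn_modifier(0.5, 0.1, 0.5, 0.4), "mu1")
  expect_error(bhn_modifier(0.5, -0.1, 0.5, -0.4), "mu2")
})

test_that("joint sampling reproduces the marginals (KS at alpha = 0.01, n = 10,000)", {
  joint <- sample_joint(gamma_frailty(1, 1), shifted_gamma_modifier(1, 1, 0.5),
                        copula_spec(0.5), n = 10000, seed = 42)
  expect_gt(ks.test(joint$u0, pgamma, shape = 1, scale = 1)$p.value, 0.01)
  expect_gt(ks.test(joint$u1 + 0.5, pgamma, shape = 1, scale = 1)$p.value, 0.01)
  # BHN marginal: class frequencies within 4 binomial SEs
  jb <- sample_joint(gamma_frailty(), bhn_modifier(0.3, -0.2, 0.5, 0.7),
                     copula_spec(-0.5), n = 10000, seed = 7)
  p_hat <- mean(jb$u1 == -0.2)
  expect_lt(abs(p_hat - 0.3), 4 * sqrt(0.3 * 0.7 / 10000))
})

test_that("empirical Kendall tau converges to the copula parameter", {
  joint <- sample_joint(gamma_frailty(1, 1), shifted_gamma_modifier(1, 1, 0),
                        copula_spec(0.5), n = 10000, seed = 11)
  tau_hat <- cor(joint$u0, joint$u1, method = "kendall")
  expect_lt(abs(tau_hat - 0.5), 0.03)
})

test_that("tau = +/-1 are exact monotone quantile couplings and tau = 0 is independent", {
  co <- sample_joint(gamma_frailty(1, 1), shifted_gamma_modifier(1, 1, 0),
                     copula_spec(1), n = 500, seed = 5)
  expect_equal(cor(co$u0, co$u1, method = "spearman"), 1)
  # u1 is exactly the modifier quantile of the u0 rank
  expect_equal(co$u1,
               law_quantile(shifted_gamma_modifier(1, 1, 0),
                            pgamma(co$u0, 1, scale = 1)),
               tolerance = 1e-10)
  anti <- sample_joint(gamma_frailty(1, 1), shifted_gamma_modifier(1, 1, 0),
                       copula_spec(-1), n = 500, seed = 5)
  expect_equal(cor(anti$u0, anti$u1, method = "spearman"), -1)
  ind <- sample_joint(gamma_frailty(1, 1), shifted_gamma_modifier(1, 1, 0),
                      copula_spec(0), n = 10000, seed = 5)
  expect_lt(abs(cor(ind$u0, ind$u1)), 3 / sqrt(10000))
})

test_that("joint sampling is deterministic given the seed", {
  a <- sample_joint(gamma_frailty(), shifted_gamma_modifier(), copula_spec(0.5),
                    n = 100, seed = 9)
  b <- sample_joint(gamma_frailty(), shifted_gamma_modifier(), copula_spec(0.5),
                    n = 100, seed = 9)
  expect_identical(a, b)
})

test_that("closed-form Laplace transforms agree with a Monte-Carlo fallback", {
  set.seed(31)
  b <- bhn_modifier(0.5, -0.25, 0.25, 0.5)
  expect_equal(smchd:::laplace_mc(b, c(0.5, 2), n = 2e5), laplace(b, c(0.5, 2)),
               tolerance = 0.01)
})

test_that("law configs build the laws they describe", {
  m <- modifier_from_config(list(type = "bhn", p1 = 0.5, mu1 = -0.1,
                                 p2 = 0.5, mu2 = 0.4))
  expect_s3_class(m, "bhn_modifier")
  expect_equal(law_mean(m), 0.15)
  f <- frailty_from_config(list(type = "gamma", shape = 2, scale = 0.5))
  expect_equal(law_mean(f), 1)
  expect_error(modifier_from_config(list(type = "bhn", p1 = 0.5, mu1 = -0.1,
                                         p2 = 0.5, mu2 = 0.4, bogus = 1)),
               "unknown")
  expect_error(frailty_from_config(list(type = "lognormal")), "unknown")
})
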