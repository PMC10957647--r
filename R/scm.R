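#' Additive-hazard structural causal model
#'
#' Builds the structural model under which each individual's potential-
#' outcome hazard is `lambda_i^a(t) = f0(t, U0i) + U1i * a`: a baseline
#' hazard driven by the frailty `U0` plus an additive, time-invariant
#' treatment effect scaled by the individual modifier `U1`.  Supported
#' baseline families:
#'
#' * `"constant"`: `f0(t, u0) = ell + u0`
#' * `"quadratic"`: `f0(t, u0) = ell + u0 * t^2`
#' * `"scaled_quadratic"`: `f0(t, u0) = ell + u0 * t^2 / 20`
#'
#' Construction enforces positivity of the hazard over the whole latent
#' support: the infimum of `f0` over `t` and the `u0` support must be at
#' least the magnitude of the most negative supported `u1`.
#'
#' @param baseline Baseline family name.
#' @param ell Nonnegative hazard offset of the baseline family.
#' @param frailty Frailty law (see [gamma_frailty()]).
#' @param modifier Effect-modifier law (see [bhn_modifier()]).
#' @param copula [copula_spec()] coupling `(U0, U1)`; defaults to
#'   independence.
#' @param exposure_prob Randomization probability `P(A = 1)`, in `(0, 1)`.
#' @return An object of class `"additive_hazard_scm"`.
#' @examples
#' scm <- additive_hazard_scm("constant", ell = 0.1,
#'                            frailty = gamma_frailty(1, 0.25),
#'                            modifier = bhn_modifier(0.5, -0.1, 0.5, 0.4))
#' chd(scm, 1)
#' @export
additive_hazard_scm <- function(baseline = c("quadratic", "constant",
                                             "scaled_quadratic"),
                                ell = 0,
                                frailty = gamma_frailty(1, 1),
                                modifier,
                                copula = copula_spec(0),
                                exposure_prob = 0.5) {
  baseline <- match.arg(baseline)
  stopifnot(is.numeric(ell), ell >= 0,
            inherits(frailty, "frailty_law"),
            inherits(modifier, "modifier_law"),
            inherits(copula, "copula_spec"),
            exposure_prob > 0, exposure_prob < 1)
  # positivity: inf_t f0 is ell (+ u0-support min for the constant family,
  # since the quadratic terms vanish at t = 0)
  f0_inf <- ell + if (baseline == "constant") law_support_min(frailty) else 0
  u1_min <- law_support_min(modifier)
  if (f0_inf + u1_min < -1e-12)
    stop("hazard positivity violated: baseline infimum ", f0_inf,
         " cannot absorb the most negative modifier value ", u1_min)
  structure(list(baseline = baseline, ell = ell, frailty = frailty,
                 modifier = modifier, copula = copula,
                 exposure_prob = exposure_prob),
            class = "additive_hazard_scm")
}

#' @export
print.additive_hazard_scm <- function(x, ...) {
  cat("Additive-hazard structural causal model\n")
  cat("  baseline:", x$baseline, "with offset ell =", x$ell, "\n")
  cat("  frailty:", class(x$frailty)[1], "\n")
  cat("  modifier:", class(x$modifier)[1],
      sprintf("(mean %.4g)", law_mean(x$modifier)), "\n")
  cat("  Kendall tau:", x$copula$kendall_tau,
      " exposure prob:", x$exposure_prob, "\n")
  invisible(x)
}

# instantaneous baseline hazard f0(t, u0); vectorized over t and u0
baseline_hazard <- function(scm, t, u0) {
  switch(scm$baseline,
         constant = scm$ell + u0 + 0 * t,
         quadratic = scm$ell + u0 * t^2,
         scaled_quadratic = scm$ell + u0 * t^2 / 20)
}

# cubic coefficient of the integrated baseline: Lambda0 = ell*t + c3(u0)*t^3
cubic_coef <- function(scm, u0) {
  switch(scm$baseline,
         constant = 0 * u0,
         quadratic = u0 / 3,
         scaled_quadratic = u0 / 60)
}

#' Integrated potential-outcome hazard
#'
#' Closed-form cumulative hazard
#' `Lambda^a(t) = int_0^t f0(s, u0) + u1 * a ds` for the configured
#' baseline family.  Errors if the instantaneous hazard is negative
#' anywhere on `[0, t]` (for all supported families the minimum over time
#' is at `t = 0`).
#'
#' @param scm An [additive_hazard_scm()].
#' @param t Nonnegative time(s).
#' @param u0,u1 Latent frailty and modifier values (vectorized).
#' @param a Arm, 0 or 1.
#' @return The cumulative hazard, nondecreasing in `t`.
#' @export
cumulative_hazard <- function(scm, t, u0, u1, a) {
  stopifnot(inherits(scm, "additive_hazard_scm"), all(t >= 0),
            all(a %in% c(0, 1)))
  lin <- scm$ell + u1 * a +
    if (scm$baseline == "constant") u0 else 0
  if (any(lin < -1e-12))
    stop("negative instantaneous hazard at t = 0 for some (u0, u1)")
  lin * t + cubic_coef(scm, u0) * t^3
}

# Invert lin * t + c3 * t^3 = e for t >= 0 (lin, c3 >= 0, not both 0),
# vectorized.  Lambda is convex increasing, so Newton started from an upper
# bracket converges monotonically; residual checked to 1e-10.
invert_cumhaz <- function(lin, c3, e) {
  lin <- pmax(lin, 0)
  if (any(lin <= 0 & c3 <= 0))
    stop("cumulative hazard is identically zero for some individual")
  hi <- pmin(ifelse(lin > 0, e / lin, Inf),
             ifelse(c3 > 0, (e / c3)^(1 / 3), Inf))
  t <- hi
  for (i in 1:200) {
    f <- lin * t + c3 * t^3 - e
    if (max(abs(f)) < 1e-13 * max(1, max(e))) break
    t <- t - f / (lin + 3 * c3 * t^2)
  }
  resid <- abs(lin * t + c3 * t^3 - e)
  if (any(resid > 1e-10 * pmax(1, e)))
    stop("event-time inversion failed to converge")
  t
}

#' Sample both potential event times per individual
#'
#' Draws `(u0, u1)` through [sample_joint()], then a single unit-exponential
#' structural noise per individual, shared between the two arms, and solves
#' `Lambda^a(t_a) = e` for each arm by inverting the closed-form cumulative
#' hazard.  Sharing the noise makes `(T0, T1)` comonotone given the latents,
#' so with `u1 >= 0` every individual's treated event time is no later than
#' the untreated one.
#'
#' @param scm An [additive_hazard_scm()].
#' @param n Number of individuals.
#' @param seed Optional integer seed.
#' @return A data frame with columns `u0`, `u1`, `t0`, `t1`.
#' @export
sample_potential_times <- function(scm, n, seed = NULL) {
  stopifnot(inherits(scm, "additive_hazard_scm"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  lat <- sample_joint(scm$frailty, scm$modifier, scm$copula, n)
  e <- stats::rexp(n)
  c3 <- cubic_coef(scm, lat$u0)
  lin0 <- scm$ell + if (scm$baseline == "constant") lat$u0 else 0
  t0 <- invert_cumhaz(lin0, c3, e)
  t1 <- invert_cumhaz(lin0 + lat$u1, c3, e)
  data.frame(u0 = lat$u0, u1 = lat$u1, t0 = t0, t1 = t1)
}

#' Generate a randomized-trial dataset from the structural model
#'
#' Exposure is Bernoulli(`exposure_prob`), independent of all latents; by
#' causal consistency the observed time is the potential event time of the
#' assigned arm, optionally censored by an independent censoring law.
#'
#' @param scm An [additive_hazard_scm()].
#' @param n Number of subjects.
#' @param censoring `NULL` for none, or a list such as
#'   `list(type = "uniform", max = 5)` or
#'   `list(type = "exponential", rate = 0.2)`.
#' @param seed Optional integer seed.
#' @return A data frame with columns `id`, `time`, `status`, `exposure`;
#'   the latent draws are attached as `attr(, "latents")`.
#' @export
generate_rct <- function(scm, n, censoring = NULL, seed = NULL) {
  stopifnot(inherits(scm, "additive_hazard_scm"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  po <- sample_potential_times(scm, n)
  a <- stats::rbinom(n, 1L, scm$exposure_prob)
  t_obs <- ifelse(a == 1L, po$t1, po$t0)
  if (is.null(censoring)) {
    time <- t_obs
    status <- rep(1L, n)
  } else {
    cens <- switch(censoring$type,
                   uniform = stats::runif(n, 0, censoring$max),
                   exponential = stats::rexp(n, censoring$rate),
                   stop("unknown censoring type: ", censoring$type))
    time <- pmin(t_obs, cens)
    status <- as.integer(t_obs <= cens)
  }
  out <- data.frame(id = seq_len(n), time = time, status = status,
                    exposure = a)
  attr(out, "latents") <- po
  out
}

#' Monte-Carlo marginal survival of a potential outcome
#'
#' Estimates `P(T^a >= t)` on a time grid from simulated potential event
#' times.
#'
#' @param scm An [additive_hazard_scm()].
#' @param grid Nonnegative, increasing time grid.
#' @param a Arm, 0 or 1.
#' @param n Monte-Carlo sample size.
#' @param seed Optional integer seed.
#' @return A data frame with columns `time` and `survival` (nonincreasing,
#'   `survival = 1` at `t = 0`).
#' @export
marginal_survival <- function(scm, grid, a, n = 10000, seed = NULL) {
  stopifnot(all(diff(grid) > 0), all(grid >= 0), a %in% c(0, 1))
  po <- sample_potential_times(scm, n, seed = seed)
  ta <- if (a == 1) po$t1 else po$t0
  data.frame(time = grid,
             survival = vapply(grid, function(t) mean(ta >= t), numeric(1)))
}
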