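#' Causal hazard difference (CHD)
#'
#' The population-marginal difference of the potential-outcome hazards,
#' `E[lambda^1(t)] - E[lambda^0(t)] = E[U1]`.  For the time-invariant
#' multiplicative effect family implemented here the CHD is constant in `t`.
#'
#' @param scm An [additive_hazard_scm()].
#' @param t Time(s); the value does not depend on `t` but is returned
#'   elementwise for convenience.
#' @return `E[U1]`, recycled to the length of `t`.
#' @examples
#' scm <- additive_hazard_scm("constant", ell = 0.1,
#'                            modifier = bhn_modifier(0.5, -0.1, 0.5, 0.4))
#' chd(scm, c(0, 1, 5))  # 0.15 everywhere
#' @export
chd <- function(scm, t) {
  stopifnot(inherits(scm, "additive_hazard_scm"))
  rep(law_mean(scm$modifier), length(t))
}

#' Survivor-conditional modifier mean for the BHN law
#'
#' Closed form for `E[U1 | T1 >= t]` when `U1` follows a
#' Benefit-Harm-Neutral law, the effect is `U1 * a`, and `(U0, U1)` are
#' independent: survivors of the treated universe are exponentially tilted
#' towards beneficial modifier values,
#' \deqn{\frac{\mu_1 p_1 e^{-t\mu_1} + \mu_2 p_2 e^{-t\mu_2}}{
#'       p_1 e^{-t\mu_1} + p_2 e^{-t\mu_2} + (1 - p_1 - p_2)}.}
#' The dominant exponent is factored out before exponentiating so large
#' `t * |mu|` cannot overflow.
#'
#' @param bhn A [bhn_modifier()].
#' @param t Nonnegative time(s).
#' @return The tilted mean, always within `[mu1, mu2]`.
#' @export
bhn_survivor_mean <- function(bhn, t) {
  stopifnot(inherits(bhn, "bhn_modifier"), all(t >= 0))
  m <- pmax(-t * bhn$mu1, pmax(-t * bhn$mu2, 0))
  w1 <- bhn$p1 * exp(-t * bhn$mu1 - m)
  w2 <- bhn$p2 * exp(-t * bhn$mu2 - m)
  w0 <- (1 - bhn$p1 - bhn$p2) * exp(-m)
  (bhn$mu1 * w1 + bhn$mu2 * w2) / (w1 + w2 + w0)
}

#' Survivor-conditional modifier mean via the Laplace transform
#'
#' For the multiplicative effect family `U1 * g(t) * a` with `(U0, U1)`
#' independent, the mean modifier among treated survivors is
#' `-L'(F1t) / L(F1t)` with `L` the Laplace transform of `U1` and
#' `F1t = int_0^t g(s) ds` the integrated effect profile (equal to `t`
#' for the package's time-invariant profile `g == 1`).
#'
#' @param modifier A modifier law object.
#' @param F1t Integrated effect profile, nonnegative; vectorized.
#' @return `E[U1 | T1 >= t]`; equals `E[U1]` at `F1t = 0`.
#' @export
laplace_survivor_mean <- function(modifier, F1t) {
  stopifnot(inherits(modifier, "modifier_law"), all(F1t >= 0))
  -laplace_deriv(modifier, F1t) / laplace(modifier, F1t)
}

#' Integrated survivor-marginalized curve for the BHN law
#'
#' Closed form of `B(t) = int_0^t E[U1 | T1 >= s] ds` under independence:
#' `-log(p1 (e^{-t mu1} - 1) + p2 (e^{-t mu2} - 1) + 1)`, evaluated with
#' `expm1` for accuracy near 0.  This is the integrated observed hazard
#' difference an additive-hazards fit estimates in a randomized trial, and
#' it is non-linear even though every individual effect is constant.
#'
#' @param bhn A [bhn_modifier()].
#' @param t Nonnegative time(s).
#' @return `B(t)`, with `B(0) = 0`.
#' @export
bhn_integrated_curve <- function(bhn, t) {
  stopifnot(inherits(bhn, "bhn_modifier"), all(t >= 0))
  arg <- 1 + bhn$p1 * expm1(-t * bhn$mu1) + bhn$p2 * expm1(-t * bhn$mu2)
  if (any(arg <= 0)) stop("log argument non-positive; invalid BHN parameters")
  -log(arg)
}

#' Integrated survivor-marginalized curve for any modifier law
#'
#' Under independence with the time-invariant effect profile,
#' `B(t) = -log L_{U1}(t)`: the integral of the tilted mean is minus the
#' log-Laplace transform.  Specializes to [bhn_integrated_curve()] for the
#' BHN law and to `shape * log(1 + t * scale) - shift * t` for the shifted
#' gamma.
#'
#' @param modifier A modifier law object.
#' @param t Nonnegative time(s).
#' @return `B(t)`.
#' @export
integrated_smchd_analytic <- function(modifier, t) {
  stopifnot(inherits(modifier, "modifier_law"), all(t >= 0))
  -log(laplace(modifier, t))
}

#' Survivor-marginalized causal hazard difference (SMCHD)
#'
#' The hazard difference marginalized over survivors of each counterfactual
#' universe,
#' `E[U1 | T1 >= t] + E[f0(t, U0) | T1 >= t] - E[f0(t, U0) | T0 >= t]`.
#' In a randomized trial the observed hazard difference equals the SMCHD.
#' The analytic mode requires independent `(U0, U1)` (Kendall tau 0), in
#' which case the baseline terms cancel and the SMCHD reduces to the
#' Laplace-transform tilted mean; the Monte-Carlo mode evaluates all three
#' survivor expectations by simulation and works for any copula.
#'
#' @param scm An [additive_hazard_scm()].
#' @param t Nonnegative time(s).
#' @param mode `"analytic"` (default, tau = 0 only) or `"montecarlo"`.
#' @param n,seed Monte-Carlo sample size and seed (montecarlo mode).
#' @return The SMCHD at each `t`.
#' @examples
#' scm <- additive_hazard_scm("constant", ell = 0.1,
#'                            modifier = bhn_modifier(0.5, -0.1, 0.5, 0.4))
#' smchd(scm, c(0, 1, 100))  # 0.15 at t = 0, tending to -0.1
#' @export
smchd <- function(scm, t, mode = c("analytic", "montecarlo"),
                  n = 10000, seed = NULL) {
  stopifnot(inherits(scm, "additive_hazard_scm"), all(t >= 0))
  mode <- match.arg(mode)
  if (mode == "analytic") {
    if (scm$copula$kendall_tau != 0)
      stop("analytic SMCHD requires independent (U0, U1); use mode = \"montecarlo\"")
    laplace_survivor_mean(scm$modifier, t)
  } else {
    po <- sample_potential_times(scm, n, seed = seed)
    vapply(t, function(ti) {
      survivor_expectation(scm, po, ti, "effect") +
        survivor_expectation(scm, po, ti, "baseline_exposed") -
        survivor_expectation(scm, po, ti, "baseline_unexposed")
    }, numeric(1))
  }
}

#' Selection bias of the observed hazard difference
#'
#' `chd(t) - smchd(t)`: how much the survivor-marginalized (= observed, in a
#' randomized trial) hazard difference understates the causal one.  Zero at
#' `t = 0` and nonnegative for all `t` when `(U0, U1)` are independent.
#'
#' @inheritParams smchd
#' @return `chd(scm, t) - smchd(scm, t, ...)`.
#' @export
hazard_bias <- function(scm, t, mode = c("analytic", "montecarlo"),
                        n = 10000, seed = NULL) {
  chd(scm, t) - smchd(scm, t, mode = mode, n = n, seed = seed)
}

#' Exact large-time limit of the survivor-conditional modifier mean
#'
#' As `t` grows, exponential tilting concentrates the survivor law of `U1`
#' on the minimum support point with positive mass: `mu1` when `p1 > 0`,
#' else 0 when the neutral class has mass, else `mu2`; `-shift` for the
#' shifted gamma; the point itself for a degenerate modifier.
#'
#' @param modifier A modifier law object.
#' @return The limit of `E[U1 | T1 >= t]` as `t -> Inf`.
#' @export
smchd_limit <- function(modifier) UseMethod("smchd_limit")

#' @export
smchd_limit.bhn_modifier <- function(modifier) {
  if (modifier$p1 > 0) modifier$mu1
  else if (modifier$p1 + modifier$p2 < 1) 0
  else modifier$mu2
}

#' @export
smchd_limit.shifted_gamma_modifier <- function(modifier) -modifier$shift

#' @export
smchd_limit.degenerate_modifier <- function(modifier) modifier$value

#' Estimand curves on a time grid
#'
#' Tabulates the CHD, analytic SMCHD, their difference, and the integrated
#' SMCHD on a grid.  Requires independent `(U0, U1)`; use
#' [smchd_curve_mc()] for dependent latents.
#'
#' @param scm An [additive_hazard_scm()] with Kendall tau 0.
#' @param grid Strictly increasing, nonnegative time grid.
#' @return A data frame with columns `time`, `chd`, `smchd`, `bias`,
#'   `integrated_smchd`.
#' @export
estimand_curve <- function(scm, grid) {
  stopifnot(all(grid >= 0), all(diff(grid) > 0))
  s <- smchd(scm, grid)
  data.frame(time = grid,
             chd = chd(scm, grid),
             smchd = s,
             bias = chd(scm, grid) - s,
             integrated_smchd = integrated_smchd_analytic(scm$modifier, grid))
}
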