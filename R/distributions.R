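#' Latent-variable laws for frailty and effect modification
#'
#' The additive-hazard structural model used throughout this package carries
#' two latent variables per individual: a nonnegative frailty `U0` entering
#' the baseline hazard, and an effect modifier `U1` that shifts the
#' treatment's additive effect on the hazard.  The constructors below build
#' validated law objects; generic accessors ([laplace()], [law_mean()],
#' [law_quantile()], ...) provide the closed-form quantities the estimand
#' layer needs.
#'
#' @name modifier-laws
NULL

#' Benefit-Harm-Neutral (BHN) effect-modifier law
#'
#' Three-point law for the additive effect modifier: `U1 = mu1` (benefit,
#' `mu1 <= 0`) with probability `p1`, `U1 = mu2` (harm, `mu2 >= 0`) with
#' probability `p2`, and `U1 = 0` (no effect) otherwise.
#'
#' @param p1 Probability of the benefit class, in `[0, 1]`.
#' @param mu1 Hazard-difference for the benefit class (`mu1 <= 0`).
#' @param p2 Probability of the harm class, with `p1 + p2 <= 1`.
#' @param mu2 Hazard-difference for the harm class (`mu2 >= 0`).
#' @return An object of class `c("bhn_modifier", "modifier_law")`.
#' @examples
#' bhn <- bhn_modifier(0.5, -0.1, 0.5, 0.4)
#' law_mean(bhn)  # the causal hazard difference, 0.15
#' @export
bhn_modifier <- function(p1, mu1, p2, mu2) {
  stopifnot(is.numeric(p1), is.numeric(mu1), is.numeric(p2), is.numeric(mu2))
  if (p1 < 0 || p2 < 0 || p1 + p2 > 1 + 1e-12)
    stop("BHN probabilities must satisfy p1 >= 0, p2 >= 0, p1 + p2 <= 1")
  if (mu1 > 0) stop("BHN benefit effect mu1 must be <= 0")
  if (mu2 < 0) stop("BHN harm effect mu2 must be >= 0")
  structure(list(p1 = p1, mu1 = mu1, p2 = p2, mu2 = mu2),
            class = c("bhn_modifier", "modifier_law"))
}

#' Shifted-gamma effect-modifier law
#'
#' Continuous modifier `U1 = G - shift` with `G ~ Gamma(shape, scale)`
#' (mean `shape * scale`).  With `shape = scale = 1` and `shift = ell` this
#' is the unit-exponential modifier used alongside the quadratic baseline:
#' `U1 + ell ~ Gamma(1, 1)`.
#'
#' @param shape,scale Gamma parameters, both positive; the mean is
#'   `shape * scale` (so `Gamma(1, 1)` is the unit exponential).
#' @param shift Amount subtracted from the gamma variate; the support of
#'   `U1` is `(-shift, Inf)`.
#' @return An object of class `c("shifted_gamma_modifier", "modifier_law")`.
#' @export
shifted_gamma_modifier <- function(shape = 1, scale = 1, shift = 0) {
  stopifnot(shape > 0, scale > 0, is.numeric(shift))
  structure(list(shape = shape, scale = scale, shift = shift),
            class = c("shifted_gamma_modifier", "modifier_law"))
}

#' Degenerate (homogeneous) effect-modifier law
#'
#' Point mass at `value`: every individual has the same additive effect, the
#' homogeneous special case in which the observed hazard difference equals
#' the causal hazard difference.
#'
#' @param value The common effect (hazard units).
#' @return An object of class `c("degenerate_modifier", "modifier_law")`.
#' @export
degenerate_modifier <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  structure(list(value = value),
            class = c("degenerate_modifier", "modifier_law"))
}

#' Gamma frailty law
#'
#' Nonnegative frailty `U0 ~ Gamma(shape, scale)` with mean `shape * scale`;
#' `Gamma(1, 1)` is the unit exponential.
#'
#' @param shape,scale Positive gamma parameters.
#' @return An object of class `c("gamma_frailty", "frailty_law")`.
#' @export
gamma_frailty <- function(shape = 1, scale = 1) {
  stopifnot(shape > 0, scale > 0)
  structure(list(shape = shape, scale = scale),
            class = c("gamma_frailty", "frailty_law"))
}

#' Degenerate frailty law
#'
#' Point mass at `value >= 0`; useful for homogeneous-baseline checks.
#'
#' @param value Common frailty value, nonnegative.
#' @return An object of class `c("degenerate_frailty", "frailty_law")`.
#' @export
degenerate_frailty <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, value >= 0)
  structure(list(value = value),
            class = c("degenerate_frailty", "frailty_law"))
}

#' Gaussian copula specification by Kendall's tau
#'
#' The joint law of `(U0, U1)` is coupled through a Gaussian copula
#' `C(x, y) = Phi2_rho(Phi^-1(x), Phi^-1(y))` whose correlation is
#' `rho = sin(pi * tau / 2)`.  The boundaries `tau = 1` and `tau = -1`
#' are handled as deterministic comonotone / antitone quantile couplings
#' (the bivariate normal is degenerate there).
#'
#' @param kendall_tau Kendall rank correlation in `[-1, 1]`.
#' @return An object of class `"copula_spec"` with fields `kendall_tau`
#'   and `rho`.
#' @export
copula_spec <- function(kendall_tau = 0) {
  structure(list(kendall_tau = kendall_tau,
                 rho = kendall_to_gaussian_rho(kendall_tau)),
            class = "copula_spec")
}

#' Convert Kendall's tau to the Gaussian-copula correlation
#'
#' @param tau Kendall rank correlation in `[-1, 1]`.
#' @return `sin(pi * tau / 2)`.
#' @examples
#' kendall_to_gaussian_rho(0.5)  # sin(pi/4) ~ 0.7071
#' @export
kendall_to_gaussian_rho <- function(tau) {
  stopifnot(is.numeric(tau))
  if (any(abs(tau) > 1)) stop("Kendall's tau must lie in [-1, 1]")
  sin(pi * tau / 2)
}

# ---- Laplace transforms ----------------------------------------------------

#' Laplace transform of a latent law
#'
#' Returns `E[exp(-c * U)]` for the law object.  Closed form per supported
#' law; `laplace(law, 0)` is exactly 1.  Negative arguments are allowed only
#' where the expectation is finite (for the shifted gamma this requires
#' `c * scale > -1`).
#'
#' @param law A modifier or frailty law object.
#' @param c Transform argument(s); vectorized.
#' @return `E[exp(-c * U)]`, same length as `c`.
#' @seealso [laplace_deriv()], [laplace_survivor_mean()]
#' @export
laplace <- function(law, c) UseMethod("laplace")

#' @export
laplace.bhn_modifier <- function(law, c) {
  law$p1 * exp(-c * law$mu1) + law$p2 * exp(-c * law$mu2) +
    (1 - law$p1 - law$p2)
}

#' @export
laplace.shifted_gamma_modifier <- function(law, c) {
  if (any(c * law$scale <= -1))
    stop("Laplace transform diverges: need c * scale > -1 for a gamma law")
  exp(c * law$shift) * (1 + c * law$scale)^(-law$shape)
}

#' @export
laplace.degenerate_modifier <- function(law, c) exp(-c * law$value)

#' @export
laplace.gamma_frailty <- function(law, c) {
  if (any(c * law$scale <= -1))
    stop("Laplace transform diverges: need c * scale > -1 for a gamma law")
  (1 + c * law$scale)^(-law$shape)
}

#' @export
laplace.degenerate_frailty <- function(law, c) exp(-c * law$value)

#' Derivative of the Laplace transform
#'
#' Returns `d/dc E[exp(-c * U)] = -E[U exp(-c * U)]`; at `c = 0` this is
#' minus the mean.
#'
#' @inheritParams laplace
#' @return The derivative, same length as `c`.
#' @export
laplace_deriv <- function(law, c) UseMethod("laplace_deriv")

#' @export
laplace_deriv.bhn_modifier <- function(law, c) {
  -(law$p1 * law$mu1 * exp(-c * law$mu1) +
      law$p2 * law$mu2 * exp(-c * law$mu2))
}

#' @export
laplace_deriv.shifted_gamma_modifier <- function(law, c) {
  # d/dc log L = shift - shape*scale/(1 + c*scale)
  laplace(law, c) * (law$shift - law$shape * law$scale / (1 + c * law$scale))
}

#' @export
laplace_deriv.degenerate_modifier <- function(law, c) {
  -law$value * exp(-c * law$value)
}

# ---- moments, quantiles, support -------------------------------------------

#' Mean of a latent law
#' @param law A modifier or frailty law object.
#' @return `E[U]`.
#' @export
law_mean <- function(law) UseMethod("law_mean")

#' @export
law_mean.bhn_modifier <- function(law) law$p1 * law$mu1 + law$p2 * law$mu2

#' @export
law_mean.shifted_gamma_modifier <- function(law) {
  law$shape * law$scale - law$shift
}

#' @export
law_mean.degenerate_modifier <- function(law) law$value

#' @export
law_mean.gamma_frailty <- function(law) law$shape * law$scale

#' @export
law_mean.degenerate_frailty <- function(law) law$value

#' Quantile function of a latent law
#' @param law A modifier or frailty law object.
#' @param p Probabilities in `[0, 1]`; vectorized.
#' @return Quantiles `Q(p)` (left-continuous generalized inverse for
#'   discrete laws).
#' @export
law_quantile <- function(law, p) UseMethod("law_quantile")

#' @export
law_quantile.bhn_modifier <- function(law, p) {
  # support ordered mu1 <= 0 <= mu2 with masses p1, 1 - p1 - p2, p2
  out <- rep(law$mu2, length(p))
  out[p <= law$p1 + (1 - law$p1 - law$p2)] <- 0
  out[p <= law$p1] <- law$mu1
  out
}

#' @export
law_quantile.shifted_gamma_modifier <- function(law, p) {
  stats::qgamma(p, shape = law$shape, scale = law$scale) - law$shift
}

#' @export
law_quantile.degenerate_modifier <- function(law, p) rep(law$value, length(p))

#' @export
law_quantile.gamma_frailty <- function(law, p) {
  stats::qgamma(p, shape = law$shape, scale = law$scale)
}

#' @export
law_quantile.degenerate_frailty <- function(law, p) rep(law$value, length(p))

#' Infimum of the support of a latent law
#'
#' Used by the structural model's positivity check: the hazard
#' `f0(t, u0) + u1 * a` must be nonnegative for every supported `(u0, u1)`.
#'
#' @param law A modifier or frailty law object.
#' @return The essential infimum of the law's support.
#' @export
law_support_min <- function(law) UseMethod("law_support_min")

#' @export
law_support_min.bhn_modifier <- function(law) {
  if (law$p1 > 0) law$mu1 else 0
}

#' @export
law_support_min.shifted_gamma_modifier <- function(law) -law$shift

#' @export
law_support_min.degenerate_modifier <- function(law) law$value

#' @export
law_support_min.gamma_frailty <- function(law) 0

#' @export
law_support_min.degenerate_frailty <- function(law) law$value

# Monte-Carlo fallback for Laplace transforms of laws without a closed form;
# exercised only in tests as an independent cross-check.
laplace_mc <- function(law, c, n = 1e5) {
  u <- law_quantile(law, stats::runif(n))
  vapply(c, function(ci) mean(exp(-ci * u)), numeric(1))
}

# ---- joint sampling through the copula -------------------------------------

#' Sample the joint law of frailty and effect modifier
#'
#' Draws `n` pairs `(u0, u1)` whose marginals follow the given laws and
#' whose dependence is the Gaussian copula implied by the copula spec's
#' Kendall tau.  `tau = 0` draws the marginals independently; `tau = 1`
#' (`-1`) uses the exact comonotone (antitone) quantile coupling, since the
#' bivariate normal is degenerate at `rho = +/-1`.
#'
#' @param frailty A frailty law object.
#' @param modifier A modifier law object.
#' @param copula A [copula_spec()].
#' @param n Number of pairs to draw.
#' @param seed Optional integer; when supplied, `set.seed(seed)` is called
#'   first so the draw is reproducible.
#' @return A data frame with columns `u0` and `u1`.
#' @examples
#' joint <- sample_joint(gamma_frailty(), shifted_gamma_modifier(),
#'                       copula_spec(0.5), n = 500, seed = 1)
#' cor(joint$u0, joint$u1, method = "kendall")
#' @export
sample_joint <- function(frailty, modifier, copula = copula_spec(0), n,
                         seed = NULL) {
  stopifnot(inherits(frailty, "frailty_law"), inherits(modifier, "modifier_law"),
            inherits(copula, "copula_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  tau <- copula$kendall_tau
  if (tau == 1 || tau == -1) {
    p <- stats::runif(n)
    u0 <- law_quantile(frailty, p)
    u1 <- law_quantile(modifier, if (tau == 1) p else 1 - p)
  } else if (tau == 0) {
    u0 <- law_quantile(frailty, stats::runif(n))
    u1 <- law_quantile(modifier, stats::runif(n))
  } else {
    rho <- copula$rho
    z0 <- stats::rnorm(n)
    z1 <- rho * z0 + sqrt(1 - rho^2) * stats::rnorm(n)
    u0 <- law_quantile(frailty, stats::pnorm(z0))
    u1 <- law_quantile(modifier, stats::pnorm(z1))
  }
  data.frame(u0 = u0, u1 = u1)
}

# ---- config serialization ---------------------------------------------------

#' Build a latent law from a configuration list
#'
#' Accepts the YAML-style spec used by the run configuration, e.g.
#' `list(type = "bhn", p1 = 0.5, mu1 = -0.1, p2 = 0.5, mu2 = 0.4)`.
#' Supported types: `bhn`, `shifted_gamma`, `degenerate` (modifiers);
#' `gamma`, `degenerate` (frailties).
#'
#' @param spec Named list with a `type` field.
#' @return A modifier law object.
#' @export
modifier_from_config <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$type))
  extra <- setdiff(names(spec),
                   c("type", "p1", "mu1", "p2", "mu2", "shape", "scale",
                     "shift", "value"))
  if (length(extra)) stop("unknown modifier config keys: ",
                          paste(extra, collapse = ", "))
  switch(spec$type,
    bhn = bhn_modifier(spec$p1, spec$mu1, spec$p2, spec$mu2),
    shifted_gamma = shifted_gamma_modifier(
      shape = spec$shape %||% 1, scale = spec$scale %||% 1,
      shift = spec$shift %||% 0),
    degenerate = degenerate_modifier(spec$value),
    stop("unknown modifier type: ", spec$type))
}

#' @rdname modifier_from_config
#' @return For `frailty_from_config`, a frailty law object.
#' @export
frailty_from_config <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$type))
  extra <- setdiff(names(spec), c("type", "shape", "scale", "value"))
  if (length(extra)) stop("unknown frailty config keys: ",
                          paste(extra, collapse = ", "))
  switch(spec$type,
    gamma = gamma_frailty(shape = spec$shape %||% 1, scale = spec$scale %||% 1),
    degenerate = degenerate_frailty(spec$value),
    stop("unknown frailty type: ", spec$type))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
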