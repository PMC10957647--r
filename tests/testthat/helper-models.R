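# Shared fixtures: the BHN law used in the case-study overlay, the
# quadratic-baseline model of the dependent-latents experiments, and a
# constant-baseline analog with enough late survivors for estimator checks.

case_study_bhn <- function() bhn_modifier(0.5, -0.1, 0.5, 0.4)

# quadratic baseline f0 = ell + U0 t^2, U0 ~ Gamma(1,1), U1 + ell ~ Gamma(1,1)
fig2_scm <- function(tau = 0, ell = 0.5, baseline = "quadratic") {
  additive_hazard_scm(baseline, ell = ell,
                      frailty = gamma_frailty(1, 1),
                      modifier = shifted_gamma_modifier(1, 1, shift = ell),
                      copula = copula_spec(tau))
}

# constant baseline f0 = 0.1 + U0, small frailty so ~25% of the exposed arm
# survives past t = 4; the synthetic analog of the trial re-analysis
case_study_scm <- function() {
  additive_hazard_scm("constant", ell = 0.1,
                      frailty = gamma_frailty(1, 0.25),
                      modifier = case_study_bhn())
}

toy_dataset <- function() {
  data.frame(id = 1:4, time = c(1, 3, 2, 4), status = c(1, 1, 1, 0),
             exposure = c(1, 1, 0, 0))
}

# Nelson-Aalen difference oracle via the survival package
na_difference <- function(data, at) {
  na_one <- function(d) {
    sf <- survival::survfit(survival::Surv(time, status) ~ 1, data = d,
                            ctype = 1)
    stats::stepfun(sf$time, c(0, sf$cumhaz), right = FALSE)
  }
  na_one(data[data$exposure == 1, ])(at) - na_one(data[data$exposure == 0, ])(at)
}
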