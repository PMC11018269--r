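# Shared fixtures. Expensive fixtures are memoized so that several test
# files can reuse one simulated cohort / one fitted model within a session.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

# ---- hand-built three-subject toy cohort -----------------------------------
# Subject 1: three complete visits, survived both risk intervals.
# Subject 2: two visits, brain missing at the second, died in interval 2.
# Subject 3: baseline only (memory missing there), drop-out: survival unknown.
toy_spec <- function(include_survival = FALSE) {
  growth_spec(outcomes = c("memory", "brain"),
              intercept_covariates = list(memory = c("age_c", "dart_z"),
                                          brain = "age_c"),
              slope_covariates = list(memory = "dart_z", brain = character()),
              practice_on = "memory", residual_cross = TRUE,
              include_survival = include_survival, n_intervals = 2L)
}

toy_params <- function(spec) {
  growth_params(
    spec,
    alpha = c(0.10, -0.09, -0.05, -0.14),
    beta = list(memory.intercept = c(age_c = -0.02, dart_z = 0.35),
                memory.slope = c(dart_z = 0.008),
                brain.intercept = c(age_c = -0.03)),
    psi = matrix(c(0.550, -0.010, 0.300, 0.004,
                   -0.010, 0.0030, 0.006, 0.0010,
                   0.300, 0.006, 0.850, -0.008,
                   0.004, 0.0010, -0.008, 0.0020), 4, 4),
    theta = c(memory = 0.30, brain = 0.10),
    theta_cross = 0.02,
    mu_practice = 0.18,
    tau = if (spec$include_survival) qlogis(c(0.09, 0.16)) else NULL,
    gamma_surv = if (spec$include_survival)
      c(memory.intercept = -0.30, memory.slope = -6) else NULL)
}

toy_data <- function() {
  data.frame(
    subject_id = c(1, 1, 1, 2, 2, 3),
    visit_order = c(0, 1, 2, 0, 1, 0),
    time_in_study = c(0, 3.8, 11.6, 0, 4.3, 0),
    memory = c(0.45, 0.20, -0.85, -0.60, -1.10, NA),
    brain_bpf = c(-0.30, -0.90, -1.70, 0.25, NA, 0.80),
    died_in_next_interval = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    age_c = c(1.2, 1.2, 1.2, -0.7, -0.7, 0.4),
    dart_z = c(0.5, 0.5, 0.5, -1.1, -1.1, 0.9))
}

# multivariate normal log-density written out directly (test oracle)
mvn_logdens <- function(y, mu, V) {
  ch <- chol(V)
  u <- backsolve(ch, y - mu, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(u^2)
}

# the longitudinal-only spec/params implied by a simulated cohort's truth
marginalize <- function(sim) {
  spec <- growth_spec(intercept_covariates = sim$spec$intercept_covariates,
                      slope_covariates = sim$spec$slope_covariates,
                      include_survival = FALSE)
  params <- growth_params(spec, alpha = sim$truth$alpha, beta = sim$truth$beta,
                          psi = sim$truth$psi, theta = sim$truth$theta,
                          theta_cross = sim$truth$theta_cross,
                          mu_practice = sim$truth$mu_practice)
  list(spec = spec, params = params)
}

# ---- memoized simulated fixtures -------------------------------------------

fx_sim_small <- function() memo("sim_small", {
  simulate_cohort(sim_scenario(n_subjects = 200L, seed = 42L))
})

fx_sim_mid <- function() memo("sim_mid", {
  simulate_cohort(sim_scenario(n_subjects = 600L, seed = 99L))
})

# marginal bivariate fit (no covariates) on a 600-subject cohort
fx_fit_biv <- function() memo("fit_biv", {
  sim <- fx_sim_mid()
  spec <- growth_spec(outcomes = c("memory", "brain"),
                      include_survival = FALSE, residual_cross = TRUE)
  fit_growth(sim$data, spec)
})
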