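test_that("the marginal bivariate fit recovers the generator", {
  sim <- fx_sim_mid()
  fit <- fx_fit_biv()
  expect_s3_class(fit, "growsurv_fit")
  expect_true(fit$converged)
  expect_lt(fit$gradient_norm, 1e-3)
  est <- coef(fit)
  # factor means within 4 SEs of the generating values (no covariates in the
  # fitted model, so the generator's centered covariate effects fold into
  # the random-effect spread, not the means)
  se <- sqrt(diag(vcov(fit)))
  for (nm in c("alpha.memory.intercept", "alpha.memory.slope",
               "alpha.brain.intercept", "alpha.brain.slope")) {
    tr <- growsurv:::par_flatten(sim$truth, sim$spec)[[nm]]
    expect_lt(abs(est[[nm]] - tr) / se[[nm]], 4, label = nm)
  }
  expect_gt(est[["practice.mean"]], 0)
  expect_gt(est[["theta.memory"]], 0)
  expect_gt(est[["psi.memory.intercept.memory.intercept"]], 0)
})

test_that("vcov is symmetric positive semi-definite with finite SEs", {
  fit <- fx_fit_biv()
  V <- vcov(fit)
  expect_equal(V, t(V), tolerance = 1e-10)
  expect_true(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values) > -1e-10)
  expect_true(all(is.finite(sqrt(pmax(diag(V), 0)))))
  td <- tidy_fit(fit)
  expect_identical(names(td), c("parameter", "estimate", "se", "ci_lo",
                                "ci_hi", "z", "p"))
  expect_true(all(td$ci_lo < td$ci_hi))
  lk <- logLik(fit)
  expect_equal(as.numeric(lk), fit$loglik)
  expect_identical(attr(lk, "df"), length(fit$estimates_u))
})

test_that("the fit is deterministic given the data", {
  sim <- fx_sim_small()
  spec <- growth_spec(outcomes = "memory", include_survival = FALSE)
  f1 <- fit_growth(sim$data, spec)
  f2 <- fit_growth(sim$data, spec)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("the optimum does not depend on a reasonable starting point", {
  sim <- fx_sim_small()
  spec <- growth_spec(outcomes = "memory", include_survival = FALSE)
  f1 <- fit_growth(sim$data, spec)
  st <- growth_params(spec, alpha = c(0.2, -0.03),
                      psi = diag(c(0.9, 0.006)), theta = c(memory = 0.5),
                      mu_practice = 0.05)
  f2 <- fit_growth(sim$data, spec, start = st)
  expect_true(f2$converged)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-3)
})

test_that("a fit stuck away from the optimum is flagged, never silently valid", {
  sim <- fx_sim_small()
  spec <- growth_spec(outcomes = "memory", include_survival = FALSE)
  f1 <- fit_growth(sim$data, spec)
  # a pathological start that collapses the slope variance
  st <- growth_params(spec, alpha = c(0.3, 0.05),
                      psi = diag(c(1, 0.01)), theta = c(memory = 1),
                      mu_practice = 0)
  f2 <- fit_growth(sim$data, spec, start = st)
  same <- isTRUE(all.equal(f1$loglik, f2$loglik, tolerance = 1e-6))
  expect_true(same || !f2$converged)
})

test_that("the joint univariate fit maximizes the joint likelihood", {
  sim <- fx_sim_small()
  spec <- growth_spec(outcomes = "memory", include_survival = TRUE)
  rule <- gh_rule(5, 2)
  fit <- fit_growth(sim$data, spec, rule = rule)
  expect_true(fit$converged)
  # the reported optimum reproduces the likelihood at the estimates
  expect_equal(joint_loglik(sim$data, spec, fit$params, rule), fit$loglik,
               tolerance = 1e-8)
  # and beats the generating parameters (it is the in-sample maximizer)
  tr <- growsurv:::scenario_params(sim_scenario(n_subjects = 200L, seed = 42L),
                                   outcomes = "memory")
  expect_gte(fit$loglik, joint_loglik(sim$data, spec, tr, rule) - 1e-6)
})

test_that("degenerate data is rejected with a clear error", {
  d <- data.frame(subject_id = 1:30, visit_order = 0, time_in_study = 0,
                  memory = rnorm(30), brain_bpf = rnorm(30))
  spec <- growth_spec(outcomes = "memory", include_survival = FALSE)
  expect_error(fit_growth(d, spec), "non-identifiable")
  expect_error(fit_growth(d[0, ], spec), "empty|no subject")
})
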