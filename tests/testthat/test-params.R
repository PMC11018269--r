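test_that("growth_params validates its inputs", {
  sp <- toy_spec()
  p <- toy_params(sp)
  expect_s3_class(p, "growth_params")
  expect_error(growth_params(sp, alpha = 1:3, psi = diag(4),
                             theta = c(memory = 1, brain = 1)),
               "one entry per latent factor")
  # nonzero effect on a path the spec fixes to zero
  expect_error(growth_params(sp, alpha = numeric(4),
                             beta = list(brain.slope = c(age_c = 0.1)),
                             psi = diag(4), theta = c(memory = 1, brain = 1)),
               "paths the spec fixes to zero")
  bad_psi <- diag(4); bad_psi[1, 1] <- -1
  expect_error(growth_params(sp, alpha = numeric(4), psi = bad_psi,
                             theta = c(memory = 1, brain = 1)),
               "positive semi-definite")
  expect_error(growth_params(sp, alpha = numeric(4), psi = diag(4),
                             theta = c(memory = 0, brain = 1)),
               "theta")
  # residual cross-covariance must respect the Cauchy-Schwarz bound
  expect_error(growth_params(sp, alpha = numeric(4), psi = diag(4),
                             theta = c(memory = 0.3, brain = 0.1),
                             theta_cross = 0.5),
               "theta_cross")
  ssp <- toy_spec(include_survival = TRUE)
  expect_error(growth_params(ssp, alpha = numeric(4), psi = diag(4),
                             theta = c(memory = 1, brain = 1)),
               "tau required")
})

test_that("pack/unpack round-trips exactly for positive-definite blocks", {
  for (surv in c(FALSE, TRUE)) {
    sp <- toy_spec(include_survival = surv)
    p <- toy_params(sp)
    v <- growsurv:::par_pack(p, sp)
    q <- growsurv:::par_unpack(v, sp)
    expect_equal(q$alpha, p$alpha, tolerance = 1e-12)
    expect_equal(q$beta, p$beta, tolerance = 1e-12)
    expect_equal(q$psi, p$psi, tolerance = 1e-12)
    expect_equal(q$theta, p$theta, tolerance = 1e-12)
    expect_equal(q$theta_cross, p$theta_cross, tolerance = 1e-12)
    expect_equal(q$mu_practice, p$mu_practice)
    if (surv) {
      expect_equal(q$tau, p$tau)
      expect_equal(q$gamma_surv, p$gamma_surv)
    }
    expect_identical(length(v),
                     length(growsurv:::par_names_unconstrained(sp)))
  }
})

test_that("property: random parameter vectors survive unpack -> pack", {
  sp <- toy_spec(include_survival = TRUE)
  n_par <- length(growsurv:::par_names_unconstrained(sp))
  set.seed(101)
  for (r in 1:20) {
    v <- rnorm(n_par, sd = 0.7)
    p <- growsurv:::par_unpack(v, sp)
    # unpacked covariance blocks are valid by construction
    expect_true(min(eigen(p$psi, symmetric = TRUE,
                          only.values = TRUE)$values) >= 0)
    expect_true(all(p$theta > 0))
    v2 <- growsurv:::par_pack(p, sp)
    expect_equal(v2, v, tolerance = 1e-9)
  }
})

test_that("par_flatten names every reported parameter", {
  sp <- toy_spec(include_survival = TRUE)
  p <- toy_params(sp)
  fl <- growsurv:::par_flatten(p, sp)
  expect_true(all(c("alpha.memory.slope", "beta.memory.intercept.dart_z",
                    "psi.brain.slope.memory.slope", "theta.cross",
                    "practice.mean", "surv.tau.1",
                    "surv.gamma.memory.slope") %in% names(fl)))
  expect_identical(unname(fl["psi.brain.slope.memory.slope"]), p$psi[4, 2])
  expect_identical(unname(fl["alpha.brain.slope"]), unname(p$alpha[4]))
})
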