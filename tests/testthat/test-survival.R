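test_that("discrete hazard and conditional survival are exact", {
  b <- survival_block(tau = qlogis(c(0.09, 0.16)),
                      gamma = c(memory.intercept = -0.3, memory.slope = -6))
  expect_equal(discrete_hazard(c(0, 0), 1, b), 0.09)
  expect_equal(discrete_hazard(c(0, 0), 2, b), 0.16)
  eta <- c(0.5, -0.05)
  expect_equal(discrete_hazard(eta, 1, b),
               plogis(qlogis(0.09) - 0.3 * 0.5 - 6 * (-0.05)))
  expect_error(discrete_hazard(eta, 3, b), "interval")
  bp <- survival_block(tau = c(0, -1), link = "probit")
  expect_equal(discrete_hazard(c(0, 0), 1, bp), 0.5)
  expect_error(survival_block(tau = c(0, Inf)), "finite")
})

test_that("per-subject survival log-likelihood handles every status", {
  b <- survival_block(tau = qlogis(c(0.1, 0.2)))
  expect_equal(survival_loglik_given_eta(c(0L, 0L), c(0, 0), b),
               log(0.9) + log(0.8))
  expect_equal(survival_loglik_given_eta(c(0L, 1L), c(0, 0), b),
               log(0.9) + log(0.2))
  expect_equal(survival_loglik_given_eta(c(1L, NA), c(0, 0), b), log(0.1))
  # unknown intervals contribute nothing
  expect_equal(survival_loglik_given_eta(c(0L, NA), c(0, 0), b), log(0.9))
  expect_equal(survival_loglik_given_eta(c(NA, NA), c(0, 0), b), 0)
  expect_error(survival_loglik_given_eta(c(1L, 1L), c(0, 0), b),
               "more than one death")
  expect_error(survival_loglik_given_eta(c(1L, 0L), c(0, 0), b),
               "status known after a death")
  expect_error(survival_loglik_given_eta(0L, c(0, 0), b),
               "one entry per risk interval")
})

test_that("cohort survival log-likelihood matches a hand aggregation", {
  sp <- toy_spec(include_survival = TRUE)
  p <- toy_params(sp)
  d <- toy_data()
  b <- survival_block(p$tau, p$gamma_surv)
  eta_of <- function(x) (p$alpha + as.vector(p$beta %*% x))[1:2]
  by_hand <-
    survival_loglik_given_eta(c(0L, 0L), eta_of(c(1.2, 0.5)), b) +   # subject 1
    survival_loglik_given_eta(c(0L, 1L), eta_of(c(-0.7, -1.1)), b) + # subject 2
    survival_loglik_given_eta(c(NA, NA), eta_of(c(0.4, 0.9)), b)     # subject 3
  expect_equal(survival_loglik(d, sp, p), by_hand, tolerance = 1e-12)
})

test_that("design extraction encodes the survival status correctly", {
  sp <- toy_spec(include_survival = TRUE)
  des <- growsurv:::build_design(toy_data(), sp)
  expect_identical(des$surv, matrix(c(0L, 0L, -1L, 0L, 1L, -1L), 3, 2))
  bad <- toy_data()
  bad$died_in_next_interval[bad$subject_id == 1 & bad$visit_order == 0] <- TRUE
  expect_error(growsurv:::build_design(bad, sp), "after its death interval")
})

test_that("probit and logit joint likelihoods differ but stay close", {
  sim <- fx_sim_small()
  spl <- sim$spec
  spp <- spl; spp$link <- "probit"
  pl <- sim$truth
  ll_l <- joint_loglik(sim$data, spl, pl, gh_rule(9, 2))
  ll_p <- joint_loglik(sim$data, spp, pl, gh_rule(9, 2))
  expect_false(isTRUE(all.equal(ll_l, ll_p)))
  expect_lt(abs(ll_l - ll_p) / abs(ll_l), 0.25)
})
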