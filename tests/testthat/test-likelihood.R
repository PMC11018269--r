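test_that("practice loadings follow sqrt(previous occasions)", {
  expect_equal(practice_loading(0:2), c(0, 1, sqrt(2)))
  expect_equal(practice_loading(0:2, mode = "one-decimal"), c(0, 1, 1.4))
  expect_error(practice_loading(-1), "visit_order")
})

test_that("implied moments match a hand-computed subject", {
  sp <- toy_spec()
  p <- toy_params(sp)
  # memory and brain at visits 0 and 1 (t = 0, 3.8), memory only at visit 2
  sub <- subject_design(time = c(0, 0, 3.8, 3.8, 11.6),
                        visit_order = c(0L, 0L, 1L, 1L, 2L),
                        outcome = c("memory", "brain", "memory", "brain", "memory"),
                        spec = sp, x = c(age_c = 1.2, dart_z = 0.5))
  mom <- implied_moments(sub, p, sp)
  eta <- p$alpha + as.vector(p$beta %*% c(1.2, 0.5))
  L <- rbind(c(1, 0, 0, 0), c(0, 0, 1, 0),
             c(1, 3.8, 0, 0), c(0, 0, 1, 3.8), c(1, 11.6, 0, 0))
  lam <- c(0, 0, 1, 0, sqrt(2))
  mu <- as.vector(L %*% eta) + lam * 0.18
  Th <- diag(c(0.3, 0.1, 0.3, 0.1, 0.3))
  Th[1, 2] <- Th[2, 1] <- Th[3, 4] <- Th[4, 3] <- 0.02  # same-occasion cross
  V <- L %*% p$psi %*% t(L) + Th
  expect_equal(mom$mean, mu, tolerance = 1e-12)
  expect_equal(mom$cov, V, tolerance = 1e-12)
})

test_that("missing outcomes contribute nothing (full-information handling)", {
  sp <- toy_spec()
  p <- toy_params(sp)
  d <- toy_data()
  ll_all <- marginal_loglik(d, sp, p, by_subject = TRUE)
  # dropping subject 2's missing brain row entirely must change nothing
  d2 <- d[!(d$subject_id == 2 & d$visit_order == 1), , drop = FALSE]
  extra <- d[d$subject_id == 2 & d$visit_order == 1, , drop = FALSE]
  extra$brain_bpf <- NA
  d2 <- rbind(d2, extra)
  expect_equal(marginal_loglik(d2, sp, p), sum(ll_all), tolerance = 1e-12)
})

test_that("compiled and reference engines agree on simulated data", {
  sim <- fx_sim_small()
  spm <- growth_spec(intercept_covariates = sim$spec$intercept_covariates,
                     slope_covariates = sim$spec$slope_covariates,
                     include_survival = FALSE)
  pm <- growth_params(spm, alpha = sim$truth$alpha, beta = sim$truth$beta,
                      psi = sim$truth$psi, theta = sim$truth$theta,
                      theta_cross = sim$truth$theta_cross,
                      mu_practice = sim$truth$mu_practice)
  a <- marginal_loglik(sim$data, spm, pm, engine = "cpp", by_subject = TRUE)
  b <- marginal_loglik(sim$data, spm, pm, engine = "R", by_subject = TRUE)
  expect_equal(a, b, tolerance = 1e-10)
  rule <- gh_rule(7, 2)
  aj <- joint_loglik(sim$data, sim$spec, sim$truth, rule, engine = "cpp")
  bj <- joint_loglik(sim$data, sim$spec, sim$truth, rule, engine = "R")
  expect_equal(aj, bj, tolerance = 1e-8)
})

test_that("the compiled gradient matches finite differences", {
  sim <- fx_sim_small()
  des <- growsurv:::build_design(sim$data, sim$spec)
  v <- growsurv:::par_pack(sim$truth, sim$spec)
  obj <- growsurv:::.make_obj(des, sim$spec, gh_rule(5, 2), v)
  g_ad <- as.vector(obj$gr(v))
  g_fd <- growsurv:::fd_gradient(function(x) obj$fn(x), v)
  expect_equal(g_ad, g_fd, tolerance = 1e-4)
})

test_that("quadrature accuracy: coarse rules agree with a dense rule", {
  sim <- fx_sim_small()
  dense <- joint_loglik(sim$data, sim$spec, sim$truth, gh_rule(25, 2))
  coarse <- joint_loglik(sim$data, sim$spec, sim$truth, gh_rule(5, 2))
  mid <- joint_loglik(sim$data, sim$spec, sim$truth, gh_rule(9, 2))
  expect_lt(abs(coarse - dense), 1e-3)
  expect_lt(abs(mid - dense), 1e-5)
  expect_lt(abs(mid - dense), abs(coarse - dense) + 1e-12)
})

test_that("likelihood interfaces validate their inputs", {
  sp <- toy_spec(include_survival = TRUE)
  spm <- toy_spec(include_survival = FALSE)
  p <- toy_params(sp)
  pm <- toy_params(spm)
  d <- toy_data()
  expect_error(marginal_loglik(d, sp, p), "use joint_loglik")
  expect_error(joint_loglik(d, spm, pm), "use marginal_loglik")
  expect_error(joint_loglik(d, sp, p, rule = gh_rule(5, 1)),
               "dimension")
  expect_error(marginal_loglik(d[, setdiff(names(d), "memory")], spm, pm),
               "outcome columns")
})

test_that("gh_rule weights are normalized and moments are exact", {
  r <- gh_rule(9, 2)
  w <- exp(r$logw)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # with the sqrt(2) scaling used by the likelihood, nodes integrate a
  # standard Gaussian: E[z] = 0, E[z^2] = 1
  z <- sqrt(2) * r$nodes
  expect_equal(colSums(w * z), c(0, 0), tolerance = 1e-12)
  expect_equal(colSums(w * z^2), c(1, 1), tolerance = 1e-10)
  expect_error(gh_rule(2), "n_points")
})
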