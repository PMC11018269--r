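test_that("sim_scenario validates generator settings", {
  expect_error(sim_scenario(n_subjects = 0), "n_subjects")
  expect_error(sim_scenario(visit_schedule = c(0, 4, 4)), "strictly increasing")
  expect_error(sim_scenario(factor_means = c(a = 1, b = 2)), "4 entries")
  expect_error(sim_scenario(factor_cov = matrix(1, 4, 5)), "symmetric")
  m <- diag(4); m[1, 1] <- -1
  expect_error(sim_scenario(factor_cov = m), "positive semi-definite")
  expect_error(sim_scenario(hazard_thresholds = 0), "per inter-visit interval")
  expect_error(sim_scenario(mar_dropout_prob = 1), "mar_dropout_prob")
  # unnamed factor means get the canonical names in canonical order
  sc <- sim_scenario(factor_means = c(0.1, -0.2, 0.3, -0.4))
  expect_identical(names(sc$factor_means),
                   c("memory.intercept", "memory.slope",
                     "brain.intercept", "brain.slope"))
  sc2 <- sim_scenario(covariate_effects = NULL)
  expect_identical(sc2$covariate_effects, list())
})

test_that("simulated cohorts are reproducible and structurally valid", {
  sc <- sim_scenario(n_subjects = 120L, seed = 7L)
  s1 <- simulate_cohort(sc)
  s2 <- simulate_cohort(sc)
  expect_identical(s1$data, s2$data)
  expect_silent(validate_cohort(s1$data))
  d <- s1$data
  expect_true(all(d$visit_order %in% 0:2))
  expect_true(all(d$time_in_study[d$visit_order == 0] == 0))
  # strictly increasing times within subject
  expect_true(all(tapply(d$time_in_study, d$subject_id,
                         function(t) all(diff(t) > 0))))
  # a death terminates the record
  dd <- d[d$died_in_next_interval, ]
  for (id in dd$subject_id) {
    rows <- d[d$subject_id == id, ]
    expect_true(rows$died_in_next_interval[nrow(rows)])
  }
  expect_identical(nrow(s1$latent), 120L)
})

test_that("different seeds give different cohorts", {
  a <- simulate_cohort(sim_scenario(n_subjects = 60L, seed = 1L))$data
  b <- simulate_cohort(sim_scenario(n_subjects = 60L, seed = 2L))$data
  expect_false(identical(a$memory, b$memory))
})

test_that("reserve covariates are calibrated to their configuration", {
  cov <- simulate_reserve_covariates(20000, seed = 3)
  expect_true(abs(cor(cov$dart, cov$edu_propensity) - 0.50) < 0.04)
  expect_true(all(cov$dart >= 35 & cov$dart <= 100))
  expect_true(all(cov$edu_level %in% 1:7))
  expect_true(abs(mean(cov$sex) - 0.208) < 0.02)
  expect_true(abs(mean(cov$stroke) - 0.108) < 0.02)
  # sex-specific head-size distributions
  expect_true(mean(cov$icv_ml[cov$sex == 0]) > mean(cov$icv_ml[cov$sex == 1]))
  expect_error(simulate_reserve_covariates(1), "n must be")
  expect_error(simulate_reserve_covariates(10, correlation = 1), "correlation")
})

test_that("informative mortality removes faster decliners", {
  sim <- simulate_cohort(sim_scenario(n_subjects = 4000L, seed = 31L))
  d <- sim$data
  died <- unique(d$subject_id[d$died_in_next_interval])
  slopes <- sim$latent[, "memory.slope"]
  # hazard loads negatively on the memory slope: decedents decline faster
  expect_lt(mean(slopes[died]), mean(slopes[-died]))
})

test_that("mortality and drop-out shape retention", {
  sim <- simulate_cohort(sim_scenario(n_subjects = 2000L, seed = 17L))
  nvis <- table(factor(tapply(sim$data$visit_order, sim$data$subject_id, max),
                       levels = 0:2))
  expect_true(all(nvis > 0))
  # with hazard ~9%/16% plus 20% drop-out, under half reach the third visit
  expect_lt(nvis[["2"]] / 2000, 0.65)
  sim0 <- simulate_cohort(sim_scenario(n_subjects = 500L, seed = 17L,
                                       hazard_thresholds = qlogis(c(1e-6, 1e-6)),
                                       mar_dropout_prob = 0))
  expect_true(all(tapply(sim0$data$visit_order, sim0$data$subject_id, max) == 2))
  expect_false(any(sim0$data$died_in_next_interval))
})

test_that("validate_cohort rejects corrupted records", {
  d <- simulate_cohort(sim_scenario(n_subjects = 20L, seed = 5L))$data
  bad <- d
  bad$time_in_study[bad$subject_id == bad$subject_id[1]][1] <- 0.5
  expect_error(validate_cohort(bad), "visit 0 must be at time 0|strictly increasing")
  bad2 <- d[d$subject_id == d$subject_id[1], ][c(1, 1, 1, 1), ]
  bad2$visit_order <- 0:3
  bad2$time_in_study <- c(0, 1, 2, 3)
  expect_error(validate_cohort(bad2), "1..3 visits")
})

test_that("write_cohort persists the data and the generating truth", {
  sim <- fx_sim_small()
  dir <- tempfile("cohort")
  write_cohort(sim, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  tr <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(tr$alpha.memory.slope, -0.085)
  expect_equal(tr$alpha.brain.slope, -0.137)
  back <- read.csv(file.path(dir, "cohort.csv"))
  expect_identical(nrow(back), nrow(sim$data))
  unlink(dir, recursive = TRUE)
})
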