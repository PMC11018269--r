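mg_fixture <- function() memo("mgfit", {
  sim <- fx_sim_mid()
  pp <- preprocess_cohort(sim$data)
  spec <- growth_spec(outcomes = c("memory", "brain"),
                      include_survival = FALSE, residual_cross = TRUE,
                      grouping = "dart_tertile")
  list(data = pp$data, spec = spec,
       mg = multiple_group_fit(pp$data, spec))
})

test_that("multiple-group fits stack estimates with group prefixes", {
  fx <- mg_fixture()
  mg <- fx$mg
  expect_s3_class(mg, "growsurv_mgfit")
  expect_identical(names(mg$fits), c("low", "mid", "high"))
  expect_true(mg$converged)
  p <- length(mg$fits$low$estimates)
  expect_identical(length(mg$estimates), 3L * p)
  expect_identical(names(mg$estimates)[1],
                   paste0("low|", names(mg$fits$low$estimates)[1]))
  # per-group estimates equal independent fits of the subsets
  sub <- fx$data[fx$data$dart_tertile == "mid", ]
  solo <- fit_growth(sub, growth_spec(outcomes = c("memory", "brain"),
                                      include_survival = FALSE))
  expect_equal(unname(mg$fits$mid$estimates), unname(solo$estimates),
               tolerance = 1e-6)
})

test_that("the stacked covariance is block-diagonal across groups", {
  mg <- mg_fixture()$mg
  p <- length(mg$fits$low$estimates)
  V <- mg$vcov
  expect_equal(V[seq_len(p), seq_len(p)], unname(mg$fits$low$vcov),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(V[seq_len(p), p + seq_len(p)] == 0))
})

test_that("across-group Wald comparisons run off the standard contrasts", {
  mg <- mg_fixture()$mg
  cons <- standard_contrasts(mg)
  expect_true("dB.low" %in% names(cons))
  expect_true("memory.slope.low.vs.mid" %in% names(cons))
  expect_true("slope.cov.low.vs.high" %in% names(cons))
  w <- wald_test(mg, cons$memory.slope.low.vs.high)
  expect_identical(w$df, 1L)
  expect_equal(w$estimate,
               unname(mg$estimates["low|alpha.memory.slope"] -
                        mg$estimates["high|alpha.memory.slope"]))
  expect_true(w$p_value >= 0 && w$p_value <= 1)
})

test_that("grouping problems raise informative errors", {
  fx <- mg_fixture()
  expect_error(multiple_group_fit(fx$data, growth_spec(include_survival = FALSE)),
               "no grouping variable")
  expect_error(multiple_group_fit(fx$data, fx$spec, grouping = "nope"),
               "not in data")
  small <- fx$data[fx$data$subject_id %in% unique(fx$data$subject_id)[1:40], ]
  expect_error(multiple_group_fit(small, fx$spec), "empty|subjects")
})
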