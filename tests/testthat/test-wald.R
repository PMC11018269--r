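# A stub fit with known estimates and covariance lets every Wald quantity
# be checked against hand arithmetic.
stub_fit <- function() {
  est <- c(a = 1.0, b = 0.4, c = -0.2)
  V <- matrix(c(0.04, 0.01, 0.00,
                0.01, 0.09, 0.02,
                0.00, 0.02, 0.25), 3, 3,
              dimnames = list(names(est), names(est)))
  structure(list(estimates = est, vcov = V), class = "growsurv_fit")
}

test_that("rank-1 Wald test matches hand arithmetic", {
  f <- stub_fit()
  w <- wald_test(f, c(a = 1, b = -1))
  diff <- 1.0 - 0.4
  se2 <- 0.04 + 0.09 - 2 * 0.01
  expect_equal(w$estimate, diff)
  expect_equal(w$statistic, diff^2 / se2)
  expect_identical(w$df, 1L)
  expect_equal(w$p_value, pchisq(diff^2 / se2, 1, lower.tail = FALSE))
  expect_equal(unname(w$ci),
               diff + c(-1, 1) * qnorm(0.975) * sqrt(se2))
  # non-zero null shifts the statistic but not the interval's center
  w0 <- wald_test(f, c(a = 1, b = -1), null = 0.6)
  expect_equal(w0$statistic, 0, tolerance = 1e-12)
  expect_equal(w0$estimate, diff)
})

test_that("multi-row contrasts use the full covariance", {
  f <- stub_fit()
  L <- rbind(c(a = 1, b = -1, c = 0), c(a = 0, b = 1, c = -1))
  w <- wald_test(f, L)
  r <- c(0.6, 0.6)
  M <- rbind(c(0.04 + 0.09 - 2 * 0.01, 0.01 + 0.02 - 0.09 - 0.00),
             c(0.01 + 0.02 - 0.09 - 0.00, 0.09 + 0.25 - 2 * 0.02))
  expect_equal(w$statistic, drop(t(r) %*% solve(M, r)))
  expect_identical(w$df, 2L)
  expect_null(w$ci)
})

test_that("duplicated names collapse and degenerate contrasts are handled", {
  f <- stub_fit()
  # a parameter contrasted with itself cancels out
  w <- wald_test(f, setNames(c(1, -1, 1), c("a", "a", "b")))
  wb <- wald_test(f, c(b = 1))
  expect_equal(w$statistic, wb$statistic)
  z <- wald_test(f, setNames(c(1, -1), c("a", "a")))
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  expect_error(wald_test(f, c(zz = 1)), "not in the estimate vector")
  expect_error(wald_test(f, unname(c(1, 0, 0))), "column names|parameter names")
  # redundant rows make the contrast covariance singular
  expect_error(wald_test(f, rbind(c(a = 1, b = -1), c(a = 2, b = -2))),
               "singular|redundant")
})

test_that("standard contrasts cover the reported quantities", {
  fit <- fx_fit_biv()
  cons <- standard_contrasts(fit)
  expect_true(all(c("intercept.memory", "slope.memory", "slope.brain", "dB")
                  %in% names(cons)))
  w <- wald_test(fit, cons$dB)
  expect_equal(w$estimate,
               unname(coef(fit)["alpha.memory.slope"] -
                        coef(fit)["alpha.brain.slope"]))
  expect_identical(w$df, 1L)
})
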