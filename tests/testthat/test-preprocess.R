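test_that("std_reference freezes baseline moments and is invertible", {
  d <- data.frame(x = c(10, 12, 14, 20), sex = c(0, 0, 1, 1))
  ref <- std_reference(d, "x")
  z <- apply_reference(d$x, "x", ref)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  # invertible given the stored reference
  expect_equal(z * ref$ref$pooled$sd[["x"]] + ref$ref$pooled$mean[["x"]], d$x)
  # applying a frozen reference to new data never changes the reference
  z2 <- apply_reference(c(100, 200), "x", ref)
  expect_equal(z2, (c(100, 200) - mean(d$x)) / sd(d$x))
  refs <- std_reference(d, "x", by = "sex")
  zs <- apply_reference(d$x, "x", refs, stratum = d$sex)
  expect_equal(zs, c(-1, 1, -1, 1) / sqrt(2))
  expect_error(apply_reference(d$x, "x", refs), "stratified")
  expect_error(std_reference(data.frame(x = c(1, 1, 1)), "x"), "zero or undefined")
})

test_that("reference JSON round trip is exact", {
  d <- data.frame(icv_ml = c(1300, 1400, 1500, 1600), sex = c(0, 1, 0, 1))
  ref <- std_reference(d, "icv_ml", by = "sex")
  f <- tempfile(fileext = ".json")
  write_reference(ref, f)
  ref2 <- read_reference(f)
  expect_equal(standardize_icv_by_sex(d$icv_ml, d$sex, ref2),
               standardize_icv_by_sex(d$icv_ml, d$sex, ref))
  unlink(f)
})

test_that("memory composite is baseline-standardized with the min-tests rule", {
  set.seed(8)
  n <- 60
  d <- data.frame(subject_id = rep(1:(n / 2), each = 2),
                  visit_order = rep(0:1, n / 2),
                  wlt_total_recall = rnorm(n, 40, 8),
                  wlt_delayed_recall = rnorm(n, 8, 3),
                  rey_delayed_recall = rnorm(n, 15, 6))
  # one baseline visit with only one observed test -> composite missing
  d$wlt_total_recall[1] <- NA
  d$wlt_delayed_recall[1] <- NA
  # one baseline visit with two observed tests -> composite present
  d$rey_delayed_recall[3] <- NA
  mc <- memory_composite(d)
  base <- d$visit_order == 0
  expect_true(is.na(mc$score[1]))
  expect_false(is.na(mc$score[3]))
  expect_equal(mean(mc$score[base], na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sd(mc$score[base], na.rm = TRUE), 1, tolerance = 1e-12)
  # the frozen reference reproduces the same scores on re-application
  mc2 <- memory_composite(d, ref = mc$ref)
  expect_equal(mc2$score, mc$score)
})

test_that("brain parenchymal fraction and its standardization are exact", {
  expect_equal(round(compute_bpf(1154.3, 1461.2), 2), 0.79)
  expect_equal(compute_bpf(750, 1000), 0.75)
  expect_error(compute_bpf(-1, 1000), "positive")
  expect_error(compute_bpf(1100, 1000), "icv_ml must be >=")
  ref <- std_reference(data.frame(bpf = c(0.76, 0.80, 0.84)), "bpf")
  expect_equal(standardize_bpf(0.80, ref), 0)
  expect_equal(standardize_bpf(0.84, ref), 1)
})

test_that("age group uses the follow-up midpoint with ties to late-life", {
  expect_identical(assign_age_group(58, 4), "late-life")   # midpoint exactly 60
  expect_identical(assign_age_group(57.9, 4), "mid-life")  # midpoint 59.9
  expect_identical(assign_age_group(60, 0), "late-life")
  expect_identical(assign_age_group(c(50.5, 65.2, 58), c(4, 0, 4)),
                   c("mid-life", "late-life", "late-life"))
  expect_error(assign_age_group(-1, 0), "baseline_age")
  expect_error(assign_age_group(50, -1), "time_in_study")
})

test_that("fixed tertile boundaries are exact at the edges", {
  expect_identical(as.character(assign_tertile(c(35, 75, 76, 89, 90, 100), "dart")),
                   c("low", "low", "mid", "mid", "high", "high"))
  expect_identical(as.character(assign_tertile(c(-2.66, -0.46, -0.45, 0.40, 0.41, 3.29), "icv")),
                   c("low", "low", "mid", "mid", "high", "high"))
  expect_identical(as.character(assign_tertile(c(-3.65, -0.37, -0.36, 0.51, 0.52, 2.91), "bpf")),
                   c("low", "low", "mid", "mid", "high", "high"))
  expect_error(assign_tertile(101, "dart"), "admissible range")
  expect_error(assign_tertile(-2.7, "icv"), "admissible range")
  expect_identical(levels(assign_tertile(50, "dart")), c("low", "mid", "high"))
  # data-driven tertiles split a balanced sample into thirds
  td <- assign_tertile(1:9, "dart", boundaries = "data")
  expect_identical(as.vector(table(td)), c(3L, 3L, 3L))
})

test_that("education levels map to the three categories", {
  got <- categorize_education(1:7)
  expect_identical(as.character(got),
                   c("less than high school", "less than high school",
                     "high school", "high school", "high school",
                     "college/university", "college/university"))
  expect_error(categorize_education(0), "1..7")
  expect_error(categorize_education(8), "1..7")
  expect_true(is.na(categorize_education(NA)))
})

test_that("centering is idempotent and warns on constants", {
  d <- data.frame(age = c(50, 60, 70), k = c(1, 1, 1))
  d2 <- center_covariates(d, "age")
  expect_equal(d2$age_c, c(-10, 0, 10))
  d3 <- center_covariates(d2, "age_c", suffix = "")
  expect_equal(d3$age_c, d2$age_c)
  expect_warning(center_covariates(d, "k"), "constant")
})

test_that("preprocess_cohort derives every analysis column", {
  sim <- fx_sim_small()
  pp <- preprocess_cohort(sim$data)
  d <- pp$data
  for (cc in c("dart_z", "edu_z", "icv_z", "bpf_base_z", "edu_cat",
               "age_group", "dart_tertile", "icv_tertile", "bpf_tertile",
               "age_c", "sex_c", "stroke_c"))
    expect_true(cc %in% names(d), label = cc)
  base <- d[d$visit_order == 0, ]
  expect_equal(mean(base$dart_z), 0, tolerance = 1e-10)
  expect_equal(sd(base$dart_z), 1, tolerance = 1e-10)
  expect_equal(mean(base$bpf_base_z), 0, tolerance = 1e-10)
  # ICV z-scores have mean 0 within each sex at baseline
  expect_equal(as.vector(tapply(base$icv_z, base$sex, mean)), c(0, 0),
               tolerance = 1e-10)
  # baseline BPF z is carried to every row of the subject
  expect_true(all(tapply(d$bpf_base_z, d$subject_id,
                         function(x) length(unique(x)) == 1)))
  expect_identical(levels(d$dart_tertile), c("low", "mid", "high"))
  expect_true(all(d$age_group %in% c("mid-life", "late-life")))
  expect_true(pp$n_clamped >= 0)
  expect_error(preprocess_cohort(sim$data[, setdiff(names(sim$data), "dart")]),
               "lacks columns")
})
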