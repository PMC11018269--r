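#' Define a simulation scenario
#'
#' A scenario fixes the generative conditions of a synthetic cohort: a
#' three-visit design (nominal years 0, 4, 12) with individually-varying
#' intervals, bivariate correlated random intercepts and slopes for memory
#' and brain parenchymal fraction (both on the standardized scale), a
#' practice effect on memory, baseline covariate effects, reserve covariates
#' with a DART-education correlation of about .50, death generated from a
#' discrete-time logistic hazard linked to the latent memory intercept and
#' slope, and missing-at-random drop-out for reasons other than death.
#'
#' The defaults are calibrated to the cohort the package emulates: memory
#' declining at -.085 standardized units/year and brain volume at -.137, a
#' small positive covariance between the two rates, DART effects of .350 on
#' the memory intercept and .008 on its slope, and retention shaped by both
#' mortality and a 0.2 per-visit drop-out probability.
#'
#' @param n_subjects number of subjects.
#' @param visit_schedule nominal visit times in years.
#' @param visit_jitter_sd SD (years) of the Gaussian jitter around nominal
#'   times for visits after the first (times are kept strictly increasing).
#' @param factor_means named means of (memory.intercept, memory.slope,
#'   brain.intercept, brain.slope); slopes in standardized units/year.
#' @param factor_cov 4x4 covariance of the latent factors (symmetric PSD).
#' @param residual_sd named residual SDs per outcome (> 0).
#' @param residual_cross_cov within-occasion memory-brain residual covariance.
#' @param practice_mean practice-effect mean per unit loading.
#' @param practice_var practice-effect variance (0: pure fixed effect).
#' @param covariate_effects named list `list(factor = c(covariate = effect))`
#'   over the factors; covariates are the centered/standardized baseline
#'   columns (`age_c`, `sex_c`, `stroke_c`, `dart_z`, ...).
#' @param covariate_config list passed to [simulate_reserve_covariates()].
#' @param hazard_thresholds per-interval hazard intercepts on the logit scale
#'   (two risk intervals: after visit 1 and after visit 2).
#' @param hazard_loadings `c(gamma_intercept, gamma_slope)` linking the
#'   latent memory intercept and slope to the death hazard.
#' @param mar_dropout_prob per-visit probability of non-death drop-out.
#' @param seed integer seed; with the seed fixed the cohort is bit-identical
#'   across runs.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_subjects = 1000L,
                         visit_schedule = c(0, 4, 12),
                         visit_jitter_sd = 0.5,
                         factor_means = c(memory.intercept = 0, memory.slope = -0.085,
                                          brain.intercept = 0, brain.slope = -0.137),
                         factor_cov = default_factor_cov(),
                         residual_sd = c(memory = sqrt(0.30), brain = sqrt(0.10)),
                         residual_cross_cov = 0.02,
                         practice_mean = 0.18,
                         practice_var = 0,
                         covariate_effects = default_covariate_effects(),
                         covariate_config = list(),
                         hazard_thresholds = qlogis(c(0.09, 0.16)),
                         hazard_loadings = c(-0.30, -8),
                         mar_dropout_prob = 0.2,
                         seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (any(diff(visit_schedule) <= 0) || any(visit_schedule < 0))
    stop("visit_schedule must be non-negative and strictly increasing")
  fn <- c("memory.intercept", "memory.slope", "brain.intercept", "brain.slope")
  if (length(factor_means) != 4L)
    stop("factor_means must have 4 entries (memory/brain intercept and slope)")
  if (is.null(names(factor_means))) names(factor_means) <- fn
  if (!setequal(names(factor_means), fn))
    stop("factor_means must be named: ", paste(fn, collapse = ", "))
  factor_means <- factor_means[fn]
  if (is.null(covariate_effects)) covariate_effects <- list()
  fc <- as.matrix(factor_cov)
  if (nrow(fc) != 4L || ncol(fc) != 4L || max(abs(fc - t(fc))) > 1e-10)
    stop("factor_cov must be a symmetric 4x4 matrix")
  ev <- eigen(fc, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev)))
    stop("factor_cov is not positive semi-definite")
  if (any(residual_sd <= 0)) stop("residual_sd must be > 0")
  if (length(hazard_thresholds) != length(visit_schedule) - 1L)
    stop("need one hazard threshold per inter-visit interval")
  if (mar_dropout_prob < 0 || mar_dropout_prob >= 1)
    stop("mar_dropout_prob must be in [0, 1)")
  structure(list(
    n_subjects = as.integer(n_subjects), visit_schedule = visit_schedule,
    visit_jitter_sd = visit_jitter_sd, factor_means = factor_means,
    factor_cov = fc, residual_sd = residual_sd,
    residual_cross_cov = residual_cross_cov, practice_mean = practice_mean,
    practice_var = practice_var, covariate_effects = covariate_effects,
    covariate_config = covariate_config,
    hazard_thresholds = hazard_thresholds, hazard_loadings = hazard_loadings,
    mar_dropout_prob = mar_dropout_prob, seed = seed
  ), class = "sim_scenario")
}

#' @rdname sim_scenario
#' @export
default_factor_cov <- function() {
  f <- c("memory.intercept", "memory.slope", "brain.intercept", "brain.slope")
  m <- matrix(c(
    0.550, -0.010, 0.300, 0.004,
    -0.010, 0.0030, 0.006, 0.0010,
    0.300, 0.006, 0.850, -0.008,
    0.004, 0.0010, -0.008, 0.0020), 4, 4, byrow = TRUE,
    dimnames = list(f, f))
  m
}

#' @rdname sim_scenario
#' @export
default_covariate_effects <- function() {
  list(
    memory.intercept = c(age_c = -0.020, sex_c = 0.15, stroke_c = -0.20, dart_z = 0.350),
    memory.slope = c(age_c = -0.0015, dart_z = 0.008),
    brain.intercept = c(age_c = -0.035, sex_c = 0.05, stroke_c = -0.15),
    brain.slope = c(age_c = -0.0020)
  )
}

#' Simulate baseline reserve and demographic covariates
#'
#' DART score and a continuous education propensity are drawn from a
#' bivariate Gaussian with configurable correlation (default .50); the
#' propensity is discretized into the 7 ordered Dutch education levels and
#' mapped to 3 categories; DART is clipped to its admissible range 35-100;
#' intracranial volume is drawn per sex with distinct means. Baseline age,
#' sex and stroke history are drawn from the configured marginals.
#'
#' @param n number of subjects (>= 2).
#' @param seed optional integer seed (`NULL`: continue the current RNG
#'   stream).
#' @param correlation DART-education propensity correlation, in (-1, 1).
#' @param config optional overrides: `dart_mean`, `dart_sd`, `edu_probs`
#'   (length-7 level probabilities), `age_mean`, `age_sd`, `age_range`,
#'   `p_female`, `p_stroke`, `icv_mean_male`, `icv_sd_male`,
#'   `icv_mean_female`, `icv_sd_female`.
#' @return `data.frame` with columns `subject_id`, `age`, `sex`
#'   (1 = female), `stroke`, `dart`, `edu_propensity`, `edu_level` (1-7),
#'   `edu_cat`, `icv_ml`.
#' @export
simulate_reserve_covariates <- function(n, seed = NULL, correlation = 0.50,
                                        config = list()) {
  if (n < 2) stop("n must be >= 2")
  if (abs(correlation) >= 1) stop("correlation must be inside (-1, 1)")
  if (!is.null(seed)) set.seed(seed)
  cfg <- modifyList(list(
    dart_mean = 79.5, dart_sd = 15.0,
    edu_probs = c(0.040, 0.077, 0.150, 0.300, 0.197, 0.136, 0.100),
    age_mean = 58.7, age_sd = 9.1, age_range = c(40, 79),
    p_female = 0.208, p_stroke = 0.108,
    icv_mean_male = 1490, icv_sd_male = 122,
    icv_mean_female = 1350, icv_sd_female = 110), config)

  z1 <- rnorm(n)
  z2 <- correlation * z1 + sqrt(1 - correlation^2) * rnorm(n)
  dart <- pmin(100, pmax(35, cfg$dart_mean + cfg$dart_sd * z1))
  cuts <- qnorm(cumsum(cfg$edu_probs))[1:6]
  edu_level <- findInterval(z2, cuts) + 1L
  edu_cat <- categorize_education(edu_level)

  age <- pmin(cfg$age_range[2], pmax(cfg$age_range[1],
                                     rnorm(n, cfg$age_mean, cfg$age_sd)))
  sex <- rbinom(n, 1, cfg$p_female)
  stroke <- rbinom(n, 1, cfg$p_stroke)
  icv <- ifelse(sex == 1,
                rnorm(n, cfg$icv_mean_female, cfg$icv_sd_female),
                rnorm(n, cfg$icv_mean_male, cfg$icv_sd_male))
  data.frame(subject_id = seq_len(n), age = age, sex = sex, stroke = stroke,
             dart = dart, edu_propensity = z2, edu_level = edu_level,
             edu_cat = edu_cat, icv_ml = icv)
}

# the model spec implied by a scenario's generative structure
scenario_spec <- function(scenario, outcomes = c("memory", "brain"),
                          include_survival = TRUE, ...) {
  eff <- scenario$covariate_effects
  ic <- lapply(outcomes, function(o) names(eff[[paste0(o, ".intercept")]]))
  sc <- lapply(outcomes, function(o) names(eff[[paste0(o, ".slope")]]))
  names(ic) <- names(sc) <- outcomes
  growth_spec(outcomes = outcomes,
              intercept_covariates = ic, slope_covariates = sc,
              practice_on = if ("memory" %in% outcomes) "memory" else character(),
              practice_variance_free = scenario$practice_var > 0,
              residual_cross = length(outcomes) == 2,
              include_survival = include_survival,
              hazard_factors = c("memory.intercept", "memory.slope"),
              n_intervals = length(scenario$visit_schedule) - 1L, ...)
}

# the ground-truth parameter object matching scenario_spec(scenario)
scenario_params <- function(scenario, outcomes = c("memory", "brain"),
                            include_survival = TRUE) {
  spec <- scenario_spec(scenario, outcomes, include_survival)
  fi <- match(spec$factors, names(scenario$factor_means))
  beta <- scenario$covariate_effects[spec$factors]
  names(beta) <- spec$factors
  growth_params(
    spec,
    alpha = scenario$factor_means[fi],
    beta = beta,
    psi = scenario$factor_cov[fi, fi, drop = FALSE],
    theta = scenario$residual_sd[spec$outcomes]^2,
    theta_cross = if (length(outcomes) == 2) scenario$residual_cross_cov else 0,
    mu_practice = scenario$practice_mean,
    psi_practice = scenario$practice_var,
    tau = if (include_survival) scenario$hazard_thresholds else NULL,
    gamma_surv = if (include_survival)
      setNames(scenario$hazard_loadings, c("memory.intercept", "memory.slope")) else NULL)
}

#' Simulate a longitudinal cohort with informative mortality
#'
#' Generates a long-format subject-visit table following the scenario's
#' latent growth structure. Outcomes follow
#' `y_ij = eta0 + eta1 t_ij + lambda_j mu_practice + covariate effects +
#' residual`, with the factor pairs drawn from the scenario's 4x4 factor
#' covariance. After each attended visit (except the last planned one) the
#' subject may die, with probability `plogis(tau_k + gamma0 eta0_memory +
#' gamma1 eta1_memory)`, or drop out at random; either ends the record, and
#' only a death is flagged.
#'
#' @param scenario a [sim_scenario()].
#' @return List with `data` (the cohort; one row per subject-visit, columns
#'   `subject_id`, `visit_order`, `time_in_study`, `memory`, `brain_bpf`,
#'   `died_in_next_interval`, raw and centered/standardized baseline
#'   covariates), `truth` (the generating [growth_params()]), `spec` (the
#'   matching [growth_spec()]), and `latent` (per-subject factor values, for
#'   diagnostics).
#' @export
#' @examples
#' sim <- simulate_cohort(sim_scenario(n_subjects = 50, seed = 7))
#' head(sim$data)
simulate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  n <- scenario$n_subjects
  nv <- length(scenario$visit_schedule)

  # covariate_config: `correlation` and `config` are passed through as-is;
  # any other entry is a config override (e.g. age_mean, icv_sd_male)
  cc <- scenario$covariate_config
  extra <- setdiff(names(cc), c("correlation", "config"))
  args <- c(list(n = n, seed = NULL), cc[intersect(names(cc), c("correlation", "config"))])
  if (length(extra))
    args$config <- modifyList(as.list(args$config), cc[extra])
  covs <- do.call(simulate_reserve_covariates, args)
  # centered / standardized generator covariates
  covs$age_c <- covs$age - mean(covs$age)
  covs$sex_c <- covs$sex - mean(covs$sex)
  covs$stroke_c <- covs$stroke - mean(covs$stroke)
  covs$dart_z <- as.vector(scale(covs$dart))
  icv_ref <- std_reference(covs, "icv_ml", by = "sex")
  covs$icv_z <- standardize_icv_by_sex(covs$icv_ml, covs$sex, icv_ref)

  fnames <- names(scenario$factor_means)
  nf <- length(fnames)
  eff <- scenario$covariate_effects
  cov_names <- unique(unlist(lapply(eff, names)))
  Xc <- as.matrix(covs[, cov_names, drop = FALSE])
  B <- matrix(0, nf, length(cov_names), dimnames = list(fnames, cov_names))
  for (f in names(eff)) B[f, names(eff[[f]])] <- eff[[f]]

  Lf <- chol_psd(scenario$factor_cov)
  eta <- matrix(rep(scenario$factor_means, each = n), n, nf,
                dimnames = list(NULL, fnames)) +
    Xc %*% t(B) + matrix(rnorm(n * nf), n, nf) %*% t(Lf)
  prac <- if (scenario$practice_var > 0)
    rnorm(n, scenario$practice_mean, sqrt(scenario$practice_var))
  else rep(scenario$practice_mean, n)

  # individually-varying times: nominal plus truncated jitter, increasing
  tmat <- matrix(0, n, nv)
  for (j in 2:nv) {
    tj <- scenario$visit_schedule[j] + rnorm(n, 0, scenario$visit_jitter_sd)
    tmat[, j] <- pmax(tmat[, j - 1] + 0.25, tj)
  }

  # residuals with within-occasion cross-covariance
  sd_m <- scenario$residual_sd[["memory"]]
  sd_b <- scenario$residual_sd[["brain"]]
  Sr <- matrix(c(sd_m^2, scenario$residual_cross_cov,
                 scenario$residual_cross_cov, sd_b^2), 2, 2)
  Lr <- chol_psd(Sr)

  g0 <- scenario$hazard_loadings[1]; g1 <- scenario$hazard_loadings[2]
  nr_max <- n * nv
  c_sid <- integer(nr_max); c_vis <- integer(nr_max); c_tim <- numeric(nr_max)
  c_mem <- numeric(nr_max); c_brn <- numeric(nr_max); c_die <- logical(nr_max)
  pos <- 0L
  for (i in seq_len(n)) {
    alive <- TRUE; last <- nv
    for (k in seq_len(nv - 1)) {
      # the drop-out draw must come before the hazard draw: a subject who
      # drops out in interval k is censored at the previous visit, so their
      # continuation must not be conditioned on surviving interval k —
      # otherwise the drop-out is informative and no longer ignorable
      if (runif(1) < scenario$mar_dropout_prob) { last <- k; break }
      h <- plogis(scenario$hazard_thresholds[k] +
                    g0 * eta[i, "memory.intercept"] + g1 * eta[i, "memory.slope"])
      if (runif(1) < h) { last <- k; alive <- FALSE; break }
    }
    jj <- seq_len(last)
    e <- matrix(rnorm(2 * last), last, 2) %*% t(Lr)
    tv <- tmat[i, jj]
    lamv <- practice_loading(jj - 1L)
    idx <- pos + jj
    c_sid[idx] <- i
    c_vis[idx] <- jj - 1L
    c_tim[idx] <- tv
    c_mem[idx] <- eta[i, "memory.intercept"] + eta[i, "memory.slope"] * tv +
      lamv * prac[i] + e[, 1]
    c_brn[idx] <- eta[i, "brain.intercept"] + eta[i, "brain.slope"] * tv + e[, 2]
    if (!alive) c_die[pos + last] <- TRUE
    pos <- pos + last
  }
  keep <- seq_len(pos)
  data <- data.frame(subject_id = c_sid[keep], visit_order = c_vis[keep],
                     time_in_study = c_tim[keep], memory = c_mem[keep],
                     brain_bpf = c_brn[keep],
                     died_in_next_interval = c_die[keep])
  data <- cbind(data, covs[data$subject_id, setdiff(names(covs), "subject_id"),
                           drop = FALSE])
  rownames(data) <- NULL

  list(data = data,
       truth = scenario_params(scenario),
       spec = scenario_spec(scenario),
       latent = eta)
}

# lower Cholesky factor tolerant of semi-definite (incl. zero) matrices
chol_psd <- function(S) {
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
  d <- pmax(ev$values, 0)
  L <- ev$vectors %*% diag(sqrt(d), nrow(S))
  L
}

#' Write a simulated cohort and its ground truth to disk
#'
#' The cohort goes to `<dir>/cohort.csv` (one row per subject-visit) and the
#' generating parameters to `<dir>/ground_truth.json`.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(sim$data, file.path(dir, "cohort.csv"), row.names = FALSE)
  truth <- par_flatten(sim$truth, sim$spec)
  jsonlite::write_json(as.list(truth), file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
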