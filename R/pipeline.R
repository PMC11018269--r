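#' Configure the end-to-end analysis pipeline
#'
#' Bundles everything one full analysis run needs: the input (a simulation
#' scenario, an in-memory cohort, or a cohort CSV), which reserve proxies to
#' analyze, which age strata the univariate models run in, the tertile mode,
#' model options, the seed, and the output directory. The seed is recorded in
#' every output artifact.
#'
#' The default configuration mirrors the design the package emulates:
#' univariate reserve models for the overall sample and stratified by
#' mid-life/late-life; one bivariate joint model; and tertile multiple-group
#' comparisons run unstratified only (the stratified samples are too small to
#' split again into three groups).
#'
#' @param output_dir directory for all artifacts (created if needed).
#' @param scenario a [sim_scenario()] used by the `simulate` stage (ignored
#'   when `data`/`input_csv` is given).
#' @param data optional in-memory long-format cohort; skips simulation.
#' @param input_csv optional path to a cohort CSV; skips simulation.
#' @param proxies reserve proxies to run: subset of `"dart"`, `"education"`,
#'   `"icv"`, `"bpf"`.
#' @param strata strata for the univariate models: subset of `"overall"`,
#'   `"mid-life"`, `"late-life"`.
#' @param tertile_boundaries `"paper-fixed"` or `"data"` (see
#'   [assign_tertile()]).
#' @param link hazard link for joint models.
#' @param gh_points Gauss-Hermite points per hazard-factor dimension.
#' @param residual_cross estimate the within-occasion cross-outcome residual
#'   covariance in bivariate models.
#' @param joint_survival adjust the bivariate model for death-related
#'   attrition via the joint survival submodel.
#' @param loading_mode practice-loading mode (`"exact"` or `"one-decimal"`).
#' @param seed integer seed; overrides the scenario's seed so one number
#'   controls the whole run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            scenario = sim_scenario(),
                            data = NULL,
                            input_csv = NULL,
                            proxies = c("dart", "education", "icv", "bpf"),
                            strata = c("overall", "mid-life", "late-life"),
                            tertile_boundaries = c("paper-fixed", "data"),
                            link = c("logit", "probit"),
                            gh_points = 9L,
                            residual_cross = TRUE,
                            joint_survival = TRUE,
                            loading_mode = c("exact", "one-decimal"),
                            seed = 1L) {
  if (!length(proxies)) stop("select at least one reserve proxy")
  if (!length(strata)) stop("select at least one stratum")
  proxies <- match.arg(proxies, several.ok = TRUE)
  strata <- match.arg(strata, several.ok = TRUE)
  tertile_boundaries <- match.arg(tertile_boundaries)
  link <- match.arg(link)
  loading_mode <- match.arg(loading_mode)
  if (gh_points < 1) stop("gh_points must be >= 1")
  if (!is.null(scenario)) scenario$seed <- as.integer(seed)
  structure(list(output_dir = output_dir, scenario = scenario, data = data,
                 input_csv = input_csv, proxies = proxies, strata = strata,
                 tertile_boundaries = tertile_boundaries, link = link,
                 gh_points = as.integer(gh_points),
                 residual_cross = residual_cross,
                 joint_survival = joint_survival,
                 loading_mode = loading_mode, seed = as.integer(seed)),
            class = "pipeline_config")
}

# proxy -> (z-scored covariate column, grouping column) used downstream
.proxy_columns <- function(proxy) {
  switch(proxy,
         dart = list(z = "dart_z", group = "dart_tertile"),
         education = list(z = "edu_z", group = "edu_cat"),
         icv = list(z = "icv_z", group = "icv_tertile"),
         bpf = list(z = "bpf_base_z", group = "bpf_tertile"),
         stop("unknown proxy: ", proxy))
}

#' Preprocess a cohort for the reserve analyses
#'
#' Derives every analysis column the models need, all frozen against the
#' baseline rows of the sample at hand: z-scored DART and education level,
#' sex-stratified ICV z-scores, the baseline brain-volume (BPF) z-score
#' carried as a subject-level covariate, mid-life/late-life age groups from
#' the midpoint-age rule, tertile (or education-category) group labels, and
#' centered demographic covariates. If raw memory test columns are present
#' and no `memory` column is, the memory composite is built first.
#'
#' Values outside a fixed tertile boundary's admissible range are clamped to
#' its edge before binning; the count of clamped values is returned so it
#' can be surfaced in the run manifest.
#'
#' @param data long-format cohort (one row per subject-visit) with baseline
#'   covariates `age`, `sex`, `stroke`, `dart`, `edu_level`, `icv_ml` and the
#'   outcome columns `memory` and `brain_bpf`.
#' @param tertile_boundaries passed to [assign_tertile()].
#' @return List with `data` (augmented cohort), `references` (the frozen
#'   [std_reference()]s), and `n_clamped`.
#' @export
preprocess_cohort <- function(data, tertile_boundaries = "paper-fixed") {
  data <- as.data.frame(data)
  validate_cohort(data)
  if (!"memory" %in% names(data) &&
      all(c("wlt_total_recall", "wlt_delayed_recall", "rey_delayed_recall") %in% names(data))) {
    mc <- memory_composite(data)
    data$memory <- mc$score
  }
  need <- c("subject_id", "visit_order", "time_in_study", "memory", "brain_bpf",
            "age", "sex", "stroke", "dart", "edu_level", "icv_ml")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))

  base <- data[data$visit_order == 0, , drop = FALSE]
  if (!nrow(base)) stop("cohort has no baseline (visit_order == 0) rows")

  refs <- list(
    dart = std_reference(base, "dart"),
    edu = std_reference(transform(base, edu_num = as.numeric(edu_level)), "edu_num"),
    icv = std_reference(base, "icv_ml", by = "sex"),
    bpf = std_reference(base, "brain_bpf")
  )
  data$dart_z <- apply_reference(data$dart, "dart", refs$dart)
  data$edu_z <- apply_reference(as.numeric(data$edu_level), "edu_num", refs$edu)
  data$icv_z <- standardize_icv_by_sex(data$icv_ml, data$sex, refs$icv)
  # baseline BPF as a subject-level (time-invariant) reserve proxy
  bz <- apply_reference(base$brain_bpf, "brain_bpf", refs$bpf)
  data$bpf_base_z <- bz[match(data$subject_id, base$subject_id)]
  data$edu_cat <- categorize_education(data$edu_level)

  # age group from the midpoint of each subject's observed follow-up
  fup <- tapply(data$time_in_study, data$subject_id, max)
  fup <- fup[match(as.character(data$subject_id), names(fup))]
  data$age_group <- assign_age_group(data$age, as.numeric(fup))

  clamp <- function(x, measure) {
    rng <- .tertile_bounds[[measure]]$range
    pmin(rng[2], pmax(rng[1], x))
  }
  n_clamped <- 0L
  if (tertile_boundaries == "paper-fixed") {
    for (m in c("icv", "bpf")) {
      col <- if (m == "icv") data$icv_z else data$bpf_base_z
      rng <- .tertile_bounds[[m]]$range
      n_clamped <- n_clamped + sum(col < rng[1] | col > rng[2], na.rm = TRUE)
    }
    data$dart_tertile <- assign_tertile(clamp(data$dart, "dart"), "dart")
    data$icv_tertile <- assign_tertile(clamp(data$icv_z, "icv"), "icv")
    data$bpf_tertile <- assign_tertile(clamp(data$bpf_base_z, "bpf"), "bpf")
  } else {
    bsub <- !duplicated(data$subject_id)
    qcut <- function(x) {
      q <- quantile(x[bsub], c(1, 2) / 3, na.rm = TRUE, type = 7)
      factor(ifelse(x <= q[1], "low", ifelse(x <= q[2], "mid", "high")),
             levels = c("low", "mid", "high"))
    }
    data$dart_tertile <- qcut(data$dart)
    data$icv_tertile <- qcut(data$icv_z)
    data$bpf_tertile <- qcut(data$bpf_base_z)
  }
  data <- center_covariates(data, c("age", "sex", "stroke"))
  list(data = data, references = refs, n_clamped = n_clamped)
}

# model specs used by the pipeline stages ------------------------------------

.univariate_spec <- function(proxy_z, loading_mode = "exact") {
  growth_spec(outcomes = "memory",
              intercept_covariates = unique(c("age_c", "sex_c", "stroke_c", proxy_z)),
              slope_covariates = unique(c("age_c", proxy_z)),
              practice_on = "memory", include_survival = FALSE,
              loading_mode = loading_mode)
}

.bivariate_spec <- function(include_survival, residual_cross = TRUE,
                            link = "logit", loading_mode = "exact",
                            grouping = NULL) {
  growth_spec(outcomes = c("memory", "brain"),
              intercept_covariates = list(memory = c("age_c", "sex_c", "stroke_c"),
                                          brain = c("age_c", "sex_c", "stroke_c")),
              slope_covariates = list(memory = "age_c", brain = "age_c"),
              practice_on = "memory", residual_cross = residual_cross,
              include_survival = include_survival, link = link,
              loading_mode = loading_mode, grouping = grouping)
}

# ---- stages -----------------------------------------------------------------

.stage_simulate <- function(config, paths) {
  sim <- simulate_cohort(config$scenario)
  write_cohort(sim, dirname(paths$cohort))
  sim$data
}

.stage_preprocess <- function(config, cohort, paths) {
  pp <- preprocess_cohort(cohort, config$tertile_boundaries)
  write.csv(pp$data, paths$analysis, row.names = FALSE)
  pp
}

.stage_fit <- function(config, adata, paths) {
  rows <- list()
  fits <- list()
  for (proxy in config$proxies) {
    pc <- .proxy_columns(proxy)
    spec <- .univariate_spec(pc$z, config$loading_mode)
    for (stratum in config$strata) {
      d <- if (stratum == "overall") adata else adata[adata$age_group == stratum, , drop = FALSE]
      if (!nrow(d)) stop("stratum '", stratum, "' is empty")
      fit <- fit_growth(d, spec, group_label = paste(proxy, stratum, sep = "/"))
      fits[[paste(proxy, stratum, sep = "/")]] <- fit
      td <- tidy_fit(fit)
      for (what in c("intercept", "slope")) {
        par <- paste0("beta.memory.", what, ".", pc$z)
        r <- td[td$parameter == par, , drop = FALSE]
        rows[[length(rows) + 1L]] <- data.frame(
          proxy = proxy, stratum = stratum, effect_on = what,
          n_subjects = fit$n_subjects, estimate = r$estimate, se = r$se,
          ci_lo = r$ci_lo, ci_hi = r$ci_hi, p = r$p, converged = fit$converged)
      }
    }
  }
  tab2 <- do.call(rbind, rows)
  write.csv(tab2, paths$table2, row.names = FALSE)

  # one bivariate model for the overall sample (joint with survival when
  # configured and the cohort records deaths)
  joint <- config$joint_survival && "died_in_next_interval" %in% names(adata)
  bspec <- .bivariate_spec(joint, config$residual_cross, config$link,
                           config$loading_mode)
  brule <- if (joint) gh_rule(config$gh_points, length(bspec$hazard_factors)) else NULL
  bfit <- fit_growth(adata, bspec, rule = brule, group_label = "overall")
  td <- tidy_fit(bfit)
  keep <- c("alpha.memory.slope", "alpha.brain.slope",
            "psi.brain.slope.memory.slope")
  bt <- td[td$parameter %in% keep, , drop = FALSE]
  dB <- wald_test(bfit, c(alpha.memory.slope = 1, alpha.brain.slope = -1))
  dB_se <- (dB$ci[2] - dB$estimate) / qnorm(0.975)
  bt <- rbind(bt, data.frame(parameter = "dB", estimate = dB$estimate,
                             se = dB_se, ci_lo = dB$ci[1], ci_hi = dB$ci[2],
                             z = NA_real_, p = dB$p_value))
  bt$n_subjects <- bfit$n_subjects
  bt$joint_survival <- joint
  bt$converged <- bfit$converged
  write.csv(bt, paths$bivariate, row.names = FALSE)
  list(table2 = tab2, bivariate = bt, fits = fits, bivariate_fit = bfit)
}

.stage_compare_groups <- function(config, adata, paths) {
  gtab <- list()
  wtab <- list()
  for (proxy in config$proxies) {
    pc <- .proxy_columns(proxy)
    spec <- .bivariate_spec(FALSE, config$residual_cross, config$link,
                            config$loading_mode, grouping = pc$group)
    mg <- multiple_group_fit(adata, spec)
    for (g in names(mg$fits)) {
      f <- mg$fits[[g]]
      e <- f$estimates
      se <- sqrt(pmax(diag(f$vcov), 0))
      dB <- wald_test(f, c(alpha.memory.slope = 1, alpha.brain.slope = -1))
      gtab[[length(gtab) + 1L]] <- data.frame(
        proxy = proxy, group = g, n_subjects = f$n_subjects,
        memory_intercept = e[["alpha.memory.intercept"]],
        memory_slope = e[["alpha.memory.slope"]],
        memory_slope_se = se[["alpha.memory.slope"]],
        brain_intercept = e[["alpha.brain.intercept"]],
        brain_slope = e[["alpha.brain.slope"]],
        brain_slope_se = se[["alpha.brain.slope"]],
        slope_cov = e[["psi.brain.slope.memory.slope"]],
        practice_mean = e[["practice.mean"]],
        dB = dB$estimate, dB_ci_lo = dB$ci[1], dB_ci_hi = dB$ci[2],
        dB_p = dB$p_value, converged = f$converged)
    }
    cons <- standard_contrasts(mg)
    for (cn in names(cons)) {
      w <- wald_test(mg, cons[[cn]])
      wtab[[length(wtab) + 1L]] <- data.frame(
        proxy = proxy, contrast = cn, estimate = w$estimate,
        statistic = w$statistic, df = w$df, p = w$p_value,
        ci_lo = if (w$df == 1L) w$ci[1] else NA_real_,
        ci_hi = if (w$df == 1L) w$ci[2] else NA_real_)
    }
  }
  gtab <- do.call(rbind, gtab)
  wtab <- do.call(rbind, wtab)
  write.csv(gtab, paths$table3, row.names = FALSE)
  write.csv(wtab, paths$wald, row.names = FALSE)
  list(table3 = gtab, wald = wtab)
}

.stage_report <- function(config, paths, stage_log) {
  tab3 <- read.csv(paths$table3)
  figures <- character()
  for (proxy in unique(tab3$proxy)) {
    d <- tab3[tab3$proxy == proxy, , drop = FALSE]
    times <- seq(0, 12, by = 0.25)
    lamv <- practice_loading(0:2, config$loading_mode)
    traj <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
      data.frame(group = d$group[i], time = times,
                 memory = d$memory_intercept[i] + d$memory_slope[i] * times,
                 brain = d$brain_intercept[i] + d$brain_slope[i] * times)
    }))
    long <- rbind(
      data.frame(group = traj$group, time = traj$time, outcome = "memory",
                 value = traj$memory),
      data.frame(group = traj$group, time = traj$time, outcome = "brain",
                 value = traj$brain))
    long$group <- factor(long$group, levels = d$group)
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                            color = .data$group)) +
      ggplot2::geom_line(linewidth = 0.9) +
      ggplot2::facet_wrap(~outcome, scales = "free_y") +
      ggplot2::labs(title = paste0("Model-implied trajectories by ", proxy, " group"),
                    x = "Time in study (years)", y = "Standardized score",
                    color = proxy) +
      ggplot2::theme_minimal()
    for (ext in c("png", "svg")) {
      fp <- file.path(paths$figdir, paste0("trajectories_", proxy, ".", ext))
      ok <- tryCatch({
        if (ext == "png") {
          grDevices::png(fp, width = 1600, height = 800, res = 160)
        } else {
          grDevices::svg(fp, width = 10, height = 5)
        }
        print(p)
        grDevices::dev.off()
        TRUE
      }, error = function(e) {
        try(grDevices::dev.off(), silent = TRUE)
        FALSE
      })
      if (ok) figures <- c(figures, fp)
    }
  }

  outputs <- Filter(file.exists, unlist(paths[c("cohort", "truth", "analysis",
                                                "table2", "bivariate",
                                                "table3", "wald")]))
  cfg_hash <- rlang::hash(list(proxies = config$proxies, strata = config$strata,
                               tertile_boundaries = config$tertile_boundaries,
                               link = config$link, gh_points = config$gh_points,
                               residual_cross = config$residual_cross,
                               joint_survival = config$joint_survival,
                               loading_mode = config$loading_mode,
                               seed = config$seed,
                               scenario = if (is.null(config$data) && is.null(config$input_csv))
                                 unclass(config$scenario) else NULL))
  manifest <- list(
    package = "growsurv",
    package_version = as.character(utils::packageVersion("growsurv")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = cfg_hash,
    stages = stage_log,
    outputs = basename(unname(outputs)),
    figures = basename(figures))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest
}

.pipeline_paths <- function(output_dir) {
  list(datadir = file.path(output_dir, "data"),
       resdir = file.path(output_dir, "results"),
       figdir = file.path(output_dir, "figures"),
       cohort = file.path(output_dir, "data", "cohort.csv"),
       truth = file.path(output_dir, "data", "ground_truth.json"),
       analysis = file.path(output_dir, "data", "analysis.csv"),
       table2 = file.path(output_dir, "results", "table2_univariate.csv"),
       bivariate = file.path(output_dir, "results", "bivariate_joint.csv"),
       table3 = file.path(output_dir, "results", "table3_groups.csv"),
       wald = file.path(output_dir, "results", "wald_comparisons.csv"),
       manifest = file.path(output_dir, "results", "manifest.json"),
       log = file.path(output_dir, "pipeline.log"))
}

#' Run the full reserve analysis pipeline
#'
#' Executes, in order: `simulate` (skipped when the config carries data),
#' `preprocess`, `fit` (univariate reserve models per proxy and stratum, plus
#' the bivariate joint model), `compare-groups` (tertile/education
#' multiple-group models with Wald comparisons), and `report` (figures and a
#' JSON manifest). Every stage persists its outputs under the configured
#' output directory, a failing stage aborts with its name, and with
#' `resume = TRUE` stages whose outputs already exist are skipped and their
#' intermediates reloaded, so a run is restartable from any completed stage.
#'
#' @param config a [pipeline_config()].
#' @param stages stages to run (in pipeline order).
#' @param resume reuse existing stage outputs instead of recomputing them.
#' @return List with the result tables, the manifest, and the fitted models
#'   (invisible).
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "preprocess", "fit",
                                    "compare-groups", "report"),
                         resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "preprocess", "fit", "compare-groups", "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  paths <- .pipeline_paths(config$output_dir)
  for (d in c(config$output_dir, paths$datadir, paths$resdir, paths$figdir))
    dir.create(d, showWarnings = FALSE, recursive = TRUE)

  logline <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ..., "\n", sep = "",
        file = paths$log, append = TRUE)
  }
  stage_log <- list()
  res <- list()

  run_stage <- function(name, outputs_exist, runner, loader) {
    if (!(name %in% stages)) {
      if (outputs_exist()) return(loader())
      return(NULL)
    }
    if (resume && outputs_exist()) {
      logline("stage ", name, ": resumed from existing outputs")
      stage_log[[name]] <<- list(status = "resumed")
      return(loader())
    }
    t0 <- proc.time()[3]
    out <- tryCatch(runner(), error = function(e) {
      logline("stage ", name, " FAILED: ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    dt <- round(proc.time()[3] - t0, 2)
    logline("stage ", name, ": done in ", dt, " s")
    stage_log[[name]] <<- list(status = "run", wall_time_s = dt)
    out
  }

  set.seed(config$seed)

  # simulate (or take the provided cohort)
  cohort <- NULL
  if (!is.null(config$data)) {
    cohort <- as.data.frame(config$data)
  } else if (!is.null(config$input_csv)) {
    cohort <- read.csv(config$input_csv)
  } else {
    cohort <- run_stage("simulate",
                        function() file.exists(paths$cohort),
                        function() .stage_simulate(config, paths),
                        function() read.csv(paths$cohort))
  }
  preprocess_runs <- "preprocess" %in% stages &&
    !(resume && file.exists(paths$analysis))
  if (is.null(cohort) && preprocess_runs)
    stop("no cohort available: run the 'simulate' stage or supply data")

  pp <- run_stage("preprocess",
                  function() file.exists(paths$analysis),
                  function() .stage_preprocess(config, cohort, paths),
                  function() list(data = read.csv(paths$analysis), n_clamped = NA))
  if (is.null(pp) && any(c("fit", "compare-groups") %in% stages))
    stop("no preprocessed data available: run the 'preprocess' stage")
  adata <- NULL
  if (!is.null(pp)) {
    adata <- pp$data
    # CSV round trips drop factor levels; restore the canonical orders
    tlev <- c("low", "mid", "high")
    for (cc in c("dart_tertile", "icv_tertile", "bpf_tertile"))
      if (is.character(adata[[cc]])) adata[[cc]] <- factor(adata[[cc]], levels = tlev)
    if (is.character(adata$edu_cat))
      adata$edu_cat <- factor(adata$edu_cat,
                              levels = c("less than high school", "high school",
                                         "college/university"))
  }

  res$fit <- run_stage("fit",
                       function() file.exists(paths$table2) && file.exists(paths$bivariate),
                       function() .stage_fit(config, adata, paths),
                       function() list(table2 = read.csv(paths$table2),
                                       bivariate = read.csv(paths$bivariate)))

  res$groups <- run_stage("compare-groups",
                          function() file.exists(paths$table3) && file.exists(paths$wald),
                          function() .stage_compare_groups(config, adata, paths),
                          function() list(table3 = read.csv(paths$table3),
                                          wald = read.csv(paths$wald)))

  res$manifest <- run_stage("report",
                            function() file.exists(paths$manifest),
                            function() .stage_report(config, paths, stage_log),
                            function() jsonlite::read_json(paths$manifest))

  res$paths <- paths
  res$config <- config
  invisible(res)
}

#' Command-line entry point for the pipeline
#'
#' Dispatches the CLI verbs to [run_pipeline()] stages: `simulate`,
#' `preprocess`, `fit`, `compare-groups`, `report` run that single stage
#' (resuming earlier stages from disk); `replicate-design` runs the full
#' pipeline. Arguments: `--config <yaml>` (a file of [pipeline_config()]
#' fields; scenario fields under `scenario:`), `--out <dir>` (overrides the
#' output directory), `--seed <int>`.
#'
#' @param args character vector (default: the command line).
#' @return The [run_pipeline()] result, invisibly.
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: <verb> [--config file.yaml] [--out dir] [--seed n]")
  verb <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i[1] < length(args)) args[i[1] + 1] else default
  }
  cfg_path <- opt("--config")
  cfg_args <- list()
  if (!is.null(cfg_path)) {
    y <- yaml::read_yaml(cfg_path)
    if (!is.null(y$scenario)) y$scenario <- do.call(sim_scenario, y$scenario)
    cfg_args <- y
  }
  out <- opt("--out")
  if (!is.null(out)) cfg_args$output_dir <- out
  if (is.null(cfg_args$output_dir)) stop("an output directory is required (--out or config)")
  seed <- opt("--seed")
  if (!is.null(seed)) cfg_args$seed <- as.integer(seed)
  config <- do.call(pipeline_config, cfg_args)

  verbs <- c(simulate = "simulate", preprocess = "preprocess", fit = "fit",
             `compare-groups` = "compare-groups", report = "report")
  if (verb == "replicate-design") {
    return(invisible(run_pipeline(config)))
  }
  if (!verb %in% names(verbs)) {
    stop("unknown verb '", verb, "'; use one of: ",
         paste(c(names(verbs), "replicate-design"), collapse = ", "))
  }
  invisible(run_pipeline(config, stages = verbs[[verb]], resume = TRUE))
}
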