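#' Baseline standardization reference
#'
#' Means and SDs of the listed variables computed from the baseline rows of
#' the analysis sample, optionally within strata (e.g., intracranial volume
#' within men and within women). The reference is computed once and frozen:
#' applying it to later waves never changes it, and every standardization is
#' invertible given the stored reference.
#'
#' @param data data frame of baseline rows.
#' @param vars variable names to reference.
#' @param by optional stratification column (e.g., `"sex"`).
#' @return An object of class `std_reference`.
#' @export
std_reference <- function(data, vars, by = NULL) {
  data <- as.data.frame(data)
  one <- function(d) {
    m <- vapply(vars, function(v) mean(d[[v]], na.rm = TRUE), numeric(1))
    s <- vapply(vars, function(v) sd(d[[v]], na.rm = TRUE), numeric(1))
    bad <- !is.finite(s) | s <= 0
    if (any(bad))
      stop("zero or undefined baseline SD for: ", paste(vars[bad], collapse = ", "))
    list(mean = m, sd = s)
  }
  if (is.null(by)) {
    ref <- list(pooled = one(data))
  } else {
    sp <- split(data, data[[by]])
    if (any(vapply(sp, nrow, 1L) < 2))
      stop("stratum of '", by, "' with fewer than 2 subjects: SD undefined")
    ref <- lapply(sp, one)
  }
  structure(list(ref = ref, vars = vars, by = by), class = "std_reference")
}

#' @export
print.std_reference <- function(x, ...) {
  cat("Baseline standardization reference for:", paste(x$vars, collapse = ", "))
  if (!is.null(x$by)) cat("  (within", x$by, ")")
  cat("\n")
  for (g in names(x$ref))
    cat("  ", g, ": mean = ", paste(signif(x$ref[[g]]$mean, 5), collapse = ", "),
        "; sd = ", paste(signif(x$ref[[g]]$sd, 5), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Apply a frozen standardization reference
#'
#' Z-scores values against the stored baseline mean and SD of `var` (within
#' `stratum` for stratified references). The inverse transform is
#' `z * sd + mean` with the stored reference values.
#'
#' @param x values to standardize.
#' @param var variable name in the reference.
#' @param ref a [std_reference()].
#' @param stratum per-value stratum (required for stratified references).
#' @return Numeric z-scores.
#' @export
apply_reference <- function(x, var, ref, stratum = NULL) {
  if (is.null(ref$by)) {
    r <- ref$ref$pooled
    (x - r$mean[[var]]) / r$sd[[var]]
  } else {
    if (is.null(stratum)) stop("reference is stratified by '", ref$by, "'")
    out <- rep(NA_real_, length(x))
    for (g in names(ref$ref)) {
      idx <- as.character(stratum) == g
      out[idx] <- (x[idx] - ref$ref[[g]]$mean[[var]]) / ref$ref[[g]]$sd[[var]]
    }
    out
  }
}

#' Write / read a standardization reference as JSON
#' @param ref a [std_reference()].
#' @param path file path.
#' @return `read_reference` returns a `std_reference`.
#' @export
write_reference <- function(ref, path) {
  x <- unclass(ref)
  # keep variable names for length-1 vectors under auto_unbox
  x$ref <- lapply(x$ref, function(r) list(mean = as.list(r$mean),
                                          sd = as.list(r$sd)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$ref <- lapply(x$ref, function(r) list(mean = unlist(r$mean), sd = unlist(r$sd)))
  structure(list(ref = x$ref, vars = x$vars, by = x$by %||% NULL),
            class = "std_reference")
}

#' Memory composite score
#'
#' The domain score for memory is a composite of three tests: total recall
#' and delayed recall on the 15-word learning test, and delayed recall of the
#' Rey-Osterrieth Complex Figure. Each raw test score at every wave is
#' z-scored against the test's baseline mean and SD in the analysis sample;
#' the three z-scores are averaged; and the average is re-standardized
#' against its own baseline mean and SD, so the baseline composite has mean 0
#' and SD 1 by construction.
#'
#' A visit's composite is computed from the observed tests' mean when at
#' least `min_tests` of the three are observed, and is missing otherwise
#' (preserving full-information sample size downstream).
#'
#' @param data subject-visit table with the three raw test columns and
#'   `visit_order`.
#' @param tests the three raw score column names.
#' @param ref optional frozen reference from a previous call (its `composite`
#'   entry re-standardizes new data); by default computed from the
#'   `visit_order == 0` rows of `data`.
#' @param min_tests minimum observed tests per visit (default 2).
#' @return List with `score` (numeric per row) and `ref` (a frozen list of
#'   [std_reference()]s: per-test and for the composite).
#' @export
memory_composite <- function(data,
                             tests = c("wlt_total_recall", "wlt_delayed_recall",
                                       "rey_delayed_recall"),
                             ref = NULL, min_tests = 2L) {
  data <- as.data.frame(data)
  if (is.null(ref)) {
    base <- data[data$visit_order == 0, , drop = FALSE]
    if (!nrow(base)) stop("no baseline (visit_order == 0) rows to build the reference")
    test_ref <- std_reference(base, tests)
    z <- sapply(tests, function(v) apply_reference(base[[v]], v, test_ref))
    avg <- rowMeans(z, na.rm = TRUE)
    nobs <- rowSums(!is.na(z))
    avg[nobs < min_tests] <- NA
    comp_ref <- std_reference(data.frame(avg = avg), "avg")
    ref <- list(tests = test_ref, composite = comp_ref)
  }
  z <- sapply(tests, function(v) apply_reference(data[[v]], v, ref$tests))
  z <- matrix(z, nrow = nrow(data))
  avg <- rowMeans(z, na.rm = TRUE)
  nobs <- rowSums(!is.na(z))
  avg[nobs < min_tests] <- NA
  list(score = apply_reference(avg, "avg", ref$composite), ref = ref)
}

#' Brain parenchymal fraction
#'
#' BPF is total brain volume divided by intracranial volume: the volumetric
#' status of the brain, tracked over visits as a global atrophy measure.
#'
#' @param brain_volume_ml total brain volume (> 0).
#' @param icv_ml intracranial volume (>= brain volume).
#' @return BPF in (0, 1].
#' @export
#' @examples
#' round(compute_bpf(1154.3, 1461.2), 2)  # 0.79
compute_bpf <- function(brain_volume_ml, icv_ml) {
  if (any(brain_volume_ml <= 0, na.rm = TRUE) || any(icv_ml <= 0, na.rm = TRUE))
    stop("volumes must be positive")
  if (any(icv_ml < brain_volume_ml, na.rm = TRUE))
    stop("icv_ml must be >= brain_volume_ml")
  brain_volume_ml / icv_ml
}

#' @rdname compute_bpf
#' @param bpf BPF series (fraction scale).
#' @param ref [std_reference()] built on baseline BPF (variable `"bpf"`).
#' @return `standardize_bpf`: z-scores against the baseline mean/SD at every
#'   wave.
#' @export
standardize_bpf <- function(bpf, ref) {
  apply_reference(bpf, "bpf", ref)
}

#' Sex-stratified intracranial volume z-score
#'
#' Head size differs between men and women, so ICV is standardized
#' separately within each sex: each subject's ICV minus their sex's reference
#' mean, divided by that sex's reference SD.
#'
#' @param icv_ml intracranial volumes.
#' @param sex stratum per subject (coded as in the reference).
#' @param ref [std_reference()] with `by = "sex"` on variable `"icv_ml"`.
#' @return z-scores with mean 0 / SD 1 within each sex of the reference
#'   sample.
#' @export
standardize_icv_by_sex <- function(icv_ml, sex, ref) {
  if (is.null(ref$by)) stop("reference must be stratified by sex")
  apply_reference(icv_ml, "icv_ml", ref, stratum = sex)
}

#' Mid-life versus late-life age group
#'
#' Classified by the age at the middle of the subject's time in the study:
#' `baseline_age + time_in_study / 2`. A midpoint age of 60 or above is
#' late-life (ties go to late-life).
#'
#' @param baseline_age age in years at the first visit (> 0).
#' @param time_in_study total follow-up in years (>= 0).
#' @param cutoff midpoint-age cutoff (default 60).
#' @return `"mid-life"` or `"late-life"` (vectorized).
#' @export
#' @examples
#' assign_age_group(c(50.5, 65.2, 58), c(4, 0, 4))
assign_age_group <- function(baseline_age, time_in_study, cutoff = 60) {
  if (any(baseline_age <= 0)) stop("baseline_age must be > 0")
  if (any(time_in_study < 0)) stop("time_in_study must be >= 0")
  ifelse(baseline_age + time_in_study / 2 >= cutoff, "late-life", "mid-life")
}

# fixed tertile boundaries; intervals are left-open / right-closed
.tertile_bounds <- list(
  dart = list(range = c(35, 100), upper = c(75, 89, 100)),
  icv = list(range = c(-2.66, 3.29), upper = c(-0.46, 0.40, 3.29)),
  bpf = list(range = c(-3.65, 2.91), upper = c(-0.37, 0.51, 2.91))
)

#' Reserve tertile assignment
#'
#' Fixed low/mid/high boundaries per reserve proxy: DART 35-75 / 76-89 /
#' 90-100 (raw score); ICV z-score up to -.46 / to .40 / to 3.29; baseline
#' BPF z-score up to -.37 / to .51 / to 2.91. Intervals are left-open,
#' right-closed, so the three bins partition the admissible range without
#' gaps or overlaps. `boundaries = "data"` computes sample tertiles instead
#' (ties to the lower bin).
#'
#' @param value values to bin (raw DART; z-scores for ICV/BPF).
#' @param measure `"dart"`, `"icv"` or `"bpf"`.
#' @param boundaries `"paper-fixed"` (default) or `"data"`.
#' @return Factor with levels `low`, `mid`, `high`.
#' @export
#' @examples
#' assign_tertile(c(75, 76, 90), "dart")
#' assign_tertile(c(0.40, 0.41), "icv")
assign_tertile <- function(value, measure = c("dart", "icv", "bpf"),
                           boundaries = c("paper-fixed", "data")) {
  measure <- match.arg(measure)
  boundaries <- match.arg(boundaries)
  if (boundaries == "paper-fixed") {
    b <- .tertile_bounds[[measure]]
    ok <- is.na(value) | (value >= b$range[1] & value <= b$range[2])
    if (!all(ok))
      stop(measure, " value outside the admissible range [",
           b$range[1], ", ", b$range[2], "]: ", value[!ok][1])
    lab <- ifelse(value <= b$upper[1], "low",
                  ifelse(value <= b$upper[2], "mid", "high"))
  } else {
    q <- quantile(value, c(1, 2) / 3, na.rm = TRUE, type = 7)
    lab <- ifelse(value <= q[1], "low", ifelse(value <= q[2], "mid", "high"))
  }
  factor(lab, levels = c("low", "mid", "high"))
}

#' Education in three categories
#'
#' Maps the 7 ordered levels of the Dutch educational system to less than
#' high school (levels 1-2), at least some high school (3-5), and a
#' college/university degree (6-7). The split points are configurable.
#'
#' @param level integer education level, 1-7.
#' @param split upper levels of the first two categories (default `c(2, 5)`).
#' @return Factor with levels `less than high school`, `high school`,
#'   `college/university`.
#' @export
categorize_education <- function(level, split = c(2L, 5L)) {
  bad <- !is.na(level) & (level < 1 | level > 7 | level != round(level))
  if (any(bad)) stop("education level outside 1..7: ", level[bad][1])
  lab <- ifelse(level <= split[1], "less than high school",
                ifelse(level <= split[2], "high school", "college/university"))
  factor(lab, levels = c("less than high school", "high school",
                         "college/university"))
}

#' Center covariates on the analysis sample
#'
#' Subtracts each listed covariate's sample mean so model intercept effects
#' read as effects for an average participant. Constant covariates are
#' centered to 0 with a warning. Re-centering is idempotent.
#'
#' @param data data frame.
#' @param vars covariate columns (numeric or 0/1 dummies).
#' @param suffix appended to each centered column's name (default `"_c"`;
#'   use `""` to overwrite in place).
#' @return `data` with centered columns added (or overwritten).
#' @export
center_covariates <- function(data, vars, suffix = "_c") {
  for (v in vars) {
    x <- data[[v]]
    if (!is.numeric(x)) stop("covariate '", v, "' is not numeric")
    if (isTRUE(sd(x, na.rm = TRUE) == 0))
      warning("covariate '", v, "' is constant; centered to 0")
    data[[paste0(v, suffix)]] <- x - mean(x, na.rm = TRUE)
  }
  data
}
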