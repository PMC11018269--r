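#' Declare a latent growth curve model
#'
#' A `growth_spec` describes one model: which outcomes it follows over time,
#' which baseline covariates act on the latent intercept and slope of each
#' outcome, whether a practice-effect factor is attached to repeated cognitive
#' testing, and whether the longitudinal process is modeled jointly with a
#' discrete-time survival process for death-related attrition.
#'
#' Each outcome contributes two latent growth factors, an intercept and a
#' slope, with factor loadings `1` and `t_ij` (time in study, in years, which
#' may vary between subjects). The practice factor has fixed loadings equal to
#' the square root of the number of previous testing occasions (see
#' [practice_loading()]).
#'
#' @param outcomes character, one or both of `"memory"` and `"brain"`.
#' @param intercept_covariates,slope_covariates named list (one entry per
#'   outcome) of covariate column names acting on that outcome's intercept or
#'   slope; a plain character vector is recycled to every outcome.
#' @param practice_on outcomes carrying the practice-effect factor (default:
#'   memory only; brain volume has no retest analogue).
#' @param practice_variance_free logical; if `FALSE` (default) the practice
#'   factor is a pure fixed effect (variance fixed at 0), if `TRUE` its
#'   variance is estimated.
#' @param residual_cross logical; estimate the within-occasion residual
#'   covariance between the two outcomes (bivariate models only).
#' @param include_survival logical; adjust for informative censoring by death
#'   through the joint discrete-time survival submodel.
#' @param hazard_factors latent factors the discrete-time hazard is regressed
#'   on (default: the memory intercept and slope).
#' @param n_intervals number of inter-visit risk intervals (2 for the
#'   three-visit design: death can occur after visit 1 or visit 2).
#' @param link link for the discrete-time hazard, `"logit"` (default) or
#'   `"probit"`.
#' @param loading_mode `"exact"` uses sqrt(number of previous visits) for the
#'   practice loadings; `"one-decimal"` rounds them to one decimal place
#'   (0, 1, 1.4).
#' @param grouping optional column name for multiple-group estimation.
#' @param outcome_columns named map from outcome to data column (defaults:
#'   `memory -> "memory"`, `brain -> "brain_bpf"`).
#'
#' @return An object of class `growth_spec`.
#' @seealso [fit_growth()], [marginal_loglik()], [joint_loglik()]
#' @export
#' @examples
#' growth_spec(outcomes = "memory",
#'             intercept_covariates = c("age_c", "sex_c", "stroke_c", "dart_z"),
#'             slope_covariates = c("age_c", "dart_z"),
#'             include_survival = TRUE)
growth_spec <- function(outcomes = c("memory", "brain"),
                        intercept_covariates = character(),
                        slope_covariates = character(),
                        practice_on = "memory",
                        practice_variance_free = FALSE,
                        residual_cross = TRUE,
                        include_survival = FALSE,
                        hazard_factors = c("memory.intercept", "memory.slope"),
                        n_intervals = 2L,
                        link = c("logit", "probit"),
                        loading_mode = c("exact", "one-decimal"),
                        grouping = NULL,
                        outcome_columns = NULL) {
  outcomes <- match.arg(outcomes, c("memory", "brain"), several.ok = TRUE)
  if (anyDuplicated(outcomes)) stop("outcomes must be distinct")
  link <- match.arg(link)
  loading_mode <- match.arg(loading_mode)

  as_cov_list <- function(x) {
    if (is.list(x)) {
      out <- lapply(outcomes, function(o) as.character(x[[o]] %||% character()))
    } else {
      out <- rep(list(as.character(x)), length(outcomes))
    }
    names(out) <- outcomes
    out
  }
  intercept_covariates <- as_cov_list(intercept_covariates)
  slope_covariates <- as_cov_list(slope_covariates)

  practice_on <- intersect(practice_on, outcomes)
  default_cols <- c(memory = "memory", brain = "brain_bpf")
  cols <- default_cols[outcomes]
  if (!is.null(outcome_columns)) cols[names(outcome_columns)] <- outcome_columns

  fac <- as.vector(t(outer(outcomes, c("intercept", "slope"), paste, sep = ".")))
  if (include_survival) {
    if (!length(hazard_factors)) stop("include_survival = TRUE needs at least one hazard factor")
    hazard_factors <- match.arg(hazard_factors, fac, several.ok = TRUE)
  } else {
    hazard_factors <- character()
  }
  if (n_intervals < 1L) stop("n_intervals must be >= 1")

  structure(list(
    outcomes = outcomes,
    factors = fac,
    intercept_covariates = intercept_covariates,
    slope_covariates = slope_covariates,
    practice_on = practice_on,
    practice_variance_free = practice_variance_free,
    residual_cross = residual_cross && length(outcomes) == 2L,
    include_survival = include_survival,
    hazard_factors = hazard_factors,
    n_intervals = as.integer(n_intervals),
    link = link,
    loading_mode = loading_mode,
    grouping = grouping,
    outcome_columns = cols
  ), class = "growth_spec")
}

#' @export
print.growth_spec <- function(x, ...) {
  cat("Latent growth curve model spec\n")
  cat("  outcomes:  ", paste(x$outcomes, collapse = " + "), "\n")
  for (o in x$outcomes) {
    cat("  ", o, " intercept ~ ", paste(x$intercept_covariates[[o]], collapse = " + ") %|0|% "1",
        "; slope ~ ", paste(x$slope_covariates[[o]], collapse = " + ") %|0|% "1", "\n", sep = "")
  }
  if (length(x$practice_on))
    cat("  practice factor on:", paste(x$practice_on, collapse = ", "),
        if (x$practice_variance_free) "(variance free)" else "(variance fixed at 0)", "\n")
  if (x$include_survival)
    cat("  joint discrete-time survival (", x$link, " link), hazard ~ ",
        paste(x$hazard_factors, collapse = " + "), ", ", x$n_intervals,
        " risk intervals\n", sep = "")
  invisible(x)
}

# all covariate columns used by a spec, in stable order of first appearance
spec_covariates <- function(spec) {
  unique(unlist(c(spec$intercept_covariates, spec$slope_covariates), use.names = FALSE))
}

# logical n_factors x n_cov mask of free covariate -> factor paths
spec_beta_mask <- function(spec) {
  cn <- spec_covariates(spec)
  m <- matrix(FALSE, length(spec$factors), length(cn),
              dimnames = list(spec$factors, cn))
  for (o in spec$outcomes) {
    m[paste0(o, ".intercept"), spec$intercept_covariates[[o]]] <- TRUE
    m[paste0(o, ".slope"), spec$slope_covariates[[o]]] <- TRUE
  }
  m
}

#' Serialize / read a model spec as YAML
#'
#' @param spec a [growth_spec()].
#' @param path file path.
#' @return `read_spec` returns a `growth_spec`.
#' @export
write_spec <- function(spec, path) {
  x <- unclass(spec)
  x$factors <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(growth_spec, x[setdiff(names(x), "outcome_columns")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
`%|0|%` <- function(a, b) if (length(a) == 0 || !nzchar(a)) b else a
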