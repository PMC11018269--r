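#' Wald test for linear parameter constraints
#'
#' Tests `L theta = 0` (or `= null`) with the chi-square statistic
#' `(L theta - null)' (L V L')^{-1} (L theta - null)`, degrees of freedom
#' equal to the rank of `L`, and the p-value from the upper tail. For a
#' rank-1 contrast the signed estimate with its delta-method 95% confidence
#' interval is also returned — the form used to report a difference in rates
#' of change such as `dB = slope(memory) - slope(brain)`.
#'
#' @param fit a `growsurv_fit` or `growsurv_mgfit` (multiple-group fit; its
#'   stacked estimates are named `<group>|<parameter>`).
#' @param contrast a named numeric vector (one contrast) or a matrix with
#'   one contrast per row, columns named after (a subset of) the parameters.
#' @param null hypothesized value(s) of the contrast(s) (default 0).
#' @param level confidence level for the rank-1 interval.
#' @return An object of class `wald_result`: `contrast`, `estimate`,
#'   `statistic`, `df`, `p_value`, and `ci` (rank-1 only).
#' @export
wald_test <- function(fit, contrast, null = 0, level = 0.95) {
  est <- stacked_estimates(fit)
  V <- stacked_vcov(fit)
  if (is.null(dim(contrast))) contrast <- t(as.matrix(contrast))
  if (is.null(colnames(contrast)))
    stop("contrast must have parameter names as column names")
  miss <- setdiff(colnames(contrast), names(est))
  if (length(miss))
    stop("contrast names not in the estimate vector: ", paste(miss, collapse = ", "))
  if (anyDuplicated(colnames(contrast))) {
    # repeated names add up, so a parameter contrasted with itself cancels
    contrast <- t(rowsum(t(contrast), colnames(contrast), reorder = FALSE))
  }
  L <- matrix(0, nrow(contrast), length(est),
              dimnames = list(rownames(contrast), names(est)))
  L[, colnames(contrast)] <- contrast
  if (all(L == 0)) {
    return(structure(list(contrast = L, estimate = 0, statistic = 0,
                          df = 0L, p_value = 1, ci = NULL, level = level),
                     class = "wald_result"))
  }
  r <- as.vector(L %*% est) - null
  M <- L %*% V %*% t(L)
  qr_ <- qr(M)
  if (qr_$rank < nrow(L)) {
    dep <- setdiff(seq_len(nrow(L)), qr_$pivot[seq_len(qr_$rank)])
    stop("singular contrast covariance; redundant contrast row(s): ",
         paste(dep, collapse = ", "))
  }
  stat <- as.numeric(crossprod(r, solve(M, r)))
  df <- nrow(L)
  ci <- NULL
  if (df == 1L) {
    se <- sqrt(M[1, 1])
    zq <- qnorm(1 - (1 - level) / 2)
    ci <- c(lower = r + null - zq * se, upper = r + null + zq * se)
  }
  structure(list(contrast = L[, colSums(L != 0) > 0, drop = FALSE],
                 estimate = if (df == 1L) as.numeric(r + null) else as.vector(L %*% est),
                 statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 ci = ci, level = level),
            class = "wald_result")
}

#' @export
print.wald_result <- function(x, ...) {
  cat("Wald test (df = ", x$df, "): chi-square = ", format(x$statistic, digits = 5),
      ", p = ", format.pval(x$p_value, digits = 3), "\n", sep = "")
  if (x$df == 1L)
    cat("  estimate = ", format(x$estimate, digits = 4), "  ",
        100 * x$level, "% CI [", format(x$ci[1], digits = 4), ", ",
        format(x$ci[2], digits = 4), "]\n", sep = "")
  invisible(x)
}

stacked_estimates <- function(fit) {
  if (inherits(fit, "growsurv_fit")) return(fit$estimates)
  if (inherits(fit, "growsurv_mgfit")) return(fit$estimates)
  stop("fit must be a growsurv_fit or growsurv_mgfit")
}

stacked_vcov <- function(fit) {
  if (inherits(fit, "growsurv_fit")) return(fit$vcov)
  if (inherits(fit, "growsurv_mgfit")) return(fit$vcov)
  stop("fit must be a growsurv_fit or growsurv_mgfit")
}

#' The standard comparison set for reserve-group analyses
#'
#' Emits the named contrasts the multiple-group analysis reports: per group,
#' the within-model memory-minus-brain slope difference (`dB`); and for each
#' group pair, differences in the memory slope, the brain slope, `dB`, and
#' the memory-brain slope covariance. For a single-group univariate fit only
#' the intercept and slope mean contrasts are emitted; covariance contrasts
#' require a bivariate fit.
#'
#' @param fit a `growsurv_fit` or `growsurv_mgfit`.
#' @return Named list of contrast vectors usable with [wald_test()].
#' @export
standard_contrasts <- function(fit) {
  if (inherits(fit, "growsurv_fit")) {
    spec <- fit$spec
    out <- list()
    for (o in spec$outcomes) {
      out[[paste0("intercept.", o)]] <- setNames(1, paste0("alpha.", o, ".intercept"))
      out[[paste0("slope.", o)]] <- setNames(1, paste0("alpha.", o, ".slope"))
    }
    if (length(spec$outcomes) == 2L)
      out[["dB"]] <- c(alpha.memory.slope = 1, alpha.brain.slope = -1)
    return(out)
  }
  if (!inherits(fit, "growsurv_mgfit")) stop("unsupported fit object")
  spec <- fit$fits[[1]]$spec
  groups <- names(fit$fits)
  biv <- length(spec$outcomes) == 2L
  qty <- list(memory.slope = c(alpha.memory.slope = 1))
  if (biv) {
    qty$brain.slope <- c(alpha.brain.slope = 1)
    qty$dB <- c(alpha.memory.slope = 1, alpha.brain.slope = -1)
    qty$slope.cov <- c(psi.brain.slope.memory.slope = 1)
  }
  out <- list()
  if (biv) for (g in groups) {
    out[[paste0("dB.", g)]] <- setNames(c(1, -1),
      paste0(g, "|", c("alpha.memory.slope", "alpha.brain.slope")))
  }
  if (length(groups) >= 2) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    for (q in names(qty)) {
      for (pr in pairs) {
        v <- c(qty[[q]], -qty[[q]])
        names(v) <- c(paste0(pr[1], "|", names(qty[[q]])),
                      paste0(pr[2], "|", names(qty[[q]])))
        out[[paste0(q, ".", pr[1], ".vs.", pr[2])]] <- v
      }
    }
  }
  out
}
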