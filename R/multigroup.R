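#' Multiple-group estimation over reserve strata
#'
#' Fits the model independently in each level of a grouping variable (e.g.,
#' low/mid/high tertiles of a reserve proxy) with all parameters free, and
#' stacks the results. Groups are independent samples, so the stacked
#' covariance matrix of the estimates is block-diagonal across groups —
#' the basis for across-group Wald equality tests via [wald_test()] and
#' [standard_contrasts()].
#'
#' @inheritParams fit_growth
#' @param grouping column name holding the group label (default:
#'   `spec$grouping`).
#' @param min_group_size smallest admissible group (default 30 subjects).
#' @param ... passed to [fit_growth()].
#' @return An object of class `growsurv_mgfit`: `fits` (named list of
#'   per-group `growsurv_fit`s), stacked `estimates` (named
#'   `<group>|<parameter>`) and block-diagonal `vcov`.
#' @export
multiple_group_fit <- function(data, spec, grouping = spec$grouping,
                               min_group_size = 30L, ...) {
  if (is.null(grouping)) stop("no grouping variable given")
  data <- as.data.frame(data)
  if (!grouping %in% names(data)) stop("grouping column '", grouping, "' not in data")
  g <- data[[grouping]]
  glev <- if (is.factor(g)) levels(droplevels(g)) else sort(unique(as.character(g)))
  fits <- list()
  for (lev in glev) {
    d <- data[as.character(g) == lev & !is.na(g), , drop = FALSE]
    n_subj <- length(unique(d$subject_id))
    if (n_subj == 0) stop("group '", lev, "' is empty")
    if (n_subj < min_group_size)
      stop("group '", lev, "' has ", n_subj, " subjects (< ", min_group_size, ")")
    fits[[lev]] <- fit_growth(d, spec, group_label = lev, ...)
  }
  est <- unlist(lapply(glev, function(lev) {
    e <- fits[[lev]]$estimates
    setNames(e, paste0(lev, "|", names(e)))
  }))
  p <- length(fits[[1]]$estimates)
  V <- matrix(0, length(est), length(est), dimnames = list(names(est), names(est)))
  for (i in seq_along(glev)) {
    idx <- (i - 1) * p + seq_len(p)
    V[idx, idx] <- fits[[glev[i]]]$vcov
  }
  structure(list(fits = fits, estimates = est, vcov = V,
                 grouping = grouping,
                 converged = all(vapply(fits, `[[`, TRUE, "converged"))),
            class = "growsurv_mgfit")
}

#' @export
print.growsurv_mgfit <- function(x, ...) {
  cat("Multiple-group latent growth curve fit over '", x$grouping, "' (",
      length(x$fits), " groups)\n", sep = "")
  for (g in names(x$fits)) {
    f <- x$fits[[g]]
    cat("  ", g, ": n = ", f$n_subjects, ", logLik = ",
        format(f$loglik, digits = 8), ", converged = ", f$converged, "\n", sep = "")
  }
  invisible(x)
}
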