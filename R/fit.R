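#' Maximum-likelihood fit of a latent growth curve model
#'
#' Maximizes [marginal_loglik()] (or [joint_loglik()] when the spec includes
#' the survival submodel) over all free parameters. Variance parameters are
#' optimized on an unconstrained transform (log-Cholesky for the
#' random-effect and residual covariance blocks), by quasi-Newton iterations
#' started from per-subject regression / method-of-moments values, followed
#' by Newton polishing steps on the observed information. The covariance
#' matrix of the estimates is the inverse observed information at the
#' optimum, mapped back to the natural scale by the delta method. The fit is
#' deterministic given the data and starting rule.
#'
#' @param data long-format cohort table.
#' @param spec a [growth_spec()].
#' @param start optional [growth_params()] with starting values (default:
#'   data-driven starting rule).
#' @param rule Gauss-Hermite rule for joint models (default
#'   `gh_rule(9, length(spec$hazard_factors))`).
#' @param control passed to [stats::optim()] (`maxit`, `reltol`, ...).
#' @param max_retries additional quasi-Newton restarts (from the incumbent,
#'   then from deterministically perturbed starts) before a fit is declared
#'   non-converged.
#' @param hessian compute the observed information and standard errors
#'   (disable only for profiling).
#' @param group_label optional label recorded on the result.
#' @return An object of class `growsurv_fit`: named `estimates`, their
#'   covariance matrix `vcov`, `loglik`, `n_subjects`, `converged`,
#'   `n_iterations`, `gradient_norm` (unconstrained scale), the structured
#'   `params`, and the `spec`. A non-converged fit is returned flagged, never
#'   silently as valid.
#' @export
fit_growth <- function(data, spec, start = NULL, rule = NULL,
                       control = list(), max_retries = 2L, hessian = TRUE,
                       group_label = NULL) {
  des <- build_design(data, spec)
  if (des$n < 1L) stop("data is empty")
  # slope identification needs repeated observations at distinct times
  off <- c(0L, cumsum(des$nelem))
  two <- sum(vapply(seq_len(des$n), function(i) {
    if (des$nelem[i] < 2) return(FALSE)
    length(unique(des$t[(off[i] + 1):(off[i + 1])])) >= 2
  }, logical(1)))
  if (two == 0)
    stop("non-identifiable model: no subject has two distinct observation times")

  if (spec$include_survival && is.null(rule))
    rule <- gh_rule(9L, length(spec$hazard_factors))
  user_start <- !is.null(start)
  if (is.null(start)) start <- start_values(data, spec, des)
  v0 <- par_pack(start, spec)
  p <- length(v0)

  obj <- .make_obj(des, spec, rule, v0)
  negll <- function(v) {
    s <- obj$fn(v)
    # a negative log-likelihood below -1e8 can only be numerical garbage
    if (!is.finite(s) || s < -1e8) return(1e10)
    s
  }
  grad <- function(v) {
    g <- as.vector(obj$gr(v))
    g[!is.finite(g)] <- 0
    g
  }

  run_from <- function(v0) {
  ctrl <- modifyList(list(maxit = 500L, reltol = 1e-9,
                          parscale = pmax(abs(v0), 0.02)), control)
  opt <- optim(v0, negll, grad, method = "BFGS", control = ctrl)
  iters <- opt$counts[1]
  retry <- 0L
  while (retry < max_retries && opt$convergence != 0) {
    retry <- retry + 1L
    # deterministic perturbation ladder
    v_r <- opt$par * (1 + 0.02 * retry * sin(seq_len(p) * retry)) +
      0.01 * retry * sin(seq_len(p) + retry)
    cand <- optim(v_r, negll, grad, method = "BFGS", control = ctrl)
    iters <- iters + cand$counts[1]
    if (cand$value <= opt$value) opt <- cand
  }
  v_hat <- opt$par

  H <- NULL
  gnorm <- NA_real_
  if (hessian) {
    for (cycle in 1:3) {
      H <- fd_hessian(grad, v_hat)
      # Newton polish on the observed information
      moved <- 0
      for (step in 1:6) {
        g <- grad(v_hat)
        gnorm <- max(abs(g))
        if (!is.finite(gnorm) || gnorm < 1e-6) break
        f0 <- negll(v_hat)
        improved <- FALSE
        # Newton step with Levenberg damping: an inexact finite-difference
        # information can make the raw step an ascent direction, in which
        # case increasingly damped steps fall back towards steepest descent
        for (lam in c(0, 10^(-4:2) * max(abs(diag(H)), 1))) {
          dv <- tryCatch(-solve(H + lam * diag(p), g), error = function(e) NULL)
          if (is.null(dv)) next
          stp <- 1
          for (ls in 1:8) {
            f1 <- negll(v_hat + stp * dv)
            if (f1 < f0) { v_hat <- v_hat + stp * dv; improved <- TRUE; break }
            stp <- stp / 2
          }
          if (improved) break
        }
        if (!improved) break
        moved <- moved + max(abs(stp * dv))
      }
      # the information is reused from the polish unless the polish moved far
      if (moved > 1e-2) H <- fd_hessian(grad, v_hat)
      gnorm <- max(abs(grad(v_hat)))
      if (is.finite(gnorm) && gnorm < 1e-3) break
      if (cycle == 3L) break
      # quasi-Newton stopped short of a stationary point (small relative
      # improvements along a flat valley): restart from here with steps
      # rescaled to the current iterate, then re-polish
      ctrl2 <- ctrl
      ctrl2$parscale <- pmax(abs(v_hat), 0.02)
      opt2 <- optim(v_hat, negll, grad, method = "BFGS", control = ctrl2)
      iters <- iters + opt2$counts[1]
      if (opt2$value <= negll(v_hat) && all(is.finite(opt2$par))) {
        v_hat <- opt2$par
        if (opt2$convergence == 0) opt <- opt2
      }
    }
  }
    pd <- !hessian || (!is.null(H) && all(is.finite(H)) &&
      min(eigen((H + t(H)) / 2, symmetric = TRUE,
                only.values = TRUE)$values) > 0)
    list(v_hat = v_hat, opt = opt, H = H, gnorm = gnorm, iters = iters,
         value = negll(v_hat),
         ok = opt$convergence == 0 && pd &&
           (!hessian || (is.finite(gnorm) && gnorm < 1e-3)))
  }

  res <- run_from(v0)
  # a user-supplied start can trap the quasi-Newton iterations away from a
  # stationary point; fall back to the data-driven starting rule and keep
  # whichever run is converged, breaking ties by likelihood
  if (user_start && !res$ok) {
    alt <- run_from(par_pack(start_values(data, spec, des), spec))
    if ((alt$ok && !res$ok) || alt$value < res$value) res <- alt
  }
  v_hat <- res$v_hat; opt <- res$opt; H <- res$H
  gnorm <- res$gnorm; iters <- res$iters

  params <- par_unpack(v_hat, spec)
  est <- par_flatten(params, spec)
  loglik <- -negll(v_hat)

  V_c <- NULL
  pd_info <- TRUE
  if (hessian) {
    ei <- eigen((H + t(H)) / 2, symmetric = TRUE)
    if (min(ei$values) <= 0) {
      pd_info <- FALSE
      lam <- pmax(ei$values, 1e-8 * max(abs(ei$values)))
    } else lam <- ei$values
    V_u <- ei$vectors %*% (t(ei$vectors) / lam)
    J <- fd_jacobian(function(v) par_flatten(par_unpack(v, spec), spec), v_hat)
    V_c <- J %*% V_u %*% t(J)
    V_c <- (V_c + t(V_c)) / 2
    dimnames(V_c) <- list(names(est), names(est))
  }

  converged <- opt$convergence == 0 && pd_info &&
    (!hessian || (is.finite(gnorm) && gnorm < 1e-3))
  structure(list(estimates = est, vcov = V_c, loglik = loglik,
                 n_subjects = des$n, n_obs = des$n_obs,
                 converged = converged, n_iterations = unname(iters),
                 gradient_norm = gnorm, optim_code = opt$convergence,
                 params = params, estimates_u = v_hat,
                 spec = spec, group_label = group_label),
            class = "growsurv_fit")
}

fd_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- x; e[j] <- e[j] + h
    f1 <- f(e)
    e[j] <- x[j] - h
    (f1 - f(e)) / (2 * h)
  }, numeric(1))
}

# observed information by forward-differencing the exact gradient
fd_hessian <- function(grad, x, h = 1e-5) {
  g0 <- grad(x)
  H <- matrix(0, length(x), length(x))
  for (j in seq_along(x)) {
    e <- x
    e[j] <- e[j] + h
    H[, j] <- (grad(e) - g0) / h
  }
  (H + t(H)) / 2
}

fd_jacobian <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    e <- x; e[j] <- e[j] + h
    fp <- f(e)
    e[j] <- x[j] - h
    J[, j] <- (fp - f(e)) / (2 * h)
  }
  rownames(J) <- names(f0)
  J
}

# cheap data-driven starting rule: per-subject OLS for the factor means and
# covariate effects, method-of-moments for the variance components, empirical
# death fractions for tau, zeros for the hazard loadings
start_values <- function(data, spec, des = NULL) {
  if (is.null(des)) des <- build_design(data, spec)
  data <- as.data.frame(data)
  cn <- spec_covariates(spec)
  first <- data[!duplicated(data$subject_id), , drop = FALSE]
  first <- first[order(first$subject_id), , drop = FALSE]

  nf <- length(spec$factors)
  alpha <- setNames(numeric(nf), spec$factors)
  beta <- list()
  psi_d <- setNames(numeric(nf), spec$factors)
  theta <- setNames(numeric(length(spec$outcomes)), spec$outcomes)

  for (o in spec$outcomes) {
    col <- spec$outcome_columns[[o]]
    d <- data[!is.na(data[[col]]), c("subject_id", "time_in_study", col)]
    sp <- split(d, d$subject_id)
    ols <- t(vapply(sp, function(s) {
      if (nrow(s) < 2 || length(unique(s$time_in_study)) < 2)
        return(c(NA_real_, NA_real_, NA_real_, NA_real_))
      x <- s$time_in_study; y <- s[[col]]
      sxx <- sum((x - mean(x))^2)
      b <- sum((x - mean(x)) * (y - mean(y))) / sxx
      a <- mean(y) - b * mean(x)
      r2 <- sum((y - a - b * x)^2)
      c(a, b, r2 / max(nrow(s) - 2, 1), sxx)
    }, numeric(4)))
    ok <- is.finite(ols[, 1])
    a <- ols[ok, 1]; b <- ols[ok, 2]
    theta[o] <- max(mean(ols[ok & ols[, 3] > 0, 3], na.rm = TRUE), 0.05, na.rm = TRUE)
    # subtract the OLS sampling noise from the raw between-subject variances
    noise_b <- mean(theta[o] / ols[ok, 4])
    psi_d[paste0(o, ".intercept")] <- max(var(a) * 0.7, 0.05)
    psi_d[paste0(o, ".slope")] <- max(var(b) - noise_b, 1e-4)
    alpha[paste0(o, ".intercept")] <- mean(a)
    alpha[paste0(o, ".slope")] <- mean(b)
    # covariate effects from regressing the OLS coefficients on the baseline
    ids_ok <- names(sp)[ok]
    fx <- first[match(ids_ok, as.character(first$subject_id)), , drop = FALSE]
    for (what in c("intercept", "slope")) {
      fac <- paste0(o, ".", what)
      cv <- if (what == "intercept") spec$intercept_covariates[[o]]
            else spec$slope_covariates[[o]]
      if (!length(cv)) next
      yv <- if (what == "intercept") a else b
      X <- as.matrix(fx[, cv, drop = FALSE])
      cf <- tryCatch(coef(lm(yv ~ X)), error = function(e) NULL)
      bb <- setNames(numeric(length(cv)), cv)
      if (!is.null(cf)) {
        est <- cf[-1]
        est[!is.finite(est)] <- 0
        bb[] <- est
        alpha[fac] <- cf[1]
      }
      beta[[fac]] <- bb
    }
  }
  psi <- diag(psi_d, nf, nf)

  tau <- NULL; gam <- NULL
  if (spec$include_survival) {
    tau <- vapply(seq_len(spec$n_intervals), function(k) {
      s <- des$surv[, k]
      atrisk <- sum(s >= 0)
      died <- sum(s == 1)
      qlogis(min(max((died + 0.5) / (atrisk + 1), 0.005), 0.6))
    }, numeric(1))
    gam <- setNames(numeric(length(spec$hazard_factors)), spec$hazard_factors)
  }
  growth_params(spec, alpha = alpha, beta = beta, psi = psi, theta = theta,
                theta_cross = 0,
                mu_practice = if (length(spec$practice_on)) 0.05 else 0,
                psi_practice = if (spec$practice_variance_free) 0.01 else 0,
                tau = tau, gamma_surv = gam)
}

#' @export
print.growsurv_fit <- function(x, ...) {
  cat("Latent growth curve fit",
      if (x$spec$include_survival) "(joint with discrete-time survival)" else "",
      "\n")
  if (!is.null(x$group_label)) cat("  group:", x$group_label, "\n")
  cat("  subjects:", x$n_subjects, "  observations:", x$n_obs, "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      "  converged:", x$converged, "\n")
  print(tidy_fit(x), digits = 4)
  invisible(x)
}

#' @export
coef.growsurv_fit <- function(object, ...) object$estimates

#' @export
vcov.growsurv_fit <- function(object, ...) object$vcov

#' @export
logLik.growsurv_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$estimates_u),
            nobs = object$n_subjects, class = "logLik")
}

#' Estimates with Wald-type confidence intervals
#'
#' @param fit a `growsurv_fit`.
#' @param level confidence level (default .95); intervals are
#'   `estimate +/- z * SE` from the observed-information standard errors.
#' @return `data.frame` with `parameter`, `estimate`, `se`, `ci_lo`,
#'   `ci_hi`, `z`, `p`.
#' @export
tidy_fit <- function(fit, level = 0.95) {
  est <- fit$estimates
  se <- if (is.null(fit$vcov)) rep(NA_real_, length(est)) else sqrt(pmax(diag(fit$vcov), 0))
  zq <- qnorm(1 - (1 - level) / 2)
  z <- est / se
  data.frame(parameter = names(est), estimate = unname(est), se = unname(se),
             ci_lo = unname(est - zq * se), ci_hi = unname(est + zq * se),
             z = unname(z), p = unname(2 * pnorm(-abs(z))),
             row.names = NULL)
}
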