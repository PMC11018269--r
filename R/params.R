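#' Construct a full growth-model parameter set
#'
#' Bundles every parameter of a (possibly joint) latent growth curve model:
#' factor means, covariate effects on the factors, the random-effect
#' covariance matrix, residual (co)variances, the practice-effect mean (and
#' optionally variance), and the discrete-time hazard block.
#'
#' @param spec a [growth_spec()].
#' @param alpha named numeric of factor means, one per latent factor
#'   (`<outcome>.intercept`, `<outcome>.slope`); slope means are in
#'   standardized units per year.
#' @param beta matrix of covariate effects (factors x covariates). Entries on
#'   paths the spec does not free must be 0. A named list of named vectors
#'   (per factor) is also accepted.
#' @param psi random-effect covariance matrix (2x2 univariate, 4x4
#'   bivariate), symmetric positive semi-definite. Houses the slope
#'   covariance between memory decline and atrophy in bivariate models.
#' @param theta named residual variances, one per outcome (> 0).
#' @param theta_cross within-occasion residual covariance between the two
#'   outcomes (bivariate models with `residual_cross = TRUE`).
#' @param mu_practice mean of the practice-effect factor (standardized units
#'   per unit loading).
#' @param psi_practice practice-factor variance (0 unless
#'   `practice_variance_free`).
#' @param tau per-interval hazard intercepts on the link scale.
#' @param gamma_surv named regressions of the hazard on the latent factors in
#'   `spec$hazard_factors`.
#'
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(spec, alpha, beta = NULL, psi, theta,
                          theta_cross = 0, mu_practice = 0, psi_practice = 0,
                          tau = NULL, gamma_surv = NULL) {
  nf <- length(spec$factors)
  cn <- spec_covariates(spec)
  if (length(alpha) != nf) stop("alpha must have one entry per latent factor")
  alpha <- setNames(as.numeric(alpha), spec$factors)

  B <- matrix(0, nf, length(cn), dimnames = list(spec$factors, cn))
  if (!is.null(beta) && length(cn)) {
    if (is.list(beta)) {
      for (f in names(beta)) if (length(beta[[f]])) B[f, names(beta[[f]])] <- beta[[f]]
    } else {
      beta <- as.matrix(beta)
      B[rownames(beta), colnames(beta)] <- beta
    }
    mask <- spec_beta_mask(spec)
    if (any(B[!mask] != 0)) stop("beta has nonzero entries on paths the spec fixes to zero")
  }

  psi <- as.matrix(psi)
  if (!all(dim(psi) == nf)) stop("psi must be ", nf, "x", nf)
  if (max(abs(psi - t(psi))) > 1e-8) stop("psi (random-effect covariance) must be symmetric")
  ev <- eigen(psi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("psi (random-effect covariance) is not positive semi-definite")
  }
  dimnames(psi) <- list(spec$factors, spec$factors)

  theta <- setNames(as.numeric(theta), spec$outcomes)
  if (any(theta <= 0)) stop("residual variances theta must be > 0")
  if (length(spec$outcomes) == 2L) {
    if (abs(theta_cross) > sqrt(prod(theta)))
      stop("|theta_cross| exceeds sqrt(theta_memory * theta_brain)")
  } else theta_cross <- 0
  if (psi_practice < 0) stop("psi_practice must be >= 0")

  if (spec$include_survival) {
    if (is.null(tau)) stop("spec includes survival: tau required")
    if (length(tau) != spec$n_intervals)
      stop("tau must have one hazard intercept per risk interval")
    g <- setNames(numeric(length(spec$hazard_factors)), spec$hazard_factors)
    if (!is.null(gamma_surv)) {
      if (is.null(names(gamma_surv)) && length(gamma_surv) == length(g)) {
        g[] <- gamma_surv
      } else g[names(gamma_surv)] <- gamma_surv
    }
    gamma_surv <- g
    tau <- as.numeric(tau)
  } else {
    tau <- NULL; gamma_surv <- NULL
  }

  structure(list(alpha = alpha, beta = B, psi = psi, theta = theta,
                 theta_cross = theta_cross, mu_practice = mu_practice,
                 psi_practice = psi_practice, tau = tau,
                 gamma_surv = gamma_surv),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Growth model parameters\n")
  cat("  factor means:\n"); print(round(x$alpha, 4))
  if (length(x$beta)) { cat("  covariate effects:\n"); print(round(x$beta, 4)) }
  cat("  random-effect covariance psi:\n"); print(round(x$psi, 5))
  cat("  residual variances:", paste(names(x$theta), round(x$theta, 4),
                                     sep = " = ", collapse = ", "), "\n")
  if (length(x$theta) == 2) cat("  residual cross-covariance:", round(x$theta_cross, 4), "\n")
  cat("  practice mean:", round(x$mu_practice, 4),
      " variance:", round(x$psi_practice, 5), "\n")
  if (!is.null(x$tau)) {
    cat("  hazard intercepts tau:", paste(round(x$tau, 3), collapse = ", "), "\n")
    cat("  hazard loadings:\n"); print(round(x$gamma_surv, 4))
  }
  invisible(x)
}

# ---- flatten to the named reporting vector (constrained scale) -------------

par_flatten <- function(params, spec) {
  out <- c(setNames(params$alpha, paste0("alpha.", spec$factors)))
  mask <- spec_beta_mask(spec)
  if (any(mask)) {
    idx <- which(mask, arr.ind = TRUE)
    b <- params$beta[mask]
    names(b) <- paste0("beta.", rownames(mask)[idx[, 1]], ".", colnames(mask)[idx[, 2]])
    out <- c(out, b)
  }
  nf <- length(spec$factors)
  for (j in seq_len(nf)) for (i in j:nf) {
    out[paste0("psi.", spec$factors[i], ".", spec$factors[j])] <- params$psi[i, j]
  }
  out[paste0("theta.", spec$outcomes)] <- params$theta
  if (spec$residual_cross) out["theta.cross"] <- params$theta_cross
  if (length(spec$practice_on)) out["practice.mean"] <- params$mu_practice
  if (spec$practice_variance_free) out["practice.var"] <- params$psi_practice
  if (spec$include_survival) {
    out[paste0("surv.tau.", seq_len(spec$n_intervals))] <- params$tau
    out[paste0("surv.gamma.", spec$hazard_factors)] <- params$gamma_surv
  }
  out
}

# ---- unconstrained transform (log-Cholesky for covariance blocks) ----------

chol_pack <- function(S) {
  # jitter only when the matrix is semi-definite and plain chol fails, so
  # that pack/unpack round-trips positive-definite matrices exactly
  L <- tryCatch(t(chol(S)),
                error = function(e) t(chol(S + diag(1e-10, nrow(S)))))
  out <- numeric(0)
  for (j in seq_len(ncol(L))) for (i in j:nrow(L)) {
    out <- c(out, if (i == j) log(L[i, j]) else L[i, j])
  }
  out
}

chol_unpack <- function(v, d) {
  L <- matrix(0, d, d)
  k <- 1L
  for (j in seq_len(d)) for (i in j:d) {
    L[i, j] <- if (i == j) exp(v[k]) else v[k]
    k <- k + 1L
  }
  L %*% t(L)
}

par_pack <- function(params, spec) {
  v <- unname(params$alpha)
  mask <- spec_beta_mask(spec)
  if (any(mask)) v <- c(v, params$beta[mask])
  v <- c(v, chol_pack(params$psi))
  if (spec$residual_cross) {
    Th <- matrix(c(params$theta[1], params$theta_cross,
                   params$theta_cross, params$theta[2]), 2, 2)
    v <- c(v, chol_pack(Th))
  } else {
    v <- c(v, 0.5 * log(params$theta))
  }
  if (length(spec$practice_on)) v <- c(v, params$mu_practice)
  if (spec$practice_variance_free) v <- c(v, 0.5 * log(max(params$psi_practice, 1e-10)))
  if (spec$include_survival) v <- c(v, params$tau, unname(params$gamma_surv))
  unname(v)
}

par_unpack <- function(v, spec) {
  nf <- length(spec$factors)
  cn <- spec_covariates(spec)
  mask <- spec_beta_mask(spec)
  k <- 0L
  take <- function(n) { out <- v[k + seq_len(n)]; k <<- k + n; out }

  alpha <- take(nf)
  B <- matrix(0, nf, length(cn), dimnames = list(spec$factors, cn))
  if (any(mask)) B[mask] <- take(sum(mask))
  psi <- chol_unpack(take(nf * (nf + 1) / 2), nf)
  dimnames(psi) <- list(spec$factors, spec$factors)
  if (spec$residual_cross) {
    Th <- chol_unpack(take(3L), 2L)
    theta <- setNames(diag(Th), spec$outcomes)
    theta_cross <- Th[2, 1]
  } else {
    theta <- setNames(exp(2 * take(length(spec$outcomes))), spec$outcomes)
    theta_cross <- 0
  }
  mu_p <- if (length(spec$practice_on)) take(1L) else 0
  psi_p <- if (spec$practice_variance_free) exp(2 * take(1L)) else 0
  tau <- NULL; gam <- NULL
  if (spec$include_survival) {
    tau <- take(spec$n_intervals)
    gam <- setNames(take(length(spec$hazard_factors)), spec$hazard_factors)
  }
  if (k != length(v)) stop("parameter vector length mismatch: used ", k, " of ", length(v))
  structure(list(alpha = setNames(alpha, spec$factors), beta = B, psi = psi,
                 theta = theta, theta_cross = theta_cross, mu_practice = mu_p,
                 psi_practice = psi_p, tau = tau, gamma_surv = gam),
            class = "growth_params")
}

par_names_unconstrained <- function(spec) {
  nf <- length(spec$factors)
  nm <- paste0("alpha.", spec$factors)
  mask <- spec_beta_mask(spec)
  if (any(mask)) {
    idx <- which(mask, arr.ind = TRUE)
    nm <- c(nm, paste0("beta.", rownames(mask)[idx[, 1]], ".", colnames(mask)[idx[, 2]]))
  }
  for (j in seq_len(nf)) for (i in j:nf) nm <- c(nm, paste0("Lpsi.", i, ".", j))
  if (spec$residual_cross) nm <- c(nm, "Ltheta.1.1", "Ltheta.2.1", "Ltheta.2.2")
  else nm <- c(nm, paste0("log_sd.", spec$outcomes))
  if (length(spec$practice_on)) nm <- c(nm, "practice.mean")
  if (spec$practice_variance_free) nm <- c(nm, "log_sd.practice")
  if (spec$include_survival)
    nm <- c(nm, paste0("surv.tau.", seq_len(spec$n_intervals)),
            paste0("surv.gamma.", spec$hazard_factors))
  nm
}
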