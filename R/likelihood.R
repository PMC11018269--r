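#' Practice-effect factor loading
#'
#' Repeated cognitive testing improves scores through test familiarity. The
#' practice effect is modeled as a latent factor whose loading at each visit
#' is fixed at the square root of the number of previous testing occasions:
#' 0 at the first visit, 1 at the second, sqrt(2) at the third. In
#' `"one-decimal"` mode the loadings are rounded to one decimal place, giving
#' the conventional fixed values 0, 1 and 1.4.
#'
#' @param visit_order 0-based visit index (0 = first visit); vectorized.
#' @param mode `"exact"` (default) or `"one-decimal"`.
#' @return Numeric loading(s).
#' @export
#' @examples
#' practice_loading(0:2)                  # 0, 1, sqrt(2)
#' practice_loading(2, "one-decimal")     # 1.4
practice_loading <- function(visit_order, mode = c("exact", "one-decimal")) {
  mode <- match.arg(mode)
  if (any(visit_order < 0)) stop("visit_order must be >= 0")
  l <- sqrt(visit_order)
  if (mode == "one-decimal") l <- round(l, 1)
  l
}

#' Single-subject design for the growth model
#'
#' Describes one subject's observed outcome stack: which outcome was observed
#' at which visit and time, with the practice loadings implied by the visit
#' order, plus the subject's covariate values. Unobserved outcome-occasions
#' are simply absent (full-information handling of missingness).
#'
#' @param time observation time in years, one per observed element.
#' @param visit_order 0-based visit index per element.
#' @param outcome outcome name per element (`"memory"`/`"brain"`).
#' @param spec a [growth_spec()].
#' @param x named covariate values (must cover `spec`'s covariates).
#' @return An object of class `subject_design`.
#' @export
subject_design <- function(time, visit_order, outcome, spec, x = NULL) {
  outcome <- match.arg(outcome, spec$outcomes, several.ok = TRUE)
  stopifnot(length(time) == length(visit_order), length(time) == length(outcome))
  if (length(time) == 0) stop("subject has no observed outcome entries")
  cn <- spec_covariates(spec)
  xv <- setNames(numeric(length(cn)), cn)
  if (length(cn)) {
    if (is.null(x) || !all(cn %in% names(x)))
      stop("x must supply covariates: ", paste(cn, collapse = ", "))
    xv[cn] <- x[cn]
  }
  lam <- ifelse(outcome %in% spec$practice_on,
                practice_loading(visit_order, spec$loading_mode), 0)
  structure(list(time = time, visit_order = as.integer(visit_order),
                 outcome = outcome, lam = lam, x = xv),
            class = "subject_design")
}

#' Implied mean and covariance of a subject's outcome stack
#'
#' Reduces the latent growth curve model to its observed-data moments for one
#' subject: mean `Lambda (alpha + Beta x) + lambda mu_practice` and covariance
#' `Lambda Psi Lambda' + lambda lambda' psi_practice + Theta`, where `Lambda`
#' carries the loadings `(1, t_ij)` per outcome, `lambda` the practice
#' loadings, and `Theta` the residual (co)variances (cross-outcome residual
#' covariance only within the same occasion).
#'
#' @param subject a [subject_design()].
#' @param params a [growth_params()].
#' @param spec the [growth_spec()] the parameters belong to.
#' @return List with `mean` and `cov` over the subject's observed elements.
#' @export
implied_moments <- function(subject, params, spec) {
  ne <- length(subject$time)
  nf <- length(spec$factors)
  L <- matrix(0, ne, nf)
  oi <- match(subject$outcome, spec$outcomes)
  for (e in seq_len(ne)) {
    L[e, 2 * oi[e] - 1] <- 1
    L[e, 2 * oi[e]] <- subject$time[e]
  }
  eta_mean <- params$alpha + as.vector(params$beta %*% subject$x)
  mu <- as.vector(L %*% eta_mean) + subject$lam * params$mu_practice
  Th <- matrix(0, ne, ne)
  for (e in seq_len(ne)) for (f in seq_len(ne)) {
    if (subject$visit_order[e] == subject$visit_order[f]) {
      Th[e, f] <- if (oi[e] == oi[f]) {
        if (e == f) params$theta[oi[e]] else 0
      } else params$theta_cross
    }
  }
  V <- L %*% params$psi %*% t(L) + params$psi_practice * tcrossprod(subject$lam) + Th
  list(mean = mu, cov = (V + t(V)) / 2)
}

# link the structured parameters to the flat arrays the C++ kernel consumes
.theta_matrix <- function(params, spec) {
  no <- length(spec$outcomes)
  Th <- diag(params$theta, no, no)
  if (no == 2) Th[1, 2] <- Th[2, 1] <- params$theta_cross
  Th
}

# data list for the compiled objective; field names match the template
.tmb_data <- function(des, spec, rule = NULL) {
  survival_on <- isTRUE(spec$include_survival)
  hf <- if (survival_on) match(spec$hazard_factors, spec$factors) - 1L else integer()
  if (survival_on) {
    if (is.null(rule)) rule <- gh_rule(15L, length(hf))
    if (rule$dim != length(hf))
      stop("quadrature rule dimension (", rule$dim,
           ") must match the number of hazard factors (", length(hf), ")")
  }
  mask <- spec_beta_mask(spec)
  idx <- which(mask, arr.ind = TRUE)  # column-major, same order as par_pack()
  list(nf = length(spec$factors), no = length(spec$outcomes),
       brow = as.integer(idx[, 1] - 1L), bcol = as.integer(idx[, 2] - 1L),
       resid_cross = as.integer(isTRUE(spec$residual_cross)),
       prac_on = as.integer(length(spec$practice_on) > 0),
       prac_var_on = as.integer(isTRUE(spec$practice_variance_free)),
       surv_on = as.integer(survival_on),
       K = if (survival_on) spec$n_intervals else 0L,
       hf = as.integer(hf),
       link = if (spec$link == "logit") 0L else 1L,
       nelem = des$nelem, y = des$y, tt = des$t, lam = des$lam,
       occ = des$occ, outi = des$out, X = des$X,
       surv = if (survival_on) des$surv else matrix(-1L, des$n, 0L),
       zgrid = if (survival_on) rule$nodes else matrix(0, 1, 0),
       lw = if (survival_on) rule$logw else numeric())
}

# compiled objective with exact derivatives; obj$fn is the negative joint
# (or marginal) log-likelihood, obj$gr its gradient, obj$report(v)$ll the
# per-subject log-likelihood vector
.make_obj <- function(des, spec, rule = NULL, v) {
  TMB::MakeADFun(data = .tmb_data(des, spec, rule),
                 parameters = list(theta = v),
                 DLL = "growsurv", silent = TRUE)
}

.call_kernel <- function(des, params, spec, rule = NULL, survival_on = FALSE) {
  v <- par_pack(params, spec)
  obj <- .make_obj(des, spec, rule, v)
  obj$report(v)$ll
}

.check_subject_ll <- function(ll, des) {
  bad <- which(!is.finite(ll))
  if (length(bad)) {
    stop("implied covariance not positive definite (or quadrature underflow; ",
         "increase n_points) for subject ", des$ids[bad[1]])
  }
  invisible(ll)
}

#' Marginal log-likelihood of the longitudinal model
#'
#' Closed-form full-information maximum likelihood: the sum over subjects of
#' the multivariate normal log-density of each subject's observed outcome
#' stack at its implied moments ([implied_moments()]). Missing outcome
#' entries contribute nothing; no imputation or deletion is performed.
#'
#' @param data long-format cohort (see [simulate_cohort()] for the layout).
#' @param spec a [growth_spec()] with `include_survival = FALSE`.
#' @param params a [growth_params()].
#' @param engine `"cpp"` (compiled kernel, default) or `"R"` (reference
#'   implementation).
#' @param by_subject return the per-subject vector instead of the sum.
#' @return Scalar log-likelihood (or per-subject vector).
#' @export
marginal_loglik <- function(data, spec, params, engine = c("cpp", "R"),
                            by_subject = FALSE) {
  engine <- match.arg(engine)
  if (spec$include_survival)
    stop("spec includes survival: use joint_loglik()")
  des <- build_design(data, spec)
  ll <- if (engine == "cpp") {
    .call_kernel(des, params, spec, survival_on = FALSE)
  } else {
    .loglik_R(des, params, spec, rule = NULL, survival_on = FALSE)
  }
  .check_subject_ll(ll, des)
  if (by_subject) setNames(ll, des$ids) else sum(ll)
}

#' Joint longitudinal-survival log-likelihood
#'
#' Per subject, the Gaussian longitudinal density is factored analytically
#' and the discrete-time survival likelihood is integrated over the latent
#' growth factors the hazard is regressed on, using Gauss-Hermite quadrature
#' re-centered at the subject's posterior factor distribution given the
#' observed outcomes. With hazard loadings equal to zero the integral is
#' exact and the joint log-likelihood reduces to
#' [marginal_loglik()] + [survival_loglik()].
#'
#' @inheritParams marginal_loglik
#' @param spec a [growth_spec()] with `include_survival = TRUE`.
#' @param rule a [gh_rule()] whose dimension matches
#'   `length(spec$hazard_factors)`.
#' @return Scalar log-likelihood (or per-subject vector).
#' @export
joint_loglik <- function(data, spec, params,
                         rule = gh_rule(15L, length(spec$hazard_factors)),
                         engine = c("cpp", "R"), by_subject = FALSE) {
  engine <- match.arg(engine)
  if (!spec$include_survival)
    stop("spec does not include survival: use marginal_loglik()")
  des <- build_design(data, spec)
  ll <- if (engine == "cpp") {
    .call_kernel(des, params, spec, rule = rule, survival_on = TRUE)
  } else {
    .loglik_R(des, params, spec, rule = rule, survival_on = TRUE)
  }
  .check_subject_ll(ll, des)
  if (by_subject) setNames(ll, des$ids) else sum(ll)
}

# ---- pure-R reference implementation (cross-checked against the kernel) ----

.loglik_R <- function(des, params, spec, rule, survival_on) {
  nf <- length(spec$factors)
  off <- c(0L, cumsum(des$nelem))
  hf <- match(spec$hazard_factors, spec$factors)
  Thm <- .theta_matrix(params, spec)
  ll <- numeric(des$n)
  for (i in seq_len(des$n)) {
    idx <- if (des$nelem[i] > 0) (off[i] + 1):(off[i + 1]) else integer()
    ne <- length(idx)
    x <- if (ncol(des$X)) des$X[i, ] else numeric()
    eta_mean <- params$alpha + as.vector(params$beta %*% x)
    lmarg <- 0
    ch <- NULL; u <- NULL; L <- NULL
    if (ne) {
      L <- matrix(0, ne, nf)
      for (e in seq_len(ne)) {
        o <- des$out[idx[e]] + 1L
        L[e, 2 * o - 1] <- 1
        L[e, 2 * o] <- des$t[idx[e]]
      }
      lam <- des$lam[idx]
      oo <- des$out[idx] + 1L
      Th <- (outer(des$occ[idx], des$occ[idx], "==")) *
        matrix(Thm[cbind(rep(oo, times = ne), rep(oo, each = ne))], ne, ne)
      V <- L %*% params$psi %*% t(L) + params$psi_practice * tcrossprod(lam) + Th
      mu <- as.vector(L %*% eta_mean) + lam * params$mu_practice
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) { ll[i] <- NA_real_; next }
      u <- backsolve(ch, des$y[idx] - mu, transpose = TRUE)
      lmarg <- -0.5 * ne * .log2pi - sum(log(diag(ch))) - 0.5 * sum(u^2)
    }
    if (!survival_on) { ll[i] <- lmarg; next }
    ds <- length(hf)
    # posterior of the hazard factors' deviations given the observed stack
    if (ne) {
      Cm <- L %*% params$psi[, hf, drop = FALSE]
      W <- backsolve(ch, Cm, transpose = TRUE)
      pm <- as.vector(crossprod(W, u))
      P <- params$psi[hf, hf, drop = FALSE] - crossprod(W)
    } else {
      pm <- numeric(ds)
      P <- params$psi[hf, hf, drop = FALSE]
    }
    Lp <- t(chol(P + diag(1e-12, ds)))
    stat <- des$surv[i, ]
    terms <- vapply(seq_len(nrow(rule$nodes)), function(q) {
      eta <- eta_mean[hf] + pm + sqrt(2) * as.vector(Lp %*% rule$nodes[q, ])
      ls <- 0
      for (k in seq_len(spec$n_intervals)) {
        if (stat[k] < 0) next
        lp <- params$tau[k] + sum(params$gamma_surv * eta)
        lh <- if (spec$link == "logit") plogis(lp, log.p = TRUE) else pnorm(lp, log.p = TRUE)
        lh1 <- if (spec$link == "logit") plogis(-lp, log.p = TRUE) else pnorm(-lp, log.p = TRUE)
        ls <- ls + if (stat[k] == 1L) lh else lh1
      }
      rule$logw[q] + ls
    }, numeric(1))
    m <- max(terms)
    ll[i] <- lmarg + m + log(sum(exp(terms - m)))
  }
  ll
}
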