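#' Discrete-time survival block
#'
#' Parameters of the latent hazard: per-interval hazard intercepts `tau` on
#' the link scale (one per inter-visit risk interval; two risk intervals for
#' a three-visit design) and the regressions `gamma` of the hazard on the
#' latent growth factors. The hazard is the conditional probability of death
#' in an interval given survival of (and no drop-out at) all previous ones.
#'
#' @param tau numeric hazard intercepts, one per risk interval.
#' @param gamma named regressions of the hazard on latent factors (e.g.
#'   `c(memory.intercept = -0.3, memory.slope = -8)`).
#' @param link `"logit"` (default) or `"probit"`.
#' @return An object of class `survival_block`.
#' @export
survival_block <- function(tau, gamma = c(memory.intercept = 0, memory.slope = 0),
                           link = c("logit", "probit")) {
  link <- match.arg(link)
  if (!all(is.finite(tau)) || !all(is.finite(gamma)))
    stop("survival parameters must be finite")
  structure(list(tau = as.numeric(tau), gamma = gamma, link = link),
            class = "survival_block")
}

.linkinv_log <- function(lp, link) {
  if (link == "logit") plogis(lp, log.p = TRUE) else pnorm(lp, log.p = TRUE)
}

#' Conditional probability of death in a risk interval
#'
#' `inverse-link(tau_k + gamma . eta)`: the hazard for interval `k` given the
#' subject's latent growth factor values `eta`.
#'
#' @param eta latent factor values, ordered as `block$gamma` (or a matrix
#'   with one row per subject).
#' @param interval 1-based risk interval index.
#' @param block a [survival_block()].
#' @return Hazard probability in (0, 1); vectorized over rows of `eta`.
#' @export
#' @examples
#' discrete_hazard(c(0, 0), 1, survival_block(tau = c(0, -1)))  # 0.5
discrete_hazard <- function(eta, interval, block) {
  if (interval < 1 || interval > length(block$tau))
    stop("interval must be in 1..", length(block$tau))
  eta <- if (is.matrix(eta)) eta else matrix(eta, nrow = 1)
  lp <- block$tau[interval] + as.vector(eta %*% block$gamma)
  if (block$link == "logit") plogis(lp) else pnorm(lp)
}

#' Survival log-likelihood for one subject given the latent factors
#'
#' Sum over intervals the subject is known to have survived of
#' `log(1 - h_k)`, plus `log(h_K)` if death occurred in interval `K`.
#' Intervals with unknown status (drop-out for reasons other than death)
#' contribute nothing.
#'
#' @param status integer vector over risk intervals: 0 survived, 1 died,
#'   `NA` unknown. A death must terminate the record (no later known status).
#' @param eta latent factor values ordered as `block$gamma`.
#' @param block a [survival_block()].
#' @return Scalar log-likelihood.
#' @export
#' @examples
#' b <- survival_block(tau = qlogis(c(.1, .2)))
#' survival_loglik_given_eta(c(0, 0), c(0, 0), b)  # log(.9) + log(.8)
survival_loglik_given_eta <- function(status, eta, block) {
  if (length(status) != length(block$tau))
    stop("status must have one entry per risk interval")
  died <- which(status %in% 1L)
  if (length(died) > 1L)
    stop("inconsistent survival record: more than one death interval")
  if (length(died) == 1L && died < length(status) &&
      any(!is.na(status[(died + 1L):length(status)])))
    stop("inconsistent survival record: status known after a death interval")
  ll <- 0
  for (k in seq_along(status)) {
    if (is.na(status[k])) next
    lp <- block$tau[k] + sum(block$gamma * eta)
    ll <- ll + if (status[k] == 1L) .linkinv_log(lp, block$link)
               else .linkinv_log(-lp, block$link)
  }
  ll
}

#' Standalone discrete-time survival log-likelihood of a cohort
#'
#' Aggregates [survival_loglik_given_eta()] over the cohort with each
#' subject's latent factors fixed at their covariate-implied means
#' `alpha + Beta x` (no random-effect integration). With hazard loadings
#' `gamma = 0` this is the exact survival component of the joint likelihood.
#'
#' @inheritParams joint_loglik
#' @return Scalar log-likelihood.
#' @export
survival_loglik <- function(data, spec, params) {
  if (!spec$include_survival) stop("spec does not include survival")
  des <- build_design(data, spec)
  hf <- match(spec$hazard_factors, spec$factors)
  block <- survival_block(params$tau, params$gamma_surv, link = spec$link)
  ll <- 0
  for (i in seq_len(des$n)) {
    x <- if (ncol(des$X)) des$X[i, ] else numeric()
    eta <- (params$alpha + as.vector(params$beta %*% x))[hf]
    stat <- des$surv[i, ]
    stat[stat < 0] <- NA_integer_
    ll <- ll + survival_loglik_given_eta(stat, eta, block)
  }
  ll
}
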