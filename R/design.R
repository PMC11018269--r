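# Internal: flatten a long-format cohort into the stacked arrays the
# likelihood kernels consume. One "element" is one observed outcome value at
# one visit; missing outcomes simply contribute no element (FIML).

build_design <- function(data, spec) {
  data <- as.data.frame(data)
  req <- c("subject_id", "visit_order", "time_in_study")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("data lacks required columns: ", paste(miss, collapse = ", "))
  cols <- spec$outcome_columns
  miss <- setdiff(unname(cols), names(data))
  if (length(miss)) stop("data lacks outcome columns: ", paste(miss, collapse = ", "))
  cn <- spec_covariates(spec)
  miss <- setdiff(cn, names(data))
  if (length(miss)) stop("data lacks covariate columns: ", paste(miss, collapse = ", "))

  ord <- order(data$subject_id, data$visit_order)
  data <- data[ord, , drop = FALSE]
  ids <- unique(data$subject_id)
  n <- length(ids)
  sub <- match(data$subject_id, ids)

  # stack observed elements: per row, one element per observed outcome
  el_sub <- el_t <- el_lam <- el_y <- el_occ <- el_out <- list()
  for (oi in seq_along(spec$outcomes)) {
    o <- spec$outcomes[oi]
    yv <- data[[cols[[o]]]]
    keep <- !is.na(yv)
    lam <- if (o %in% spec$practice_on) {
      practice_loading(data$visit_order[keep], mode = spec$loading_mode)
    } else rep(0, sum(keep))
    el_sub[[oi]] <- sub[keep]
    el_y[[oi]] <- yv[keep]
    el_t[[oi]] <- data$time_in_study[keep]
    el_lam[[oi]] <- lam
    el_occ[[oi]] <- data$visit_order[keep]
    el_out[[oi]] <- rep(oi - 1L, sum(keep))
  }
  el_sub <- unlist(el_sub); el_y <- unlist(el_y); el_t <- unlist(el_t)
  el_lam <- unlist(el_lam); el_occ <- unlist(el_occ); el_out <- unlist(el_out)
  o2 <- order(el_sub, el_occ, el_out)
  el_sub <- el_sub[o2]
  nelem <- tabulate(el_sub, nbins = n)

  # baseline covariates: first row per subject
  first <- !duplicated(data$subject_id)
  X <- if (length(cn)) as.matrix(data[first, cn, drop = FALSE]) else matrix(0, n, 0)
  storage.mode(X) <- "double"

  # survival status per risk interval: 0 survived, 1 died, -1 unknown
  K <- spec$n_intervals
  surv <- matrix(-1L, n, K)
  if (spec$include_survival) {
    if (!"died_in_next_interval" %in% names(data))
      stop("data lacks 'died_in_next_interval' needed for the survival submodel")
    died <- data$died_in_next_interval
    died[is.na(died)] <- FALSE
    last <- !duplicated(data$subject_id, fromLast = TRUE)
    max_order <- data$visit_order[last]  # data sorted by subject, visit
    for (k in seq_len(K)) surv[max_order >= k, k] <- 0L
    dd <- data[died, , drop = FALSE]
    if (nrow(dd)) {
      ks <- dd$visit_order + 1L
      ok <- ks <= K
      surv[cbind(match(dd$subject_id[ok], ids), ks[ok])] <- 1L
      # no outcome rows may follow a death interval
      for (r in which(ok)) {
        later <- data$subject_id == dd$subject_id[ok][r] & data$visit_order >= ks[ok][r]
        if (any(later)) stop("subject ", dd$subject_id[ok][r],
                             " has outcome rows after its death interval")
      }
    }
  }

  list(ids = ids, n = n, nelem = as.integer(nelem),
       y = el_y[o2], t = el_t[o2], lam = el_lam[o2],
       occ = as.integer(el_occ[o2]), out = as.integer(el_out[o2]),
       X = X, surv = surv, n_obs = length(el_y))
}

#' Validate long-format cohort invariants
#'
#' Checks the structural invariants a subject-visit table must satisfy before
#' modeling: each subject's first visit (order 0) is at time 0, times are
#' strictly increasing within subject, subjects have between 1 and
#' `max_visits` visits, and no outcome rows follow a death interval.
#'
#' @param data long-format cohort (one row per subject-visit).
#' @param max_visits maximum planned visits (default 3).
#' @return `data`, invisibly; invalid data raises an error.
#' @export
validate_cohort <- function(data, max_visits = 3L) {
  data <- as.data.frame(data)
  sp <- split(data, data$subject_id)
  for (d in sp) {
    d <- d[order(d$visit_order), , drop = FALSE]
    if (d$visit_order[1] == 0 && abs(d$time_in_study[1]) > 1e-9)
      stop("subject ", d$subject_id[1], ": visit 0 must be at time 0")
    if (nrow(d) > 1 && any(diff(d$time_in_study) <= 0))
      stop("subject ", d$subject_id[1], ": times must be strictly increasing")
    if (nrow(d) < 1 || nrow(d) > max_visits)
      stop("subject ", d$subject_id[1], ": must have 1..", max_visits, " visits")
    if ("died_in_next_interval" %in% names(d)) {
      w <- which(d$died_in_next_interval %in% TRUE)
      if (length(w) && any(seq_len(nrow(d)) > min(w)))
        stop("subject ", d$subject_id[1], ": outcome rows after death interval")
    }
  }
  invisible(data)
}
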