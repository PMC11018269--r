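#' Gauss-Hermite quadrature rule for the latent factors
#'
#' Tensor-product Gauss-Hermite rule used to integrate the survival likelihood
#' over the latent growth factors the hazard is regressed on. The joint
#' likelihood factors the Gaussian longitudinal part analytically and
#' integrates only the survival factor against the (Gaussian) posterior of the
#' latent factors given the observed outcomes, so the rule is re-centered at
#' each subject's posterior automatically.
#'
#' @param n_points nodes per latent dimension (default 15; must be >= 3).
#' @param dim number of latent dimensions (2 for a hazard regressed on the
#'   intercept and slope of one process).
#' @return An object of class `gh_rule` with a `Q x dim` node matrix (on the
#'   raw Gauss-Hermite scale) and normalized log-weights summing to 1 on the
#'   probability scale.
#' @export
#' @examples
#' r <- gh_rule(7, 2)
#' sum(exp(r$logw))  # 1
gh_rule <- function(n_points = 15L, dim = 2L) {
  if (n_points < 3L) stop("n_points must be >= 3")
  if (dim < 1L) stop("dim must be >= 1")
  g <- pracma::gaussHermite(n_points)
  nodes <- as.matrix(expand.grid(rep(list(g$x), dim)))
  lw <- rowSums(as.matrix(expand.grid(rep(list(log(g$w)), dim)))) - dim / 2 * log(pi)
  structure(list(nodes = unname(nodes), logw = lw,
                 n_points = as.integer(n_points), dim = as.integer(dim)),
            class = "gh_rule")
}

#' @export
print.gh_rule <- function(x, ...) {
  cat("Gauss-Hermite rule:", x$n_points, "points per dimension,",
      x$dim, "dimension(s),", nrow(x$nodes), "nodes total\n")
  invisible(x)
}
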