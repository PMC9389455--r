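#' Cluster-robust (sandwich) parameter covariance
#'
#' Computes \eqn{A^{-1} B A^{-1}} where \eqn{A} is the observed information
#' of the marginal likelihood and \eqn{B = \sum_c s_c s_c'} sums the outer
#' products of within-cluster score sums. With repeated measures (several
#' rows per subject) this corrects standard errors for residual correlation
#' within subject; with singleton clusters and a correctly specified model it
#' agrees asymptotically with the model-based covariance.
#'
#' @param fit a `"mimic_fit"` carrying per-row scores and (unless `info` is
#'   supplied) an observed information matrix (fit with `se = "model"`).
#' @param clusters length-n cluster labels; defaults to the fit's clusters.
#' @param info optional observed information to use for \eqn{A}.
#' @return the sandwich covariance matrix.
#' @export
cluster_sandwich_cov <- function(fit, clusters = fit$cluster, info = fit$info) {
  if (is.null(clusters)) stop("no cluster labels available")
  if (is.null(info)) stop("observed information unavailable; fit with se = \"model\"")
  stopifnot(length(clusters) == nrow(fit$scores))
  Sc <- rowsum(fit$scores, group = clusters)
  B <- crossprod(Sc)
  Ainv <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
  if (is.null(Ainv)) {
    stop(sprintf("observed information is singular (condition number %s)",
                 format(kappa(info), digits = 3)))
  }
  V <- Ainv %*% B %*% Ainv
  V <- (V + t(V)) / 2
  dimnames(V) <- dimnames(info)
  V
}

#' Wald test for a single coefficient
#'
#' \eqn{t = \hat\beta / se}, with a two-sided p-value from the standard
#' normal reference distribution (the large-sample convention used for all
#' DIF and brain-behavior coefficient reports).
#'
#' @param estimate coefficient estimate(s).
#' @param se standard error(s); must be positive.
#' @return list with elements `t` and `p` (vectorized).
#' @export
wald_test <- function(estimate, se) {
  if (any(!is.finite(se)) || any(se <= 0)) stop("'se' must be positive")
  t <- estimate / se
  list(t = t, p = 2 * stats::pnorm(-abs(t)))
}
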