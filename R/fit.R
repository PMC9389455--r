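#' Control parameters for MIMIC model fitting
#'
#' @param quadrature number of Gauss-Hermite nodes (or a rule from
#'   [make_quadrature()]).
#' @param maxit maximum BFGS iterations.
#' @param reltol relative log-likelihood convergence tolerance passed to
#'   [stats::optim()].
#' @param grad_tol infinity-norm tolerance on the score vector used to set
#'   the `converged` flag.
#' @param hessian_step relative step for the central-difference observed
#'   information.
#' @return a list of class `"mimic_control"`.
#' @export
mimic_control <- function(quadrature = 61, maxit = 500, reltol = 1e-8,
                          grad_tol = 0.05, hessian_step = 1e-5) {
  structure(list(quadrature = quadrature, maxit = maxit, reltol = reltol,
                 grad_tol = grad_tol, hessian_step = hessian_step),
            class = "mimic_control")
}

# transformed <-> natural parameter maps; lambda via atanh (probit only),
# gamma via the open-unit-ball map g -> g/sqrt(1 + g'g)
par_to_trans <- function(par, I, k, probit, n_beta) {
  lambda <- par[seq_len(I)]
  l <- if (probit) atanh(pmin(pmax(lambda, -0.999), 0.999)) else lambda
  out <- c(l, par[I + seq_len(I)])
  if (k > 0L) {
    gamma <- par[2L * I + seq_len(k)]
    ss <- sum(gamma^2)
    g <- gamma / sqrt(max(1 - ss, 1e-8))
    out <- c(out, g)
  }
  if (n_beta > 0L) out <- c(out, par[2L * I + k + seq_len(n_beta)])
  out
}

trans_to_par <- function(tp, I, k, probit, n_beta) {
  l <- tp[seq_len(I)]
  lambda <- if (probit) tanh(l) else l
  out <- c(lambda, tp[I + seq_len(I)])
  if (k > 0L) {
    g <- tp[2L * I + seq_len(k)]
    out <- c(out, g / sqrt(1 + sum(g^2)))
  }
  if (n_beta > 0L) out <- c(out, tp[2L * I + k + seq_len(n_beta)])
  out
}

grad_to_trans <- function(grad, tp, I, k, probit, n_beta) {
  out <- grad
  if (probit) {
    l <- tp[seq_len(I)]
    out[seq_len(I)] <- grad[seq_len(I)] * (1 - tanh(l)^2)
  }
  if (k > 0L) {
    idx <- 2L * I + seq_len(k)
    g <- tp[idx]
    cc <- 1 / sqrt(1 + sum(g^2))
    gg <- grad[idx]
    out[idx] <- cc * gg - cc^3 * g * sum(g * gg)
  }
  out
}

#' Fit a MIMIC (latent-regression IRT) model by marginal maximum likelihood
#'
#' `mimic()` is the workhorse estimator of the package. A unidimensional
#' latent trait \eqn{\theta} is measured by binary items through a
#' two-parameter probit (default) or logit response model and regressed on
#' observed causes: \eqn{\theta_j = \gamma'x_j + \zeta_j}. The model is
#' standardized so \eqn{Var(\theta) = 1}, i.e.
#' \eqn{Var(\zeta) = 1 - \sum\gamma_k^2}; loadings, thresholds and
#' \eqn{\gamma} are estimated jointly by maximizing the marginal likelihood
#' (latent trait integrated on a fixed Gauss-Hermite rule) with BFGS and
#' analytic scores. Without covariates this is the plain 2PL. A single item
#' may additionally carry free DIF terms: uniform DIF frees a direct
#' covariate effect on that item's intercept, nonuniform DIF a covariate
#' moderation of its loading.
#'
#' Degenerate items (all observed responses identical) are dropped with a
#' warning. Respondents with all-missing response vectors are retained (their
#' posterior is the prior). Non-convergence is flagged in the result, not
#' raised as an error.
#'
#' @param y n x I binary response matrix; NAs are skipped item-wise.
#' @param x optional n x k covariate matrix (the causes); `NULL` for a 2PL.
#' @param cluster optional length-n cluster labels (e.g. subject ids for
#'   repeated measures); enables the cluster-robust sandwich covariance.
#' @param dif_item optional single item index carrying free DIF terms.
#' @param dif_kind `"uniform"` (intercept DIF) or `"nonuniform"` (loading
#'   DIF); used only when `dif_item` is given.
#' @param link `"probit"` or `"logit"`.
#' @param se `"model"` to compute the observed-information covariance (and
#'   the sandwich covariance when `cluster` is given), `"none"` to skip the
#'   Hessian (much faster; point estimates only).
#' @param control a [mimic_control()] list.
#' @return an object of class `"mimic_fit"`; see Details. Key elements:
#'   `bank` and `latent` (estimated [item_bank()] / [latent_structure()]),
#'   `coefficients`, `loglik`, `model_cov`, `sandwich_cov`, `scores`
#'   (n x p score matrix), `ability` (EAP and posterior SD per respondent),
#'   `converged`, `grad_norm`, `n_iter`, and for DIF fits `dif_test`
#'   (per-covariate Wald statistics).
#' @seealso [fit_2pl()], [fit_mimic()], [fit_mimic_with_dif()],
#'   [cluster_sandwich_cov()]
#' @examples
#' set.seed(1)
#' bank <- item_bank(loading = rep(c(0.4, 0.8), 5), difficulty = seq(-1, 1, length = 10))
#' pop <- latent_structure(gamma = 0.5)
#' dat <- simulate_mimic_dataset(bank, pop, n = 300)
#' fit <- mimic(dat$y, dat$x, se = "none")
#' coef(fit)["gamma1"]
#' @export
mimic <- function(y, x = NULL, cluster = NULL, dif_item = NULL,
                  dif_kind = c("uniform", "nonuniform"),
                  link = c("probit", "logit"), se = c("model", "none"),
                  control = mimic_control()) {
  link <- match.arg(link)
  se <- match.arg(se)
  cl <- match.call()
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  n <- nrow(y)
  if (!is.null(x)) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    stopifnot(nrow(x) == n)
    if (anyNA(x)) stop("covariates must be complete")
  }
  k <- if (is.null(x)) 0L else ncol(x)
  if (!is.null(dif_item)) {
    dif_kind <- match.arg(dif_kind)
    if (k == 0L) stop("DIF terms require covariates")
    stopifnot(length(dif_item) == 1L, dif_item >= 1, dif_item <= ncol(y))
  } else dif_kind <- NULL

  # drop degenerate items (all observed responses identical)
  obs_mean <- colMeans(y, na.rm = TRUE)
  n_obs <- colSums(!is.na(y))
  degenerate <- n_obs == 0L | obs_mean %in% c(0, 1)
  kept <- unname(which(!degenerate))
  if (length(kept) < ncol(y)) {
    warning(sprintf("dropping %d degenerate item(s): %s",
                    sum(degenerate), paste(which(degenerate), collapse = ", ")))
    if (!is.null(dif_item)) {
      if (degenerate[dif_item]) stop("the DIF item is degenerate")
      dif_item <- match(dif_item, kept)
    }
    y <- y[, kept, drop = FALSE]
  }
  I <- ncol(y)
  if (I < 2L) stop("need at least two non-degenerate items")

  rule <- as_quadrature(control$quadrature)
  obj <- mimic_objective(y, x, rule, link = link,
                         dif_item = dif_item, dif_kind = dif_kind)
  n_beta <- if (!is.null(dif_item)) k else 0L
  probit <- link == "probit"

  start <- mimic_start(y, x, link)
  if (n_beta > 0L) start <- c(start, rep(0, n_beta))
  tp0 <- par_to_trans(start, I, k, probit, n_beta)

  # cache so optim's paired fn/gr calls cost one evaluation
  cache <- new.env(parent = emptyenv())
  evalat <- function(tp) {
    key <- paste(tp, collapse = ",")
    if (!identical(cache$key, key)) {
      par <- trans_to_par(tp, I, k, probit, n_beta)
      res <- obj$eval(par, want_scores = TRUE)
      cache$key <- key
      cache$res <- res
      cache$par <- par
    }
    cache$res
  }
  fn <- function(tp) -evalat(tp)$loglik
  gr <- function(tp) {
    res <- evalat(tp)
    -grad_to_trans(colSums(res$scores), tp, I, k, probit, n_beta)
  }

  opt <- tryCatch(
    stats::optim(tp0, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = control$maxit,
                                factr = control$reltol / .Machine$double.eps)),
    error = function(e) tryCatch(
      stats::optim(tp0, fn, gr, method = "BFGS",
                   control = list(maxit = control$maxit,
                                  reltol = control$reltol)),
      error = function(e2) e2))
  failed <- inherits(opt, "error")
  if (failed) {
    tp_hat <- tp0
    warning("optimization failed: ", conditionMessage(opt))
  } else tp_hat <- opt$par

  par_hat <- trans_to_par(tp_hat, I, k, probit, n_beta)
  final <- obj$eval(par_hat, want_scores = TRUE, want_posterior = TRUE)
  grad_nat <- colSums(final$scores)
  grad_norm <- max(abs(grad_nat))
  converged <- !failed && opt$convergence == 0 && grad_norm < control$grad_tol * n

  lambda_hat <- par_hat[seq_len(I)]
  tau_hat <- par_hat[I + seq_len(I)]
  gamma_hat <- if (k > 0L) par_hat[2L * I + seq_len(k)] else numeric(0)
  beta_hat <- if (n_beta > 0L) par_hat[2L * I + k + seq_len(n_beta)] else NULL

  dif_int <- matrix(0, I, k); dif_load <- matrix(0, I, k)
  if (!is.null(dif_item)) {
    if (dif_kind == "uniform") dif_int[dif_item, ] <- beta_hat
    else dif_load[dif_item, ] <- beta_hat
  }
  # guard against boundary loadings when rebuilding the bank
  lam_bank <- if (probit) pmin(pmax(lambda_hat, 1e-4), 1 - 1e-8) else lambda_hat
  bank <- item_bank(loading = lam_bank, threshold = tau_hat,
                    dif_intercept = if (k > 0L) dif_int else NULL,
                    dif_loading = if (k > 0L) dif_load else NULL,
                    link = link)
  latent <- latent_structure(gamma_hat,
                             resid_var = max(1 - sum(gamma_hat^2), 0))

  coefs <- par_hat
  names(coefs) <- obj$parnames

  fit <- structure(list(
    call = cl, bank = bank, latent = latent, coefficients = coefs,
    loglik = final$loglik, n = n, n_items = I, k = k, kept_items = kept,
    link = link, quadrature = rule, dif_item = dif_item, dif_kind = dif_kind,
    scores = `colnames<-`(final$scores, obj$parnames),
    cluster = cluster,
    ability = data.frame(eap = final$eap, psd = final$psd),
    converged = converged, failed = failed, grad_norm = grad_norm,
    n_iter = if (failed) NA_integer_ else opt$counts[["function"]],
    model_cov = NULL, sandwich_cov = NULL, info = NULL,
    x = x, y = y, control = control), class = "mimic_fit")

  if (se == "model") {
    fit$info <- observed_information(obj, par_hat, control$hessian_step)
    fit$model_cov <- cov_from_info(fit$info, obj$parnames)
    if (!is.null(cluster)) {
      fit$sandwich_cov <- tryCatch(cluster_sandwich_cov(fit, cluster),
                                   error = function(e) {
                                     warning("sandwich covariance failed: ",
                                             conditionMessage(e))
                                     NULL
                                   })
    }
    if (!is.null(dif_item)) fit$dif_test <- dif_wald_table(fit)
  }
  fit
}

# starting values: thresholds from inverse-link item means, loadings from
# item-total correlations, gamma from OLS of the z-scored proportion correct
mimic_start <- function(y, x, link) {
  I <- ncol(y)
  p <- pmin(pmax(colMeans(y, na.rm = TRUE), 0.02), 0.98)
  tau0 <- if (link == "probit") -stats::qnorm(p) else -stats::qlogis(p)
  prop <- rowMeans(y, na.rm = TRUE)
  prop[is.nan(prop)] <- mean(prop, na.rm = TRUE)
  r <- suppressWarnings(stats::cor(y, prop, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0.3
  lam0 <- pmin(pmax(r * 1.1, 0.15), 0.85)
  if (link == "logit") lam0 <- lam0 / sqrt(1 - lam0^2) * 1.7
  start <- c(lam0, tau0)
  if (!is.null(x)) {
    z <- prop - mean(prop)
    sdz <- stats::sd(z)
    g0 <- if (sdz > 0) {
      drop(stats::coef(stats::lm.fit(cbind(1, x), z / sdz))[-1])
    } else rep(0, ncol(x))
    ss <- sum(g0^2)
    if (ss > 0.64) g0 <- g0 * sqrt(0.64 / ss)
    start <- c(start, g0)
  }
  start
}

# observed information (negative Hessian of the marginal log-likelihood) by
# central differences of the analytic score, symmetrized
observed_information <- function(obj, par, rel_step = 1e-5) {
  p <- length(par)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    h <- rel_step * (1 + abs(par[j]))
    pp <- par; pp[j] <- par[j] + h
    pm <- par; pm[j] <- par[j] - h
    gp <- colSums(obj$eval(pp, want_scores = TRUE)$scores)
    gm <- colSums(obj$eval(pm, want_scores = TRUE)$scores)
    H[, j] <- (gp - gm) / (2 * h)
  }
  A <- -(H + t(H)) / 2
  dimnames(A) <- list(obj$parnames, obj$parnames)
  A
}

cov_from_info <- function(A, parnames) {
  V <- tryCatch(chol2inv(chol(A)), error = function(e) {
    tryCatch(solve(A), error = function(e2) NULL)
  })
  if (is.null(V)) {
    warning("observed information is singular (condition number ",
            format(kappa(A), digits = 3), "); model covariance unavailable")
    return(NULL)
  }
  V <- (V + t(V)) / 2
  dimnames(V) <- list(parnames, parnames)
  V
}

dif_wald_table <- function(fit) {
  pre <- if (fit$dif_kind == "uniform") "bdif" else "bdis"
  idx <- grep(paste0("^", pre), names(fit$coefficients))
  V <- if (!is.null(fit$sandwich_cov)) fit$sandwich_cov else fit$model_cov
  if (is.null(V)) return(NULL)
  est <- fit$coefficients[idx]
  sev <- sqrt(pmax(diag(V)[idx], 0))
  wt <- wald_test(est, sev)
  data.frame(term = names(est), estimate = unname(est), se = unname(sev),
             t = wt$t, p = wt$p,
             se_type = if (!is.null(fit$sandwich_cov)) "sandwich" else "model",
             row.names = NULL)
}

#' Fit a two-parameter IRT model (no causes)
#'
#' Marginal-ML 2PL with the latent trait standardized to \eqn{N(0,1)};
#' equivalent to [mimic()] with no covariates. EAP ability estimates are
#' returned in the fit's `ability` element.
#'
#' @inheritParams mimic
#' @param ... passed to [mimic()].
#' @return a `"mimic_fit"` object; `$ability` holds EAP scores and posterior
#'   SDs.
#' @export
fit_2pl <- function(y, link = "probit", se = "model", ...) {
  mimic(y, x = NULL, link = link, se = se, ...)
}

#' Fit the joint MIMIC model
#'
#' @inheritParams mimic
#' @param ... passed to [mimic()].
#' @return a `"mimic_fit"` object.
#' @export
fit_mimic <- function(y, x, cluster = NULL, link = "probit", se = "model", ...) {
  mimic(y, x = x, cluster = cluster, link = link, se = se, ...)
}

#' Fit a MIMIC model with free DIF terms on one item
#'
#' Uniform DIF frees a direct covariate path into the tested item's
#' intercept (a difficulty shift per covariate unit, the mediation check:
#' DIF is present when the cause's effect on the item is not fully mediated
#' by the latent trait). Nonuniform DIF frees a covariate moderation of the
#' item's loading (a discrimination shift, the moderated-mediation check).
#' All other items' DIF terms stay fixed at zero. Wald statistics for the
#' freed coefficients are returned in `$dif_test` (sandwich-based when
#' `cluster` is given).
#'
#' @inheritParams mimic
#' @param item_index the single item whose DIF terms are freed.
#' @param kind `"uniform"` or `"nonuniform"`.
#' @param ... passed to [mimic()].
#' @return a `"mimic_fit"` object with a `dif_test` data.frame.
#' @export
fit_mimic_with_dif <- function(y, x, cluster = NULL, item_index,
                               kind = c("uniform", "nonuniform"),
                               se = "model", ...) {
  kind <- match.arg(kind)
  mimic(y, x = x, cluster = cluster, dif_item = item_index, dif_kind = kind,
        se = se, ...)
}
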