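# Marginal-likelihood machinery for the latent-regression (MIMIC) 2PL.
#
# The latent trait is integrated out on a fixed Gauss-Hermite rule with base
# measure N(0,1). The covariate-shifted prior N(mu_j, sigma^2) of respondent j
# is handled by reweighting the fixed rule with the density ratio
# phi(theta; mu_j, sigma)/phi(theta; 0, 1), normalized per respondent. Keeping
# one grid lets all non-DIF item probabilities be computed once per iteration
# (items x nodes), so a full evaluation of the log-likelihood and the n x p
# score matrix costs two n x items x nodes matrix products.

# parameter layout (natural scale):
#   lambda[1..I], tau[1..I], gamma[1..k] (if k > 0),
#   beta[1..k] for the single DIF item (uniform -> intercept shifts,
#   nonuniform -> loading shifts)
mimic_parnames <- function(I, k, dif_item = NULL, dif_kind = NULL) {
  nm <- c(paste0("lambda", seq_len(I)), paste0("tau", seq_len(I)))
  if (k > 0L) nm <- c(nm, paste0("gamma", seq_len(k)))
  if (!is.null(dif_item)) {
    pre <- if (dif_kind == "uniform") "bdif" else "bdis"
    nm <- c(nm, paste0(pre, seq_len(k)))
  }
  nm
}

# Builds closures evaluating the marginal log-likelihood and score matrix.
# Y: n x I binary matrix with NAs; X: n x k or NULL; rule: mimic_quadrature.
mimic_objective <- function(Y, X, rule, link = "probit",
                            dif_item = NULL, dif_kind = NULL) {
  M <- !is.na(Y)
  Y1 <- ifelse(M, Y, 0)           # indicator of observed endorsement
  Y0 <- ifelse(M, 1 - Y, 0)       # indicator of observed non-endorsement
  storage.mode(Y1) <- "double"; storage.mode(Y0) <- "double"
  n <- nrow(Y); I <- ncol(Y)
  k <- if (is.null(X)) 0L else ncol(X)
  th <- rule$nodes; q <- length(th)
  logw <- log(rule$weights)
  probit <- link == "probit"
  npar <- 2L * I + k + if (!is.null(dif_item)) k else 0L

  unpack <- function(par) {
    lambda <- par[seq_len(I)]
    tau <- par[I + seq_len(I)]
    gamma <- if (k > 0L) par[2L * I + seq_len(k)] else numeric(0)
    beta <- if (!is.null(dif_item)) par[2L * I + k + seq_len(k)] else numeric(0)
    list(lambda = lambda, tau = tau, gamma = gamma, beta = beta)
  }

  # log F and log(1-F) on a matrix of linear predictors, stably
  logF <- if (probit) function(z) stats::pnorm(z, log.p = TRUE)
          else function(z) stats::plogis(z, log.p = TRUE)
  # d log F / dz and -d log(1-F) / dz
  ratio1 <- if (probit) {
    function(z, lp) exp(stats::dnorm(z, log = TRUE) - lp)
  } else {
    function(z, lp) stats::plogis(-z)
  }
  ratio0 <- if (probit) {
    function(z, lq) exp(stats::dnorm(z, log = TRUE) - lq)
  } else {
    function(z, lq) stats::plogis(z)
  }

  eval_core <- function(par, want_scores = FALSE, want_posterior = FALSE) {
    pp <- unpack(par)
    lambda <- pp$lambda; tau <- pp$tau; gamma <- pp$gamma; beta <- pp$beta
    s <- if (probit) sqrt(pmax(1 - lambda^2, 1e-10)) else rep(1, I)

    # item probabilities on the grid (I x q)
    Zg <- (outer(lambda, th) - tau) / s
    logPg <- logF(Zg); logQg <- logF(-Zg)

    LF <- Y1 %*% logPg + Y0 %*% logQg          # n x q pattern log-likelihood

    Zd <- NULL
    if (!is.null(dif_item)) {
      d <- dif_item
      # remove item d's grid contribution, add its person-specific one
      LF <- LF - Y1[, d] %o% logPg[d, ] - Y0[, d] %o% logQg[d, ]
      u <- numeric(n); v <- numeric(n)
      if (dif_kind == "uniform") u <- drop(X %*% beta) else v <- drop(X %*% beta)
      slope_d <- lambda[d] + v                                   # length n
      Zd <- (slope_d %o% th + (u - tau[d])) / s[d]               # n x q
      logPd <- logF(Zd); logQd <- logF(-Zd)
      LF <- LF + M[, d] * (Y1[, d] * logPd + Y0[, d] * logQd)
    }

    # per-respondent prior weights on the grid
    if (k > 0L) {
      mu <- drop(X %*% gamma)
      sig2 <- max(1 - sum(gamma^2), 1e-10)
      aq <- logw + th^2 * (0.5 - 0.5 / sig2)
      LW <- matrix(aq, n, q, byrow = TRUE) + (mu / sig2) %o% th
      mx <- matrixStats_rowMaxs(LW)
      W <- exp(LW - mx)
      rs <- rowSums(W)
      W <- W / rs
      logWn <- LW - mx - log(rs)
    } else {
      mu <- rep(0, n); sig2 <- 1
      logWn <- matrix(logw, n, q, byrow = TRUE)
      W <- matrix(rule$weights, n, q, byrow = TRUE)
    }

    A <- LF + logWn
    mA <- matrixStats_rowMaxs(A)
    eA <- exp(A - mA)
    rsA <- rowSums(eA)
    ll_i <- mA + log(rsA)
    out <- list(loglik = sum(ll_i), loglik_i = ll_i)

    if (want_scores || want_posterior) {
      R <- eA / rsA                            # n x q posterior over nodes
      if (want_posterior) {
        out$posterior <- R
        out$eap <- drop(R %*% th)
        out$psd <- sqrt(pmax(drop(R %*% th^2) - out$eap^2, 0))
      }
      if (want_scores) {
        S <- matrix(0, n, npar)
        D1 <- ratio1(Zg, logPg); D0 <- ratio0(Zg, logQg)   # I x q
        dZdl <- if (probit) {
          sweep(Zg, 1, lambda / s^2, "*") + outer(1 / s, th)
        } else {
          matrix(th, I, q, byrow = TRUE)
        }
        G1l <- R %*% t(D1 * dZdl); G0l <- R %*% t(D0 * dZdl)
        G1 <- R %*% t(D1); G0 <- R %*% t(D0)
        S_lam <- Y1 * G1l - Y0 * G0l
        S_tau <- -sweep(Y1 * G1 - Y0 * G0, 2, 1 / s, "*")
        if (!is.null(dif_item)) {
          d <- dif_item
          D1d <- ratio1(Zd, logF(Zd)); D0d <- ratio0(Zd, logF(-Zd))  # n x q
          TH <- matrix(th, n, q, byrow = TRUE)
          e1 <- rowSums(R * D1d); e0 <- rowSums(R * D0d)
          e1t <- rowSums(R * D1d * TH); e0t <- rowSums(R * D0d * TH)
          E <- Y1[, d] * e1 - Y0[, d] * e0
          Et <- Y1[, d] * e1t - Y0[, d] * e0t
          # dZd/dlambda_d = theta/s_d + Zd * lambda_d/s_d^2 (probit), theta (logit)
          if (probit) {
            e1z <- rowSums(R * D1d * Zd); e0z <- rowSums(R * D0d * Zd)
            Ez <- Y1[, d] * e1z - Y0[, d] * e0z
            S_lam[, d] <- Et / s[d] + (lambda[d] / s[d]^2) * Ez
          } else {
            S_lam[, d] <- Et
          }
          S_tau[, d] <- -E / s[d]
          if (dif_kind == "uniform") {
            S_beta <- X * (E / s[d])
          } else {
            S_beta <- X * (Et / s[d])
          }
        }
        S[, seq_len(I)] <- S_lam
        S[, I + seq_len(I)] <- S_tau
        if (k > 0L) {
          Dq <- R - W
          A1 <- drop(Dq %*% th); A2 <- drop(Dq %*% th^2)
          T1 <- A1 / sig2
          T2 <- (A2 - 2 * mu * A1) / sig2^1.5
          sg <- sqrt(sig2)
          Sg <- X * T1 - outer(T2 / sg, gamma)
          S[, 2L * I + seq_len(k)] <- Sg
        }
        if (!is.null(dif_item)) S[, 2L * I + k + seq_len(k)] <- S_beta
        out$scores <- S
      }
    }
    out
  }

  list(eval = eval_core, npar = npar, n = n, I = I, k = k,
       parnames = mimic_parnames(I, k, dif_item, dif_kind))
}

# rowMaxs without a matrixStats dependency
matrixStats_rowMaxs <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
}

#' Marginal log-likelihood of a MIMIC model at given parameters
#'
#' Integrates the conditional response likelihood over the latent trait
#' \eqn{\theta \sim N(\gamma'x_j, \sigma^2_\zeta)} on a Gauss-Hermite rule,
#' item-wise skipping missing responses. Mainly useful for diagnostics and
#' for validating the quadrature against brute-force integration.
#'
#' @param bank an [item_bank()] holding the measurement parameters.
#' @param latent a [latent_structure()]; use `latent_structure(numeric(0))`
#'   for a pure 2PL.
#' @param y n x n_items binary response matrix (NAs allowed).
#' @param x n x k covariate matrix (required when the structure has causes).
#' @param cluster optional cluster labels for per-cluster score sums.
#' @param quadrature node count or a [make_quadrature()] rule.
#' @return list with `loglik`, per-respondent `loglik_i`, and (when `cluster`
#'   is given) `cluster_scores`, the per-cluster sums of parameter score
#'   vectors.
#' @export
marginal_loglik <- function(bank, latent, y, x = NULL, cluster = NULL,
                            quadrature = 61) {
  rule <- as_quadrature(quadrature)
  y <- as.matrix(y)
  k <- latent$n_covariates
  if (k > 0L) {
    x <- as.matrix(x)
    stopifnot(nrow(x) == nrow(y), ncol(x) == k)
    if (anyNA(x)) stop("covariates must be complete")
  } else x <- NULL
  obj <- mimic_objective(y, x, rule, link = bank$link)
  par <- c(bank$loading, bank$threshold, latent$gamma)
  if (!all(is.finite(par))) stop("non-finite parameters")
  res <- obj$eval(par, want_scores = !is.null(cluster))
  out <- list(loglik = res$loglik, loglik_i = res$loglik_i)
  if (!is.null(cluster)) {
    sc <- rowsum(res$scores, group = cluster)
    colnames(sc) <- obj$parnames
    out$cluster_scores <- sc
  }
  out
}
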