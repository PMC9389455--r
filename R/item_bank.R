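#' Item bank for a MIMIC-structured itemset
#'
#' An item bank stores the measurement side of the model: per-item loadings
#' and thresholds on the latent-response scale, plus optional differential
#' item functioning (DIF) coefficients linking each item directly to the
#' causal covariates. Under the probit (normal-ogive) parameterization the
#' latent response of item \eqn{i} is
#' \deqn{y^*_i = \lambda_i \theta + (\beta_{dis,i}'x)\,\theta +
#'   \beta_{dif,i}'x + \epsilon_i,\qquad \epsilon_i \sim N(0, 1-\lambda_i^2),}
#' and \eqn{y_i = 1} iff \eqn{y^*_i > \tau_i}. With \eqn{Var(\theta) = 1}
#' this keeps \eqn{Var(y^*_i) = 1}, so loadings are standardized and the
#' classical 2PL display parameters are \eqn{a_i = \lambda_i/\sqrt{1-\lambda_i^2}}
#' and \eqn{b_i = \tau_i/\lambda_i}. Under the logit link the loading slot
#' holds the discrimination \eqn{a_i} directly and the residual is standard
#' logistic.
#'
#' @param loading numeric vector of loadings; in (0, 1) for probit.
#' @param difficulty latent-trait difficulties \eqn{b_i}; exactly one of
#'   `difficulty`/`threshold` must be given (the other is derived via
#'   \eqn{\tau_i = b_i \lambda_i}).
#' @param threshold latent-response thresholds \eqn{\tau_i}.
#' @param dif_intercept optional n_items x k matrix of uniform-DIF
#'   coefficients \eqn{\beta_{dif}} (difficulty shifts per covariate).
#' @param dif_loading optional n_items x k matrix of nonuniform-DIF
#'   coefficients \eqn{\beta_{dis}} (discrimination shifts per covariate).
#' @param link `"probit"` (default) or `"logit"`.
#' @return an object of class `"item_bank"`.
#' @seealso [item_prob()], [simulate_mimic_dataset()]
#' @export
item_bank <- function(loading, difficulty = NULL, threshold = NULL,
                      dif_intercept = NULL, dif_loading = NULL,
                      link = c("probit", "logit")) {
  link <- match.arg(link)
  loading <- as.numeric(loading)
  n_items <- length(loading)
  if (n_items < 1L) stop("need at least one item")
  if (link == "probit" && any(loading <= 0 | loading >= 1)) {
    stop("probit loadings must lie strictly in (0, 1)")
  }
  if (is.null(difficulty) == is.null(threshold)) {
    stop("give exactly one of 'difficulty' or 'threshold'")
  }
  if (is.null(threshold)) {
    difficulty <- as.numeric(difficulty)
    if (length(difficulty) != n_items) stop("length mismatch: difficulty")
    threshold <- difficulty * loading
  } else {
    threshold <- as.numeric(threshold)
    if (length(threshold) != n_items) stop("length mismatch: threshold")
    difficulty <- threshold / loading
  }
  k <- 0L
  for (nm in c("dif_intercept", "dif_loading")) {
    m <- get(nm)
    if (!is.null(m)) {
      m <- as.matrix(m)
      if (nrow(m) != n_items) stop(nm, " must have one row per item")
      k <- max(k, ncol(m))
      assign(nm, m)
    }
  }
  if (is.null(dif_intercept)) dif_intercept <- matrix(0, n_items, k)
  if (is.null(dif_loading)) dif_loading <- matrix(0, n_items, k)
  if (ncol(dif_intercept) != ncol(dif_loading)) {
    stop("dif_intercept and dif_loading must have the same covariate count")
  }
  structure(list(n_items = n_items, loading = loading,
                 difficulty = difficulty, threshold = threshold,
                 dif_intercept = dif_intercept, dif_loading = dif_loading,
                 link = link),
            class = "item_bank")
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("Item bank: %d items, link = %s\n", x$n_items, x$link))
  has_dif <- any(x$dif_intercept != 0) || any(x$dif_loading != 0)
  cat(sprintf("  loading in [%.3f, %.3f], difficulty in [%.3f, %.3f], DIF: %s\n",
              min(x$loading), max(x$loading),
              min(x$difficulty), max(x$difficulty),
              if (has_dif) "yes" else "none"))
  invisible(x)
}

#' @export
as.data.frame.item_bank <- function(x, ...) {
  data.frame(item = seq_len(x$n_items),
             lambda = x$loading,
             a = discrimination(x),
             b = x$difficulty,
             tau = x$threshold)
}

#' Display-scale discrimination parameters
#'
#' Converts probit loadings to normal-ogive discriminations
#' \eqn{a_i = \lambda_i/\sqrt{1-\lambda_i^2}}; for a logit bank the loading
#' slot already holds \eqn{a_i}.
#' @param bank an [item_bank()].
#' @return numeric vector of discriminations.
#' @export
discrimination <- function(bank) {
  if (bank$link == "probit") bank$loading / sqrt(1 - bank$loading^2)
  else bank$loading
}

# residual SD of the latent response per item
item_resid_sd <- function(bank) {
  if (bank$link == "probit") sqrt(1 - bank$loading^2) else rep(1, bank$n_items)
}

#' Endorsement probability of one item
#'
#' Evaluates \eqn{P(y_i = 1 \mid \theta, x) = F\{(\lambda_i\theta +
#' (\beta_{dis,i}'x)\theta + \beta_{dif,i}'x - \tau_i)/s_i\}} with
#' \eqn{s_i = \sqrt{1-\lambda_i^2}} (probit) or \eqn{s_i = 1} (logit).
#'
#' @param bank an [item_bank()].
#' @param item item index.
#' @param theta latent-trait value(s).
#' @param covariates optional covariate vector (or matrix with one row per
#'   theta) entering the item's DIF terms.
#' @return vector of probabilities, one per theta.
#' @export
item_prob <- function(bank, item, theta, covariates = NULL) {
  stopifnot(item >= 1, item <= bank$n_items)
  lam <- bank$loading[item]
  tau <- bank$threshold[item]
  s <- item_resid_sd(bank)[item]
  u <- 0; v <- 0
  if (!is.null(covariates) && ncol(bank$dif_intercept) > 0L) {
    xm <- if (is.matrix(covariates)) covariates else
      matrix(covariates, nrow = length(theta), ncol = length(covariates),
             byrow = TRUE)
    u <- drop(xm %*% bank$dif_intercept[item, ])
    v <- drop(xm %*% bank$dif_loading[item, ])
  }
  z <- ((lam + v) * theta + u - tau) / s
  if (bank$link == "probit") stats::pnorm(z) else stats::plogis(z)
}

#' Latent causal structure of a MIMIC model
#'
#' The structural side of the model: the latent trait is
#' \eqn{\theta = \gamma'x + \zeta} with \eqn{\zeta \sim N(0, \sigma^2_\zeta)}.
#' With z-scored independent covariates the population is standardized by
#' \eqn{\sigma^2_\zeta = 1 - \sum_k \gamma_k^2}, so \eqn{Var(\theta) = 1};
#' construction rejects \eqn{\sum\gamma_k^2 \ge 1}.
#'
#' @param gamma numeric vector of standardized causal coefficients.
#' @param resid_var residual variance of \eqn{\zeta}; defaults to
#'   \eqn{1 - \sum\gamma^2}.
#' @return an object of class `"latent_structure"`.
#' @export
latent_structure <- function(gamma, resid_var = NULL) {
  gamma <- as.numeric(gamma)
  ss <- sum(gamma^2)
  if (is.null(resid_var)) {
    if (ss >= 1) stop("sum(gamma^2) must be < 1 for a standardized latent trait")
    resid_var <- 1 - ss
  }
  if (resid_var < 0) stop("resid_var must be non-negative")
  structure(list(gamma = gamma, resid_var = resid_var,
                 n_covariates = length(gamma)),
            class = "latent_structure")
}

#' @export
print.latent_structure <- function(x, ...) {
  cat(sprintf("Latent structure: %d cause(s), gamma = (%s), Var(zeta) = %.3f\n",
              x$n_covariates, paste(round(x$gamma, 3), collapse = ", "),
              x$resid_var))
  invisible(x)
}
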