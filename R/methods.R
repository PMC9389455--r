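#' @export
print.mimic_fit <- function(x, ...) {
  kind <- if (x$k == 0L) "2PL (no causes)"
          else if (!is.null(x$dif_item)) sprintf("MIMIC + %s DIF on item %d",
                                                 x$dif_kind, x$dif_item)
          else "MIMIC"
  cat(sprintf("%s model, %s link: %d respondents, %d items",
              kind, x$link, x$n, x$n_items))
  if (x$k > 0L) cat(sprintf(", %d cause(s)", x$k))
  cat(sprintf("\nlog-likelihood: %.3f  (converged: %s)\n",
              x$loglik, x$converged))
  if (x$k > 0L) {
    cat("gamma:", paste(round(x$latent$gamma, 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.mimic_fit <- function(object, ...) object$coefficients

#' @export
logLik.mimic_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' Parameter covariance of a fitted MIMIC model
#'
#' @param object a `"mimic_fit"`.
#' @param type `"model"` for the inverse observed information, `"sandwich"`
#'   for the cluster-robust covariance (requires the fit to have been given
#'   clusters and standard errors).
#' @param ... unused.
#' @return covariance matrix of the natural-scale parameters.
#' @export
vcov.mimic_fit <- function(object, type = c("model", "sandwich"), ...) {
  type <- match.arg(type)
  V <- if (type == "model") object$model_cov else object$sandwich_cov
  if (is.null(V)) stop("requested '", type, "' covariance not available; ",
                       "refit with se = \"model\"",
                       if (type == "sandwich") " and a cluster argument")
  V
}

#' @export
summary.mimic_fit <- function(object, ...) {
  V <- object$model_cov
  se <- if (!is.null(V)) sqrt(pmax(diag(V), 0)) else
    rep(NA_real_, length(object$coefficients))
  items <- as.data.frame(object$bank)
  I <- object$n_items
  items$se_lambda <- se[seq_len(I)]
  items$se_tau <- se[I + seq_len(I)]
  out <- list(call = object$call, items = items, loglik = object$loglik,
              converged = object$converged, n = object$n, k = object$k,
              dif_test = object$dif_test)
  if (object$k > 0L) {
    gidx <- grep("^gamma", names(object$coefficients))
    gse <- se[gidx]
    sand <- if (!is.null(object$sandwich_cov))
      sqrt(pmax(diag(object$sandwich_cov)[gidx], 0)) else NULL
    use <- if (!is.null(sand)) sand else gse
    wt <- if (all(is.finite(use)) && all(use > 0))
      wald_test(object$coefficients[gidx], use) else list(t = NA, p = NA)
    out$gamma <- data.frame(term = names(object$coefficients)[gidx],
                            estimate = object$latent$gamma,
                            se_model = unname(gse),
                            se_sandwich = if (!is.null(sand)) unname(sand) else NA,
                            t = wt$t, p = wt$p, row.names = NULL)
  }
  class(out) <- "summary.mimic_fit"
  out
}

#' @export
print.summary.mimic_fit <- function(x, ...) {
  cat("Call: "); print(x$call)
  cat(sprintf("log-likelihood %.3f (converged: %s), n = %d\n",
              x$loglik, x$converged, x$n))
  if (!is.null(x$gamma)) {
    cat("\nStructural (causal) coefficients:\n")
    print(x$gamma, digits = 4)
  }
  if (!is.null(x$dif_test)) {
    cat("\nDIF Wald tests:\n")
    print(x$dif_test, digits = 4)
  }
  cat("\nItem parameters:\n")
  print(utils::head(x$items, 10), digits = 3)
  if (nrow(x$items) > 10) cat("  ...", nrow(x$items) - 10, "more items\n")
  invisible(x)
}

#' Predict from a fitted MIMIC model
#'
#' @param object a `"mimic_fit"`.
#' @param newdata optional list with elements `y` (responses) and, for models
#'   with causes, `x`; defaults to the training data.
#' @param type `"eap"` for expected-a-posteriori trait estimates (with
#'   posterior SDs), `"prob"` for fitted endorsement probabilities at the EAP.
#' @param ... unused.
#' @return for `"eap"` a data.frame with `eap` and `psd`; for `"prob"` an
#'   n x items probability matrix.
#' @export
predict.mimic_fit <- function(object, newdata = NULL,
                              type = c("eap", "prob"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    ab <- object$ability
    y <- object$y; x <- object$x
  } else {
    y <- as.matrix(newdata$y)[, object$kept_items, drop = FALSE]
    x <- if (object$k > 0L) as.matrix(newdata$x) else NULL
    obj <- mimic_objective(y, x, object$quadrature, link = object$link,
                           dif_item = object$dif_item,
                           dif_kind = object$dif_kind)
    res <- obj$eval(object$coefficients, want_posterior = TRUE)
    ab <- data.frame(eap = res$eap, psd = res$psd)
  }
  if (type == "eap") return(ab)
  P <- vapply(seq_len(object$n_items), function(i)
    item_prob(object$bank, i, ab$eap, covariates = x),
    numeric(nrow(ab)))
  colnames(P) <- paste0("item", seq_len(object$n_items))
  P
}

#' Simulate response data from a fitted MIMIC model
#'
#' Draws new datasets from the estimated item bank and latent structure
#' (parametric-bootstrap style).
#'
#' @param object a `"mimic_fit"`.
#' @param nsim number of datasets.
#' @param seed optional seed.
#' @param n respondents per dataset (defaults to the fitted n).
#' @param ... unused.
#' @return a list of `nsim` [simulate_mimic_dataset()] objects.
#' @export
simulate.mimic_fit <- function(object, nsim = 1, seed = NULL, n = object$n, ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim,
            simulate_mimic_dataset(object$bank, object$latent, n),
            simplify = FALSE)
}

#' Item characteristic curves of a fitted model
#'
#' @param x a `"mimic_fit"`.
#' @param items which items to draw.
#' @param theta_range latent-trait range.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mimic_fit <- function(x, items = seq_len(x$n_items),
                           theta_range = c(-3, 3), ...) {
  th <- seq(theta_range[1], theta_range[2], length.out = 101)
  P <- vapply(items, function(i) item_prob(x$bank, i, th), numeric(101))
  graphics::matplot(th, P, type = "l", lty = 1,
                    xlab = expression(theta),
                    ylab = "P(endorse)", main = "Item characteristic curves",
                    ...)
  invisible(x)
}
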