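#' Three-method brain-behavior comparison on a purified itemset
#'
#' Within each emotion, relates identification performance to the P200
#' covariates (amplitude, latency, amplitude x latency) with the three
#' summarization methods: z-scored sum scores and two-stage IRT EAP scores
#' regressed on the covariates by OLS with naive standard errors
#' (deliberately ignoring the repeated-measures nesting), and the joint
#' MIMIC model with cluster-robust sandwich standard errors (clusters =
#' subjects). Benjamini-Hochberg FDR is applied across the four emotions
#' within each covariate and method. Cross-method correlations of the
#' behavioral summary scores are also reported.
#'
#' @param study an `"empirical_study"` (after [preprocess_responses()]).
#' @param purified named list of [purify_itemset()] results, one per emotion
#'   (or `NULL` to use all items).
#' @param methods which summaries to compare.
#' @param control a [mimic_control()] for the model-based fits.
#' @return list of class `"bb_comparison"` with `coefficients` (long
#'   data.frame: emotion, method, covariate, estimate, se, t, p, q, se_type),
#'   `score_correlations`, and `errors` (per-emotion fit failures).
#' @export
brain_behavior_compare <- function(study, purified = NULL,
                                   methods = c("sumscore", "irt", "mimic"),
                                   control = mimic_control(quadrature = 31)) {
  emos <- study$config$emotions
  covnames <- c("amplitude", "latency", "interaction")
  rows <- list(); cors <- list(); errors <- list()
  for (e in emos) {
    mats <- study_matrices(study, e)
    keep_items <- if (!is.null(purified)) purified[[e]]$retained
                  else seq_len(ncol(mats$y))
    y <- mats$y[, keep_items, drop = FALSE]
    x <- mats$x
    if (any(apply(x, 2, stats::sd) == 0)) {
      errors[[e]] <- "constant covariate(s); coefficients undefined"
      next
    }
    scores <- list()
    for (m in methods) {
      res <- tryCatch({
        if (m == "sumscore") {
          z <- summarize_sumscore(y)
          scores[[m]] <- z
          ols_coef_table(z, x, e, m)
        } else if (m == "irt") {
          f <- suppressWarnings(fit_2pl(y, se = "none", control = control))
          if (f$failed) stop("2PL fit failed")
          eap <- f$ability$eap
          z <- (eap - mean(eap)) / stats::sd(eap)
          scores[[m]] <- z
          ols_coef_table(z, x, e, m)
        } else {
          f <- suppressWarnings(fit_mimic(y, x, cluster = mats$cluster,
                                          se = "model", control = control))
          if (f$failed) stop("MIMIC fit failed")
          scores[[m]] <- f$ability$eap
          gidx <- grep("^gamma", names(f$coefficients))
          V <- if (!is.null(f$sandwich_cov)) f$sandwich_cov else f$model_cov
          sev <- sqrt(pmax(diag(V)[gidx], 0))
          wt <- wald_test(f$coefficients[gidx], sev)
          data.frame(emotion = e, method = m, covariate = covnames,
                     estimate = unname(f$coefficients[gidx]),
                     se = unname(sev), t = unname(wt$t), p = unname(wt$p),
                     se_type = if (!is.null(f$sandwich_cov)) "sandwich"
                               else "model",
                     stringsAsFactors = FALSE)
        }
      }, error = function(err) {
        errors[[e]] <<- c(errors[[e]],
                          paste0(m, ": ", conditionMessage(err)))
        NULL
      })
      if (!is.null(res)) rows[[paste(e, m)]] <- res
    }
    if (length(scores) > 1) {
      cm <- stats::cor(do.call(cbind, scores))
      cors[[e]] <- cm
    }
  }
  coefs <- do.call(rbind, rows)
  rownames(coefs) <- NULL
  # FDR across emotions, within each method x covariate
  coefs$q <- NA_real_
  for (m in unique(coefs$method)) {
    for (cv in covnames) {
      sel <- coefs$method == m & coefs$covariate == cv & !is.na(coefs$p)
      if (any(sel)) coefs$q[sel] <- bh_fdr(coefs$p[sel])
    }
  }
  structure(list(coefficients = coefs, score_correlations = cors,
                 errors = errors),
            class = "bb_comparison")
}

# naive OLS of a summary score on the covariates (z-scored columns)
ols_coef_table <- function(z, x, emotion, method) {
  xz <- scale(x)
  fit <- stats::lm(z ~ xz)
  sm <- summary(fit)$coefficients[-1, , drop = FALSE]
  data.frame(emotion = emotion, method = method,
             covariate = colnames(x), estimate = sm[, 1], se = sm[, 2],
             t = sm[, 3], p = sm[, 4], se_type = "naive",
             stringsAsFactors = FALSE)
}

#' @export
print.bb_comparison <- function(x, ...) {
  cat("Brain-behavior comparison (FDR across emotions within covariate):\n")
  sig <- x$coefficients[!is.na(x$coefficients$q) & x$coefficients$q < 0.05, ]
  if (nrow(sig)) {
    cat("significant after FDR (q < 0.05):\n")
    print(sig[, c("emotion", "method", "covariate", "estimate", "se", "q")],
          digits = 3, row.names = FALSE)
  } else cat("no coefficient significant after FDR\n")
  if (length(x$errors)) {
    cat("fit errors:\n"); utils::str(x$errors, give.attr = FALSE)
  }
  invisible(x)
}
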