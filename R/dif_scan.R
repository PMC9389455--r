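#' Brute-force uniform DIF scan over an itemset
#'
#' Fits one MIMIC model per item with that item's direct covariate paths
#' (intercept/difficulty shifts) freed, all other DIF terms fixed at zero,
#' and records Wald statistics for every freed coefficient. The flagging
#' decision is based on the test of the covariate named in `flag_on`
#' (by default the last column, conventionally the amplitude-by-latency
#' interaction); set `flag_on = "any"` to flag when any freed coefficient is
#' significant.
#'
#' @param y binary response matrix for one latent dimension (e.g. one
#'   emotion's items).
#' @param x covariate matrix (same rows as `y`).
#' @param clusters optional cluster labels; Wald tests then use sandwich
#'   standard errors.
#' @param alpha significance level for flagging.
#' @param flag_on covariate column (name or index) whose test drives the
#'   flag, or `"any"`.
#' @param group optional label (e.g. the emotion) copied into the records.
#' @param control a [mimic_control()].
#' @return a data.frame of class `"dif_records"`: one row per item x
#'   covariate with `estimate`, `se`, `t`, `p`, `flagged` (constant within
#'   item), plus `error` for items whose fit failed (scan continues).
#' @seealso [scan_nonuniform()], [purify_itemset()]
#' @export
scan_uniform <- function(y, x, clusters = NULL, alpha = 0.05,
                         flag_on = ncol(as.matrix(x)), group = NA_character_,
                         control = mimic_control(quadrature = 31)) {
  dif_scan(y, x, clusters, alpha, flag_on, group, kind = "uniform", control)
}

#' Brute-force nonuniform DIF scan over an itemset
#'
#' As [scan_uniform()], but each per-item model frees covariate moderations
#' of the tested item's loading (discrimination shifts) instead of intercept
#' shifts. The sign convention is that a positive coefficient means the
#' item's discrimination increases with the covariate.
#'
#' @inheritParams scan_uniform
#' @return a `"dif_records"` data.frame.
#' @export
scan_nonuniform <- function(y, x, clusters = NULL, alpha = 0.05,
                            flag_on = ncol(as.matrix(x)),
                            group = NA_character_,
                            control = mimic_control(quadrature = 31)) {
  dif_scan(y, x, clusters, alpha, flag_on, group, kind = "nonuniform", control)
}

dif_scan <- function(y, x, clusters, alpha, flag_on, group, kind, control) {
  stopifnot(alpha >= 0, alpha <= 1)
  y <- as.matrix(y); x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  flag_col <- if (identical(flag_on, "any")) "any"
              else if (is.numeric(flag_on)) colnames(x)[flag_on]
              else match.arg(flag_on, colnames(x))
  items <- seq_len(ncol(y))
  recs <- lapply(items, function(d) {
    fit <- tryCatch(
      suppressWarnings(
        fit_mimic_with_dif(y, x, cluster = clusters, item_index = d,
                           kind = kind, se = "model", control = control)),
      error = function(e) e)
    if (inherits(fit, "error") || is.null(fit$dif_test)) {
      msg <- if (inherits(fit, "error")) conditionMessage(fit)
             else "no covariance available"
      return(data.frame(group = group, item = d, kind = kind,
                        covariate = colnames(x), estimate = NA_real_,
                        se = NA_real_, t = NA_real_, p = NA_real_,
                        flagged = FALSE, error = msg,
                        stringsAsFactors = FALSE))
    }
    tab <- fit$dif_test
    tab$covariate <- colnames(x)
    flagged <- if (flag_col == "any") any(tab$p < alpha, na.rm = TRUE)
               else isTRUE(tab$p[tab$covariate == flag_col] < alpha)
    data.frame(group = group, item = d, kind = kind, covariate = tab$covariate,
               estimate = tab$estimate, se = tab$se, t = tab$t, p = tab$p,
               flagged = flagged, error = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  attr(out, "alpha") <- alpha
  attr(out, "flag_on") <- flag_col
  class(out) <- c("dif_records", "data.frame")
  out
}

#' Flagged items of a DIF scan
#'
#' @param records a `"dif_records"` data.frame.
#' @return integer vector of flagged item indices.
#' @export
flagged_items <- function(records) {
  sort(unique(records$item[records$flagged]))
}

#' Purify an itemset after DIF scanning
#'
#' Removes the union of items flagged in the uniform and nonuniform scans
#' (single pass, no re-scan).
#'
#' @param uniform `"dif_records"` from [scan_uniform()].
#' @param nonuniform `"dif_records"` from [scan_nonuniform()] over the same
#'   itemset.
#' @param n_items total itemset size (defaults to the largest item index
#'   seen).
#' @return list of class `"purified_itemset"` with `retained`, `removed` and
#'   a `reasons` data.frame.
#' @export
purify_itemset <- function(uniform, nonuniform,
                           n_items = max(uniform$item, nonuniform$item)) {
  items <- seq_len(n_items)
  rm_u <- flagged_items(uniform)
  rm_n <- flagged_items(nonuniform)
  removed <- sort(union(rm_u, rm_n))
  reasons <- data.frame(item = removed,
                        reason = vapply(removed, function(i) {
                          paste(c(if (i %in% rm_u) "uniform",
                                  if (i %in% rm_n) "nonuniform"),
                                collapse = "+")
                        }, character(1)))
  structure(list(retained = setdiff(items, removed), removed = removed,
                 reasons = reasons, n_items = n_items),
            class = "purified_itemset")
}

#' @export
print.purified_itemset <- function(x, ...) {
  cat(sprintf("Purified itemset: %d of %d items retained (%d removed)\n",
              length(x$retained), x$n_items, length(x$removed)))
  if (length(x$removed)) print(x$reasons, row.names = FALSE)
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1) controlling the false
#' discovery rate.
#'
#' @param pvals p-values in [0, 1].
#' @return adjusted q-values in the original order.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}
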