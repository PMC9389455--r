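#' Z-scored sum scores of a binary response matrix
#'
#' Row sums of endorsed items (missing responses count as not endorsed),
#' standardized to mean 0 and SD 1 (denominator n - 1).
#'
#' @param y binary response matrix.
#' @return numeric vector of z-scored sum scores.
#' @export
summarize_sumscore <- function(y) {
  s <- rowSums(y, na.rm = TRUE)
  sdv <- stats::sd(s)
  if (!is.finite(sdv) || sdv == 0) stop("sum scores have zero variance")
  (s - mean(s)) / sdv
}

#' Two-stage standardized regression of a behavioral summary on a cause
#'
#' OLS slope of the summary scores on the (z-scored) covariate. When both
#' variables are standardized this is their Pearson correlation, i.e. the
#' two-stage analogue of the standardized causal coefficient \eqn{\gamma}.
#'
#' @param scores behavioral summary per respondent (sum score or EAP).
#' @param x covariate vector.
#' @return the standardized slope.
#' @export
two_stage_estimate <- function(scores, x) {
  stopifnot(length(scores) == length(x))
  xz <- (x - mean(x)) / stats::sd(x)
  unname(stats::coef(stats::lm.fit(cbind(1, xz), scores))[2])
}

# one replication of one population cell: simulate once, summarize with the
# requested methods; seed depends on (root, cell, rep) but not on the method,
# so different methods see identical data
run_one_rep <- function(cond, methods, rep_id, root_seed, n_items, quadrature,
                        reltol, link = "logit") {
  cell_key <- cond_key(cond)
  set.seed(spawn_seed(root_seed, cell_key, rep_id))
  bank <- draw_item_bank(cond, n_items, link = link)
  latent <- latent_structure(cond$gamma)
  dat <- simulate_mimic_dataset(bank, latent, cond$n)
  ctrl <- mimic_control(quadrature = quadrature, reltol = reltol)
  out <- lapply(methods, function(m) {
    est <- tryCatch(switch(m,
      sumscore = {
        z <- summarize_sumscore(dat$y)
        two_stage_estimate(z, dat$x[, 1])
      },
      irt = {
        f <- suppressWarnings(fit_2pl(dat$y, link = link, se = "none",
                                      control = ctrl))
        if (f$failed) stop("2PL fit failed")
        eap <- f$ability$eap
        sdv <- stats::sd(eap)
        if (sdv == 0) stop("degenerate EAP scores")
        two_stage_estimate((eap - mean(eap)) / sdv, dat$x[, 1])
      },
      mimic = {
        f <- suppressWarnings(fit_mimic(dat$y, dat$x, link = link,
                                        se = "none", control = ctrl))
        if (f$failed) stop("MIMIC fit failed")
        f$latent$gamma[1]
      },
      stop("unknown method: ", m)), error = function(e) NA_real_)
    data.frame(n = cond$n, loading_even = cond$loading_even,
               loading_odd = cond$loading_odd, gamma = cond$gamma,
               diff_lo = cond$diff_lo, diff_hi = cond$diff_hi,
               method = m, rep = rep_id,
               seed = spawn_seed(root_seed, cell_key, rep_id),
               estimate = est, bias = cond$gamma - est,
               failed = is.na(est), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

cond_key <- function(cond) {
  sum(c(cond$n, cond$loading_even * 1e3, cond$loading_odd * 1e5,
        cond$gamma * 1e2, (cond$diff_lo + 2) * 1e6))
}

#' Run one simulation condition for one summarization method
#'
#' Simulates `reps` independent datasets from the condition's population
#' MIMIC model (20 items, one cause) and records the standardized causal
#' estimate of the chosen method and its bias, defined as
#' true minus estimated (positive bias = underestimation). Failed fits are
#' recorded with `failed = TRUE` and an `NA` estimate.
#'
#' @param cond one row of [build_condition_grid()].
#' @param method `"sumscore"`, `"irt"` or `"mimic"`.
#' @param reps number of replications.
#' @param root_seed root seed; per-replication seeds are spawned
#'   deterministically from (root, condition, replication) and do not depend
#'   on the method.
#' @param n_items number of indicator items.
#' @param quadrature Gauss-Hermite node count for the likelihood-based
#'   methods.
#' @param reltol optimizer tolerance.
#' @param link response link; the study's indicator-strength values are 2PL
#'   discriminations, so `"logit"` is the default.
#' @return a data.frame of bias records (one row per replication).
#' @export
run_condition <- function(cond, method = c("sumscore", "irt", "mimic"),
                          reps = 100, root_seed = 1, n_items = 20L,
                          quadrature = 21, reltol = 1e-8, link = "logit") {
  method <- match.arg(method)
  do.call(rbind, lapply(seq_len(reps), function(r)
    run_one_rep(cond, method, r, root_seed, n_items, quadrature, reltol,
                link)))
}

#' Run the full three-method parameter-bias study
#'
#' Crosses every population cell of the grid with the three summarization
#' methods (sum-score, two-stage IRT, joint MIMIC). Each replication draws
#' one dataset per cell and summarizes it with all methods, so method
#' contrasts are paired. Per-replication seeds are spawned from the root
#' seed; a given (cell, replication) is bit-reproducible regardless of
#' worker count.
#'
#' @param grid a [build_condition_grid()] data.frame (or a subset of it).
#' @param reps replications per cell.
#' @param root_seed root seed.
#' @param methods summarization methods to include.
#' @param n_items indicator count per dataset.
#' @param quadrature node count for likelihood-based fits.
#' @param reltol optimizer tolerance.
#' @param link response link for simulation and model-based fits (`"logit"`:
#'   the indicator-strength levels are 2PL discriminations).
#' @param workers number of parallel workers (forked; results identical for
#'   any worker count).
#' @param checkpoint_dir optional directory: per-cell results are written as
#'   CSV and finished cells are skipped on re-run.
#' @return a long-format data.frame of class `"bias_table"` (cell fields,
#'   method, rep, seed, estimate, bias, failed).
#' @export
run_full_study <- function(grid = build_condition_grid(), reps = 100,
                           root_seed = 1,
                           methods = c("sumscore", "irt", "mimic"),
                           n_items = 20L, quadrature = 21, reltol = 1e-8,
                           link = "logit", workers = 1L,
                           checkpoint_dir = NULL) {
  run_cell <- function(i) {
    cond <- grid[i, ]
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      f <- file.path(checkpoint_dir, sprintf("cell%03d.csv", i))
      if (file.exists(f)) {
        return(utils::read.csv(f, stringsAsFactors = FALSE))
      }
    }
    res <- do.call(rbind, lapply(seq_len(reps), function(r)
      run_one_rep(cond, methods, r, root_seed, n_items, quadrature, reltol,
                  link)))
    if (!is.null(checkpoint_dir)) utils::write.csv(res, f, row.names = FALSE)
    res
  }
  idx <- seq_len(nrow(grid))
  cells <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, run_cell, mc.cores = workers)
  } else {
    lapply(idx, run_cell)
  }
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  class(out) <- c("bias_table", "data.frame")
  out
}

#' Cohen's f from eta-squared
#'
#' \eqn{f = \sqrt{\eta^2 / (1 - \eta^2)}}.
#'
#' @param eta2 eta-squared value(s) in [0, 1).
#' @return Cohen's f.
#' @export
cohens_f <- function(eta2) {
  if (any(eta2 < 0 | eta2 >= 1)) stop("eta2 must lie in [0, 1)")
  sqrt(eta2 / (1 - eta2))
}

#' Factorial ANOVA of parameter bias over the simulation design
#'
#' Fits the balanced five-factor ANOVA of bias on summarization method (3
#' levels), magnitude of cause (3), indicator strength (one 4-level factor:
#' the even-by-odd loading permutations), item-intercept range (2) and sample
#' size (2), with all two-, three- and four-way interactions (30 effect
#' terms). Effect sizes are classical eta-squared
#' (\eqn{SS_{term}/SS_{total}}, residual included in the total) and Cohen's
#' f. Replications with failed fits are dropped listwise with a recorded
#' count.
#'
#' @param table a `"bias_table"` from [run_full_study()].
#' @return a data.frame of class `"anova_effects"`: term, df, sum_sq, eta2,
#'   cohens_f, p; the dropped-replication count is in attribute `"n_dropped"`.
#' @export
bias_anova <- function(table) {
  dat <- as.data.frame(table)
  n_dropped <- sum(dat$failed)
  dat <- dat[!dat$failed, ]
  dat$method <- factor(dat$method, levels = c("sumscore", "irt", "mimic"))
  dat$cause <- factor(dat$gamma)
  dat$indicator <- factor(paste0(dat$loading_odd, "/", dat$loading_even))
  dat$intercept <- factor(ifelse(dat$diff_lo < 0, "[-1,1]", "[0,2]"))
  dat$nsize <- factor(dat$n)
  need <- c(method = 3L, cause = 3L, indicator = 4L, intercept = 2L,
            nsize = 2L)
  for (f in names(need)) {
    if (nlevels(droplevels(dat[[f]])) < need[[f]]) {
      stop("factor '", f, "' is missing levels; the ANOVA needs the full grid")
    }
  }
  fit <- stats::aov(bias ~ (method + cause + indicator + intercept + nsize)^4,
                    data = dat)
  ss <- summary(fit)[[1]]
  term <- trimws(rownames(ss))
  sum_sq <- ss[["Sum Sq"]]
  ss_total <- sum(sum_sq)
  eta2 <- sum_sq / ss_total
  out <- data.frame(term = term, df = ss[["Df"]], sum_sq = sum_sq,
                    eta2 = eta2,
                    cohens_f = ifelse(term == "Residuals", NA,
                                      cohens_f(pmin(eta2, 1 - 1e-12))),
                    p = ss[["Pr(>F)"]], stringsAsFactors = FALSE,
                    row.names = NULL)
  eff <- out[out$term != "Residuals", ]
  out <- rbind(eff[order(-eff$eta2), ], out[out$term == "Residuals", ])
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("anova_effects", "data.frame")
  out
}

#' @export
print.anova_effects <- function(x, digits = 3, ...) {
  cat("Bias ANOVA effect sizes (eta^2 = SS/SS_total):\n")
  df <- as.data.frame(x)
  df$sum_sq <- signif(df$sum_sq, digits)
  df$eta2 <- round(df$eta2, 3)
  df$cohens_f <- round(df$cohens_f, 3)
  print(utils::head(df[, c("term", "df", "eta2", "cohens_f")], 12))
  if (nrow(df) > 12) cat("  ...", nrow(df) - 12, "more terms\n")
  nd <- attr(x, "n_dropped")
  if (!is.null(nd) && nd > 0) cat("dropped failed replications:", nd, "\n")
  invisible(x)
}
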