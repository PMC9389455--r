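#' Condition grid for the parameter-bias simulation
#'
#' Fully crosses the population design of the bias study: sample size
#' (200, 500), even- and odd-item loading strength (0.4, 0.8 each), causal
#' magnitude (0.2, 0.4, 0.6) and the item-difficulty range ([-1, 1] or
#' [0, 2]), giving 48 population cells. Crossing those with the three
#' behavioral-summary methods (sum-score, two-stage IRT, joint MIMIC) yields
#' the 144 analysis cells of the full study.
#'
#' @return a data.frame of class `"sim_grid"` with 48 rows and columns
#'   `n`, `loading_even`, `loading_odd`, `gamma`, `diff_lo`, `diff_hi`.
#' @seealso [run_full_study()]
#' @export
build_condition_grid <- function() {
  grid <- expand.grid(n = c(200L, 500L),
                      loading_even = c(0.4, 0.8),
                      loading_odd = c(0.4, 0.8),
                      gamma = c(0.2, 0.4, 0.6),
                      diff_range = c("[-1,1]", "[0,2]"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$diff_lo <- ifelse(grid$diff_range == "[-1,1]", -1, 0)
  grid$diff_hi <- ifelse(grid$diff_range == "[-1,1]", 1, 2)
  grid$diff_range <- NULL
  class(grid) <- c("sim_grid", "data.frame")
  grid
}

#' Analysis cells: population conditions crossed with summary methods
#'
#' @param grid a condition grid from [build_condition_grid()].
#' @param methods summarization methods to cross with.
#' @return a data.frame with one row per population cell x method
#'   (144 rows for the full design).
#' @export
analysis_grid <- function(grid = build_condition_grid(),
                          methods = c("sumscore", "irt", "mimic")) {
  out <- merge(grid, data.frame(method = methods, stringsAsFactors = FALSE))
  out[, c("method", setdiff(names(out), "method"))]
}

#' Draw an item bank for one simulation condition
#'
#' Odd-numbered items (1-based) receive `loading_odd` and even-numbered
#' items `loading_even`; difficulties are drawn i.i.d. uniform on the
#' condition's range and thresholds derived as \eqn{\tau_i = b_i\lambda_i}.
#' All DIF coefficients are zero.
#'
#' @param cond one row of [build_condition_grid()] (or a list with fields
#'   `loading_even`, `loading_odd`, `diff_lo`, `diff_hi`).
#' @param n_items number of items; must be even (20 in the study design).
#' @param link link function for the bank.
#' @return an [item_bank()].
#' @export
draw_item_bank <- function(cond, n_items = 20L, link = "probit") {
  if (n_items %% 2L != 0L) stop("'n_items' must be even (odd/even loading split)")
  idx <- seq_len(n_items)
  loading <- ifelse(idx %% 2L == 1L, cond$loading_odd, cond$loading_even)
  b <- stats::runif(n_items, cond$diff_lo, cond$diff_hi)
  item_bank(loading = loading, difficulty = b, link = link)
}

#' Simulate a MIMIC-structured item-response dataset
#'
#' Draws covariates \eqn{x \sim N(0, I)}, the latent trait
#' \eqn{\theta = \gamma'x + \zeta} with \eqn{\zeta \sim N(0, \sigma^2_\zeta)},
#' and binary responses from the bank's measurement model (including any DIF
#' coefficients): \eqn{y_{ij} = 1} iff
#' \eqn{(\lambda_i + \beta_{dis,i}'x_j)\theta_j + \beta_{dif,i}'x_j +
#' \epsilon_{ij} > \tau_i}, with probit or logistic residuals per the bank's
#' link.
#'
#' @param bank an [item_bank()].
#' @param latent a [latent_structure()].
#' @param n number of respondents.
#' @param x optional covariate matrix (n x k); drawn standard normal when
#'   `NULL`.
#' @param theta optional latent values to condition on (length n); drawn from
#'   the structural model when `NULL`.
#' @param cluster_id optional cluster labels (default: singletons).
#' @return a list of class `"simulated_dataset"` with elements `y` (n x
#'   n_items binary matrix), `x`, `cluster_id`, `true_theta` and `true_model`.
#' @export
simulate_mimic_dataset <- function(bank, latent, n, x = NULL, theta = NULL,
                                   cluster_id = NULL) {
  k <- latent$n_covariates
  if (is.null(x)) {
    x <- matrix(stats::rnorm(n * k), n, k)
  } else {
    x <- as.matrix(x)
    stopifnot(nrow(x) == n, ncol(x) == k)
  }
  if (is.null(theta)) {
    mu <- if (k > 0L) drop(x %*% latent$gamma) else rep(0, n)
    theta <- mu + stats::rnorm(n, sd = sqrt(latent$resid_var))
  }
  I <- bank$n_items
  kd <- ncol(bank$dif_intercept)
  slope <- matrix(bank$loading, n, I, byrow = TRUE)
  shift <- matrix(0, n, I)
  if (kd > 0L && k > 0L) {
    kd_use <- min(kd, k)
    xs <- x[, seq_len(kd_use), drop = FALSE]
    slope <- slope + xs %*% t(bank$dif_loading[, seq_len(kd_use), drop = FALSE])
    shift <- xs %*% t(bank$dif_intercept[, seq_len(kd_use), drop = FALSE])
  }
  ystar <- slope * theta + shift
  s <- item_resid_sd(bank)
  eps <- if (bank$link == "probit") {
    matrix(stats::rnorm(n * I), n, I) * rep(s, each = n)
  } else {
    matrix(stats::rlogis(n * I), n, I)
  }
  y <- (ystar + eps > matrix(bank$threshold, n, I, byrow = TRUE)) * 1L
  colnames(y) <- paste0("item", seq_len(I))
  if (is.null(cluster_id)) cluster_id <- seq_len(n)
  structure(list(y = y, x = x, cluster_id = cluster_id, true_theta = theta,
                 true_model = list(bank = bank, latent = latent)),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("Simulated MIMIC dataset: %d respondents x %d items, %d cause(s)\n",
              nrow(x$y), ncol(x$y), ncol(x$x)))
  invisible(x)
}

# Deterministic seed spawning: one root seed plus a stream of integer keys
# yields independent-looking 31-bit seeds (multiplicative congruential hash).
spawn_seed <- function(root, ...) {
  keys <- c(root, ...)
  m <- 2147483647
  h <- 17
  for (k in keys) {
    h <- (h * 48271 + (as.numeric(k) %% m) * 16807 + 12345) %% m
  }
  as.integer(h %% (m - 2) + 1)
}
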