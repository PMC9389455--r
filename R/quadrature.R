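#' Gauss-Hermite quadrature on the standard-normal measure
#'
#' Builds a fixed quadrature rule for integrals of the form
#' \eqn{\int f(\theta)\,\phi(\theta)\,d\theta} where \eqn{\phi} is the
#' standard-normal density. Nodes and weights are obtained from the
#' physicists' Gauss-Hermite rule and rescaled, so the rule is exact for
#' polynomial \eqn{f} up to degree \eqn{2q-1}.
#'
#' @param q number of nodes (at least 2).
#' @return an object of class `"mimic_quadrature"`: a list with `nodes`
#'   (strictly increasing) and `weights` (positive, summing to one).
#' @examples
#' rule <- make_quadrature(21)
#' sum(rule$weights * rule$nodes^2)  # = Var of N(0,1) = 1
#' @export
make_quadrature <- function(q) {
  if (!is.numeric(q) || length(q) != 1L || q < 2 || q != round(q)) {
    stop("'q' must be a single integer >= 2")
  }
  gh <- pracma::gaussHermite(as.integer(q))
  nodes <- gh$x * sqrt(2)
  weights <- gh$w / sqrt(pi)
  weights <- weights / sum(weights)
  structure(list(nodes = nodes, weights = weights),
            class = "mimic_quadrature")
}

#' @export
print.mimic_quadrature <- function(x, ...) {
  cat("Gauss-Hermite rule on N(0,1):", length(x$nodes), "nodes spanning [",
      round(min(x$nodes), 2), ",", round(max(x$nodes), 2), "]\n")
  invisible(x)
}

as_quadrature <- function(q) {
  if (inherits(q, "mimic_quadrature")) q else make_quadrature(q)
}
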