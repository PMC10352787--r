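# Comparison statistics: Spearman correlations, Williams' test for dependent
# correlations, repeated-subsample correlation distributions.

#' Spearman rank correlation
#'
#' Rank correlation with average-rank tie handling (thin wrapper around
#' [stats::cor()] with input checks matching the evaluation contract).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return rho in [-1, 1].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  stats::cor(x, y, method = "spearman")
}

#' Williams' test for two dependent correlations sharing a variable
#'
#' Tests whether \eqn{r_{12}} and \eqn{r_{13}} (both involving variable 1)
#' differ, given the correlation \eqn{r_{23}} between variables 2 and 3:
#' \deqn{t = (r_{12} - r_{13})
#'   \sqrt{\frac{(n-1)(1+r_{23})}
#'        {2K\frac{n-1}{n-3} + \bar r^2 (1-r_{23})^3}}}
#' with \eqn{K = 1 - r_{12}^2 - r_{13}^2 - r_{23}^2 + 2 r_{12} r_{13} r_{23}}
#' and \eqn{\bar r = (r_{12}+r_{13})/2}, on \eqn{n-3} degrees of freedom with
#' a two-sided p-value.
#'
#' @param r12,r13 The two correlations being compared (each in (-1, 1)).
#' @param r23 Correlation between the two non-shared variables.
#' @param n Sample size (>= 4).
#' @return List with `t`, `p` (two-sided) and `df`.
#' @export
williams_test <- function(r12, r13, r23, n) {
  if (n < 4) stop("Williams' test needs n >= 4 (df = n - 3)")
  if (any(abs(c(r12, r13, r23)) >= 1)) stop("correlations must lie in (-1, 1)")
  K <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (K <= 0) stop("degenerate correlation matrix (K <= 0)")
  rbar <- (r12 + r13) / 2
  tstat <- (r12 - r13) *
    sqrt(((n - 1) * (1 + r23)) /
           (2 * K * (n - 1) / (n - 3) + rbar^2 * (1 - r23)^3))
  df <- n - 3
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df = df), df = df)
}

#' Repeated random-subsample correlation distribution
#'
#' Draws `replicates` subsamples of size `ceiling(fraction * n)` (with
#' replacement by default) and computes the Spearman correlation of each,
#' checking that an observed full-sample correlation is not driven by a small
#' subset of genes.  Replicates whose subsample is degenerate (a constant
#' vector) are recorded as `NA` and counted, with a warning.
#'
#' @param x,y Paired numeric vectors.
#' @param fraction Subsample fraction in (0, 1] (default 0.25).
#' @param replicates Number of replicates (default 1000).
#' @param seed Integer seed for reproducibility.
#' @param replace Sample with replacement (default `TRUE`).
#' @return Numeric vector of replicate rho values (`NA` for degenerate
#'   draws), with attribute `n_degenerate`.
#' @export
repeated_subsample_correlation <- function(x, y, fraction = 0.25,
                                           replicates = 1000, seed = NULL,
                                           replace = TRUE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (replicates < 1) stop("need at least 1 replicate")
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  k <- ceiling(fraction * n)
  rhos <- vapply(seq_len(replicates), function(i) {
    idx <- sample.int(n, k, replace = replace)
    xs <- x[idx]; ys <- y[idx]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
    stats::cor(xs, ys, method = "spearman")
  }, numeric(1))
  n_bad <- sum(is.na(rhos))
  if (n_bad > 0)
    warning(n_bad, " replicate(s) had a degenerate subsample and were dropped")
  attr(rhos, "n_degenerate") <- n_bad
  rhos
}
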