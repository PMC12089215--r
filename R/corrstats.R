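# Core correlation statistics: Pearson r, Fisher z, and the modified-z test
# for the difference between two dependent correlations sharing one variable.

#' Pearson product-moment correlation with input validation
#'
#' A thin, validating wrapper around [stats::cor()] used throughout the
#' package. Unlike `cor()`, degenerate inputs (length mismatch, fewer than
#' three observations, zero variance, missing values) raise explicit errors
#' instead of returning `NA`.
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with
#'   nonzero variance.
#' @return The Pearson correlation, a single number in \[-1, 1\].
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 0.8
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length (", length(x), " vs ",
         length(y), ").", call. = FALSE)
  }
  if (length(x) < 3L) {
    stop("need at least 3 paired observations.", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("missing values in `x` or `y`; remove or impute them first.",
         call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in `x` or `y`; the correlation is undefined.",
         call. = FALSE)
  }
  stats::cor(x, y)
}

#' Fisher z transformation
#'
#' `fisher_z()` is the variance-stabilising transformation
#' \eqn{z = \mathrm{artanh}(r) = \tfrac12 \log\{(1+r)/(1-r)\}};
#' `fisher_z_inv()` is its inverse, \eqn{\tanh(z)}. The transform is
#' unbounded as \eqn{|r| \to 1}, so correlations of exactly \eqn{\pm 1}
#' are rejected.
#'
#' @param r Correlation(s) strictly inside (-1, 1).
#' @param z Fisher-transformed value(s).
#' @return Transformed values of the same length as the input.
#' @examples
#' fisher_z(0.5)      # 0.5493
#' fisher_z_inv(fisher_z(0.3))
#' @export
fisher_z <- function(r) {
  r <- as.numeric(r)
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("`r` must lie strictly inside (-1, 1).", call. = FALSE)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) {
  tanh(as.numeric(z))
}

# Smallest eigenvalue tolerated when checking positive semi-definiteness:
# round-off on a valid correlation matrix can push an exact-zero eigenvalue
# slightly negative.
.psd_tol <- 1e-10

# 3x3 correlation matrix implied by (r12, r13, r23); variable order is
# (criterion, X, Y) in the power module and (X, Y, criterion) semantics do
# not matter for the PSD check.
.corr3 <- function(r12, r13, r23) {
  matrix(c(1, r12, r13,
           r12, 1, r23,
           r13, r23, 1), nrow = 3L, byrow = TRUE)
}

.check_psd3 <- function(r12, r13, r23) {
  ev <- eigen(.corr3(r12, r13, r23), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -.psd_tol) {
    stop("the implied 3x3 correlation matrix is not positive semi-definite ",
         "(smallest eigenvalue ", format(min(ev), digits = 4), "); ",
         "the three correlations are mutually inconsistent.", call. = FALSE)
  }
  invisible(min(ev))
}

.validate_triple <- function(r_xa, r_ya, r_xy, n) {
  for (nm in c("r_xa", "r_ya", "r_xy")) {
    r <- get(nm)
    if (!is.numeric(r) || length(r) != 1L || !is.finite(r)) {
      stop("`", nm, "` must be a single finite number.", call. = FALSE)
    }
    if (abs(r) >= 1) {
      stop("`", nm, "` = ", r, " lies outside the open interval (-1, 1); ",
           "the Fisher transform is unbounded at |r| = 1.", call. = FALSE)
    }
  }
  if (!is.numeric(n) || length(n) != 1L || n < 4 || n != round(n)) {
    stop("`n` must be an integer sample size of at least 4.", call. = FALSE)
  }
  .check_psd3(r_xa, r_ya, r_xy)
  invisible(TRUE)
}

# Internal fast path: vectorised two-sided z statistic of the modified
# (pooled r-bar) dependent-correlations test. No validation; the power
# module calls this tens of thousands of times.
.diff_z_dep <- function(r_xa, r_ya, r_xy, n) {
  zd <- atanh(r_xa) - atanh(r_ya)
  rb <- (r_xa + r_ya) / 2
  rb2 <- rb * rb
  cv <- (r_xy * (1 - 2 * rb2) - 0.5 * rb2 * (1 - 2 * rb2 - r_xy^2)) /
    (1 - rb2)^2
  zd * sqrt((n - 3) / (2 - 2 * cv))
}

#' Test the difference between two dependent correlations sharing a variable
#'
#' Tests \eqn{H_0: \rho_{XA} = \rho_{YA}} for two focal measures X and Y
#' correlated with the same criterion A, accounting for the overlap induced
#' by the focal intercorrelation \eqn{r_{XY}}. The statistic is Steiger's
#' modified z with the pooled mean correlation
#' \eqn{\bar r = (r_{XA} + r_{YA})/2} entering the covariance term
#' (the variant popularised by Hittner, May and Silver):
#' \deqn{Z = (z_{XA} - z_{YA}) \sqrt{\frac{n-3}{2 - 2\bar c}}, \quad
#'   \bar c = \frac{r_{XY}(1 - 2\bar r^2) - \tfrac12 \bar r^2
#'   (1 - 2\bar r^2 - r_{XY}^2)}{(1 - \bar r^2)^2}}
#' where \eqn{z} denotes the Fisher transform. Which variant of the
#' dependent-correlations test underlies published worked examples is rarely
#' stated; this one is documented here as the package's choice and is
#' cross-checked in the test suite against an independent re-derivation.
#'
#' @param r_xa,r_ya Correlations of X and Y with the shared criterion,
#'   strictly inside (-1, 1).
#' @param r_xy Correlation between the two focal measures.
#' @param n Sample size (integer, at least 4).
#' @param alpha Significance level, strictly between 0 and 1. Default .05.
#' @param alternative `"two.sided"` (default), or `"greater"`/`"less"` for
#'   directional hypotheses about \eqn{\Delta r = r_{XA} - r_{YA}}.
#' @return An object of class `"cor_diff_test"`: a list with `delta_r`,
#'   `z_stat`, `p_value`, `alpha`, `significant`, `alternative`, and the
#'   inputs.
#' @examples
#' diff_test_dep(r_xa = .10, r_ya = .30, r_xy = .40, n = 100)   # p = .06
#' diff_test_dep(r_xa = .10, r_ya = .12, r_xy = .80, n = 4000)  # p = .04
#' @export
diff_test_dep <- function(r_xa, r_ya, r_xy, n, alpha = 0.05,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  .validate_triple(r_xa, r_ya, r_xy, n)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly between 0 and 1.", call. = FALSE)
  }
  z <- .diff_z_dep(r_xa, r_ya, r_xy, n)
  p <- switch(alternative,
    two.sided = 2 * stats::pnorm(-abs(z)),
    greater   = stats::pnorm(z, lower.tail = FALSE),
    less      = stats::pnorm(z)
  )
  structure(
    list(
      delta_r = r_xa - r_ya,
      z_stat = z,
      p_value = p,
      alpha = alpha,
      significant = p < alpha,
      alternative = alternative,
      r_xa = r_xa, r_ya = r_ya, r_xy = r_xy, n = n
    ),
    class = "cor_diff_test"
  )
}

#' @export
print.cor_diff_test <- function(x, digits = 4, ...) {
  cat("Difference between dependent correlations (shared criterion)\n")
  cat(sprintf("  r_xa = %.3f, r_ya = %.3f, r_xy = %.3f, n = %d\n",
              x$r_xa, x$r_ya, x$r_xy, as.integer(x$n)))
  cat(sprintf("  delta r = %s, z = %s, p (%s) = %s\n",
              format(x$delta_r, digits = digits),
              format(x$z_stat, digits = digits),
              x$alternative,
              format(x$p_value, digits = digits)))
  cat(sprintf("  %s at alpha = %s\n",
              if (x$significant) "significant" else "not significant",
              format(x$alpha)))
  invisible(x)
}
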