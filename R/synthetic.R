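# Synthetic participant-level data with a known population correlation
# structure and an optional classical measurement-error model.

# Upper-triangular factor U with t(U) %*% U = R. Cholesky when R is strictly
# positive definite; otherwise an eigendecomposition with small negative
# eigenvalues clipped at zero (warning), so exactly-singular but valid
# matrices are accepted.
.corr_factor <- function(R) {
  U <- tryCatch(chol(R), error = function(e) NULL)
  if (!is.null(U)) return(U)
  ed <- eigen(R, symmetric = TRUE)
  ev <- ed$values
  if (min(ev) < -.psd_tol) {
    stop("correlation matrix is not positive semi-definite (smallest ",
         "eigenvalue ", format(min(ev), digits = 4), ").", call. = FALSE)
  }
  if (any(ev < 0)) {
    warning("correlation matrix is singular up to round-off; negative ",
            "eigenvalues clipped at 0.", call. = FALSE)
    ev[ev < 0] <- 0
  }
  t(ed$vectors %*% (t(ed$vectors) * sqrt(ev)))
}

.validate_corr_matrix <- function(corr) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr)) {
    stop("`corr` must be a square matrix.", call. = FALSE)
  }
  if (!isSymmetric(unname(corr), tol = 1e-8)) {
    stop("`corr` must be symmetric.", call. = FALSE)
  }
  if (any(abs(diag(corr) - 1) > 1e-8)) {
    stop("`corr` must have a unit diagonal.", call. = FALSE)
  }
  if (any(abs(corr) > 1 + 1e-8)) {
    stop("all entries of `corr` must lie in [-1, 1].", call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate participant scores from a population correlation matrix
#'
#' Draws `n` rows of multivariate standard-normal true scores with the
#' target correlation matrix. When `reliabilities` are supplied, observed
#' scores follow the classical congeneric model
#' \eqn{x_{obs} = \sqrt{\rho_{xx}}\, x_{true} + \sqrt{1-\rho_{xx}}\, e}
#' with independent standard-normal error, so the expected observed
#' correlation between two variables is the population correlation
#' attenuated by \eqn{\sqrt{\rho_{xx}\rho_{yy}}}.
#'
#' @param n Number of participants (rows).
#' @param corr Population correlation matrix (symmetric, unit diagonal,
#'   positive semi-definite).
#' @param labels Variable names; default the column names of `corr`, or
#'   `V1, V2, ...`.
#' @param reliabilities Optional per-variable reliabilities in (0, 1\];
#'   length must match `ncol(corr)`. `NULL` (default) yields error-free
#'   scores.
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @return A data frame with `n` rows and one column per variable.
#' @examples
#' R <- matrix(c(1, .4, .1,
#'               .4, 1, .2,
#'               .1, .2, 1), 3, 3,
#'             dimnames = list(NULL, c("X", "Y", "A")))
#' head(generate_scores(100, R, seed = 1))
#' @export
generate_scores <- function(n, corr, labels = NULL, reliabilities = NULL,
                            seed = NULL) {
  .validate_corr_matrix(corr)
  k <- ncol(corr)
  if (is.null(labels)) {
    labels <- colnames(corr)
    if (is.null(labels)) labels <- paste0("V", seq_len(k))
  }
  if (length(labels) != k || anyDuplicated(labels)) {
    stop("`labels` must be ", k, " unique variable names.", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer.", call. = FALSE)
  }
  if (!is.null(reliabilities)) {
    if (length(reliabilities) != k ||
        any(reliabilities <= 0 | reliabilities > 1)) {
      stop("`reliabilities` must be ", k, " values in (0, 1].", call. = FALSE)
    }
  }
  draw <- function() {
    U <- .corr_factor(corr)
    scores <- matrix(stats::rnorm(n * k), nrow = n) %*% U
    if (!is.null(reliabilities)) {
      noise <- matrix(stats::rnorm(n * k), nrow = n)
      scores <- sweep(scores, 2L, sqrt(reliabilities), `*`) +
        sweep(noise, 2L, sqrt(1 - reliabilities), `*`)
    }
    scores
  }
  scores <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  colnames(scores) <- labels
  as.data.frame(scores)
}

#' Read a population specification from a YAML file
#'
#' The file must provide `n` and `corr` (a list of rows forming the
#' population correlation matrix) and may provide `labels`, `reliabilities`
#' and `seed`. The result can be passed to [generate_scores()] via
#' `do.call()`.
#'
#' @param path Path to a YAML file.
#' @return A named list of arguments for [generate_scores()].
#' @export
read_population_spec <- function(path) {
  # keep YAML-1.1 boolean-like scalars ("Y", "n", "yes", ...) as literal
  # strings: variable labels and the `n` key would otherwise turn boolean
  spec <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x) x,
    "bool#no" = function(x) x
  ))
  if (is.null(spec$corr) || is.null(spec$n)) {
    stop("population spec must contain `corr` and `n`.", call. = FALSE)
  }
  corr <- do.call(rbind, lapply(spec$corr, as.numeric))
  out <- list(n = as.numeric(spec$n), corr = corr)
  if (!is.null(spec$labels)) {
    out$labels <- as.character(spec$labels)
    colnames(out$corr) <- out$labels
  }
  if (!is.null(spec$reliabilities)) {
    out$reliabilities <- as.numeric(spec$reliabilities)
  }
  if (!is.null(spec$seed)) out$seed <- as.integer(spec$seed)
  out
}

#' Population ICC-DE implied by a correlation matrix
#'
#' Convenience helper: extracts the population correlation profiles of two
#' focal variables with a set of criteria from a full correlation matrix and
#' returns their double-entry intraclass correlation. Useful as the ground
#' truth in simulation studies.
#'
#' @param corr Population correlation matrix with dimnames.
#' @param x,y Names of the two focal variables.
#' @param criteria Names of the criterion variables; default all others.
#' @return The population ICC-DE.
#' @export
population_icc_de <- function(corr, x, y, criteria = NULL) {
  .validate_corr_matrix(corr)
  nms <- colnames(corr)
  if (is.null(criteria)) criteria <- setdiff(nms, c(x, y))
  stopifnot(all(c(x, y, criteria) %in% nms))
  icc_de(corr[x, criteria], corr[y, criteria])
}
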