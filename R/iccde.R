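# Double-entry intraclass correlation of two nomological-network profiles,
# with bootstrap percentile confidence intervals from participant-level data.

.validate_profiles <- function(r_x, r_y) {
  r_x <- as.numeric(r_x)
  r_y <- as.numeric(r_y)
  if (length(r_x) != length(r_y)) {
    stop("`r_x` and `r_y` must have equal length.", call. = FALSE)
  }
  if (length(r_x) < 2L) {
    stop("profiles need at least 2 criteria.", call. = FALSE)
  }
  if (anyNA(r_x) || anyNA(r_y)) {
    stop("profiles must not contain missing values.", call. = FALSE)
  }
  if (any(abs(r_x) > 1) || any(abs(r_y) > 1)) {
    stop("all profile entries must lie in [-1, 1].", call. = FALSE)
  }
  list(r_x = r_x, r_y = r_y)
}

#' Double-entry expansion of two correlation profiles
#'
#' Builds the doubly entered vectors behind the ICC-DE: each profile is
#' appended to the other, giving `u = c(r_x, r_y)` and `v = c(r_y, r_x)`.
#' Correlating `u` with `v` (rather than `r_x` with `r_y`) makes the
#' coefficient sensitive to absolute agreement of the two profiles, not
#' just their rank-order similarity.
#'
#' @param r_x,r_y Numeric vectors of correlations of the two focal measures
#'   with the same ordered set of criteria.
#' @return A list with components `u` and `v`, each of length `2t`.
#' @examples
#' double_entry(c(.1, .2, .3), c(.3, .2, .1))
#' @export
double_entry <- function(r_x, r_y) {
  p <- .validate_profiles(r_x, r_y)
  list(u = c(p$r_x, p$r_y), v = c(p$r_y, p$r_x))
}

#' Double-entry intraclass correlation of two correlation profiles
#'
#' The ICC-DE is the Pearson correlation between the doubly entered
#' profiles (see [double_entry()]). It is computed here in closed form,
#' \deqn{ICC_{DE} = \frac{2\sum_i (x_i - m)(y_i - m)}
#'   {\sum_i (x_i - m)^2 + \sum_i (y_i - m)^2}}
#' with \eqn{m} the grand mean of all \eqn{2t} entries — algebraically
#' identical to `cor(u, v)` but without constructing the doubled vectors.
#' It equals 1 only for identical profiles and is symmetric in its
#' arguments.
#'
#' @inheritParams double_entry
#' @return A single number in \[-1, 1\].
#' @examples
#' icc_de(c(.1, .2, .3), c(.3, .2, .1))
#' icc_de(c(.1, .2, .3), c(.1, .2, .3)) # identical profiles: 1
#' @export
icc_de <- function(r_x, r_y) {
  p <- .validate_profiles(r_x, r_y)
  x <- p$r_x
  y <- p$r_y
  m <- mean(c(x, y))
  den <- sum((x - m)^2) + sum((y - m)^2)
  if (den == 0) {
    stop("degenerate profiles: all ", 2L * length(x), " doubly entered ",
         "values are equal, so the ICC-DE is undefined.", call. = FALSE)
  }
  2 * sum((x - m) * (y - m)) / den
}

# correlation profile of one column with each criterion column; NA when a
# column is constant (degenerate bootstrap replicate)
.profile_of <- function(data, focal, criteria) {
  f <- data[[focal]]
  if (stats::var(f) == 0) return(rep(NA_real_, length(criteria)))
  vapply(criteria, function(cc) {
    ccol <- data[[cc]]
    if (stats::var(ccol) == 0) NA_real_ else stats::cor(f, ccol)
  }, numeric(1))
}

#' Bootstrap confidence interval for the ICC-DE from participant data
#'
#' Computes the ICC-DE of the correlation profiles of two focal columns
#' with a set of criterion columns, plus a percentile bootstrap confidence
#' interval. Participants (rows) are resampled with replacement; each
#' replicate recomputes both profiles and the replicate ICC-DE, so the
#' dependence among the profile correlations is preserved. Rows with
#' missing values are dropped listwise (with a message). A replicate in
#' which a resampled column is constant (or the doubled profile has zero
#' variance) is redrawn, at most 100 times per replicate, with a warning.
#'
#' @param data A data frame of participant scores (one row per participant).
#' @param x,y Names of the two focal columns.
#' @param criteria Names of the criterion columns; default all remaining
#'   columns. At least 2 are required.
#' @param n_boot Number of bootstrap replicates. Default 1000.
#' @param conf_level Confidence level. Default .95.
#' @param seed Optional integer seed for reproducible resampling.
#' @return An object of class `"iccde_boot"`: a list with `estimate` (the
#'   full-sample ICC-DE), `boot_mean`, `ll`, `ul`, `conf_level`, `n_boot`,
#'   `seed`, `criteria`, `n_used`, `n_dropped`, and the bootstrap
#'   distribution `boot_reps`.
#' @examples
#' R <- matrix(.3, 4, 4); diag(R) <- 1
#' colnames(R) <- c("X", "Y", "A", "B")
#' d <- generate_scores(400, R, seed = 11)
#' icc_de_boot(d, "X", "Y", n_boot = 200, seed = 2)
#' @export
icc_de_boot <- function(data, x, y, criteria = NULL, n_boot = 1000,
                        conf_level = 0.95, seed = NULL) {
  if (!is.data.frame(data)) stop("`data` must be a data frame.", call. = FALSE)
  if (is.null(criteria)) criteria <- setdiff(names(data), c(x, y))
  cols <- c(x, y, criteria)
  if (anyDuplicated(cols)) {
    stop("focal and criterion columns must be distinct.", call. = FALSE)
  }
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("columns not found in `data`: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (length(criteria) < 2L) {
    stop("at least 2 criterion columns are required.", call. = FALSE)
  }
  if (!is.numeric(conf_level) || conf_level <= 0 || conf_level >= 1) {
    stop("`conf_level` must lie strictly between 0 and 1.", call. = FALSE)
  }
  if (!is.numeric(n_boot) || n_boot < 1 || n_boot != round(n_boot)) {
    stop("`n_boot` must be a positive integer.", call. = FALSE)
  }

  data <- data[, cols, drop = FALSE]
  complete <- stats::complete.cases(data)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message("dropping ", n_dropped, " incomplete row(s) (listwise deletion).")
    data <- data[complete, , drop = FALSE]
  }
  n_used <- nrow(data)
  if (n_used < 4L) {
    stop("need at least 4 complete rows; have ", n_used, ".", call. = FALSE)
  }

  estimate <- icc_de(.profile_of(data, x, criteria),
                     .profile_of(data, y, criteria))

  boot_one <- function() {
    redraws <- 0L
    repeat {
      idx <- sample.int(n_used, n_used, replace = TRUE)
      d <- data[idx, , drop = FALSE]
      px <- .profile_of(d, x, criteria)
      py <- .profile_of(d, y, criteria)
      val <- if (anyNA(px) || anyNA(py)) {
        NA_real_
      } else {
        tryCatch(icc_de(px, py), error = function(e) NA_real_)
      }
      if (!is.na(val)) return(list(val = val, redraws = redraws))
      redraws <- redraws + 1L
      if (redraws >= 100L) {
        stop("bootstrap replicate degenerate after 100 redraws; the data ",
             "are too close to constant to bootstrap.", call. = FALSE)
      }
    }
  }
  run <- function() {
    reps <- numeric(n_boot)
    redraws <- 0L
    for (b in seq_len(n_boot)) {
      r <- boot_one()
      reps[b] <- r$val
      redraws <- redraws + r$redraws
    }
    list(reps = reps, redraws = redraws)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (res$redraws > 0) {
    warning(res$redraws, " degenerate bootstrap replicate(s) were redrawn.",
            call. = FALSE)
  }

  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  ci <- unname(stats::quantile(res$reps, probs))
  out <- list(
    estimate = estimate,
    boot_mean = mean(res$reps),
    ll = ci[1L],
    ul = ci[2L],
    conf_level = conf_level,
    n_boot = as.integer(n_boot),
    seed = seed,
    x = x, y = y, criteria = criteria,
    n_used = n_used, n_dropped = n_dropped,
    n_redrawn = res$redraws,
    boot_reps = res$reps
  )
  class(out) <- "iccde_boot"
  out
}

#' @export
print.iccde_boot <- function(x, digits = 3, ...) {
  cat("Double-entry intraclass correlation (bootstrap)\n")
  cat(sprintf("  focal: %s vs %s; criteria: %s\n", x$x, x$y,
              paste(x$criteria, collapse = ", ")))
  cat(sprintf("  n = %d participants, %d bootstrap samples, %g%% CI%s\n",
              x$n_used, x$n_boot, 100 * x$conf_level,
              if (is.null(x$seed)) "" else paste0(", seed = ", x$seed)))
  cat(sprintf("  ICC_DE = %.*f  (bootstrap mean %.*f)\n",
              digits, x$estimate, digits, x$boot_mean))
  cat(sprintf("  LL = %.*f, UL = %.*f\n", digits, x$ll, digits, x$ul))
  if (x$n_dropped > 0) {
    cat(sprintf("  note: %d incomplete row(s) dropped\n", x$n_dropped))
  }
  invisible(x)
}
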