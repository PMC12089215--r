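# Context-specific redundancy thresholds (ICC_DE,crit = 1 - d/t) and the
# jingle/jangle decision rule.

#' Context-specific redundancy threshold
#'
#' The critical ICC-DE above which two nomological networks are considered
#' redundant is \eqn{ICC_{DE,crit} = 1 - d/t}, where `d` is the number of
#' criteria with detected correlation differences and `t` the total number
#' of criteria. `d` and `t` are kept as integers and the ratio is formed
#' once, so the reported fraction carries no accumulated floating-point
#' drift.
#'
#' @param d Number of detected correlation differences (integer, `0 <= d <= t`).
#' @param t Total number of criteria (positive integer).
#' @return The threshold, a number in \[0, 1\].
#' @examples
#' icc_de_crit(5, 20) # .75
#' @export
icc_de_crit <- function(d, t) {
  if (!is.numeric(t) || length(t) != 1L || t < 1 || t != round(t)) {
    stop("`t` must be a positive integer.", call. = FALSE)
  }
  if (!is.numeric(d) || length(d) != 1L || d < 0 || d > t || d != round(d)) {
    stop("`d` must be an integer between 0 and t = ", t, ".", call. = FALSE)
  }
  1 - d / t
}

#' Count detected correlation differences and derive the threshold
#'
#' For each validation criterion, tests whether the correlations of the two
#' focal measures with that criterion differ, and derives the redundancy
#' threshold `1 - d/t` from the count of detected differences.
#'
#' Counting modes:
#' * `"standard"` — a criterion counts toward `d` when [diff_test_dep()] on
#'   `(r_x, r_y)` is significant at `alpha`.
#' * `"negative_overlap"` — for constructs assumed to be opposites (one
#'   measure is expected to mirror the other), correlations differing only
#'   in sign are functionally equivalent (e.g. .30 vs -.30), while
#'   differences in absolute strength still count (e.g. -.20 vs .50). This
#'   is implemented as [diff_test_dep()] on `(r_x, -r_y)` with the focal
#'   intercorrelation flipped to `-r_xy` (the correlation of X with the
#'   reflected measure -Y), keeping the counting inferential like the
#'   standard mode.
#' * `"descriptive"` — a criterion counts when `|r_x|` and `|r_y|` differ
#'   after rounding to `digits` decimals; no significance test. `n` and
#'   `r_xy` are not needed.
#'
#' @param profiles A data frame with columns `criterion`, `r_x`, `r_y`, and
#'   optionally a logical `expected_difference` (the content-based coding of
#'   which criteria were hypothesised to differ; it is carried through to
#'   the output, never altered).
#' @param n Sample size behind the observed correlations (required for the
#'   inferential modes).
#' @param r_xy Correlation between the two focal measures (required for the
#'   inferential modes).
#' @param mode Counting mode; see Details.
#' @param alpha Per-test significance level. Default .05.
#' @param correction Multiple-testing correction applied to the per-criterion
#'   p values before counting: `"none"` (default), `"bonferroni"`, or `"BH"`.
#' @param digits Rounding used by the descriptive mode. Default 2.
#' @param warn_low,warn_high Thresholds at or beyond which an extremity
#'   warning is raised: a cutoff this easy or this hard to exceed suggests
#'   the criterion set is uninformative. Defaults .20 and .95.
#' @return An object of class `"icc_threshold"`: a list with `d`, `t`,
#'   `icc_crit`, `mode`, `alpha`, `correction`, `extremity_warning`, and a
#'   per-criterion data frame `table` (criterion, r_x, r_y, z, p, p_adj,
#'   functionally_different, expected_difference).
#' @examples
#' prof <- data.frame(criterion = c("A", "B", "C"),
#'                    r_x = c(.45, .30, .10),
#'                    r_y = c(.15, .28, .12))
#' count_differences(prof, n = 500, r_xy = .40)
#' @export
count_differences <- function(profiles, n = NULL, r_xy = NULL,
                              mode = c("standard", "negative_overlap",
                                       "descriptive"),
                              alpha = 0.05,
                              correction = c("none", "bonferroni", "BH"),
                              digits = 2,
                              warn_low = 0.20, warn_high = 0.95) {
  mode <- match.arg(mode)
  correction <- match.arg(correction)
  if (!is.data.frame(profiles) ||
      !all(c("criterion", "r_x", "r_y") %in% names(profiles))) {
    stop("`profiles` must be a data frame with columns criterion, r_x, r_y.",
         call. = FALSE)
  }
  t_total <- nrow(profiles)
  if (t_total < 1L) stop("`profiles` must have at least one row.", call. = FALSE)
  if (anyDuplicated(profiles$criterion)) {
    stop("criterion labels must be unique.", call. = FALSE)
  }
  expected <- if ("expected_difference" %in% names(profiles)) {
    as.logical(profiles$expected_difference)
  } else {
    rep(NA, t_total)
  }

  if (mode == "descriptive") {
    z <- p <- p_adj <- rep(NA_real_, t_total)
    diffs <- round(abs(profiles$r_x), digits) != round(abs(profiles$r_y), digits)
  } else {
    if (is.null(n) || is.null(r_xy)) {
      stop("`n` and `r_xy` are required for mode = \"", mode, "\".",
           call. = FALSE)
    }
    tests <- lapply(seq_len(t_total), function(i) {
      if (mode == "standard") {
        diff_test_dep(profiles$r_x[i], profiles$r_y[i], r_xy, n, alpha = alpha)
      } else {
        diff_test_dep(profiles$r_x[i], -profiles$r_y[i], -r_xy, n,
                      alpha = alpha)
      }
    })
    z <- vapply(tests, `[[`, numeric(1), "z_stat")
    p <- vapply(tests, `[[`, numeric(1), "p_value")
    p_adj <- stats::p.adjust(p, method = switch(correction,
                                                none = "none",
                                                bonferroni = "bonferroni",
                                                BH = "BH"))
    diffs <- p_adj < alpha
  }

  d <- sum(diffs)
  crit <- icc_de_crit(d, t_total)
  out <- list(
    d = as.integer(d),
    t = as.integer(t_total),
    icc_crit = crit,
    mode = mode,
    alpha = alpha,
    correction = correction,
    n = n,
    r_xy = r_xy,
    extremity_warning = crit <= warn_low || crit >= warn_high,
    warn_low = warn_low, warn_high = warn_high,
    table = data.frame(
      criterion = profiles$criterion,
      r_x = profiles$r_x,
      r_y = profiles$r_y,
      z = z,
      p = p,
      p_adj = p_adj,
      functionally_different = diffs,
      expected_difference = expected,
      stringsAsFactors = FALSE
    )
  )
  class(out) <- "icc_threshold"
  out
}

#' @export
print.icc_threshold <- function(x, digits = 3, ...) {
  cat("Context-specific redundancy threshold\n")
  cat(sprintf("  mode = %s, alpha = %s, correction = %s\n",
              x$mode, format(x$alpha), x$correction))
  cat(sprintf("  detected differences d = %d of t = %d criteria\n", x$d, x$t))
  cat(sprintf("  ICC_DE,crit = 1 - %d/%d = %.*f\n", x$d, x$t, digits,
              x$icc_crit))
  if (x$extremity_warning) {
    cat(sprintf("  warning: cutoff at or beyond %.2f/%.2f; the criterion set",
                x$warn_low, x$warn_high),
        "may be uninformative\n")
  }
  if (any(!is.na(x$table$expected_difference))) {
    tab <- table(expected = x$table$expected_difference,
                 detected = x$table$functionally_different)
    cat("  hypothesised vs detected differences:\n")
    print(tab)
  }
  invisible(x)
}

#' Decide on a jingle/jangle fallacy from the ICC-DE and its threshold
#'
#' Applies the decision rule: the evidence is conclusive only when the whole
#' bootstrap confidence interval of the observed ICC-DE lies above the
#' context-specific threshold, i.e. when the lower bound `ll` exceeds
#' `icc_crit`. For a jangle test that is evidence *for* a strong jangle
#' fallacy (the two differently named measures assess the same construct);
#' for a jingle test it is evidence *against* a strong jingle fallacy (the
#' equally named measures overlap enough to be the same construct).
#' Otherwise no strong fallacy is indicated; when the point estimate is
#' nonetheless numerically high (>= .60), the summary frames the measures
#' as sibling constructs — closely related but not twins.
#'
#' @param icc_result An [icc_de_boot()] result.
#' @param threshold A [count_differences()] result computed on the same
#'   criterion set (labels must match).
#' @param direction `"jangle_test"` (are two differently named measures the
#'   same?) or `"jingle_test"` (are two equally named measures the same?).
#' @return An object of class `"jj_decision"`: a list with `decision`,
#'   `conclusive`, `rationale`, and the key numbers (`estimate`, `ll`, `ul`,
#'   `icc_crit`, `d`, `t`, `extremity_warning`).
#' @export
decide_fallacy <- function(icc_result, threshold,
                           direction = c("jangle_test", "jingle_test")) {
  direction <- match.arg(direction)
  if (!inherits(icc_result, "iccde_boot")) {
    stop("`icc_result` must come from icc_de_boot().", call. = FALSE)
  }
  if (!inherits(threshold, "icc_threshold")) {
    stop("`threshold` must come from count_differences().", call. = FALSE)
  }
  if (!setequal(icc_result$criteria, threshold$table$criterion)) {
    stop("criterion sets of `icc_result` and `threshold` do not match.",
         call. = FALSE)
  }
  exceeds <- icc_result$ll > threshold$icc_crit
  high_estimate <- icc_result$estimate >= 0.60

  if (direction == "jangle_test") {
    if (exceeds) {
      decision <- "strong jangle fallacy indicated"
      rationale <- sprintf(
        paste("The %g%% bootstrap CI of the observed ICC_DE [%.3f, %.3f]",
              "lies entirely above the context-specific threshold %.3f",
              "(1 - %d/%d): the nomological networks overlap more strongly",
              "than the detected differences allow, so the differently",
              "named measures appear to assess the same construct."),
        100 * icc_result$conf_level, icc_result$ll, icc_result$ul,
        threshold$icc_crit, threshold$d, threshold$t)
    } else {
      decision <- "no strong jangle fallacy indicated"
      rationale <- sprintf(
        paste("The %g%% bootstrap CI of the observed ICC_DE [%.3f, %.3f]",
              "does not lie entirely above the threshold %.3f (1 - %d/%d),",
              "so a strong jangle fallacy can be ruled out.%s"),
        100 * icc_result$conf_level, icc_result$ll, icc_result$ul,
        threshold$icc_crit, threshold$d, threshold$t,
        if (high_estimate) {
          sprintf(paste(" The point estimate (%.3f) is nonetheless high:",
                        "the measures are best described as sibling",
                        "constructs - closely related but not identical."),
                  icc_result$estimate)
        } else "")
    }
  } else {
    if (exceeds) {
      decision <- "evidence against a strong jingle fallacy"
      rationale <- sprintf(
        paste("The %g%% bootstrap CI of the observed ICC_DE [%.3f, %.3f]",
              "lies entirely above the threshold %.3f (1 - %d/%d): the",
              "nomological networks overlap enough to conclude that the",
              "equally named measures assess the same construct."),
        100 * icc_result$conf_level, icc_result$ll, icc_result$ul,
        threshold$icc_crit, threshold$d, threshold$t)
    } else {
      decision <- "no strong conclusion about a jingle fallacy"
      rationale <- sprintf(
        paste("The %g%% bootstrap CI of the observed ICC_DE [%.3f, %.3f]",
              "does not lie entirely above the threshold %.3f (1 - %d/%d);",
              "the overlap of the nomological networks is insufficient to",
              "conclude that the equally named measures assess the same",
              "construct."),
        100 * icc_result$conf_level, icc_result$ll, icc_result$ul,
        threshold$icc_crit, threshold$d, threshold$t)
    }
  }
  if (threshold$extremity_warning) {
    rationale <- paste(rationale,
      sprintf(paste("Caution: the derived cutoff (%.3f) is extreme (at or",
                    "beyond %.2f/%.2f) and very easy or very hard to exceed;",
                    "the employed criterion set may be uninformative."),
              threshold$icc_crit, threshold$warn_low, threshold$warn_high))
  }
  structure(
    list(
      direction = direction,
      decision = decision,
      conclusive = exceeds,
      rationale = rationale,
      estimate = icc_result$estimate,
      ll = icc_result$ll,
      ul = icc_result$ul,
      conf_level = icc_result$conf_level,
      icc_crit = threshold$icc_crit,
      d = threshold$d,
      t = threshold$t,
      extremity_warning = threshold$extremity_warning
    ),
    class = "jj_decision"
  )
}

#' @export
print.jj_decision <- function(x, ...) {
  cat("Jingle/jangle evaluation (", x$direction, ")\n", sep = "")
  cat(sprintf("  ICC_DE = %.3f, %g%% CI [%.3f, %.3f]; threshold = %.3f (d = %d, t = %d)\n",
              x$estimate, 100 * x$conf_level, x$ll, x$ul, x$icc_crit,
              x$d, x$t))
  cat("  decision: ", x$decision, "\n", sep = "")
  cat("  ", strwrap(x$rationale, width = 76, exdent = 2), sep = "\n  ")
  invisible(x)
}
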