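#' Difference test between two inferred cOA populations
#'
#' Two-sided Welch two-sample t-test. The degenerate case of two samples
#' with zero variance and equal means returns p = 1 by convention (with a
#' message); zero variance with unequal means returns p = 0.
#'
#' @param sample_x,sample_y numeric vectors, each with at least 2 values.
#' @return The two-sided p-value.
#' @examples
#' ttest_difference(rnorm(20), rnorm(20, 5))
#' @export
ttest_difference <- function(sample_x, sample_y) {
  check_two(sample_x, sample_y)
  if (var(sample_x) == 0 && var(sample_y) == 0) {
    if (mean(sample_x) == mean(sample_y)) {
      message("both samples constant with equal means; p = 1 by convention")
      return(1)
    }
    return(0)
  }
  t.test(sample_x, sample_y)$p.value
}

#' Equivalence test between two cOA populations (TOST)
#'
#' Two one-sided Welch t-tests of the hypotheses
#' `H01: mu_x - mu_y <= -delta` and `H02: mu_x - mu_y >= +delta`.
#' Rejecting both at level `alpha` establishes that the means differ by
#' less than the equivalence margin `delta`. The overall p-value is the
#' larger of the two one-sided p-values.
#'
#' The default margin of 15 (percentage points) is the conservative
#' resolution limit of the CNN composition estimates for population sizes.
#'
#' @param sample_x,sample_y numeric vectors, each with at least 2 values,
#'   in the same units as `delta`.
#' @param delta equivalence margin (> 0), same units as the sample means.
#' @param alpha significance level (default 0.05).
#' @return A list of class `equivalence_result` with `p_lower`, `p_upper`,
#'   `p_overall = max(p_lower, p_upper)`, `delta`, `alpha`, `mean_diff` and
#'   `verdict` (`"equivalent"` or `"not demonstrated"`).
#' @examples
#' tost_equivalence(rnorm(100), rnorm(100), delta = 1)
#' @export
tost_equivalence <- function(sample_x, sample_y, delta = 15, alpha = 0.05) {
  check_two(sample_x, sample_y)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("`delta` must be a single positive number", call. = FALSE)
  diff <- mean(sample_x) - mean(sample_y)
  if (var(sample_x) == 0 && var(sample_y) == 0) {
    # both constant: the verdict is decided by the observed difference
    inside <- abs(diff) < delta
    p1 <- p2 <- if (inside) 0 else 1
  } else {
    p1 <- t.test(sample_x, sample_y, mu = -delta,
                 alternative = "greater")$p.value
    p2 <- t.test(sample_x, sample_y, mu = delta,
                 alternative = "less")$p.value
  }
  p_overall <- max(p1, p2)
  structure(list(p_lower = p1, p_upper = p2, p_overall = p_overall,
                 delta = delta, alpha = alpha, mean_diff = diff,
                 verdict = if (p1 < alpha && p2 < alpha) "equivalent"
                           else "not demonstrated"),
            class = "equivalence_result")
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf("<equivalence_result> TOST, delta = %g\n", x$delta))
  cat(sprintf("  mean difference %.4g; p_lower %.4g, p_upper %.4g, overall %.4g\n",
              x$mean_diff, x$p_lower, x$p_upper, x$p_overall))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

check_two <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs at least 2 values", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA", call. = FALSE)
  invisible(NULL)
}

#' Compare two sets of per-fold composition estimates
#'
#' For every class, runs the difference t-test and the TOST equivalence
#' test between the fold-wise fraction estimates of two samples (e.g. the
#' type III-A and III-B compositions). No multiple-testing correction is
#' applied across class comparisons.
#'
#' @param folds_x,folds_y matrices of per-fold composition estimates
#'   (rows = folds, named columns = classes), in percent or fractions —
#'   `delta` must use the same units.
#' @param delta equivalence margin per class (default 15, for percentages).
#' @param alpha significance level.
#' @return Data frame with one row per class: `class`, `mean_x`, `mean_y`,
#'   `p_difference`, `p_tost`, `equivalent`.
#' @export
compare_compositions <- function(folds_x, folds_y, delta = 15,
                                 alpha = 0.05) {
  folds_x <- as.matrix(folds_x); folds_y <- as.matrix(folds_y)
  classes <- intersect(colnames(folds_x), colnames(folds_y))
  if (!length(classes))
    stop("no shared class columns between the two fold sets", call. = FALSE)
  rows <- lapply(classes, function(cl) {
    tost <- tost_equivalence(folds_x[, cl], folds_y[, cl], delta, alpha)
    data.frame(class = cl,
               mean_x = mean(folds_x[, cl]), mean_y = mean(folds_y[, cl]),
               p_difference = ttest_difference(folds_x[, cl], folds_y[, cl]),
               p_tost = tost$p_overall,
               equivalent = tost$verdict == "equivalent")
  })
  out <- do.call(rbind, rows)
  attr(out, "note") <- "no multiple-testing correction applied"
  out
}
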