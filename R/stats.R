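# Inferential toolkit for the pre/post comparison: the confidence-interval
# sample-size formula, a two-sample t test (Student or Welch) on per-patient
# compliance fractions, and the 2x2 chi-square test of independence for the
# sex distribution. The tests delegate to stats::t.test / stats::chisq.test;
# this module fixes the conventions (variant, tails, no continuity
# correction) and the result container.

#' Target sample size from a confidence-interval margin of error
#'
#' Evaluates \code{n = z^2 * sd^2 / e^2} for a confidence level given by the
#' standard-normal quantile \code{z}, an assumed standard deviation \code{sd}
#' of the outcome fraction, and a margin of error \code{e}. The default
#' rounding truncates (\code{floor}); \code{method = "ceiling"} rounds up
#' instead.
#'
#' @param z Standard-normal quantile (1.96 for 95% confidence).
#' @param sd Assumed standard deviation, as a fraction.
#' @param e Margin of error, as a fraction in (0, 1).
#' @param method \code{"floor"} (default) or \code{"ceiling"}.
#' @return Integer target sample size.
#' @examples
#' sample_size(1.96, 0.5, 0.123)  # 63
#' @export
sample_size <- function(z, sd, e, method = c("floor", "ceiling")) {
  method <- match.arg(method)
  if (!is.finite(z) || z <= 0) stop("z must be > 0")
  if (!is.finite(sd) || sd <= 0) stop("sd must be > 0")
  if (!is.finite(e) || e <= 0 || e >= 1) stop("e must lie in (0, 1)")
  n <- z^2 * sd^2 / e^2
  if (abs(n - round(n)) < 1e-8) n <- round(n)  # guard exact quotients
  as.integer(if (method == "floor") floor(n) else ceiling(n))
}

new_test_result <- function(statistic, df, p_value, group_means, tails,
                            method, n = NULL) {
  out <- list(statistic = unname(statistic), df = unname(df),
              p_value = unname(p_value), group_means = unname(group_means),
              tails = tails, method = method, n = n)
  class(out) <- "turnwatch_test"
  out
}

#' @export
print.turnwatch_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, df = %.4g, p = %.4g (%s-tailed)\n",
              x$method, x$statistic, x$df, x$p_value, x$tails))
  if (length(x$group_means) == 2)
    cat(sprintf("  group means: %.4g vs %.4g\n",
                x$group_means[1], x$group_means[2]))
  invisible(x)
}

#' Two-sample t test on compliance fractions
#'
#' Compares two groups of per-patient outcome fractions. \code{"student"}
#' (default) pools the variance; \code{"welch"} does not. \code{tails = "one"}
#' tests the directional alternative that group \code{b} has the larger mean
#' (the post-intervention direction).
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @param variant \code{"student"} or \code{"welch"}.
#' @param tails \code{"two"} (default) or \code{"one"}.
#' @return A test-result list: \code{statistic}, \code{df}, \code{p_value},
#'   \code{group_means}, \code{tails}.
#' @export
two_sample_t <- function(a, b, variant = c("student", "welch"),
                         tails = c("two", "one")) {
  variant <- match.arg(variant)
  tails <- match.arg(tails)
  if (length(a) < 2 || length(b) < 2)
    stop("two_sample_t: each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(new_test_result(0, length(a) + length(b) - 2, 1,
                             c(mean(a), mean(b)), tails,
                             paste0(variant, " t"), c(length(a), length(b))))
    # zero pooled variance with unequal means: p -> 0 limit
    return(new_test_result(sign(mean(b) - mean(a)) * Inf,
                           length(a) + length(b) - 2, 0,
                           c(mean(a), mean(b)), tails,
                           paste0(variant, " t"), c(length(a), length(b))))
  }
  ht <- stats::t.test(b, a,
                      var.equal = (variant == "student"),
                      alternative = if (tails == "two") "two.sided" else "greater")
  new_test_result(ht$statistic, ht$parameter, ht$p.value,
                  c(mean(a), mean(b)), tails, paste0(variant, " t"),
                  c(length(a), length(b)))
}

#' Chi-square test of independence for a 2x2 table
#'
#' Pearson chi-square without continuity correction on a 2x2 contingency
#' table (e.g. sex by study phase), df = 1.
#'
#' @param counts 2x2 matrix of non-negative counts with positive margins.
#' @return A test-result list.
#' @examples
#' chi_square_2x2(matrix(c(35, 40, 35, 28), nrow = 2))
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("counts must be 2x2")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("chi_square_2x2: zero marginal")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  new_test_result(ht$statistic, ht$parameter, ht$p.value,
                  group_means = counts[1, ] / colSums(counts),
                  tails = "two", method = "chi-square independence",
                  n = sum(counts))
}
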