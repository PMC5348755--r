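#' Bland-Altman analysis with correction for multiple measurements per subject
#'
#' Computes the bias and 95% limits of agreement between a reference and a
#' test method when each subject contributes several paired measurements and
#' the true value changes between them. Differences are taken as
#' reference - test by default, so a negative bias means the test device
#' over-reads. The SD of the differences combines the within-subject variance
#' with the between-subject heterogeneity of the differences through a
#' one-way random-effects (method-of-moments) decomposition of the
#' differences by subject:
#' \deqn{\sigma_d^2 = MSW + (MSB - MSW)/m_0,\qquad
#'       m_0 = \frac{N^2 - \sum_i m_i^2}{(n-1)\,N},}
#' where \eqn{m_i} is the number of pairs from subject \eqn{i},
#' \eqn{N = \sum_i m_i}, \eqn{n} the number of subjects, and MSB/MSW the
#' between-/within-subject mean squares of the differences. A negative
#' between-subject component is clamped to zero (flagged in the result). When
#' every subject contributes a single pair the decomposition is undefined and
#' the ordinary Bland-Altman SD of the differences is used (flagged).
#'
#' @param pairs a `paired_samples` data.frame (see [align_pairs()]).
#' @param sign_convention `"ref_minus_test"` (default) or
#'   `"test_minus_ref"`.
#' @param conf_mult multiplier for the limits of agreement (1.96 for 95%).
#' @return an object of class `bland_altman` with elements `bias`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `within_subject_var`, `between_subject_var`,
#'   `n_pairs`, `n_subjects`, `mean_ref`, `mean_test`, `percentage_error`,
#'   `clamped` and `single_pair_fallback`.
#' @examples
#' p <- paired_samples(subject = rep(c("A", "B"), each = 2),
#'                     timepoint = rep(c("T0", "T1"), 2),
#'                     ref_value = c(5.2, 5.4, 4.8, 5.0),
#'                     test_value = c(5.0, 5.0, 5.0, 5.0))
#' bland_altman_repeated(p)
#' @export
bland_altman_repeated <- function(pairs,
                                  sign_convention = c("ref_minus_test",
                                                      "test_minus_ref"),
                                  conf_mult = 1.96) {
  sign_convention <- match.arg(sign_convention)
  d <- pairs$ref_value - pairs$test_value
  if (sign_convention == "test_minus_ref") d <- -d
  subj <- factor(pairs$subject)
  n <- nlevels(subj)
  N <- length(d)
  if (n < 2)
    stop_degenerate("Bland-Altman with subject correction needs >= 2 subjects")
  m <- as.vector(table(subj))
  bias <- mean(d)

  single_pair_fallback <- all(m == 1)
  clamped <- FALSE
  if (single_pair_fallback) {
    warning("every subject contributes a single pair; ",
            "between-subject component undefined, using simple SD of differences")
    sd_diff <- sd(d)
    within_var <- NA_real_
    between_var <- NA_real_
  } else {
    subj_mean <- tapply(d, subj, mean)
    ssw <- sum((d - subj_mean[subj])^2)
    ssb <- sum(m * (subj_mean - bias)^2)
    msb <- ssb / (n - 1)
    msw <- ssw / (N - n)
    m0 <- (N^2 - sum(m^2)) / ((n - 1) * N)
    between_var <- (msb - msw) / m0
    if (between_var < 0) {
      between_var <- 0
      clamped <- TRUE
    }
    within_var <- msw
    sd_diff <- sqrt(within_var + between_var)
  }
  mean_ref <- mean(pairs$ref_value)
  mean_test <- mean(pairs$test_value)
  structure(list(
    bias = bias,
    sd_diff = sd_diff,
    loa_lower = bias - conf_mult * sd_diff,
    loa_upper = bias + conf_mult * sd_diff,
    within_subject_var = within_var,
    between_subject_var = between_var,
    n_pairs = N,
    n_subjects = n,
    mean_ref = mean_ref,
    mean_test = mean_test,
    percentage_error = percentage_error(sd_diff, mean_ref, mean_test),
    sign_convention = sign_convention,
    conf_mult = conf_mult,
    clamped = clamped,
    single_pair_fallback = single_pair_fallback),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (repeated measures, %s): %d pairs, %d subjects\n",
              x$sign_convention, x$n_pairs, x$n_subjects))
  cat(sprintf("  bias %.2f, SD %.2f, LoA [%.2f, %.2f] L/min\n",
              x$bias, x$sd_diff, x$loa_lower, x$loa_upper))
  cat(sprintf("  percentage error %.1f%%\n", x$percentage_error))
  if (x$single_pair_fallback)
    cat("  (single pair per subject: simple SD fallback)\n")
  if (x$clamped)
    cat("  (negative between-subject variance clamped to 0)\n")
  invisible(x)
}

#' Percentage error of a test method
#'
#' PE = 1.96 x SD of the differences divided by the mean CO of the test and
#' reference methods, x 100%. The conventional acceptability bound for CO
#' monitors is 30%.
#'
#' @param sd_diff SD of the between-method differences, L/min.
#' @param mean_ref mean reference CO over the compared pairs, L/min (> 0).
#' @param mean_test mean test CO over the same pairs, L/min (> 0).
#' @return the percentage error, %.
#' @examples
#' percentage_error(2.9 / 1.96, 5.9, 6.0)  # ~49%
#' @export
percentage_error <- function(sd_diff, mean_ref, mean_test) {
  if (!is.finite(mean_ref) || !is.finite(mean_test) ||
      mean_ref <= 0 || mean_test <= 0)
    stop_validation("method means must be finite and > 0")
  if (sd_diff < 0) stop_validation("sd_diff must be >= 0")
  1.96 * sd_diff / ((mean_ref + mean_test) / 2) * 100
}
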