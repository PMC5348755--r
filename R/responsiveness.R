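#' Percentage change
#'
#' @param pre baseline value (> 0).
#' @param post follow-up value.
#' @return 100 * (post - pre) / pre.
#' @export
percent_change <- function(pre, post) {
  if (any(!is.finite(pre)) || any(pre <= 0))
    stop_validation("pre-challenge values must be finite and > 0")
  100 * (post - pre) / pre
}

#' Classify fluid responders
#'
#' Fluid responsiveness is an increase in stroke volume of more than the
#' threshold after a rapid fluid bolus; the comparison is strictly greater,
#' so a change of exactly the threshold is a non-responder.
#'
#' @param delta_pct percentage SV change(s).
#' @param threshold responder threshold, % (default 10).
#' @return logical responder flag(s).
#' @export
classify_responder <- function(delta_pct, threshold = 10) {
  if (any(!is.finite(delta_pct)))
    stop_validation("delta_pct must be finite")
  delta_pct > threshold
}

#' Agreement between two responder classifications
#'
#' @param ref_flags,test_flags aligned logical vectors of equal length.
#' @return a list with `n_agree` (positions where the flags match) and
#'   `n_total`.
#' @export
responder_agreement <- function(ref_flags, test_flags) {
  if (length(ref_flags) != length(test_flags))
    stop_validation("flag vectors must have equal length (%d vs %d)",
                    length(ref_flags), length(test_flags))
  list(n_agree = sum(ref_flags == test_flags), n_total = length(ref_flags))
}

#' Spearman rank correlation of fluid-induced changes
#'
#' Rank correlation with average ranks for ties and a two-sided p-value:
#' exact for fewer than 10 pairs, t-approximation otherwise.
#'
#' @param x,y paired numeric vectors (n >= 3).
#' @return a list with `rho`, `p`, `n` and `constant_input` (TRUE when either
#'   vector is constant, in which case `rho` is undefined and reported `NA`).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stop_validation("x and y must have equal length")
  n <- length(x)
  if (n < 3)
    stop_validation("Spearman correlation needs n >= 3, got %d", n)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input vector: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, constant_input = TRUE))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = n < 10,
                    alternative = "two.sided"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n,
       constant_input = FALSE)
}

#' Compare two correlation coefficients by the Fisher transformation
#'
#' z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3)), with a two-sided
#' p-value from the standard normal. The test assumes independent
#' correlations.
#'
#' @param r1,r2 correlation coefficients with |r| < 1.
#' @param n1,n2 sample sizes (> 3).
#' @return a list with `z` and `p`.
#' @examples
#' fisher_compare(0.57, 22, 0.60, 22)  # z ~ -0.14, p ~ 0.89
#' @export
fisher_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop_validation("the Fisher transform diverges at |r| = 1")
  if (n1 <= 3 || n2 <= 3)
    stop_validation("both sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Fluid-challenge responsiveness analysis
#'
#' Computes, for every subject with stroke-volume values on both sides of the
#' fluid challenge in both methods, the percentage SV change by the reference
#' and by the test device, classifies responders (strictly more than
#' `threshold` % increase), counts cross-method agreement, and correlates the
#' fluid-induced changes (Spearman). The test device's pre-bolus value is
#' taken from `pre_state` and its post-bolus value from `post_state`, so both
#' the postcal-to-postcal and the postcal-to-precal pairing can be examined.
#'
#' @param ds a `study_dataset`.
#' @param test_method test device method id.
#' @param ref_method reference method id (default `"td"`).
#' @param pre_state,post_state calibration states of the test device's pre-
#'   and post-bolus SV values (defaults `"postcal"`, `"postcal"`).
#' @param threshold responder threshold, % (default 10).
#' @param interval length-2 character vector of the challenge timepoints
#'   (defaults to the dataset's fluid-challenge interval).
#' @return an object of class `fluid_response`: a list with the per-subject
#'   `table` (subject, delta SV % and responder flag per method) and the
#'   summary fields `n_agree`, `n_total`, `spearman_rho`, `spearman_p`,
#'   `threshold`, `pre_state`, `post_state`.
#' @export
fluid_response <- function(ds, test_method, ref_method = "td",
                           pre_state = "postcal", post_state = "postcal",
                           threshold = 10,
                           interval = ds$fluid_challenge_interval) {
  rec <- ds$records
  pick <- function(method, state, tp) {
    r <- rec[rec$method == method & rec$variable == "SV" &
               rec$calibration_state == state & rec$timepoint == tp, ]
    stats::setNames(r$value, r$subject)
  }
  ref_state <- if (any(rec$calibration_state[rec$method == ref_method] == "na"))
    "na" else pre_state
  ref_pre <- pick(ref_method, ref_state, interval[1])
  ref_post <- pick(ref_method, ref_state, interval[2])
  tst_pre <- pick(test_method, pre_state, interval[1])
  tst_post <- pick(test_method, post_state, interval[2])
  subjects <- Reduce(intersect, list(names(ref_pre), names(ref_post),
                                     names(tst_pre), names(tst_post)))
  if (length(subjects) == 0)
    stop_empty_result("no subject has SV on both sides of the %s -> %s bolus",
                      interval[1], interval[2])
  dsv_ref <- percent_change(ref_pre[subjects], ref_post[subjects])
  dsv_test <- percent_change(tst_pre[subjects], tst_post[subjects])
  flags_ref <- classify_responder(dsv_ref, threshold)
  flags_test <- classify_responder(dsv_test, threshold)
  agree <- responder_agreement(flags_ref, flags_test)
  rho <- if (length(subjects) >= 3) spearman_rho(dsv_ref, dsv_test)
         else list(rho = NA_real_, p = NA_real_)
  structure(list(
    table = data.frame(subject = subjects,
                       delta_sv_ref = unname(dsv_ref),
                       delta_sv_test = unname(dsv_test),
                       responder_ref = unname(flags_ref),
                       responder_test = unname(flags_test),
                       stringsAsFactors = FALSE),
    n_agree = agree$n_agree,
    n_total = agree$n_total,
    n_responders_ref = sum(flags_ref),
    n_responders_test = sum(flags_test),
    spearman_rho = rho$rho,
    spearman_p = rho$p,
    threshold = threshold,
    ref_method = ref_method,
    test_method = test_method,
    pre_state = pre_state,
    post_state = post_state,
    interval = interval),
    class = "fluid_response")
}

#' @export
print.fluid_response <- function(x, ...) {
  cat(sprintf("Fluid responsiveness (%s -> %s, >%g%% SV increase)\n",
              x$interval[1], x$interval[2], x$threshold))
  cat(sprintf("  %s responders: %d/%d; %s (%s pre / %s post): %d/%d\n",
              x$ref_method, x$n_responders_ref, x$n_total,
              x$test_method, x$pre_state, x$post_state,
              x$n_responders_test, x$n_total))
  cat(sprintf("  classification agreement: %d of %d subjects\n",
              x$n_agree, x$n_total))
  if (!is.na(x$spearman_rho))
    cat(sprintf("  Spearman rho of delta-SV: %.2f (p = %.3g)\n",
                x$spearman_rho, x$spearman_p))
  invisible(x)
}
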