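#' Per-subject serial changes in paired measurements
#'
#' For each subject, forms one delta pair per consecutive pair of observed
#' timepoints: delta = value(to) - value(from), computed identically for the
#' reference and the test method. A missing intermediate timepoint is bridged
#' (the delta spans the gap and `gap` records the number of schedule steps)
#' rather than dropping the segment. Subjects observed at fewer than two
#' timepoints contribute nothing and are counted in the `n_subjects_dropped`
#' attribute.
#'
#' @param pairs a `paired_samples` data.frame; both interval ends come from
#'   the same calibration state (align with the state of interest first).
#' @param schedule ordered timepoint labels (defaults to the attribute
#'   attached by [align_pairs()]).
#' @return a data.frame of class `delta_pairs` with columns `subject`,
#'   `from`, `to`, `gap`, `delta_ref`, `delta_test`.
#' @export
compute_deltas <- function(pairs, schedule = attr(pairs, "schedule")) {
  if (is.null(schedule))
    stop_validation("compute_deltas needs a schedule (none attached to pairs)")
  pos <- match(pairs$timepoint, schedule)
  if (anyNA(pos))
    stop_validation("pairs contain timepoints outside the schedule")
  ord <- order(pairs$subject, pos)
  subj <- pairs$subject[ord]
  pos <- pos[ord]
  ref <- pairs$ref_value[ord]
  tst <- pairs$test_value[ord]
  same <- subj[-1] == subj[-length(subj)]
  if (length(subj) < 2 || !any(same)) {
    out <- data.frame(subject = character(), from = character(),
                      to = character(), gap = integer(),
                      delta_ref = numeric(), delta_test = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    i <- which(same)          # consecutive rows within a subject
    out <- data.frame(subject = subj[i],
                      from = schedule[pos[i]],
                      to = schedule[pos[i + 1]],
                      gap = pos[i + 1] - pos[i],
                      delta_ref = ref[i + 1] - ref[i],
                      delta_test = tst[i + 1] - tst[i],
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("delta_pairs", "data.frame")
  attr(out, "schedule") <- schedule
  attr(out, "n_subjects_dropped") <-
    length(unique(pairs$subject)) - length(unique(out$subject))
  out
}

#' Four-quadrant concordance rate
#'
#' The fraction of delta pairs in which the two methods agree on the
#' direction of change (product of deltas > 0), reported both with and
#' without a central exclusion zone for small changes whose direction is
#' noise-dominated. Pairs in which either method reports exactly zero change
#' lie on an axis and are dropped from both denominators.
#'
#' @param deltas a `delta_pairs` data.frame (or any data.frame with columns
#'   `delta_ref`, `delta_test`).
#' @param exclusion_zone central zone half-width, L/min (default 0.75, i.e.
#'   12.5% of a typical 6 L/min mean CO).
#' @param zone_rule how a pair is judged inside the zone: `"mean"` (default;
#'   mean of the two absolute deltas below the zone), `"either"`, or
#'   `"both"`.
#' @return an object of class `four_quadrant` with the with- and
#'   without-exclusion concordance rates (%, `NA` when the denominator is
#'   empty), the zone, and the counts `n_total`, `n_excluded`,
#'   `n_zero_dropped`, `n_concordant_included`.
#' @export
four_quadrant_concordance <- function(deltas, exclusion_zone = 0.75,
                                      zone_rule = c("mean", "either", "both")) {
  zone_rule <- match.arg(zone_rule)
  dr <- deltas$delta_ref
  dt <- deltas$delta_test
  if (length(dr) < 1)
    stop_degenerate("four-quadrant concordance needs at least one delta pair")
  prod <- dr * dt
  nonzero <- prod != 0
  excluded <- switch(zone_rule,
                     mean = (abs(dr) + abs(dt)) / 2 < exclusion_zone,
                     either = pmin(abs(dr), abs(dt)) < exclusion_zone,
                     both = pmax(abs(dr), abs(dt)) < exclusion_zone)
  rate <- function(keep) {
    if (!any(keep)) return(NA_real_)
    100 * sum(prod[keep] > 0) / sum(keep)
  }
  incl <- nonzero & !excluded
  structure(list(
    concordance_with_exclusion = rate(incl),
    concordance_without_exclusion = rate(nonzero),
    exclusion_zone = exclusion_zone,
    zone_rule = zone_rule,
    n_total = length(dr),
    n_excluded = sum(excluded),
    n_zero_dropped = sum(!nonzero),
    n_concordant_included = sum(prod[incl] > 0)),
    class = "four_quadrant")
}

#' @export
print.four_quadrant <- function(x, ...) {
  cat(sprintf("Four-quadrant concordance: %d delta pairs\n", x$n_total))
  cat(sprintf("  with %.2g L/min exclusion zone: %s%% (%d excluded)\n",
              x$exclusion_zone,
              if (is.na(x$concordance_with_exclusion)) "undefined"
              else sprintf("%.1f", x$concordance_with_exclusion),
              x$n_excluded))
  cat(sprintf("  without exclusion zone: %s%%\n",
              if (is.na(x$concordance_without_exclusion)) "undefined"
              else sprintf("%.1f", x$concordance_without_exclusion)))
  invisible(x)
}

#' Polar transformation of delta pairs
#'
#' Expresses each pair of CO changes as an angle to the line of identity and
#' a radius equal to the mean CO change. The raw angle of the vector
#' (delta_ref, delta_test) is rotated by -45 degrees so that perfect
#' agreement lies on the horizontal polar axis; pairs whose mean change is
#' negative are reflected into the right half-plane by adding 180 degrees
#' (flagged), so that a negative change tracked perfectly by both methods
#' also maps to 0 degrees. Angles are reported in (-180, 180].
#'
#' @param delta_ref,delta_test numeric vectors of reference and test changes,
#'   L/min. A pair with both deltas exactly zero has no direction and is an
#'   error; exclude such pairs first.
#' @return a data.frame of class `polar_points` with columns `angle`
#'   (degrees), `radius` (L/min) and `reflected`.
#' @examples
#' to_polar(1, 0.5)  # angle -18.43 degrees, radius 0.75
#' @export
to_polar <- function(delta_ref, delta_test) {
  if (length(delta_ref) != length(delta_test))
    stop_validation("delta_ref and delta_test must have equal length")
  if (any(delta_ref == 0 & delta_test == 0))
    stop_degenerate(
      "delta pair with zero change in both methods has no direction; exclude it")
  theta <- atan2(delta_test, delta_ref) * 180 / pi
  reflected <- (delta_ref + delta_test) / 2 < 0
  theta <- theta + ifelse(reflected, 180, 0)
  angle <- theta - 45
  angle <- angle %% 360
  angle <- ifelse(angle > 180, angle - 360, angle)
  out <- data.frame(angle = angle,
                    radius = abs(delta_ref + delta_test) / 2,
                    reflected = reflected)
  class(out) <- c("polar_points", "data.frame")
  out
}

#' Angular bias and polar concordance
#'
#' Summarises polar points by the angular bias (arithmetic mean of the
#' included angles; how well the test method's changes are calibrated against
#' the reference) and the polar concordance rate (% of included points within
#' `limit` degrees of the polar axis). Points with radius below the exclusion
#' zone are excluded (strict inequality); the without-exclusion concordance
#' over all points is also reported. The angular bias refers to the
#' with-exclusion set.
#'
#' @param points a `polar_points` data.frame from [to_polar()].
#' @param exclusion_zone radius below which a point is excluded, L/min
#'   (default 0.5, i.e. about 10% of a typical mean CO).
#' @param limit concordance half-angle in degrees (default 30; inclusive).
#' @return an object of class `polar_result` with `angular_bias`,
#'   `polar_concordance_with_exclusion`, `polar_concordance_without_exclusion`
#'   (%, `NA` when all points are excluded), `exclusion_zone`,
#'   `concordance_limit`, `n_total`, `n_excluded`.
#' @export
polar_statistics <- function(points, exclusion_zone = 0.5, limit = 30) {
  if (nrow(points) < 1)
    stop_degenerate("polar statistics need at least one point")
  incl <- points$radius >= exclusion_zone
  conc <- function(keep) {
    if (!any(keep)) return(NA_real_)
    100 * sum(abs(points$angle[keep]) <= limit) / sum(keep)
  }
  structure(list(
    angular_bias = if (any(incl)) mean(points$angle[incl]) else NA_real_,
    polar_concordance_with_exclusion = conc(incl),
    polar_concordance_without_exclusion = conc(rep(TRUE, nrow(points))),
    exclusion_zone = exclusion_zone,
    concordance_limit = limit,
    n_total = nrow(points),
    n_excluded = sum(!incl)),
    class = "polar_result")
}

#' @export
print.polar_result <- function(x, ...) {
  cat(sprintf("Polar trending analysis: %d points, %d below %.2g L/min zone\n",
              x$n_total, x$n_excluded, x$exclusion_zone))
  cat(sprintf("  angular bias: %s\n",
              if (is.na(x$angular_bias)) "undefined"
              else sprintf("%.1f degrees", x$angular_bias)))
  cat(sprintf("  concordance within %g degrees: %s%% (with zone), %s%% (without)\n",
              x$concordance_limit,
              if (is.na(x$polar_concordance_with_exclusion)) "undefined"
              else sprintf("%.1f", x$polar_concordance_with_exclusion),
              if (is.na(x$polar_concordance_without_exclusion)) "undefined"
              else sprintf("%.1f", x$polar_concordance_without_exclusion)))
  invisible(x)
}

#' Plot-ready trending table
#'
#' One row per delta pair with its four-quadrant exclusion flag and polar
#' coordinates, for external rendering of four-quadrant and polar plots.
#' Pairs with zero change in both methods get `NA` polar coordinates.
#'
#' @param deltas a `delta_pairs` data.frame.
#' @param fq_zone four-quadrant exclusion zone, L/min.
#' @param polar_zone polar exclusion zone, L/min.
#' @param zone_rule see [four_quadrant_concordance()].
#' @return a data.frame with columns `subject`, `from`, `to`, `gap`,
#'   `delta_ref`, `delta_test`, `fq_excluded`, `angle`, `radius`,
#'   `reflected`, `polar_excluded`.
#' @export
trending_table <- function(deltas, fq_zone = 0.75, polar_zone = 0.5,
                           zone_rule = "mean") {
  dr <- deltas$delta_ref
  dt <- deltas$delta_test
  fq_excluded <- switch(zone_rule,
                        mean = (abs(dr) + abs(dt)) / 2 < fq_zone,
                        either = pmin(abs(dr), abs(dt)) < fq_zone,
                        both = pmax(abs(dr), abs(dt)) < fq_zone)
  out <- as.data.frame(deltas)
  out$fq_excluded <- fq_excluded
  out$angle <- NA_real_
  out$radius <- NA_real_
  out$reflected <- NA
  ok <- !(dr == 0 & dt == 0)
  if (any(ok)) {
    pp <- to_polar(dr[ok], dt[ok])
    out$angle[ok] <- pp$angle
    out$radius[ok] <- pp$radius
    out$reflected[ok] <- pp$reflected
  }
  out$polar_excluded <- is.na(out$radius) | out$radius < polar_zone
  out
}
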