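#' Descriptive summary of a sample
#'
#' Mean (SD) and median (25th-75th percentile) with a Shapiro-Wilk normality
#' assessment (alpha = 0.05) selecting which central form would be reported.
#' Percentiles use linear interpolation between order statistics
#' (`quantile()` type 7). Samples too small for the Shapiro-Wilk test
#' (n < 3) default to the mean form.
#'
#' @param values numeric vector, n >= 1.
#' @param alpha significance level of the normality test.
#' @return a list with `n`, `mean`, `sd`, `median`, `q25`, `q75`,
#'   `shapiro_p` (`NA` when not applicable), `normal` and `form`
#'   (`"mean (sd)"` or `"median (iqr)"`).
#' @export
describe_values <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1) stop_validation("describe_values needs at least one value")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  shapiro_p <- NA_real_
  normal <- TRUE
  if (n >= 3 && n <= 5000 && sd(values) > 0) {
    shapiro_p <- stats::shapiro.test(values)$p.value
    normal <- shapiro_p >= alpha
  }
  list(n = n,
       mean = mean(values),
       sd = if (n > 1) sd(values) else 0,
       median = q[2], q25 = q[1], q75 = q[3],
       shapiro_p = shapiro_p,
       normal = normal,
       form = if (normal) "mean (sd)" else "median (iqr)")
}

#' Baseline contrasts across repeated timepoints
#'
#' Tests each non-baseline timepoint against the baseline on paired
#' within-subject differences: paired t test when the Shapiro-Wilk test on
#' the differences is non-significant, Wilcoxon signed-rank otherwise (zero
#' differences dropped, Wilcoxon's convention). Significance is judged at the
#' Bonferroni-corrected level alpha / m.
#'
#' @param ds a `study_dataset`.
#' @param variable measurement variable (default `"CO"`).
#' @param method method id whose values are contrasted (default `"td"`).
#' @param calibration_state calibration state of the values (default `"na"`,
#'   the reference's state).
#' @param baseline baseline timepoint (default the first schedule entry).
#' @param m number of comparisons for the Bonferroni correction (default the
#'   number of non-baseline timepoints).
#' @param alpha family-wise level (default 0.05).
#' @return a data.frame of class `contrast_result` with one row per
#'   contrasted timepoint: `variable`, `timepoint`, `n`, `test_used`
#'   (`"paired-t"` or `"wilcoxon"`), `p_raw`, `significant`. Timepoints with
#'   fewer than two paired subjects are skipped (attribute `skipped`).
#' @export
baseline_contrasts <- function(ds, variable = "CO", method = "td",
                               calibration_state = "na",
                               baseline = ds$schedule[1],
                               m = length(ds$schedule) - 1,
                               alpha = 0.05) {
  rec <- ds$records
  rec <- rec[rec$method == method & rec$variable == variable &
               rec$calibration_state == calibration_state, ]
  if (nrow(rec) == 0)
    stop_validation("no records for %s/%s in state %s", method, variable,
                    calibration_state)
  if (!baseline %in% ds$schedule)
    stop_validation("baseline %s is not on the schedule", baseline)
  base <- rec[rec$timepoint == baseline, ]
  base_val <- stats::setNames(base$value, base$subject)
  rows <- list()
  skipped <- character()
  for (tp in setdiff(ds$schedule, baseline)) {
    cur <- rec[rec$timepoint == tp, ]
    common <- intersect(cur$subject, names(base_val))
    if (length(common) < 2) {
      skipped <- c(skipped, tp)
      next
    }
    diffs <- cur$value[match(common, cur$subject)] - base_val[common]
    if (sd(diffs) == 0) {
      # no variability: no evidence of change (all-zero) or the test is
      # meaningless; report p = 1 unless the constant shift is nonzero,
      # which a paired t cannot assess without variance
      p <- 1
      test_used <- "paired-t"
    } else {
      sw_p <- stats::shapiro.test(diffs)$p.value
      if (sw_p >= 0.05) {
        p <- stats::t.test(diffs)$p.value
        test_used <- "paired-t"
      } else {
        p <- suppressWarnings(stats::wilcox.test(diffs[diffs != 0]))$p.value
        test_used <- "wilcoxon"
      }
    }
    rows[[tp]] <- data.frame(variable = variable, timepoint = tp,
                             n = length(common), test_used = test_used,
                             p_raw = p, significant = p < alpha / m,
                             stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    stop_degenerate("no timepoint had >= 2 paired subjects against %s",
                    baseline)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("contrast_result", "data.frame")
  attr(out, "baseline") <- baseline
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  attr(out, "skipped") <- skipped
  out
}

#' Summary table of hemodynamic data across timepoints
#'
#' One row per (method, variable, calibration state) present in the dataset,
#' one column per timepoint, each cell the chosen summary form from
#' [describe_values()] with an asterisk when the baseline contrast is
#' significant at the Bonferroni-corrected level.
#'
#' @inheritParams baseline_contrasts
#' @param variables variables to include (default `c("CO", "SV")`).
#' @return a data.frame with columns `method`, `variable`,
#'   `calibration_state` and one column per schedule timepoint.
#' @export
summary_table <- function(ds, variables = c("CO", "SV"),
                          baseline = ds$schedule[1],
                          m = length(ds$schedule) - 1, alpha = 0.05) {
  rec <- ds$records
  combos <- unique(rec[rec$variable %in% variables,
                       c("method", "variable", "calibration_state")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    cmb <- combos[i, ]
    sub <- rec[rec$method == cmb$method & rec$variable == cmb$variable &
                 rec$calibration_state == cmb$calibration_state, ]
    contrasts <- tryCatch(
      baseline_contrasts(ds, cmb$variable, cmb$method, cmb$calibration_state,
                         baseline = baseline, m = m, alpha = alpha),
      cotrend_error = function(e) NULL)
    cells <- vapply(ds$schedule, function(tp) {
      v <- sub$value[sub$timepoint == tp]
      if (length(v) == 0) return("")
      dsc <- describe_values(v)
      cell <- if (dsc$form == "mean (sd)")
        sprintf("%.1f (%.1f)", dsc$mean, dsc$sd)
      else
        sprintf("%.1f (%.1f-%.1f)", dsc$median, dsc$q25, dsc$q75)
      sig <- !is.null(contrasts) && tp %in% contrasts$timepoint &&
        contrasts$significant[contrasts$timepoint == tp]
      if (isTRUE(sig)) paste0(cell, " *") else cell
    }, character(1))
    rows[[i]] <- cbind(cmb, as.data.frame(as.list(cells),
                                          col.names = ds$schedule,
                                          stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
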