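#' Configure an end-to-end pipeline run
#'
#' @param input the study input: a `study_dataset`, a measurements CSV path,
#'   a `simulation_config`, or `NULL` to simulate under the default
#'   conditions with `seed`.
#' @param out_dir output directory for the results bundle (created if
#'   needed).
#' @param ref_method reference method id (default `"td"`).
#' @param test_methods test method ids; `NULL` auto-detects every non-
#'   reference method in the data.
#' @param calibration_states states analysed for each test method.
#' @param variable variable for agreement/trending analysis (default
#'   `"CO"`).
#' @param fq_zone four-quadrant exclusion zone, L/min (default 0.75).
#' @param polar_zone polar exclusion zone, L/min (default 0.5).
#' @param polar_limit polar concordance half-angle, degrees (default 30).
#' @param responder_threshold fluid-responder threshold, % (default 10).
#' @param seed integer seed used when `input` requires simulation.
#' @return an object of class `run_config`.
#' @export
run_config <- function(input = NULL, out_dir = "cotrend_run",
                       ref_method = "td", test_methods = NULL,
                       calibration_states = c("precal", "postcal"),
                       variable = "CO",
                       fq_zone = 0.75, polar_zone = 0.5, polar_limit = 30,
                       responder_threshold = 10, seed = 1L) {
  if (fq_zone < 0 || polar_zone < 0)
    stop_validation("exclusion zones must be >= 0")
  if (responder_threshold <= 0)
    stop_validation("responder_threshold must be > 0")
  structure(list(input = input, out_dir = out_dir, ref_method = ref_method,
                 test_methods = test_methods,
                 calibration_states = calibration_states, variable = variable,
                 fq_zone = fq_zone, polar_zone = polar_zone,
                 polar_limit = polar_limit,
                 responder_threshold = responder_threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

resolve_input <- function(config) {
  input <- config$input
  if (is.null(input))
    input <- simulation_config(seed = config$seed)
  if (inherits(input, "simulation_config")) {
    sim <- simulate_study(input)
    return(list(dataset = sim$dataset, truth = sim$truth))
  }
  if (inherits(input, "study_dataset"))
    return(list(dataset = input, truth = NULL))
  if (is.character(input) && length(input) == 1)
    return(list(dataset = read_measurements(input), truth = NULL))
  stop_validation("unrecognised pipeline input")
}

#' Run the full method-comparison pipeline
#'
#' Executes pair alignment, repeated-measures Bland-Altman agreement,
#' four-quadrant and polar trending, fluid-responsiveness analysis and the
#' timepoint summary table for every (test method, calibration state)
#' combination, and writes a results bundle to `config$out_dir`:
#' `manifest.json` (configuration echo and package version),
#' `agreement.csv`, `trending_summary.json`, `trending_points.csv`
#' (plot-ready), `fluid.csv`, `table2.csv`, `measurements.csv`,
#' `ground_truth.csv` (simulated inputs only) and `run.log` (every skip and
#' exclusion). Re-running with the same configuration and seed reproduces
#' the bundle exactly.
#'
#' @param config a `run_config`.
#' @return the result bundle, invisibly: a list with elements `agreement`,
#'   `trending`, `trending_points`, `fluid`, `table2`, `dataset`, `log`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config"))
    stop_validation("run_pipeline expects a run_config")
  resolved <- resolve_input(config)
  ds <- resolved$dataset
  log_lines <- character()
  note <- function(stage, msg)
    log_lines[[length(log_lines) + 1]] <<- sprintf("[%s] %s", stage, msg)

  methods_present <- unique(ds$records$method)
  test_methods <- config$test_methods
  if (is.null(test_methods))
    test_methods <- setdiff(methods_present, config$ref_method)
  missing <- setdiff(test_methods, methods_present)
  if (length(missing) > 0)
    stop_validation("test method(s) not present in input: %s",
                    paste(missing, collapse = ", "))
  if (!config$ref_method %in% methods_present)
    stop_validation("reference method '%s' not present in input",
                    config$ref_method)

  agreement_rows <- list()
  trending_summ <- list()
  points_rows <- list()
  for (m in test_methods) {
    for (st in config$calibration_states) {
      pairs <- align_pairs(ds, config$ref_method, m, config$variable, st)
      if (attr(pairs, "n_skipped") > 0)
        note("align", sprintf("%s/%s: %d one-sided records skipped",
                              m, st, attr(pairs, "n_skipped")))
      ba <- withCallingHandlers(
        bland_altman_repeated(pairs),
        warning = function(w) {
          note("agreement", sprintf("%s/%s: %s", m, st, conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      agreement_rows[[paste(m, st)]] <- data.frame(
        method = m, calibration_state = st,
        n_pairs = ba$n_pairs, n_subjects = ba$n_subjects,
        bias = ba$bias, sd_diff = ba$sd_diff,
        loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
        within_subject_var = ba$within_subject_var,
        between_subject_var = ba$between_subject_var,
        percentage_error = ba$percentage_error,
        stringsAsFactors = FALSE)

      deltas <- compute_deltas(pairs)
      if (attr(deltas, "n_subjects_dropped") > 0)
        note("trending", sprintf("%s/%s: %d subject(s) with < 2 timepoints dropped",
                                 m, st, attr(deltas, "n_subjects_dropped")))
      fq <- four_quadrant_concordance(deltas, config$fq_zone)
      if (fq$n_zero_dropped > 0)
        note("trending", sprintf("%s/%s: %d zero-change pair(s) dropped",
                                 m, st, fq$n_zero_dropped))
      tt <- trending_table(deltas, config$fq_zone, config$polar_zone)
      keep <- !is.na(tt$angle)
      if (any(!keep))
        note("polar", sprintf("%s/%s: %d direction-less pair(s) excluded",
                              m, st, sum(!keep)))
      pol <- polar_statistics(
        structure(tt[keep, c("angle", "radius", "reflected")],
                  class = c("polar_points", "data.frame")),
        config$polar_zone, config$polar_limit)
      if (pol$n_excluded > 0)
        note("polar", sprintf("%s/%s: %d point(s) inside the %.2g L/min zone",
                              m, st, pol$n_excluded, config$polar_zone))
      trending_summ[[paste(m, st, sep = "_")]] <- list(
        method = m, calibration_state = st,
        four_quadrant = unclass(fq), polar = unclass(pol))
      tt$method <- m
      tt$calibration_state <- st
      points_rows[[paste(m, st)]] <- tt
    }
  }

  fluid_rows <- list()
  for (m in test_methods) {
    for (ps in c("postcal", "precal")) {
      fr <- tryCatch(
        fluid_response(ds, m, config$ref_method, pre_state = "postcal",
                       post_state = ps,
                       threshold = config$responder_threshold),
        cotrend_empty_result = function(e) {
          note("fluid", sprintf("%s (post %s): %s", m, ps,
                                conditionMessage(e)))
          NULL
        })
      if (is.null(fr)) next
      fluid_rows[[paste(m, ps)]] <- data.frame(
        method = m, pre_state = fr$pre_state, post_state = fr$post_state,
        n_total = fr$n_total, n_agree = fr$n_agree,
        n_responders_ref = fr$n_responders_ref,
        n_responders_test = fr$n_responders_test,
        spearman_rho = fr$spearman_rho, spearman_p = fr$spearman_p,
        stringsAsFactors = FALSE)
    }
  }

  table2 <- summary_table(ds, variables = unique(c(config$variable, "SV")))

  bundle <- list(
    agreement = do.call(rbind, agreement_rows),
    trending = trending_summ,
    trending_points = do.call(rbind, points_rows),
    fluid = do.call(rbind, fluid_rows),
    table2 = table2,
    dataset = ds,
    truth = resolved$truth,
    log = log_lines)
  write_bundle(bundle, config)
  invisible(bundle)
}

write_bundle <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$out_dir, f)
  manifest <- list(
    package = "cotrend",
    version = as.character(packageVersion("cotrend")),
    ref_method = config$ref_method,
    calibration_states = config$calibration_states,
    variable = config$variable,
    fq_zone = config$fq_zone, polar_zone = config$polar_zone,
    polar_limit = config$polar_limit,
    responder_threshold = config$responder_threshold,
    seed = config$seed,
    simulated = !is.null(bundle$truth))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  write.csv(bundle$agreement, path("agreement.csv"), row.names = FALSE)
  jsonlite::write_json(bundle$trending, path("trending_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  rownames(bundle$trending_points) <- NULL
  write.csv(bundle$trending_points, path("trending_points.csv"),
            row.names = FALSE)
  if (!is.null(bundle$fluid))
    write.csv(bundle$fluid, path("fluid.csv"), row.names = FALSE)
  write.csv(bundle$table2, path("table2.csv"), row.names = FALSE)
  write_measurements(bundle$dataset, path("measurements.csv"))
  if (!is.null(bundle$truth))
    export_ground_truth(bundle$truth, path("ground_truth.csv"))
  writeLines(bundle$log, path("run.log"))
  invisible(config$out_dir)
}
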