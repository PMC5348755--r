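#' Describe a simulated test device
#'
#' Generative error model for one pulse-contour channel. A pre-calibration
#' reading at schedule step t (0-based) is
#' `scale * true + bias + drift * t + N(0, noise_sd)`; drift accumulates with
#' the schedule step until an auto-calibration reset. If `calibration_reset`
#' is set, the post-calibration reading has the accumulated drift removed and
#' carries an independent residual: `scale * true + bias + N(0, residual_sd)`.
#' Otherwise the post-calibration reading equals the pre-calibration one.
#'
#' @param method method identifier (e.g. `"pR"`, `"pF"`).
#' @param additive_bias additive bias, L/min.
#' @param proportional_scale multiplicative slope (1 = unbiased), > 0.
#' @param noise_sd SD of the additive measurement noise, L/min, >= 0.
#' @param drift_per_step drift per schedule step, L/min.
#' @param calibration_reset logical; does auto-calibration remove the drift?
#' @param residual_sd SD of the post-calibration residual noise, L/min.
#' @return an object of class `device_model`.
#' @export
device_model <- function(method, additive_bias = 0, proportional_scale = 1,
                         noise_sd = 0, drift_per_step = 0,
                         calibration_reset = TRUE, residual_sd = noise_sd) {
  if (noise_sd < 0 || residual_sd < 0)
    stop_validation("noise_sd and residual_sd must be >= 0")
  if (proportional_scale <= 0)
    stop_validation("proportional_scale must be > 0")
  structure(list(method = method, additive_bias = additive_bias,
                 proportional_scale = proportional_scale, noise_sd = noise_sd,
                 drift_per_step = drift_per_step,
                 calibration_reset = isTRUE(calibration_reset),
                 residual_sd = residual_sd),
            class = "device_model")
}

#' Configure a synthetic validation study
#'
#' The defaults emulate a 25-patient aortic-surgery cohort measured at eight
#' perioperative timepoints (T0 induction .. T7 16 h in ICU): a reference
#' cardiac-output trajectory that is low at baseline and elevated after
#' cardiopulmonary bypass (population means per timepoint), between- and
#' within-subject variability, heart-rate means rising from about 60 to about
#' 80 bpm so that stroke volume SV = CO / HR x 1000 is realistic, two
#' pulse-contour channels with site-specific additive bias, drift and an
#' auto-calibration reset, triplicate thermodilution with GEDV quality
#' readings, and a fluid bolus between T4 and T5 to which a configurable
#' fraction of subjects respond with a drawn percentage SV increase.
#'
#' @param n_subjects number of subjects (default 25).
#' @param schedule ordered timepoint labels.
#' @param co_mean per-timepoint population mean of true CO, L/min.
#' @param co_between_sd between-subject SD of true CO, L/min.
#' @param co_within_sd within-subject (timepoint-to-timepoint) SD of true CO
#'   around the subject trajectory, L/min.
#' @param hr_mean per-timepoint population mean heart rate, bpm.
#' @param hr_sd between-subject SD of heart rate, bpm.
#' @param devices list of `device_model` objects (the test channels).
#' @param responder_fraction fraction of subjects whose true SV rises in
#'   response to the fluid bolus (default 7/22, in [0, 1]).
#' @param responder_delta_mean,responder_delta_sd mean and SD of the true
#'   percentage SV change in responders (default 20 +/- 5 %).
#' @param nonresponder_delta_mean,nonresponder_delta_sd same for
#'   non-responders (default 2 +/- 4 %).
#' @param td_noise_sd SD of a single thermodilution CO reading around the
#'   true value, L/min.
#' @param gedv_mean,gedv_between_sd population mean and between-subject SD of
#'   GEDV, mL.
#' @param gedv_cv within-set coefficient of variation of GEDV readings.
#' @param gedv_outlier_rate probability that a timepoint's thermodilution set
#'   contains a GEDV outlier (forcing a 4th reading and exercise of the
#'   extreme-exclusion rule).
#' @param fluid_challenge_interval adjacent schedule labels bracketing the
#'   bolus.
#' @param seed integer seed; identical (config, seed) gives byte-identical
#'   output.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 25,
                              schedule = paste0("T", 0:7),
                              co_mean = c(4.3, 6.8, 6.2, 5.9, 5.5, 5.9, 5.8, 5.9),
                              co_between_sd = 1.0,
                              co_within_sd = 0.5,
                              hr_mean = c(59, 78, 80, 78, 80, 80, 77, 71),
                              hr_sd = 12,
                              devices = list(
                                device_model("pR", additive_bias = 0.31,
                                             noise_sd = 1.2,
                                             drift_per_step = 0.1,
                                             residual_sd = 1.0),
                                device_model("pF", additive_bias = 0.57,
                                             noise_sd = 1.1,
                                             drift_per_step = 0.1,
                                             residual_sd = 0.9)),
                              responder_fraction = 7 / 22,
                              responder_delta_mean = 20,
                              responder_delta_sd = 5,
                              nonresponder_delta_mean = 2,
                              nonresponder_delta_sd = 4,
                              td_noise_sd = 0.3,
                              gedv_mean = 1500, gedv_between_sd = 200,
                              gedv_cv = 0.02,
                              gedv_outlier_rate = 0.05,
                              fluid_challenge_interval = c("T4", "T5"),
                              seed = 1L) {
  cfg <- structure(as.list(environment()), class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_subjects < 1) stop_validation("n_subjects must be >= 1")
  S <- length(cfg$schedule)
  if (length(cfg$co_mean) != S || length(cfg$hr_mean) != S)
    stop_validation("co_mean and hr_mean must match the schedule length (%d)", S)
  if (cfg$responder_fraction < 0 || cfg$responder_fraction > 1)
    stop_validation("responder_fraction must lie in [0, 1]")
  sds <- c(cfg$co_between_sd, cfg$co_within_sd, cfg$hr_sd, cfg$td_noise_sd,
           cfg$gedv_between_sd, cfg$gedv_cv, cfg$responder_delta_sd,
           cfg$nonresponder_delta_sd)
  if (any(sds < 0)) stop_validation("all SDs must be >= 0")
  if (cfg$gedv_outlier_rate < 0 || cfg$gedv_outlier_rate > 1)
    stop_validation("gedv_outlier_rate must lie in [0, 1]")
  for (d in cfg$devices)
    if (!inherits(d, "device_model"))
      stop_validation("devices must be a list of device_model objects")
  pos <- match(cfg$fluid_challenge_interval, cfg$schedule)
  if (anyNA(pos) || pos[2] != pos[1] + 1)
    stop_validation("fluid_challenge_interval must be adjacent schedule entries")
  invisible(cfg)
}

#' Read a simulation configuration from a YAML or JSON file
#'
#' The file mirrors the arguments of [simulation_config()]; `devices` is a
#' list of mappings with the arguments of [device_model()].
#'
#' @param path configuration file (`.json`, `.yaml` or `.yml`).
#' @return a validated `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) stop_validation("config file not found: %s", path)
  lst <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_validation("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(lst$devices))
    lst$devices <- lapply(
      if (is.data.frame(lst$devices)) split(lst$devices, seq_len(nrow(lst$devices)))
      else lst$devices,
      function(d) do.call(device_model, as.list(d)))
  do.call(simulation_config, lst)
}

# One draw of the full study. All random draws come from a single seeded
# stream in a fixed documented order (subject effects, HR, within-subject CO,
# fluid response, GEDV, thermodilution noise, then device noise per device),
# so identical (config, seed) reproduces the dataset exactly.
#' Simulate a complete validation study
#'
#' Generates a full synthetic study under the configured conditions: true
#' per-subject CO and SV trajectories with a fluid bolus between the
#' configured timepoints, triplicate thermodilution reference measurements
#' with GEDV quality readings (reduced by [reduce_thermodilution()]), and
#' per-device pre- and post-calibration CO and SV records.
#'
#' @param config a `simulation_config`.
#' @return an object of class `simulated_study`: a list with elements
#'   `dataset` (a `study_dataset` of all measurement records), `truth` (a
#'   `ground_truth` object with the per-subject true values, responder flags
#'   and device parameters), and `td_raw` (a data.frame of the raw
#'   thermodilution readings).
#' @export
simulate_study <- function(config) {
  validate_simulation_config(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_subjects
  sched <- config$schedule
  S <- length(sched)
  subjects <- sprintf("S%03d", seq_len(n))
  i_pre <- match(config$fluid_challenge_interval[1], sched)
  i_post <- i_pre + 1L

  # -- true hemodynamics ------------------------------------------------
  b <- rnorm(n, 0, config$co_between_sd)                  # subject CO offset
  hr <- matrix(rnorm(n * S, rep(config$hr_mean, each = n), config$hr_sd),
               n, S)
  hr <- pmax(hr, 40)
  e <- matrix(rnorm(n * S, 0, config$co_within_sd), n, S)
  true_co <- sweep(e, 2, config$co_mean, "+") + b
  true_co <- pmax(true_co, 1.0)                           # physiological floor
  responder <- runif(n) < config$responder_fraction
  delta_pct <- ifelse(responder,
                      rnorm(n, config$responder_delta_mean,
                            config$responder_delta_sd),
                      rnorm(n, config$nonresponder_delta_mean,
                            config$nonresponder_delta_sd))
  true_sv <- true_co / hr * 1000
  true_sv[, i_post] <- true_sv[, i_pre] * (1 + delta_pct / 100)
  true_co[, i_post] <- pmax(true_sv[, i_post] * hr[, i_post] / 1000, 1.0)
  true_sv[, i_post] <- true_co[, i_post] / hr[, i_post] * 1000

  # -- reference: triplicate thermodilution with GEDV quality filter ----
  g_subj <- pmax(rnorm(n, config$gedv_mean, config$gedv_between_sd), 500)
  N <- n * S
  co_read <- matrix(rep(as.vector(true_co), 3), N, 3) +
    rnorm(N * 3, 0, config$td_noise_sd)
  co_read <- pmax(co_read, 0.5)
  gedv_read <- matrix(rep(g_subj, S), N, 1)[, c(1, 1, 1)] *
    (1 + matrix(rnorm(N * 3, 0, config$gedv_cv), N, 3))
  outlier <- runif(N) < config$gedv_outlier_rate
  extra_co <- pmax(as.vector(true_co) + rnorm(N, 0, config$td_noise_sd), 0.5)
  extra_gedv <- rep(g_subj, S) * (1 + rnorm(N, 0, config$gedv_cv))
  gedv_read[outlier, 1] <- gedv_read[outlier, 1] * 1.2
  co_read[outlier, 1] <- co_read[outlier, 1] + 1.5

  subj_long <- rep(subjects, S)
  tp_long <- rep(sched, each = n)
  spread3 <- (apply(gedv_read, 1, max) - apply(gedv_read, 1, min)) /
    rowMeans(gedv_read)
  needs4 <- outlier | spread3 > 0.10
  co_td <- rowMeans(co_read)
  td_raw_list <- vector("list", sum(needs4))
  k <- 0
  for (j in which(needs4)) {
    k <- k + 1
    tds <- thermodilution_set(subj_long[j], tp_long[j],
                              co = c(co_read[j, ], extra_co[j]),
                              gedv = c(gedv_read[j, ], extra_gedv[j]))
    co_td[j] <- reduce_thermodilution(tds)
    td_raw_list[[k]] <- data.frame(subject = tds$subject_id,
                                   timepoint = tds$timepoint,
                                   reading = seq_along(tds$co),
                                   co = tds$co, gedv = tds$gedv,
                                   stringsAsFactors = FALSE)
  }
  td_raw3 <- data.frame(subject = rep(subj_long[!needs4], 3),
                        timepoint = rep(tp_long[!needs4], 3),
                        reading = rep(1:3, each = sum(!needs4)),
                        co = as.vector(co_read[!needs4, , drop = FALSE]),
                        gedv = as.vector(gedv_read[!needs4, , drop = FALSE]),
                        stringsAsFactors = FALSE)
  td_raw <- rbind(td_raw3, do.call(rbind, td_raw_list))

  hr_long <- as.vector(hr)
  sv_td <- co_td / hr_long * 1000
  records <- list(
    data.frame(subject = subj_long, timepoint = tp_long, method = "td",
               variable = "CO", calibration_state = "na", value = co_td,
               stringsAsFactors = FALSE),
    data.frame(subject = subj_long, timepoint = tp_long, method = "td",
               variable = "SV", calibration_state = "na", value = sv_td,
               stringsAsFactors = FALSE))

  # -- test devices -----------------------------------------------------
  step0 <- rep(seq_len(S) - 1L, each = n)                 # 0-based drift steps
  for (dev in config$devices) {
    base <- dev$proportional_scale * as.vector(true_co) + dev$additive_bias
    pre <- pmax(base + dev$drift_per_step * step0 +
                  rnorm(N, 0, dev$noise_sd), 0.1)
    post <- if (dev$calibration_reset)
      pmax(base + rnorm(N, 0, dev$residual_sd), 0.1) else pre
    for (st in c("precal", "postcal")) {
      v <- if (st == "precal") pre else post
      records <- c(records, list(
        data.frame(subject = subj_long, timepoint = tp_long,
                   method = dev$method, variable = "CO",
                   calibration_state = st, value = v,
                   stringsAsFactors = FALSE),
        data.frame(subject = subj_long, timepoint = tp_long,
                   method = dev$method, variable = "SV",
                   calibration_state = st, value = v / hr_long * 1000,
                   stringsAsFactors = FALSE)))
    }
  }
  records <- do.call(rbind, records)
  ds <- study_dataset(records, schedule = sched,
                      fluid_challenge_interval = config$fluid_challenge_interval)

  truth <- structure(
    list(subjects = data.frame(subject = subjects, responder = responder,
                               delta_sv_pct = delta_pct,
                               co_offset = b, gedv_mean = g_subj,
                               stringsAsFactors = FALSE),
         states = data.frame(subject = subj_long, timepoint = tp_long,
                             true_co = as.vector(true_co),
                             true_sv = as.vector(true_sv),
                             hr = hr_long, stringsAsFactors = FALSE),
         devices = config$devices,
         seed = config$seed),
    class = "ground_truth")
  structure(list(dataset = ds, truth = truth, td_raw = td_raw),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("Simulated validation study (seed", x$truth$seed, ")\n")
  print(x$dataset)
  cat("  responders:", sum(x$truth$subjects$responder), "of",
      nrow(x$truth$subjects), "\n")
  invisible(x)
}

#' Export simulated ground truth to CSV
#'
#' Writes one row per subject-timepoint with the true CO, SV and heart rate,
#' plus the subject's responder flag and drawn percentage SV change.
#'
#' @param truth a `ground_truth` from [simulate_study()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_ground_truth <- function(truth, path) {
  st <- truth$states
  if (nrow(st) == 0) {
    out <- data.frame(subject = character(), timepoint = character(),
                      true_co = numeric(), true_sv = numeric(), hr = numeric(),
                      responder = logical(), delta_sv_pct = numeric())
  } else {
    i <- match(st$subject, truth$subjects$subject)
    out <- cbind(st, responder = truth$subjects$responder[i],
                 delta_sv_pct = truth$subjects$delta_sv_pct[i])
  }
  num <- vapply(out, is.numeric, logical(1)) &
    !vapply(out, is.logical, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a ground-truth CSV written by [export_ground_truth()]
#'
#' @param path CSV path.
#' @return a data.frame with the per-subject-timepoint truth.
#' @export
read_ground_truth <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
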