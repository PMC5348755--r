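# Shared fixtures and independent oracles.

# Longhand one-way variance-component decomposition of differences by
# subject (explicit sums of squares; no lm/anova), the oracle for
# bland_altman_repeated().
ba_oracle <- function(subject, d) {
  subject <- as.character(subject)
  ids <- unique(subject)
  n <- length(ids)
  N <- length(d)
  gm <- sum(d) / N
  ssb <- 0
  ssw <- 0
  for (s in ids) {
    di <- d[subject == s]
    ssb <- ssb + length(di) * (mean(di) - gm)^2
    ssw <- ssw + sum((di - mean(di))^2)
  }
  msb <- ssb / (n - 1)
  msw <- ssw / (N - n)
  m <- as.vector(table(subject))
  m0 <- (N^2 - sum(m^2)) / ((n - 1) * N)
  between <- max(0, (msb - msw) / m0)
  list(bias = gm, within = msw, between = between,
       sd_diff = sqrt(msw + between))
}

# Paired samples with prescribed per-pair differences d (ref - test).
pairs_from_diffs <- function(subject, d, ref = NULL) {
  if (is.null(ref)) ref <- 6 + seq_along(d) * 0.01
  tp <- paste0("T", stats::ave(seq_along(d), subject, FUN = seq_along) - 1)
  paired_samples(subject = subject, timepoint = tp,
                 ref_value = ref, test_value = ref - d,
                 schedule = paste0("T", 0:(max(table(subject)) - 1)))
}

# A tiny fully-observed two-subject, eight-timepoint dataset.
tiny_dataset <- function() {
  grid <- expand.grid(subject = c("A", "B"), timepoint = paste0("T", 0:7),
                      stringsAsFactors = FALSE)
  rec <- rbind(
    data.frame(grid, method = "td", variable = "CO", calibration_state = "na",
               value = 5 + seq_len(nrow(grid)) * 0.1),
    data.frame(grid, method = "pR", variable = "CO",
               calibration_state = "precal",
               value = 5.5 + seq_len(nrow(grid)) * 0.1))
  study_dataset(rec)
}

# Generator conditions under which every channel reports the true value.
noiseless_config <- function(n = 10, seed = 1) {
  simulation_config(
    n_subjects = n, seed = seed,
    devices = list(device_model("dev", additive_bias = 0,
                                proportional_scale = 1, noise_sd = 0,
                                drift_per_step = 0, calibration_reset = TRUE,
                                residual_sd = 0)),
    td_noise_sd = 0, gedv_cv = 0, gedv_outlier_rate = 0)
}

write_records_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
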