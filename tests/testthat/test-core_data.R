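test_that("a well-formed CSV parses into a validated dataset", {
  df <- data.frame(subject = c("A", "A", "B"),
                   timepoint = c("T0", "T1", "T0"),
                   method = "td", variable = "CO", calibration_state = "na",
                   value = c(5.1, 5.3, 4.8))
  path <- write_records_csv(df, tempfile(fileext = ".csv"))
  ds <- read_measurements(path)
  expect_s3_class(ds, "study_dataset")
  expect_equal(nrow(ds$records), 3)
  expect_equal(ds$records$value, df$value)
})

test_that("schema errors and invalid rows are rejected with row context", {
  df <- data.frame(subject = "A", timepoint = "T0", method = "td",
                   variable = "CO", calibration_state = "na", value = 5.1)
  dup <- rbind(df, df)
  path <- write_records_csv(dup, tempfile(fileext = ".csv"))
  expect_error(read_measurements(path), "duplicate",
               class = "cotrend_validation_error")

  neg <- df
  neg$value <- -1.0
  path <- write_records_csv(neg, tempfile(fileext = ".csv"))
  expect_error(read_measurements(path), "row",
               class = "cotrend_validation_error")

  nocol <- df[setdiff(names(df), "method")]
  path <- write_records_csv(nocol, tempfile(fileext = ".csv"))
  expect_error(read_measurements(path), "missing column",
               class = "cotrend_validation_error")

  bad <- df
  bad$value <- "abc"
  path <- write_records_csv(bad, tempfile(fileext = ".csv"))
  expect_error(read_measurements(path), "non-numeric",
               class = "cotrend_validation_error")
})

test_that("a schema config remaps non-standard column names", {
  df <- data.frame(pat = "A", timepoint = "T0", method = "td",
                   variable = "CO", calibration_state = "na", co = 5.1)
  path <- write_records_csv(df, tempfile(fileext = ".csv"))
  ds <- read_measurements(path, schema_config = list(subject = "pat",
                                                     value = "co"))
  expect_equal(ds$records$subject, "A")
  expect_equal(ds$records$value, 5.1)
})

test_that("write then read round-trips every record exactly", {
  set.seed(11)
  grid <- expand.grid(subject = paste0("S", 1:4),
                      timepoint = paste0("T", 0:7),
                      stringsAsFactors = FALSE)
  rec <- data.frame(grid, method = "td", variable = "CO",
                    calibration_state = "na",
                    value = exp(rnorm(nrow(grid), log(5), 0.3)))
  ds <- study_dataset(rec)
  path <- tempfile(fileext = ".csv")
  write_measurements(ds, path)
  back <- read_measurements(path)
  expect_identical(back$records$value, ds$records$value)
  expect_identical(back$records$subject, ds$records$subject)
  expect_identical(back$records$timepoint, ds$records$timepoint)
})

test_that("triplicate reduction averages and applies the GEDV quality rule", {
  tds <- thermodilution_set("A", "T0", co = c(5.0, 5.2, 5.4),
                            gedv = c(1500, 1510, 1520))
  expect_equal(reduce_thermodilution(tds), 5.2)

  tds <- thermodilution_set("A", "T0", co = c(5, 5, 5),
                            gedv = c(1500, 1500, 1500))
  expect_equal(reduce_thermodilution(tds), 5.0)

  # 4th reading present: the GEDV-extreme reading is dropped
  tds <- thermodilution_set("A", "T0", co = c(5.0, 5.2, 5.4, 7.0),
                            gedv = c(1500, 1520, 1510, 2000))
  expect_equal(reduce_thermodilution(tds), 5.2)

  # excessive spread with only three readings asks for a 4th
  tds <- thermodilution_set("A", "T0", co = c(5.0, 5.2, 5.4),
                            gedv = c(1300, 1500, 1700))
  expect_error(reduce_thermodilution(tds), "4th reading",
               class = "cotrend_incomplete_set")
})

test_that("triplicate reduction is invariant to the order of readings", {
  set.seed(21)
  for (rep in 1:20) {
    k <- sample(3:4, 1)
    co <- round(runif(k, 3, 8), 2)
    gedv <- round(rnorm(k, 1500, if (k == 4) 150 else 20), 0)
    tds <- thermodilution_set("A", "T0", co, gedv)
    base <- reduce_thermodilution(tds)
    perm <- sample(k)
    expect_equal(
      reduce_thermodilution(thermodilution_set("A", "T0", co[perm],
                                               gedv[perm])),
      base, tolerance = 1e-12)
  }
})

test_that("pair alignment matches subjects and timepoints and counts skips", {
  ds <- tiny_dataset()
  pairs <- align_pairs(ds, "td", "pR", "CO", "precal")
  expect_equal(nrow(pairs), 16)
  expect_equal(attr(pairs, "n_skipped"), 0)
  # ordered by subject then schedule position
  expect_equal(pairs$subject, rep(c("A", "B"), each = 8))
  expect_equal(pairs$timepoint[1:8], paste0("T", 0:7))

  drop <- ds
  i <- which(drop$records$method == "pR" & drop$records$subject == "B" &
               drop$records$timepoint == "T3")
  drop$records <- drop$records[-i, ]
  pairs <- align_pairs(drop, "td", "pR", "CO", "precal")
  expect_equal(nrow(pairs), 15)
  expect_equal(attr(pairs, "n_skipped"), 1)

  # disjoint methods: both present but never at the same subject-timepoint
  rec <- rbind(
    data.frame(subject = "A", timepoint = paste0("T", 0:3), method = "td",
               variable = "CO", calibration_state = "na", value = 5),
    data.frame(subject = "B", timepoint = paste0("T", 0:3), method = "pR",
               variable = "CO", calibration_state = "precal", value = 5))
  expect_error(align_pairs(study_dataset(rec), "td", "pR", "CO", "precal"),
               class = "cotrend_empty_result")
})

test_that("pair count never exceeds either side's record count", {
  set.seed(31)
  for (rep in 1:10) {
    grid <- expand.grid(subject = paste0("S", 1:5),
                        timepoint = paste0("T", 0:7),
                        stringsAsFactors = FALSE)
    ref <- grid[runif(nrow(grid)) < 0.8, ]
    tst <- grid[runif(nrow(grid)) < 0.8, ]
    rec <- rbind(
      data.frame(ref, method = "td", variable = "CO",
                 calibration_state = "na", value = runif(nrow(ref), 4, 7)),
      data.frame(tst, method = "pR", variable = "CO",
                 calibration_state = "precal",
                 value = runif(nrow(tst), 4, 7)))
    ds <- study_dataset(rec)
    pairs <- align_pairs(ds, "td", "pR", "CO", "precal")
    expect_lte(nrow(pairs), min(nrow(ref), nrow(tst)))
    expect_equal(nrow(pairs) * 2 + attr(pairs, "n_skipped"),
                 nrow(ref) + nrow(tst))
  }
})
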