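make_pairs <- function(subject, timepoint, ref, test,
                       schedule = paste0("T", 0:7)) {
  paired_samples(subject, timepoint, ref, test, schedule = schedule)
}

test_that("serial deltas are consecutive within-subject differences", {
  p <- make_pairs("A", c("T0", "T1", "T2"), c(4, 5, 6), c(4.2, 5.1, 5.9))
  d <- compute_deltas(p)
  expect_equal(d$delta_ref, c(1, 1))
  expect_equal(d$delta_test, c(0.9, 0.8), tolerance = 1e-12)
  expect_equal(d$from, c("T0", "T1"))
  expect_equal(d$gap, c(1L, 1L))
})

test_that("a subject observed once contributes no deltas", {
  p <- make_pairs(c("A", "B", "B"), c("T0", "T0", "T1"),
                  c(5, 5, 6), c(5, 5, 6))
  d <- compute_deltas(p)
  expect_equal(nrow(d), 1)
  expect_equal(attr(d, "n_subjects_dropped"), 1)
})

test_that("a missing intermediate timepoint is bridged and flagged", {
  p <- make_pairs("A", c("T0", "T2"), c(4, 6), c(4.5, 6.1))
  d <- compute_deltas(p)
  expect_equal(nrow(d), 1)
  expect_equal(d$gap, 2L)
  expect_equal(d$delta_ref, 2)
  expect_equal(d$from, "T0")
  expect_equal(d$to, "T2")
})

test_that("four-quadrant concordance matches hand enumeration", {
  d <- data.frame(delta_ref = c(1.0, -1.0, 0.2, 1.2),
                  delta_test = c(0.8, 0.5, 0.1, 1.1))
  fq <- four_quadrant_concordance(d, exclusion_zone = 0.75)
  expect_equal(fq$n_excluded, 1)
  expect_equal(fq$concordance_with_exclusion, 100 * 2 / 3)
  expect_equal(fq$concordance_without_exclusion, 75)
  expect_equal(fq$n_concordant_included, 2)
})

test_that("perfect directional agreement gives 100% concordance", {
  d <- data.frame(delta_ref = c(1, 2, 1.5), delta_test = c(0.9, 1.8, 1.2))
  fq <- four_quadrant_concordance(d, exclusion_zone = 0.75)
  expect_equal(fq$concordance_with_exclusion, 100)
  expect_equal(fq$concordance_without_exclusion, 100)
})

test_that("axis points are dropped from the concordance denominator", {
  d <- data.frame(delta_ref = 0.0, delta_test = 1.0)
  fq <- four_quadrant_concordance(d, exclusion_zone = 0)
  expect_true(is.na(fq$concordance_with_exclusion))
  expect_true(is.na(fq$concordance_without_exclusion))
  expect_equal(fq$n_zero_dropped, 1)
})

test_that("polar transform matches closed-form trigonometry", {
  pp <- to_polar(1, 1)
  expect_equal(pp$angle, 0)
  expect_equal(pp$radius, 1)
  expect_false(pp$reflected)

  pp <- to_polar(1, 0.5)
  expect_equal(pp$angle, atan2(0.5, 1) * 180 / pi - 45, tolerance = 1e-12)
  expect_equal(pp$angle, -18.434948, tolerance = 1e-6)
  expect_equal(pp$radius, 0.75)

  # a negative change tracked by both methods reflects to the identity axis
  pp <- to_polar(-1, -1)
  expect_true(pp$reflected)
  expect_equal(pp$angle, 0)
  expect_equal(pp$radius, 1)

  expect_error(to_polar(0, 0), class = "cotrend_degenerate_error")
})

test_that("polar coordinates invert back to the deltas up to reflection", {
  set.seed(13)
  dr <- rnorm(50, 0, 1.5)
  dt <- rnorm(50, 0, 1.5)
  keep <- !(dr == 0 & dt == 0) & (dr + dt) != 0
  dr <- dr[keep]; dt <- dt[keep]
  pp <- to_polar(dr, dt)
  theta <- (pp$angle + 45) * pi / 180
  # radius = |dr + dt| / 2 and the direction is (cos, sin) of the unreflected
  # angle; reconstruct the vector's scale from the mean-change identity
  t_scale <- 2 * pp$radius / (cos(theta) + sin(theta))
  rec_ref <- t_scale * cos(theta) * ifelse(pp$reflected, -1, 1)
  rec_test <- t_scale * sin(theta) * ifelse(pp$reflected, -1, 1)
  expect_equal(rec_ref, dr, tolerance = 1e-9)
  expect_equal(rec_test, dt, tolerance = 1e-9)
})

test_that("swapping reference and test negates every polar angle", {
  set.seed(17)
  dr <- runif(40, -2, 2)
  dt <- runif(40, -2, 2)
  a <- to_polar(dr, dt)$angle
  b <- to_polar(dt, dr)$angle
  expect_equal(b, -a, tolerance = 1e-12)
})

test_that("positive rescaling leaves angles and concordance unchanged", {
  set.seed(19)
  dr <- runif(60, -3, 3)
  dt <- runif(60, -3, 3)
  d1 <- data.frame(delta_ref = dr, delta_test = dt)
  for (c_ in c(0.25, 3.7)) {
    d2 <- data.frame(delta_ref = c_ * dr, delta_test = c_ * dt)
    fq1 <- four_quadrant_concordance(d1, 0.75)
    fq2 <- four_quadrant_concordance(d2, 0.75 * c_)
    expect_equal(fq2$concordance_with_exclusion,
                 fq1$concordance_with_exclusion)
    expect_equal(fq2$concordance_without_exclusion,
                 fq1$concordance_without_exclusion)
    p1 <- to_polar(dr, dt)
    p2 <- to_polar(c_ * dr, c_ * dt)
    expect_equal(p2$angle, p1$angle, tolerance = 1e-12)
    s1 <- polar_statistics(p1, 0.5)
    s2 <- polar_statistics(p2, 0.5 * c_)
    expect_equal(s2$angular_bias, s1$angular_bias, tolerance = 1e-12)
    expect_equal(s2$polar_concordance_with_exclusion,
                 s1$polar_concordance_with_exclusion)
  }
})

test_that("polar summary statistics follow hand arithmetic", {
  pts <- to_polar(c(1, 1, 1), c(1, 1, 1))
  s <- polar_statistics(pts)
  expect_equal(s$angular_bias, 0)
  expect_equal(s$polar_concordance_with_exclusion, 100)

  # synthetic points at angles +10, -10, +40 with radius 1
  angles <- c(10, -10, 40)
  theta <- (angles + 45) * pi / 180
  t_scale <- 2 / (cos(theta) + sin(theta))
  pts <- to_polar(t_scale * cos(theta), t_scale * sin(theta))
  expect_equal(pts$angle, angles, tolerance = 1e-9)
  expect_equal(pts$radius, rep(1, 3), tolerance = 1e-12)
  s <- polar_statistics(pts, exclusion_zone = 0.5, limit = 30)
  expect_equal(s$angular_bias, mean(angles))
  expect_equal(s$polar_concordance_with_exclusion, 100 * 2 / 3)

  # single point below the zone: with-exclusion undefined
  one <- to_polar(0.2, 0.2)
  s <- polar_statistics(one, exclusion_zone = 0.5, limit = 30)
  expect_true(is.na(s$angular_bias))
  expect_true(is.na(s$polar_concordance_with_exclusion))
  expect_equal(s$polar_concordance_without_exclusion, 100)
})

test_that("boundary conventions: zone is strict, concordance limit inclusive", {
  pts <- to_polar(c(0.5, 0.5), c(0.5, 0.5))   # radius exactly at the zone
  s <- polar_statistics(pts, exclusion_zone = 0.5)
  expect_equal(s$n_excluded, 0)

  # exactly 30 degrees is concordant (inclusive limit); just beyond is not
  pts <- structure(data.frame(angle = c(30, 30.0001), radius = 1,
                              reflected = FALSE),
                   class = c("polar_points", "data.frame"))
  s <- polar_statistics(pts, exclusion_zone = 0.1, limit = 30)
  expect_equal(s$polar_concordance_with_exclusion, 50)
})

test_that("trending table flags exclusions consistently with the statistics", {
  set.seed(23)
  d <- data.frame(subject = "A", from = "T0", to = "T1", gap = 1L,
                  delta_ref = runif(30, -2, 2), delta_test = runif(30, -2, 2))
  tt <- trending_table(d, fq_zone = 0.75, polar_zone = 0.5)
  fq <- four_quadrant_concordance(d, 0.75)
  expect_equal(sum(tt$fq_excluded), fq$n_excluded)
  keep <- !is.na(tt$angle)
  pol <- polar_statistics(
    structure(tt[keep, c("angle", "radius", "reflected")],
              class = c("polar_points", "data.frame")), 0.5)
  expect_equal(sum(tt$polar_excluded[keep]), pol$n_excluded)
})
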