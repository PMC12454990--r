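test_that("zero-noise synthetic series reproduce the simulated temperatures exactly", {
  r <- ct_steady0()
  ms <- generate_synthetic_measurements(r, noise_sd = 0, bilateral_sd = 0, seed = 1)
  expect_equal(dim(ms), c(60, 12))
  sims <- site_temperatures(r)
  for (s in colnames(ms)) expect_true(all(ms[, s] == sims[[s]]))
})

test_that("the generator is seed-reproducible and leaves the caller's RNG alone", {
  r <- ct_steady0()
  set.seed(123)
  before <- runif(1)
  set.seed(123); runif(1)
  m1 <- generate_synthetic_measurements(r, seed = 42)
  after <- runif(1)
  m2 <- generate_synthetic_measurements(r, seed = 42)
  m3 <- generate_synthetic_measurements(r, seed = 43)
  expect_identical(m1, m2)
  expect_false(identical(m1, m3))
  set.seed(123); runif(1)
  expect_identical(after, runif(1)) # RNG state restored
})

test_that("generated series have the variance the noise model implies", {
  r <- ct_steady0()
  vals <- vapply(1:1000, function(s)
    generate_synthetic_measurements(r, seed = s, n_samples = 1)[1, "l_chest"],
    numeric(1))
  expect_equal(stats::var(vals), 0.05^2 + 0.6^2, tolerance = 0.15)
})

test_that("relative errors are zero for identical inputs and match hand arithmetic", {
  r <- ct_steady0()
  ms <- generate_synthetic_measurements(r, noise_sd = 0, bilateral_sd = 0, seed = 1)
  er <- relative_errors(r, ms)
  expect_equal(unname(er$per_site), rep(0, 12))
  expect_equal(er$max_relative_error, 0)
  expect_equal(er$mean_bilateral_diff, 0)

  sim <- c(head = 30)
  meas <- structure(matrix(29, 40, 1, dimnames = list(NULL, "head")),
                    class = "measurement_set", interval_s = 60)
  expect_equal(relative_errors(sim, meas)$per_site[["head"]], 100 / 29)
  expect_error(relative_errors(c(foot = 1), meas), "no common")
})

test_that("the report's maximum picks out the worst site in an error grid", {
  # grid with a known worst cell: back off by 16.58%
  sims <- c(head = 30, back = 28, l_chest = 31, r_chest = 31)
  meas_vals <- c(head = 30, back = 28 / (1 + 0.1658), l_chest = 31, r_chest = 31)
  meas <- structure(matrix(rep(meas_vals, each = 30), 30, 4,
                           dimnames = list(NULL, names(meas_vals))),
                    class = "measurement_set", interval_s = 60)
  er <- relative_errors(sims, meas)
  expect_equal(er$max_relative_error, 16.58, tolerance = 1e-10)
  expect_equal(names(which.max(er$per_site)), "back")
})

test_that("measurement sets round-trip through the CSV interface", {
  r <- ct_steady0()
  ms <- generate_synthetic_measurements(r, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(ms, path)
  back <- read_measurements(path)
  expect_equal(unclass(back)[, colnames(ms)], unclass(ms)[, ],
               tolerance = 1e-12, ignore_attr = TRUE)
  # cadence and range validation
  long <- utils::read.csv(path)
  long$timestamp <- long$timestamp * 2
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(long, path2, row.names = FALSE)
  expect_error(read_measurements(path2), "60 s")
})

test_that("temperature changes against a baseline average as expected", {
  sw <- matrix(c(20, 20, 20, 20), nrow = 2,
               dimnames = list(c("head", "back"), NULL))
  hc <- head_change_summary(sw)
  expect_equal(unname(hc$mean_change), c(0, 0))

  temps <- 20 + c(0, 4, 7.07, 5.5, 7.88, 7.55)
  hc2 <- head_change_summary(temps, baseline_index = 1)
  expect_equal(unname(hc2$mean_change), 6.4)

  hc3 <- head_change_summary(c(10, 11.5))
  expect_equal(unname(hc3$mean_change), 1.5)
  expect_error(head_change_summary(temps, baseline_index = 9), "baseline")
})

test_that("heat-source calibration recovers known sources and is monotone", {
  m <- ct_model(); cw <- ct_winter(); e0 <- environment_spec(0, 0.85)
  r0 <- ct_steady0()
  truth <- equivalent_sources(r0)
  pick <- c("head", "upper_arm", "l_calf")
  targets <- stats::setNames(r0$steady$T[pick, "skin"], pick)
  cal <- calibrate_equivalent_heat_sources(m, cw, e0, targets)
  expect_equal(cal$segment, pick)
  rel <- abs(cal$source_W - truth[pick]) / truth[pick]
  expect_true(all(rel < 0.01))
  expect_true(all(abs(cal$achieved_C - cal$target_C) <= 0.05))
  # a warmer target needs a strictly larger source
  cal_up <- calibrate_equivalent_heat_sources(
    m, cw, e0, stats::setNames(targets["head"] + 0.5, "head"))
  expect_gt(cal_up$source_W, cal$source_W[cal$segment == "head"])
  # unreachable target -> bracket failure reported with the segment name
  expect_error(
    calibrate_equivalent_heat_sources(m, cw, e0, c(head = -30),
                                      bounds = list(head = c(1, 5))),
    "head")
})
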