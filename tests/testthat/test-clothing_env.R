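test_that("hot-wire conductivity follows q/(4*pi*slope)", {
  expect_equal(hotwire_conductivity(4 * pi, 1), 1)
  expect_equal(hotwire_conductivity(1, 1 / (4 * pi)), 1)
  expect_equal(hotwire_conductivity(0.5, 0.02), 0.5 / (4 * pi * 0.02))
  expect_error(hotwire_conductivity(0, 1), "domain")
  expect_error(hotwire_conductivity(1, -2), "domain")
})

test_that("weighted garment conductivity reproduces the printed weight sets", {
  expect_equal(weighted_conductivity(c(thigh = 0.037, calf = 0.037), "lower"), 0.037)
  expect_equal(weighted_conductivity(c(thigh = 0.04, calf = 0.03), "lower"), 0.03524)
  up <- c(back = 0.1, chest = 0.1, abdomen = 0.1, buttock = 0.1,
          upper_arm = 0.1, lower_arm = 0.1)
  expect_equal(weighted_conductivity(up, "upper"), 0.0999)
  expect_error(weighted_conductivity(c(thigh = 0.04), "lower"), "missing region")
  expect_error(weighted_conductivity(c(thigh = -1, calf = 1), "lower"))
  # lower mode is a convex combination
  set.seed(3)
  for (k in 1:10) {
    v <- runif(2, 0.01, 0.1)
    w <- weighted_conductivity(c(thigh = v[1], calf = v[2]), "lower")
    expect_gte(w, min(v)); expect_lte(w, max(v))
  }
})

test_that("resistance decomposition matches its defining algebra", {
  r <- clothing_resistances(Ts = 30, Tc = 20, Ta = 20, Q_avg = 100, A = 1.92)
  expect_equal(r$Ri, r$Rt / 1.35) # Tc = Ta -> Ra = 0
  expect_equal(clothing_resistances(30, 25, 20, 100, 1.92)$Rt, 0.192)
  r2 <- clothing_resistances(30, 22, 20, 100, 1.92, fcl = 1.35)
  expect_equal((0.02 - 0.005) / 1.35, 0.011111, tolerance = 1e-4)
  # identity Ri*fcl + Ra = Rt, and the share is a percentage
  set.seed(9)
  for (k in 1:10) {
    Ts <- runif(1, 25, 35); Tc <- runif(1, 5, Ts); Ta <- runif(1, 0, Tc)
    rr <- clothing_resistances(Ts, Tc, Ta, runif(1, 50, 200), 1.92)
    expect_equal(rr$Ri * 1.35 + rr$Ra, rr$Rt, tolerance = 1e-12)
    expect_gte(rr$ra_fraction, 0); expect_lte(rr$ra_fraction, 100)
    expect_true(rr$Rt >= rr$Ra)
  }
  expect_error(clothing_resistances(30, 25, 20, 0, 1.92), "domain")
})

test_that("convective exchange is linear with the sign of the gradient", {
  expect_equal(convective_exchange(3, 20, 20, 1), 0)
  expect_equal(convective_exchange(3.27, 18 + 0, 0, 0.12), 3.27 * 18 * 0.12)
  expect_equal(convective_exchange(3.3, 10, 0, 1.92), 63.36)
  expect_equal(convective_exchange(2, 10, 30, 1), -40)
  expect_equal(convective_exchange(2, 25, 20, 2), 2 * convective_exchange(2, 25, 20, 1))
})

test_that("natural-convection coefficient is a calibrated quarter-power law", {
  expect_equal(convection_coefficient(20, 20, shape = 1, scale = 1), 0)
  expect_equal(convection_coefficient(36, 20, shape = 1, scale = 1), 2)
  expect_equal(convection_coefficient(10, 20, shape = 1, scale = 1), 0) # no buoyancy
  dts <- seq(0, 25, by = 0.5)
  hc <- convection_coefficient(20 + dts, 20, shape = 1.2)
  expect_true(all(diff(hc) >= 0))
})

test_that("ambient vapor pressure follows the Magnus saturation curve", {
  expect_equal(ambient_vapor_pressure(25, 0), 0)
  expect_gte(ambient_vapor_pressure(20, 1), ambient_vapor_pressure(20, 0.5))
  expect_gt(ambient_vapor_pressure(30, 0.5), ambient_vapor_pressure(10, 0.5))
  # steam-table saturation pressure at 34 C is 5.320 kPa
  expect_equal(ambient_vapor_pressure(34, 1), 5.320, tolerance = 0.01)
  expect_error(ambient_vapor_pressure(20, 1.4))
})

test_that("packaged ensembles cover the expected segments", {
  w <- ct_winter()
  expect_s3_class(w, "clothing_ensemble")
  expect_equal(attr(w, "fcl"), 1.35)
  expect_identical(w$segment[!w$covered], c("head", "hand"))
  s <- ct_summer()
  expect_identical(s$segment[s$covered],
                   c("shoulder", "chest", "abdomen", "upper_arm", "l_thigh", "r_thigh"))
  expect_true(all(w$thickness[w$covered] > 0))
  expect_error(clothing_ensemble("winter", fcl = 0.9))
})

test_that("environment specification derives vapor pressure and rejects wind", {
  e <- environment_spec(5, 0.85)
  expect_equal(e$Pa, ambient_vapor_pressure(5, 0.85))
  expect_identical(e$wind, 0)
  expect_false(e$radiation)
  expect_error(environment_spec(5, 0.5, wind = 1), "wind")
  expect_error(environment_spec(5, 1.2))
})
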