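test_that("cold metabolic adjustment boosts heat production below the set point", {
  expect_equal(metabolic_rate_cold(10, 34, 34), 10)
  expect_equal(metabolic_rate_cold(10, 24, 34), 15) # dQ = 10*(2^-1 - 1) = -5
  expect_equal(metabolic_rate_cold(17.17, 27, 37), 25.755)
  expect_equal(metabolic_rate_cold(0, 20, 34), 0)
  # strictly decreasing in T while unclamped
  Ts <- seq(20, 40, by = 0.5)
  q <- metabolic_rate_cold(10, Ts, 34)
  expect_true(all(diff(q[q > 0]) < 0))
  expect_true(all(q >= 0))
  # matrix input keeps its shape
  q2 <- metabolic_rate_cold(matrix(1:4, 2), matrix(30, 2, 2), matrix(34, 2, 2))
  expect_equal(dim(q2), c(2, 2))
})

test_that("external work is the above-basal activity share, clamped at zero", {
  expect_equal(external_work(1, 100, 1.92, 0.1), 1.17440, tolerance = 1e-9)
  expect_equal(external_work(0.5, 100, 1.92, 0.1), 0) # below basal
  met_bal <- 100 / (58.2 * 1.92)
  expect_equal(external_work(met_bal, 100, 1.92, 0.3), 0)
})

test_that("shivering is bilinear in the central and integrated cold signals", {
  ctl <- default_control(shiver_gain = 24.36)
  expect_equal(shivering_heat(0, 3, ctl, 0.5), 0)
  expect_equal(shivering_heat(1, 2, ctl, 0.5), 24.36)
  expect_equal(shivering_heat(1, 4, ctl, 0.5), 2 * 24.36)
  expect_error(shivering_heat(-1, 2, ctl, 0.5))
})

test_that("blood heat exchange follows a*rho_b*Bf*dT with the L/h convention", {
  ctl <- default_control()
  expect_equal(blood_heat_exchange(10, 36, 36, ctl), 0)
  expect_equal(blood_heat_exchange(10, 37, 36, ctl), 10.67)
  expect_equal(blood_heat_exchange(1, 34, 36, ctl), -2.134)
  expect_error(blood_heat_exchange(-1, 36, 36, ctl), "domain")
})

test_that("cold blood flow constricts with falling temperature (physiological mode)", {
  expect_equal(cold_blood_flow(10, 37), 10)
  expect_equal(cold_blood_flow(10, 27), 5)
  expect_equal(cold_blood_flow(8, 32), 8 * 2^-0.5)
  Ts <- seq(25, 40, by = 0.5)
  bf <- cold_blood_flow(6, Ts)
  expect_true(all(bf >= 0))
  expect_true(all(diff(bf) >= 0))
  # literal mode keeps the printed sign and so rises in the cold
  expect_gt(cold_blood_flow(10, 27, mode = "literal"), 10)
  expect_equal(cold_blood_flow(10, 37, mode = "literal"), 10)
})

test_that("respiratory loss vanishes at 34 C / 5.867 kPa and sums its two terms", {
  expect_equal(respiratory_loss(100, 34, 5.867), 0)
  expect_equal(respiratory_loss(100, 24, 1.867), 8.2)
  expect_equal(respiratory_loss(90, 0, 0.6), 0.0014 * 90 * 34 + 0.017 * 90 * 5.267)
})

test_that("an isothermal 37 C state with no sources is an exact fixed point", {
  m <- ct_neutral_body()
  cw <- ct_winter()
  env <- environment_spec(37, 0.5)
  T <- matrix(37, 12, 4)
  st <- body_state(T, 37)
  d <- node_derivatives(st, m, cw, env, options = list(met = 0))
  expect_equal(max(abs(d$dT), na.rm = TRUE), 0)
  expect_equal(d$dT_blood, 0)
  # and with the controller frozen at zero instead of evaluated
  frozen <- list(Err = matrix(0, 12, 3), Warm = matrix(0, 12, 3),
                 Cld = matrix(0, 12, 3), Warms = 0, Clds = 0, DL = 0, ST = 0,
                 km = rep(1, 12), BF_skin = m$Bb[, 3])
  d2 <- node_derivatives(st, m, cw, env, controls = frozen, options = list(met = 0))
  expect_equal(max(abs(d2$dT), na.rm = TRUE), 0)
})

test_that("derivatives conserve energy: node balances sum to production minus loss", {
  m <- ct_model()
  cw <- ct_winter()
  env <- environment_spec(5, 0.7)
  set.seed(13)
  for (k in 1:5) {
    T <- cbind(matrix(runif(36, 25, 38), 12, 3), runif(12, 5, 30))
    st <- body_state(T, runif(1, 34, 38))
    d <- node_derivatives(st, m, cw, env)
    tm <- d$terms
    cov <- cw$covered
    cloth <- coldtherm:::.prepare_clothing(cw, m)
    lhs <- sum(d$dT[, 1:3] * m$Cp) +
      sum(d$dT[cov, 4] * cloth$Cp_cl[cov]) +
      d$dT_blood * m$control$Cp_b
    production <- sum(tm$Q) + sum(tm$W_work) + sum(tm$Ch) + sum(tm$Qwall)
    loss <- sum(tm$Qconv) + tm$RES
    expect_equal(lhs, production - loss, tolerance = 1e-9)
    # blood pool gains exactly what the nodes lose
    expect_equal(d$dT_blood * m$control$Cp_b, sum(tm$Qb), tolerance = 1e-12)
    # conduction terms are shared antisymmetrically between adjacent layers
    core_balance <- tm$Q[, 1] + tm$Qwall - tm$Qb[, 1] - tm$Qc1 -
      c(0, 0, tm$RES, rep(0, 9))
    expect_equal(unname(core_balance), unname(d$dT[, 1] * m$Cp[, 1]), tolerance = 1e-9)
    eq_balance <- tm$Q[, 2] + tm$W_work + tm$Ch - tm$Qb[, 2] + tm$Qc1 - tm$Qc2
    expect_equal(unname(eq_balance), unname(d$dT[, 2] * m$Cp[, 2]), tolerance = 1e-9)
  }
})

test_that("non-finite states are rejected with the node identified", {
  m <- ct_model()
  T <- cbind(m$Tset, 20)
  st <- body_state(T, 36.9)
  st$T[2, 2] <- NaN
  expect_error(node_derivatives(st, m, ct_winter(), environment_spec(0, 0.5)),
               "non-finite")
})
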