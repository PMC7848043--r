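test_that("total_volume implements the absorber-swap volume accounting", {
  cases <- list(
    # (internal, default absorber, fitted absorber, hoses) -> V_tot
    list(c(4.7, 1.5, 1.2, 1.2), 5.6),
    list(c(4.7, 1.5, 1.5, 0.0), 4.7), # default absorber kept, no hoses
    list(c(5.0, 1.0, 2.0, 0.5), 6.5)
  )
  for (cs in cases) {
    v <- cs[[1]]
    cfg <- circuit_config(v[1], v[2], v[3], v[4])
    expect_equal(total_volume(cfg), cs[[2]])
  }
  expect_error(circuit_config(1.0, 3.0, 0.5, 0.5), "not positive")
})

test_that("wash-in equation matches its boundary and analytic values", {
  expect_equal(wash_in_fraction(0.21, 0.68, 0, 5.6), 0.21)       # t = 0
  # at t = tau, 63% of the final value is attained (2 significant figures)
  expect_equal(signif(wash_in_fraction(0, 0.68, 5.6, 5.6) / 0.68, 2), 0.63)
  expect_equal(wash_in_fraction(0.21, 0.68, 2 * 3, 3),
               0.21 + 0.47 * (1 - exp(-2)))
  # result stays between start and asymptote
  t <- seq(0, 50, by = 0.1)
  f <- wash_in_fraction(0.6, 0.3, t, 2)
  expect_true(all(f <= 0.6 + 1e-12 & f >= 0.3 - 1e-12))
  expect_error(wash_in_fraction(0.2, 0.6, 1, 0), "tau")
})

test_that("theoretical time constants follow V/FGF and the Conway correction", {
  expect_equal(tau_simple(5.6, c(0.5, 1, 2)), c(11.2, 5.6, 2.8))
  expect_equal(tau_simple(1, 1), 1)
  expect_error(tau_simple(5.6, 0), "fgf")
  expect_equal(tau_conway(5.6, 1.0, 0.3), 8.0)
  expect_identical(tau_conway(5.6, 1.0, 0), tau_simple(5.6, 1.0))
  expect_error(tau_conway(5.6, 0.5, 0.5), "steady state")
})

test_that("a step with no flows leaves the state unchanged", {
  cfg <- circuit_config()
  fg <- fresh_gas_settings(0, room_air())
  st <- circuit_state(0, gas_composition(o2 = 0.5, sevo = 0.02))
  st2 <- step_circuit(st, 0.5, cfg, fg, no_patient())
  expect_equal(unclass(st2$comp), unclass(st$comp))
  expect_equal(st2$t, 0.5)
})

test_that("simulation converges to the closed-form wash-in as dt shrinks", {
  fg <- fresh_gas_settings(1, delivered_mix(68, 5, "n2"))
  proto <- one_phase_protocol(1, fg$delivered)
  cfg <- circuit_config()
  tau <- tau_simple(total_volume(cfg), 1)
  rel_err <- function(dt) {
    tr <- run_protocol(proto, cfg, no_patient(), dt = dt)
    exact <- wash_in_fraction(0.21, 0.68, tr$time_min, tau)
    max(abs(tr$o2 - exact) / exact)
  }
  e1 <- rel_err(1/240)
  e2 <- rel_err(1/480)
  expect_lt(e1, 0.01)
  expect_lt(e2 / e1, 0.6) # first-order: error at least halves
})

test_that("pure entrainment dilutes the circuit toward room air", {
  cfg <- circuit_config(bag_connected = FALSE, entrain_flow = 2,
                        fgf_retained_fraction = 0)
  fg <- fresh_gas_settings(1, delivered_mix(68, 5, "n2"))
  st <- circuit_state(0, gas_composition(o2 = 0.68, sevo = 0.05))
  o2_prev <- 0.68
  for (i in 1:4000) {
    st <- step_circuit(st, 1/100, cfg, fg, no_patient())
    expect_true(st$comp[["o2"]] <= o2_prev + 1e-12) # monotone dilution
    o2_prev <- st$comp[["o2"]]
  }
  expect_equal(st$comp[["o2"]], 0.21, tolerance = 1e-3)
  expect_lt(st$comp[["sevo"]], 1e-3)
})

test_that("fractions stay a valid composition over randomized step sequences", {
  set.seed(7)
  for (i in 1:200) {
    cfg <- circuit_config(bag_connected = runif(1) < 0.5,
                          entrain_flow = runif(1, 0, 3),
                          fgf_retained_fraction = runif(1))
    fg <- fresh_gas_settings(runif(1, 0.2, 6),
                             delivered_mix(runif(1, 21, 95), runif(1, 0, 5)))
    pat <- patient_model(vo2 = runif(1, 0, 150), vco2 = runif(1, 0, 150))
    st <- circuit_state(0, room_air())
    for (s in 1:25) {
      st <- step_circuit(st, 1/120, cfg, fg, pat)
      expect_true(all(unclass(st$comp) >= 0))
      expect_lte(abs(sum(st$comp) - 1), 1e-9)
    }
  }
})

test_that("each gas stays within the hull of start, delivered and room air", {
  cfg <- circuit_config(bag_connected = FALSE, entrain_flow = 1.5,
                        fgf_retained_fraction = 0.5)
  fg <- fresh_gas_settings(2, delivered_mix(68, 5, "n2"))
  start <- gas_composition(o2 = 0.45, sevo = 0.02, n2o = 0.1)
  lo <- pmin(unclass(start), unclass(fg$delivered), unclass(room_air()))
  hi <- pmax(unclass(start), unclass(fg$delivered), unclass(room_air()))
  st <- circuit_state(0, start)
  for (s in 1:2000) {
    st <- step_circuit(st, 1/100, cfg, fg, no_patient())
    expect_true(all(unclass(st$comp) >= lo - 1e-9))
    expect_true(all(unclass(st$comp) <= hi + 1e-9))
  }
})

test_that("uptake exceeding inflow is rejected as non-physical", {
  cfg <- circuit_config()
  fg <- fresh_gas_settings(0.2, delivered_mix(100))
  expect_error(step_circuit(circuit_state(), 1/240, cfg, fg,
                            patient_model(vo2 = 300)),
               "uptake exceeds")
})

test_that("gas compositions enforce non-negativity and unit sum", {
  expect_error(gas_composition(o2 = -0.1, n2 = 1.1), "non-negative")
  expect_error(gas_composition(o2 = 0.5, n2 = 0.6), "sum to 1")
  expect_equal(sum(delivered_mix(68, 5, "n2")), 1)
  expect_equal(delivered_mix(60, 3.5, "n2o")[["n2o"]], 0.365)
  expect_equal(unname(unclass(room_air())), c(0.21, 0, 0, 0, 0.79))
})

test_that("oxygen delivery bookkeeping multiplies FGF by delivered fraction", {
  expect_equal(o2_delivery(fresh_gas_settings(0.5, delivered_mix(68, 5))), 340)
  expect_equal(o2_delivery(fresh_gas_settings(0.5, delivered_mix(60, 3.5, "n2o"))),
               300)
})
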