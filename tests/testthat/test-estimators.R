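test_that("window summaries reproduce direct order statistics", {
  # constant signal: all five summary numbers collapse to the constant
  tr <- trace_from_o2_pct(rep(40, 11))
  s <- window_summary(tr, "o2", c(0, 10))
  expect_equal(unlist(s[c("median", "q25", "q75", "min", "max")],
                      use.names = FALSE), rep(40, 5))
  # explicit samples: median/min/max from the declared (type 7) rule
  tr2 <- trace_from_o2_pct(c(28, 30, 31, 33, 35, 45))
  s2 <- window_summary(tr2, "o2", c(0, 5), per_minute = FALSE)
  expect_equal(s2$median, 32)
  expect_equal(s2$min, 28)
  expect_equal(s2$max, 45)
  expect_equal(s2$q25, unname(quantile(c(28, 30, 31, 33, 35, 45), 0.25)))
  expect_true(with(s2, min <= q25 && q25 <= median &&
                       median <= q75 && q75 <= max))
})

test_that("the after window spans 10 min from reconnection", {
  tr <- run_protocol(canonical_protocol("oxygen_air", 1))
  w <- disconnection_windows(tr)
  expect_equal(w$before, c(28, 38))
  expect_equal(w$during, c(38, 48))
  expect_equal(w$after, c(48, 58)) # reconnected phase itself lasts 20 min
  expect_equal(length(minute_readings(tr, "o2", "after")), 10)
})

test_that("windows outside the trace are rejected", {
  tr <- trace_from_o2_pct(rep(40, 6))
  expect_error(window_summary(tr, "o2", c(20, 30)), "window")
})

test_that("63% criterion recovers tau from noiseless exponentials", {
  for (tau in c(0.5, 1, 1.5, 2, 2.5, 3)) {
    tr <- synthetic_exponential_trace(0.57, 0.32, tau, duration = 20)
    est <- estimate_tau_63(tr, "o2", c(0, 20))
    expect_lt(abs(est$tau - tau), 1/12) # within one 5-s sample interval
    expect_equal(est$direction, "falling")
  }
  # rising direction is detected symmetrically
  tr <- synthetic_exponential_trace(0.32, 0.57, 2, duration = 20)
  est <- estimate_tau_63(tr, "o2", c(0, 20))
  expect_equal(est$direction, "rising")
  expect_lt(abs(est$tau - 2), 1/12)
})

test_that("63% criterion crosses a linear ramp at the analytic point", {
  # 50% -> 30% over 10 min: threshold 50 - 0.632*20 crossed at t = 6.32 min
  tr <- trace_from_o2_pct(seq(50, 30, by = -2))
  est <- estimate_tau_63(tr, "o2", c(0, 10))
  expect_equal(est$tau, 10 * (1 - exp(-1)), tolerance = 1e-9)
  expect_equal(est$f_initial, 50)
  expect_equal(est$f_final, 30)
})

test_that("degenerate transitions give tau 0 or a clear error", {
  # signal at its final value from the start: first sample already crossed
  tr <- trace_from_o2_pct(c(50, rep(30, 10)))
  expect_lte(estimate_tau_63(tr, "o2", c(0, 10))$tau, 1)
  expect_error(estimate_tau_63(trace_from_o2_pct(rep(40, 11)), "o2", c(0, 10)),
               "constant")
})

test_that("tau estimate is invariant to affine rescaling of the signal", {
  set.seed(3)
  base <- 100 * wash_in_fraction(0.6, 0.3, seq(0, 10, by = 1/12), 1.7) +
    rnorm(121, 0, 0.3)
  for (ab in list(c(0.3, 5), c(-0.5, 80), c(1.3, -10))) {
    tr1 <- trace_from_o2_pct(base, sample_interval = 1/12)
    scaled <- pmin(100, pmax(0, ab[1] * base + ab[2]))
    stopifnot(all(scaled == ab[1] * base + ab[2])) # no clipping in fixture
    tr2 <- trace_from_o2_pct(scaled, sample_interval = 1/12)
    e1 <- estimate_tau_63(tr1, "o2", c(0, 10))
    e2 <- estimate_tau_63(tr2, "o2", c(0, 10))
    expect_equal(e1$tau, e2$tau, tolerance = 1e-9)
  }
})

test_that("tau recovery holds under monitor quantization and noise", {
  for (tau in c(1, 2, 3)) {
    tr <- synthetic_exponential_trace(0.57, 0.32, tau, duration = 20)
    est <- sapply(1:30, function(s) {
      q <- quantize_trace(tr, monitor_model(seed = 100 + s))
      estimate_tau_63(q, "o2", c(0, 20))$tau
    })
    expect_lt(abs(median(est) - tau), 0.5)
  }
})

test_that("Friedman statistic matches the rank formula and handles ties", {
  m <- matrix(c(1, 2, 3, 2, 3, 4, 3, 4, 5), 3, 3, byrow = TRUE)
  r <- friedman_test(m) # strictly ordered rows: Q = 6 by hand
  expect_equal(r$statistic, 6)
  expect_equal(r$df, 2)
  expect_equal(r$n_blocks, 3)
  expect_equal(r$p_value, pchisq(6, 2, lower.tail = FALSE))
  # identical columns: no effect
  same <- matrix(rep(c(5, 7, 9, 11), 3), 4, 3)
  r0 <- friedman_test(same)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_error(friedman_test(matrix(c(1, NA, 2, 3, 4, 5), 2, 3)), "missing")
})

test_that("Friedman chi-square p agrees with the exhaustive permutation null", {
  for (m in list(rbind(c(55, 40, 48), c(56, 39, 47), c(54, 42, 49), c(55, 38, 50)),
                 rbind(c(44, 32, 33), c(45, 35, 34), c(41, 30, 35), c(43, 36, 42)))) {
    oracle <- perm_null_p(m)
    r <- friedman_test(m)
    expect_equal(r$statistic, oracle$q)
    expect_lt(abs(r$p_value - oracle$p_exact), 0.05)
  }
})

test_that("Friedman statistic is invariant under within-block monotone maps", {
  set.seed(11)
  m <- matrix(rnorm(15, 50, 5), 5, 3)
  q0 <- friedman_test(m)$statistic
  expect_equal(friedman_test(exp(m / 10))$statistic, q0)
  expect_equal(friedman_test(m^3 / 1000)$statistic, q0)
  # per-block monotone shifts also preserve ranks
  shifted <- sweep(m, 1, c(0, 10, -5, 100, 3), "+")
  expect_equal(friedman_test(shifted)$statistic, q0)
})
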