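# Simulation engine: determinism, recruitment dynamics, hysteresis,
# pressure accounting.

test_that("identical patients and protocols give bit-identical results", {
  p1 <- test_patient(n = 30)
  p2 <- test_patient(n = 30)
  proto <- build_si(p1, peep_end = 10, pre_min = 1, post_min = 2)
  s1 <- run_protocol(p1, proto)
  s2 <- run_protocol(p2, proto)
  expect_identical(s1$series, s2$series)
  expect_identical(s1$max_p, s2$max_p)
})

test_that("a fully open lung stays open and steady under baseline ventilation", {
  pat <- test_patient(n = 30, collapsed = 0.02)
  sim <- run_protocol(pat, short_baseline(pat, minutes = 2))
  expect_true(all(sim$series$pct_open == sim$series$pct_open[1]))
  pf <- sim$series$pf_ratio
  expect_lt(diff(range(pf)) / mean(pf), 0.02)
})

test_that("recruitment at the staircase end is monotone in PEEP_max", {
  pat <- test_patient(n = 40, tau_logmean = log(10))
  sw <- sweep_peep_max(pat, values = c(20, 30, 40, 45))
  expect_true(all(diff(sw$pct_recruited) >= 0))
  expect_gt(sw$pct_recruited[4], sw$pct_recruited[1])
})

test_that("post-maneuver PEEP controls retention (PEEP-cliff hysteresis)", {
  pat10 <- test_patient(n = 40)
  sim10 <- run_protocol(pat10, build_mrs(pat10, peep_end = 10, pre_min = 2,
                                         post_min = 5))
  pat5 <- test_patient(n = 40)
  sim5 <- run_protocol(pat5, build_mrs(pat5, peep_end = 5, pre_min = 2,
                                       post_min = 5))
  expect_gt(sim10$final_pct_open, sim5$final_pct_open)
  # post-RM oxygenation at PEEP 10 is at least the pre-RM level
  expect_gte(sim10$final_pf, sim10$baseline_pf - 1)
})

test_that("P_peak never exceeds the applied maximum airway pressure", {
  pat <- test_patient(n = 30)
  for (proto in list(build_mrs(pat, peep_end = 10, pre_min = 1, post_min = 2),
                     build_si(pat, peep_end = 10, pre_min = 1, post_min = 2),
                     build_prm(pat, peep_end = 10, pre_min = 1, post_min = 2))) {
    sim <- run_protocol(pat, proto)
    p_max_applied <- max(summary(proto)$p_peak)
    expect_lte(sim$p_peak, p_max_applied + 1)
  }
})

test_that("a sustained inflation drives compartment pressures to the hold pressure", {
  pat <- test_patient(n = 30, collapsed = 0.1)
  sim <- run_protocol(pat, build_si(pat, peep_end = 10, pre_min = 1,
                                    post_min = 2))
  # open compartments equilibrate to the 40 cm H2O hold: the top-20%
  # average sits just below it
  expect_gt(sim$p_peak, 38)
  expect_lte(sim$p_peak, 40.5)
})

test_that("venous oxygen stays between extremes and series are complete", {
  pat <- test_patient(n = 30)
  sim <- run_protocol(pat, build_prm(pat, peep_end = 10, pre_min = 1,
                                     post_min = 2))
  s <- sim$series
  expect_true(all(is.finite(s$pao2)))
  expect_true(all(s$pvo2 < s$pao2))
  expect_true(all(s$pct_open >= 0 & s$pct_open <= 100))
  expect_true(!is.unsorted(s$time_s))
  # arterial O2 content bracketed by venous and saturated end-capillary
  expect_true(all(s$pao2 > s$pvo2))
})

test_that("steady-state evaluator agrees with the breath engine", {
  pat <- test_patient(n = 30)
  ss <- patient_steady_state(pat, 10, 15)
  sim <- run_protocol(pat, short_baseline(pat, minutes = 3))
  tail_rows <- tail(sim$series, 5)
  expect_equal(mean(tail_rows$pao2), ss$pao2, tolerance = 0.03)
  expect_equal(mean(tail_rows$paco2), ss$paco2, tolerance = 0.03)
  expect_equal(mean(tail_rows$vt), ss$vt, tolerance = 0.02)
})
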