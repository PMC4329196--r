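# Calibration: goodness of fit, the synthetic dynamic reference, and
# parameter recovery on simulator-generated records.

test_that("goodness of fit is the Pearson correlation with guards", {
  x <- c(1, 5, 9, 20)
  expect_equal(goodness_of_fit(x, x), 1)
  expect_equal(goodness_of_fit(x, -x), -1)
  expect_error(goodness_of_fit(c(1, 2), c(1, 2)), "length")
  expect_error(goodness_of_fit(rep(3, 4), x), "variance")
})

test_that("embedded static records match the reference values", {
  recs <- load_patient_records()
  expect_equal(nrow(recs), 5)
  a <- load_patient_records("A")
  expect_equal(c(a$hb, a$co, a$fio2, a$pvo2, a$pvco2, a$qs_qt, a$pao2),
               c(10.5, 11.1, 0.8, 47.3, 44.4, 28.6, 153.7))
  expect_equal(load_patient_records("C")$fio2, 0.5)
  expect_equal(load_patient_records("E")$fio2, 1)
  expect_error(load_patient_records("Z"), "unknown")
  # baseline severity: PaO2/FiO2 in mmHg
  expect_equal(pf_ratio(a), 192.125, tolerance = 1e-6)
})

test_that("the dynamic reference generator is an exponential with noise", {
  ref0 <- generate_dynamic_reference(baseline_pao2 = 80, plateau_pao2 = 120,
                                     rise_tau = 300, fall_tau = 120,
                                     noise_sd = 0, seed = 3)
  # plateau reached well within a PEEP level (t -> infinity limit)
  i_end <- which(ref0$time_min == 39)
  expect_equal(ref0$pao2[i_end], 120, tolerance = 0.01)
  # one rise time constant after the step: 63.2% of the amplitude
  i_tau <- which(ref0$time_min == 25)   # 5 min = 300 s after the 20-min step
  expect_equal(ref0$pao2[i_tau], 80 + 0.632 * 40, tolerance = 0.02)
  # determinism under seed
  r1 <- generate_dynamic_reference(seed = 11)
  r2 <- generate_dynamic_reference(seed = 11)
  expect_identical(r1$pao2, r2$pao2)
  r3 <- generate_dynamic_reference(seed = 12)
  expect_false(identical(r1$pao2, r3$pao2))
  expect_error(generate_dynamic_reference(rise_tau = 0))
})

test_that("static calibration recovers parameters of a generated patient", {
  # build a ground-truth patient, measure its steady state, and present
  # those measurements as a record to the fitting routine
  truth <- c(vr = 14, ie = 0.33, rq = 0.75, vo2 = 260,
             collapsed_frac = 0.28, top_sd = 8, k_mean = 2.4,
             pext_mean = 2, raw_mean = 1, cd = 1, q_grad = 0.4)
  rec0 <- data.frame(label = "S", hb = 11, co = 7.5, fio2 = 0.7,
                     vr = 14, ie = 0.33, rq = 0.75, vo2 = 260,
                     collapsed_pct = 28, pv = 15, peep = 5)
  pat0 <- ardsim:::params_to_patient(truth, rec0, seed = 21)
  ss <- patient_steady_state(pat0, 5, 15)
  rec <- transform(rec0, pvo2 = ss$pvo2, pvco2 = ss$pvco2,
                   qs_qt = ss$qs_qt, pao2 = ss$pao2)
  # same compartment seed as the truth patient: recovery is conditioned
  # on the sampled lung, so residual error reflects the optimizer alone
  fit <- fit_static(rec, budget = 360, seed = 21)
  # blood-gas targets matched closely
  expect_lt(max(abs(fit$comparison$rel_err)), 0.02)
  # key parameters recovered: collapsed fraction within 5 points, VO2
  # within 10%
  expect_lt(abs(fit$params["collapsed_frac"] - 0.28), 0.05)
  expect_lt(abs(fit$params["vo2"] - 260) / 260, 0.10)
})

test_that("a stored fit reproduces its recorded model outputs on re-simulation", {
  rec <- load_patient_records("C")
  fit <- fit_static(rec, budget = 60, seed = 5)
  pat2 <- ardsim:::params_to_patient(fit$params, rec, seed = fit$seed,
                                     n = fit$n)
  ss2 <- patient_steady_state(pat2, rec$peep, rec$pv)
  expect_equal(ss2$pao2, fit$comparison$model[1], tolerance = 1e-8)
  expect_equal(ss2$qs_qt, fit$comparison$model[4], tolerance = 1e-8)
  # all reported parameters respect the physiological bounds
  b <- hyper_bounds()[names(fit$params), ]
  expect_true(all(fit$params >= b$lower & fit$params <= b$upper))
})

test_that("dynamic calibration recovers the opening time-constant scale", {
  # ground truth: a patient with slow openers; reference generated by
  # the simulator itself under a PEEP 5-25-5 schedule
  rec0 <- data.frame(label = "S", hb = 11, co = 7.5, fio2 = 0.7,
                     vr = 14, ie = 0.33, rq = 0.75, vo2 = 260,
                     collapsed_pct = 28, pv = 15, peep = 5)
  truth <- c(vr = 14, ie = 0.33, rq = 0.75, vo2 = 260,
             collapsed_frac = 0.28, top_sd = 8, k_mean = 2.4,
             pext_mean = 2, raw_mean = 1, cd = 1, q_grad = 0.4,
             tau_logmean = log(60), tau_logsd = 0.8, d_close = 14)
  # the raised-PEEP phase must hold PEEP above the threshold opening
  # pressures of the recruitable units, otherwise their opening timers
  # reset every expiration and the time constants leave no signature
  sched <- data.frame(t_min = c(0, 8, 24), peep = c(5, 25, 5))
  pat0 <- ardsim:::params_to_patient(truth, rec0, seed = 21)
  ref_ser <- run_protocol(pat0, ardsim:::reference_protocol(
    pat0, list(schedule = sched, peep_dp = 15), 32))
  reference <- structure(list(
    time_min = ref_ser$series$time_s / 60, pao2 = ref_ser$series$pao2,
    schedule = sched, peep_dp = 15), class = "dynamic_reference")
  ss <- patient_steady_state(pat0, 5, 15)
  rec <- transform(rec0, pvo2 = ss$pvo2, pvco2 = ss$pvco2,
                   qs_qt = ss$qs_qt, pao2 = ss$pao2)
  sfit <- fit_static(rec, budget = 120, seed = 33)
  dfit <- fit_dynamic(sfit, reference, budget = 25)
  # median opening time-constant recovered within 25% on the tau scale
  expect_lt(abs(unname(dfit$params["tau_logmean"]) - log(60)), log(1.25))
  # static targets did not degrade beyond tolerance
  expect_lt(max(abs(dfit$comparison$rel_err)), 0.15)
})
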