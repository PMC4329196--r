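# Protocol builders and the square-wave pressure waveform.

pat <- test_patient(n = 20)

test_that("MRS builds the staircase and titration exactly", {
  p <- build_mrs(pat, peep_end = 10, peep_max = 45)
  s <- summary(p)
  rm <- s[s$stage == "rm", ]
  expect_equal(rm$peep, seq(5, 45, by = 5))      # 9 recruitment steps
  expect_true(all(rm$duration_s == 120))
  expect_true(all(rm$dp == 15))
  ti <- s[s$stage == "titration", ]
  expect_equal(ti$peep, c(25, 20, 15, 10))
  expect_true(all(ti$duration_s == 300))
  expect_equal(s$peep[s$stage == "pre"], 10)
  expect_equal(s$peep[s$stage == "post"], 10)
  # MRS-5 titrates down to 5; an off-grid end PEEP is appended exactly
  expect_equal(summary(build_mrs(pat, peep_end = 5))$peep |> tail(2) |> head(1), 5)
  ti16 <- summary(build_mrs(pat, peep_end = 16))
  expect_equal(ti16$peep[ti16$stage == "titration"], c(25, 20, 16))
  # a lower staircase peak caps the titration start
  s35 <- summary(build_mrs(pat, peep_end = 10, peep_max = 35))
  expect_equal(max(s35$peep[s35$stage == "rm"]), 35)
  expect_error(build_mrs(pat, peep_end = 30))
  expect_error(build_mrs(pat, peep_max = 37))
})

test_that("SI is a single breath-free CPAP hold", {
  p <- build_si(pat, peep_end = 5)
  s <- summary(p)
  hold <- s[s$stage == "rm", ]
  expect_equal(hold$mode, "cpap")
  expect_equal(hold$peep, 40)
  expect_equal(hold$duration_s, 40)
  expect_equal(s$peep[s$stage == "post"], 5)
  expect_error(build_si(pat, hold = 0), "positive")
})

test_that("PRM ramps driving pressure over a fixed PEEP of 15", {
  p <- build_prm(pat, peep_end = 10)
  s <- summary(p)
  rm <- s[s$stage == "rm", ]
  expect_equal(rm$peep, rep(15, 3))
  expect_equal(rm$dp, c(15, 20, 25))
  expect_equal(rm$p_peak, c(30, 35, 40))
  expect_true(all(rm$duration_s == 120))
  expect_error(build_prm(pat, dp_step = 0), "positive")
  expect_error(build_prm(pat, dp_start = 30, dp_end = 25))
})

test_that("segments reject non-positive durations", {
  expect_error(build_baseline(10, 0, pat), "positive")
  expect_error(protocol_segment(-5, vent_settings(10)), "positive")
})

test_that("the waveform is a bounded square wave defined on the whole protocol", {
  p <- build_si(pat, peep_end = 10)
  s <- summary(p)
  t_hold <- s$duration_s[1] + 5
  expect_equal(pressure_at(p, t_hold), 40)
  # tidal: inspiration at PEEP + dP, expiration at PEEP
  cycle <- 60 / pat$vent$vr
  expect_equal(pressure_at(p, 0.1 * cycle * pat$vent$ie), 25)
  expect_equal(pressure_at(p, 0.99 * cycle), 10)
  tt <- seq(0, p$total_duration - 0.01, length.out = 400)
  pw <- pressure_at(p, tt)
  expect_true(all(pw >= 5 & pw <= 40))
  expect_error(pressure_at(p, p$total_duration + 1), "outside")
  expect_error(pressure_at(p, -0.5), "outside")
})

test_that("breath bookkeeping matches duration times rate", {
  sim <- run_protocol(test_patient(n = 10, collapsed = 0.1),
                      short_baseline(test_patient(n = 10), minutes = 1))
  expect_equal(nrow(sim$series), round(60 * 14 / 60), tolerance = 1)
})
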