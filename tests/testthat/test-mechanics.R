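# Compartment mechanics: PV law, flow integration, recruitment hysteresis.

test_that("alveolar pressure follows the cubic-stiffening PV law", {
  p1 <- compartment_params(k = 0.1, k3 = 0, p_ext = 2, top = 5, d_close = 2)
  expect_equal(alveolar_pressure(0, p1), 2)
  expect_equal(alveolar_pressure(100, p1), 12)
  p2 <- compartment_params(k = 0.05, k3 = 1e-7, p_ext = 0, top = 5, d_close = 2)
  expect_equal(alveolar_pressure(200, p2), 10.8)
  expect_error(alveolar_pressure(-1, p1), "non-negative")
  # strictly increasing in volume
  v <- seq(0, 30, by = 0.5)
  expect_true(all(diff(alveolar_pressure(v, compartment_params(
    k = 2, k3 = 1e-3, p_ext = 1, top = 5, d_close = 2)[1, ])) > 0))
})

test_that("step response of a single compartment matches the RC closed form", {
  pr <- compartment_params(k = 2, k3 = 0, p_ext = 0, top = 0.5, d_close = 0.4,
                           r_aw = 1)
  st <- lung_state(pr, open = TRUE, v = 0)
  t_end <- 1
  st2 <- step_mechanics(st, p_aw = 10, duration = t_end, dt = 1e-3)
  v_exact <- (10 / 2) * (1 - exp(-t_end * 2 / 1))
  expect_equal(st2$v, v_exact, tolerance = 0.005)
  # equilibrium: no volume change when P_aw equals P_alv
  st3 <- lung_state(pr, open = TRUE, v = 5)
  st4 <- step_mechanics(st3, p_aw = 10, duration = 0.5, dt = 1e-3)
  expect_equal(st4$v, 5, tolerance = 1e-9)
})

test_that("collapsed compartments admit no flow and parallel units add", {
  pr <- compartment_params(k = rep(2, 3), p_ext = 0, top = 30, d_close = 5,
                           r_aw = 1)
  st <- lung_state(pr, open = c(TRUE, TRUE, FALSE))
  st2 <- step_mechanics(st, p_aw = 10, duration = 5, dt = 0.01)
  expect_equal(st2$v[3], 0)
  expect_equal(st2$v[1], st2$v[2])
  # two identical parallel compartments double the compliance of one
  expect_equal(sum(st2$v[1:2]), 2 * st2$v[1])
})

test_that("recruitment requires the TOP to be exceeded for tau_c continuously", {
  pr <- compartment_params(k = 2, p_ext = 0, top = 20, d_close = 12,
                           tau_c = 5)
  st <- lung_state(pr, open = FALSE)
  # held above TOP for 4 s, then dropped: timer resets, still closed
  st <- update_recruitment(st, p_aw = 25, dt = 4)
  expect_false(st$open)
  expect_equal(st$timer, 4)
  st <- update_recruitment(st, p_aw = 15, dt = 1)
  expect_equal(st$timer, 0)
  expect_false(st$open)
  # held for the full 5 s: opens
  st <- update_recruitment(st, p_aw = 25, dt = 5)
  expect_true(st$open)
  expect_equal(st$timer, 0)
  # zero time-constant opens on the same step
  pr0 <- compartment_params(k = 2, p_ext = 0, top = 20, d_close = 12,
                            tau_c = 0)
  st0 <- update_recruitment(lung_state(pr0, open = FALSE), 21, dt = 0.01)
  expect_true(st0$open)
})

test_that("derecruitment is a cliff below the hysteretic closing pressure", {
  pr <- compartment_params(k = 2, p_ext = 0, top = 20, d_close = 12)
  # closing pressure = 8
  st <- lung_state(pr, open = TRUE, v = 3.5)   # P_alv = 7
  st$p_alv <- 7
  expect_false(update_derecruitment(st)$open)
  st$p_alv <- 9
  expect_true(update_derecruitment(st)$open)
  # closing strictly below TOP: a full pressure cycle above TOP and back
  # to above closing leaves the compartment open (hysteresis)
  pr2 <- compartment_params(k = 2, p_ext = 0, top = 20, d_close = 12,
                            tau_c = 0.5)
  st2 <- lung_state(pr2, open = FALSE)
  st2 <- update_recruitment(st2, p_aw = 25, dt = 1)
  expect_true(st2$open)
  st2 <- step_mechanics(st2, p_aw = 10, duration = 5, dt = 0.01)
  st2 <- update_derecruitment(st2)          # P_alv ~ 10 > 8: stays open
  expect_true(st2$open)
})

test_that("dynamic compliance is tidal volume per driving pressure", {
  expect_equal(dynamic_compliance(450, 25, 10), 30)
  expect_equal(dynamic_compliance(0, 25, 10), 0)
  expect_error(dynamic_compliance(450, 10, 10), "positive")
})

test_that("P_peak averages the top 20% of compartment pressure maxima", {
  expect_equal(p_peak_top20(rep(40, 100)), 40)
  expect_equal(p_peak_top20(1:100), mean(81:100))
  expect_equal(p_peak_top20(1:100), 90.5)
  expect_error(p_peak_top20(numeric(0)), "empty")
})

test_that("percent recruited counts open compartments", {
  expect_equal(percent_recruited(rep(TRUE, 10)), 100)
  expect_equal(percent_recruited(c(rep(TRUE, 74), rep(FALSE, 26))), 74)
  expect_equal(percent_recruited(rep(FALSE, 5)), 0)
})

test_that("mass is conserved under explicit integration", {
  pr <- compartment_params(k = runif(10, 1.5, 4), k3 = 1e-4,
                           p_ext = runif(10, 0, 3), top = 1, d_close = 0.9,
                           r_aw = runif(10, 0.5, 2))
  st <- lung_state(pr, open = rep(TRUE, 10))
  dt <- 0.005
  flows <- 0
  p_aw <- 18
  v <- st$v
  for (i in 1:400) {
    p <- alveolar_pressure(v, pr)
    flows <- flows + sum((p_aw - p) / pr$r_aw * dt)
    v <- pmax(v + (p_aw - p) / pr$r_aw * dt, 0)
  }
  st2 <- step_mechanics(st, p_aw, duration = 400 * dt, dt = dt)
  expect_equal(sum(st2$v - st$v), flows, tolerance = 1e-8)
})

test_that("compartment sampling is deterministic and hits the collapsed fraction", {
  h <- list(collapsed_frac = 0.3, top_sd = 8)
  c1 <- build_compartments(h, n = 100, seed = 5)
  c2 <- build_compartments(h, n = 100, seed = 5)
  expect_identical(c1, c2)
  c3 <- build_compartments(h, n = 100, seed = 6)
  expect_false(identical(c1$r_aw, c3$r_aw))
  # collapsed fraction anchored at baseline PEEP + d_close
  d_close <- default_hyper()$d_close
  expect_equal(mean(c1$top > 5 + d_close), 0.3)
})
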