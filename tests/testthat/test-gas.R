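# Gas exchange: perfusion distribution, alveolar balances, shunt, Fick.

metab_a <- metabolic_params(hb = 10.5, co = 11.1, vo2 = 294.3, rq = 0.6,
                            fio2 = 0.8)

test_that("perfusion is uniform for identical compartments and HPV lowers hypoxic flow", {
  q <- distribute_perfusion(rep(1, 10), rep(100, 10), v = rep(5, 10),
                            cd = 0.5, hpv = TRUE)
  expect_equal(q, rep(0.1, 10))
  expect_equal(sum(q), 1)
  # one hypoxic compartment receives strictly less than uniform
  q2 <- distribute_perfusion(rep(1, 10), c(rep(100, 9), 30), hpv = TRUE)
  expect_lt(q2[10], 0.1)
  expect_true(all(q2 > 0))   # collapsed/hypoxic units keep some flow
  # distension shifts flow away from inflated units
  q3 <- distribute_perfusion(rep(1, 10), rep(100, 10),
                             v = c(rep(20, 5), rep(2, 5)), cd = 2)
  expect_true(all(q3[1:5] < q3[6:10]))
  expect_error(distribute_perfusion(rep(Inf, 3), rep(100, 3)))
})

test_that("shunt fraction follows the Berggren equation", {
  expect_equal(shunt_fraction(20, 20, 14), 0)
  expect_equal(shunt_fraction(20, 18, 14), 1 / 3)
  expect_error(shunt_fraction(14, 14, 14), "degenerate")
})

test_that("Fick venous return has the right contents arithmetic", {
  art <- blood_sample(100, 40, 15)
  m0 <- metabolic_params(hb = 15, co = 5, vo2 = 0, rq = 0.8, fio2 = 0.21)
  ven0 <- venous_from_fick(art, m0)
  expect_equal(ven0$o2_content, art$o2_content, tolerance = 1e-6)
  expect_equal(ven0$po2, art$po2, tolerance = 0.2)
  m1 <- metabolic_params(hb = 15, co = 5, vo2 = 250, rq = 0.8, fio2 = 0.21)
  ven1 <- venous_from_fick(art, m1)
  expect_equal(art$o2_content - ven1$o2_content, 5, tolerance = 1e-4)
  expect_equal(ven1$co2_content - art$co2_content, 0.8 * 250 / 50,
               tolerance = 1e-4)
  # a-v O2 content difference implied by the reference moderate patient
  expect_equal(294.3 / (10 * 11.1), 2.65, tolerance = 0.01)
})

test_that("alveolar gas approaches the V/Q limits", {
  ven <- blood_sample(40, 46, 10.5)
  # dead-space limit: huge ventilation, vanishing perfusion
  hi <- compartment_alveolar_gas(va = 1e6, q = 1e-9, ven, metab_a)
  expect_equal(hi$pao2, 0.8 * 713, tolerance = 1)
  expect_lt(hi$paco2, 1)
  # shunt limit: no ventilation
  lo <- compartment_alveolar_gas(va = 0, q = 0.5, ven, metab_a)
  expect_equal(lo$pao2, 40)
  expect_equal(lo$paco2, 46)
})

test_that("a uniform lung reproduces the alveolar gas equation", {
  n <- 40
  comps <- uniform_lung(n)
  metab <- metabolic_params(hb = 14, co = 5.5, vo2 = 250, rq = 0.8,
                            fio2 = 0.21)
  va <- rep(4200 / n, n)
  g <- steady_state_gas(va, comps, v = rep(6, n), metab, cd = 0, hpv = FALSE)
  pao2_eq <- 0.21 * 713 - mean(g$paco2) / 0.8
  expect_equal(mean(g$pao2), pao2_eq, tolerance = 2 / pao2_eq)
  # Fick closure at steady state
  expect_equal(10 * metab$co * (g$arterial$o2_content - g$venous$o2_content),
               250, tolerance = 0.5)
  expect_equal(10 * metab$co * (g$venous$co2_content - g$arterial$co2_content),
               0.8 * 250, tolerance = 0.5)
})

test_that("the measured venous admixture recovers an imposed shunt", {
  n <- 100
  comps <- uniform_lung(n)
  open <- c(rep(TRUE, 70), rep(FALSE, 30))   # 30% of flow through shunt
  va <- ifelse(open, 4000 / 70, 0)
  g <- steady_state_gas(va, comps, v = ifelse(open, 6, 0), metab_a,
                        cd = 0, hpv = FALSE)
  expect_equal(g$qs_qt, 30, tolerance = 0.5)
  # arterial content is bracketed by venous and best end-capillary content
  expect_gt(g$arterial$o2_content, g$venous$o2_content)
  expect_lt(g$arterial$o2_content, max(g$cc_o2) + 1e-9)
})

test_that("opening more compartments never lowers PaO2 (HPV off)", {
  n <- 50
  comps <- uniform_lung(n)
  pao2 <- vapply(c(20, 30, 40, 50), function(n_open) {
    open <- seq_len(n) <= n_open
    va <- ifelse(open, 3500 / n_open, 0)
    steady_state_gas(va, comps, v = ifelse(open, 6, 0), metab_a,
                     cd = 0, hpv = FALSE)$arterial$po2
  }, 0)
  expect_true(all(diff(pao2) > 0))
})
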