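#' Per-compartment gas exchange
#'
#' Alveolar gas tensions are computed compartment by compartment from the
#' steady-state ventilation/perfusion mass balance: oxygen delivered by
#' alveolar ventilation must equal oxygen taken up by end-capillary blood,
#' and likewise for CO2 elimination. End-capillary blood equilibrates with
#' alveolar gas; collapsed (unventilated) compartments pass mixed venous
#' blood through unchanged (true shunt). Perfusion is distributed across
#' compartments in proportion to vascular conductance, modulated by
#' hypoxic pulmonary vasoconstriction (a sigmoid reduction of conductance
#' at low alveolar PO2) and by a distension factor that raises vascular
#' resistance in highly inflated compartments (creating alveolar dead
#' space at high pressure). Arterial blood is the perfusion-weighted
#' mixture of *contents* (never tensions); mixed venous blood follows from
#' the Fick principle at fixed cardiac output.
#'
#' @name gas-exchange
NULL

# conversion constant of the alveolar ventilation equation:
# PACO2 = 0.863 * VCO2(STPD, ml/min) / VA(BTPS, l/min)
.k_vent <- 0.863

#' Metabolic and circulatory constants
#'
#' @param hb Haemoglobin (g/dl).
#' @param co Cardiac output (l/min), held fixed.
#' @param vo2 Oxygen consumption (ml/min STPD).
#' @param rq Respiratory quotient.
#' @param fio2 Inspired O2 fraction.
#' @param temp Body temperature (C).
#' @param pb Barometric pressure (mmHg).
#' @return A `metabolic_params` list.
#' @export
metabolic_params <- function(hb, co, vo2, rq, fio2, temp = 37, pb = 760) {
  stopifnot(hb > 0, co > 0, vo2 >= 0, rq >= 0.5, rq <= 1.1,
            fio2 > 0, fio2 <= 1)
  structure(list(hb = hb, co = co, vo2 = vo2, rq = rq, fio2 = fio2,
                 temp = temp, pb = pb), class = "metabolic_params")
}

# hypoxic pulmonary vasoconstriction: multiplicative conductance factor,
# half-effect at 40 mmHg alveolar PO2, floor 0.3
hpv_factor <- function(pao2, half = 40, slope = 8, floor = 0.3) {
  floor + (1 - floor) * stats::plogis((pao2 - half) / slope)
}

#' Distribute perfusion over compartments
#'
#' Blood-flow fractions proportional to vascular conductance `1/r_vasc`,
#' scaled by the HPV factor (less flow to hypoxic compartments) and a
#' distension factor `1/(1 + cd (V/Vs)^2)` (less flow to highly inflated
#' compartments), then renormalised to sum to one. Collapsed compartments
#' keep nonzero perfusion: that flow is true shunt.
#'
#' @param r_vasc Per-compartment relative vascular resistances.
#' @param pao2_alv Per-compartment alveolar PO2 (mmHg) for the HPV term
#'   (mixed venous PO2 for collapsed compartments).
#' @param v Per-compartment volumes (ml) for the distension term.
#' @param cd Distension coefficient (dimensionless), default 0.
#' @param hpv Logical; apply hypoxic vasoconstriction.
#' @param v_scale Volume scale of the distension term (ml).
#' @return Vector of flow fractions summing to 1.
#' @export
distribute_perfusion <- function(r_vasc, pao2_alv, v = 0, cd = 0,
                                 hpv = TRUE, v_scale = 24) {
  w <- 1 / r_vasc
  if (hpv) w <- w * hpv_factor(pao2_alv)
  w <- w / (1 + cd * (v / v_scale)^2)
  if (all(w <= 0)) stop("all vascular conductances are zero")
  w / sum(w)
}

#' Berggren shunt fraction (venous admixture)
#'
#' @param cc End-capillary O2 content (ml/dl).
#' @param ca Arterial O2 content (ml/dl).
#' @param cv Mixed venous O2 content (ml/dl).
#' @return Qs/Qt as a fraction.
#' @export
shunt_fraction <- function(cc, ca, cv) {
  if (cc - cv <= 1e-9) stop("degenerate shunt denominator (Cc'O2 <= CvO2)")
  (cc - ca) / (cc - cv)
}

#' Mixed venous blood from the Fick principle
#'
#' At fixed cardiac output, venous O2 content is arterial content minus
#' `VO2/(10 CO)` and venous CO2 content is arterial plus
#' `RQ VO2/(10 CO)` (contents in ml/dl, CO in l/min). Tensions are
#' recovered by inverting the content relations.
#'
#' @param arterial A [blood_sample()].
#' @param metab A [metabolic_params()].
#' @return A `blood_sample` for mixed venous blood. If the implied venous
#'   O2 content is not positive the state is non-physical and an error is
#'   raised.
#' @export
venous_from_fick <- function(arterial, metab) {
  cv_o2 <- arterial$o2_content - metab$vo2 / (10 * metab$co)
  cv_co2 <- arterial$co2_content + metab$rq * metab$vo2 / (10 * metab$co)
  if (cv_o2 <= 0) stop("non-physical state: venous O2 content <= 0")
  tensions_from_contents(cv_o2, cv_co2, metab$hb)
}

# recover (po2, pco2) from a content pair by alternating inversions
# (the CO2 inversion needs SO2 for the Haldane term, the O2 inversion
# needs PCO2 for the Bohr term; two rounds suffice to < 0.05 mmHg)
tensions_from_contents <- function(c_o2, c_co2, hb) {
  pco2 <- 45; po2 <- 50
  for (i in 1:2) {
    po2 <- po2_from_content(c_o2, hb, pco2 = pco2)
    so2 <- o2_saturation(po2, pco2, ph_from_pco2(pco2))
    pco2 <- pco2_from_content(c_co2, so2, hb)
  }
  blood_sample(po2, pco2, hb)
}

#' Alveolar gas tensions from the V/Q mass balance
#'
#' Solves, for each compartment, the coupled steady-state balances
#' \deqn{\dot{V}_A (P_IO_2 - P_AO_2)/863 = 10\,\dot{Q}\,(Cc'O_2(P_AO_2) - CvO_2)}
#' \deqn{\dot{V}_A P_ACO_2/863 = 10\,\dot{Q}\,(CvCO_2 - Cc'CO_2(P_ACO_2))}
#' by vectorised bisection (both sides are monotone, so the roots are
#' unique). Compartments with zero ventilation take mixed venous
#' tensions; compartments with vanishing perfusion approach inspired gas.
#'
#' @param va Per-compartment alveolar ventilation (ml/min BTPS).
#' @param q Per-compartment blood flow fractions (of cardiac output).
#' @param venous Mixed venous [blood_sample()].
#' @param metab A [metabolic_params()].
#' @param so2_guess Saturation used in the Haldane term of the CO2
#'   balance (refined by the outer steady-state loop).
#' @return List with vectors `pao2`, `paco2`, `cc_o2`, `cc_co2`.
#' @export
compartment_alveolar_gas <- function(va, q, venous, metab, so2_guess = 0.97) {
  stopifnot(all(va >= 0), all(q >= 0))
  n <- max(length(va), length(q))
  va <- rep_len(va, n); q <- rep_len(q, n)
  hb <- metab$hb
  pio2 <- metab$fio2 * (metab$pb - 47)
  qml <- 10 * q * metab$co                       # dl-content scale, ml/min per unit content
  vent <- va > 1e-9

  # CO2 balance first (depends on O2 only through the Haldane term)
  lo <- rep(1e-3, n); hi <- rep(max(venous$pco2, 1) * 1.5 + 20, n)
  for (i in 1:22) {
    m <- 0.5 * (lo + hi)
    g <- (va / 1000) * m / .k_vent -
      qml * (venous$co2_content - co2_content(m, so2_guess, hb))
    hi <- ifelse(g > 0, m, hi)
    lo <- ifelse(g > 0, lo, m)
  }
  paco2 <- ifelse(vent, 0.5 * (lo + hi), venous$pco2)

  # O2 balance with the Bohr shift from the compartment's own PACO2
  ph <- ph_from_pco2(paco2)
  lo <- rep(0.5, n); hi <- rep(pio2, n)
  for (i in 1:22) {
    m <- 0.5 * (lo + hi)
    cc <- o2_content(m, o2_saturation(m, paco2, ph), hb)
    g <- (va / 1000) * (pio2 - m) / .k_vent - qml * (cc - venous$o2_content)
    lo <- ifelse(g > 0, m, lo)
    hi <- ifelse(g > 0, hi, m)
  }
  pao2 <- ifelse(vent, 0.5 * (lo + hi), venous$po2)

  so2 <- o2_saturation(pao2, paco2, ph_from_pco2(paco2))
  list(pao2 = pao2, paco2 = paco2,
       cc_o2 = ifelse(vent, o2_content(pao2, so2, hb), venous$o2_content),
       cc_co2 = ifelse(vent, co2_content(paco2, so2, hb), venous$co2_content))
}

#' Mix compartment effluents into arterial blood
#'
#' Arterial contents are the perfusion-weighted mixture of end-capillary
#' contents (collapsed compartments contribute venous content); arterial
#' tensions are recovered by inverting the content relations.
#'
#' @param cc_o2,cc_co2 Per-compartment end-capillary contents (ml/dl).
#' @param q Flow fractions.
#' @param hb Haemoglobin (g/dl).
#' @return Arterial `blood_sample`.
#' @export
mix_arterial <- function(cc_o2, cc_co2, q, hb) {
  tensions_from_contents(sum(q * cc_o2), sum(q * cc_co2), hb)
}

#' Steady-state whole-body gas exchange
#'
#' Iterates alveolar gas, perfusion distribution, arterial mixing and the
#' Fick venous return to a damped fixed point, at fixed per-compartment
#' ventilation. This is the quasi-steady computation performed once per
#' breath by the simulation engine (with a venous mixing delay) and run
#' to convergence for calibration.
#'
#' @param va Per-compartment alveolar ventilation (ml/min BTPS); zero for
#'   collapsed compartments.
#' @param comps `compartment_params` table (for `r_vasc`).
#' @param v Per-compartment volumes (ml) for the distension term.
#' @param metab [metabolic_params()].
#' @param cd Distension coefficient.
#' @param hpv Apply hypoxic vasoconstriction.
#' @param init Optional list with starting `venous` sample and `pao2`.
#' @param tol Convergence tolerance on venous contents (ml/dl).
#' @param max_iter Iteration cap.
#' @return List: `arterial`, `venous` (blood samples), `pao2`, `paco2`,
#'   `q`, `qs_qt` (Berggren venous admixture, %), `cc_o2`, `cc_co2`.
#' @export
steady_state_gas <- function(va, comps, v, metab, cd = 0, hpv = TRUE,
                             init = NULL, tol = 1e-3, max_iter = 80) {
  n <- nrow(comps)
  va <- rep_len(va, n); v <- rep_len(v, n)
  hb <- metab$hb
  # working venous state: contents drive the balances; tensions are only
  # refreshed approximately inside the loop and precisely at the end
  ven <- if (!is.null(init$venous)) init$venous else blood_sample(40, 46, hb)
  cv_o2 <- ven$o2_content; cv_co2 <- ven$co2_content
  pvo2 <- ven$po2; pvco2 <- ven$pco2
  pio2 <- metab$fio2 * (metab$pb - 47)
  pao2 <- if (!is.null(init$pao2)) init$pao2 else
    ifelse(va > 0, pio2, pvo2)
  so2g <- 0.95
  r_co2_prev <- r_co2_prev2 <- Inf
  for (it in seq_len(max_iter)) {
    q <- distribute_perfusion(comps$r_vasc, pao2, v, cd = cd, hpv = hpv)
    vlite <- list(po2 = pvo2, pco2 = pvco2,
                  o2_content = cv_o2, co2_content = cv_co2)
    gas <- compartment_alveolar_gas(va, q, vlite, metab, so2_guess = so2g)
    pao2 <- gas$pao2
    ca_o2 <- sum(q * gas$cc_o2); ca_co2 <- sum(q * gas$cc_co2)
    t_o2 <- ca_o2 - metab$vo2 / (10 * metab$co)
    t_co2 <- ca_co2 + metab$rq * metab$vo2 / (10 * metab$co)
    if (t_o2 <= 0) stop("non-physical state: venous O2 content <= 0")
    r_o2 <- t_o2 - cv_o2; r_co2 <- t_co2 - cv_co2
    d <- max(abs(r_o2), abs(r_co2))
    # the plain iteration contracts slowly for CO2 (flow-dominated
    # elimination): extrapolate its geometric residual series once the
    # ratio of three consecutive same-sign residuals is stable. The O2
    # channel is never extrapolated -- it couples to the steep part of
    # the HPV sigmoid and overshooting it oscillates.
    rho1 <- r_co2 / r_co2_prev; rho2 <- r_co2_prev / r_co2_prev2
    g_co2 <- if (it > 2 && is.finite(rho1) && is.finite(rho2) &&
                 rho1 > 0 && rho2 > 0 && rho1 < 0.97 &&
                 abs(rho1 - rho2) < 0.1)
      1 / (1 - min(rho1, 0.9)) else 1
    cv_o2 <- cv_o2 + r_o2
    cv_co2 <- cv_co2 + g_co2 * r_co2
    r_co2_prev2 <- r_co2_prev; r_co2_prev <- r_co2
    # cheap venous tension estimates for HPV / collapsed compartments
    pvo2 <- po2_from_content(cv_o2, hb, pco2 = pvco2)
    pvco2 <- pco2_from_content(cv_co2, o2_saturation(pvo2, pvco2), hb)
    vent_i <- va > 1e-9
    if (any(vent_i)) so2g <- mean(o2_saturation(gas$pao2[vent_i], gas$paco2[vent_i]))
    if (d < tol) break
  }
  arterial <- tensions_from_contents(ca_o2, ca_co2, hb)
  venous <- tensions_from_contents(cv_o2, cv_co2, hb)
  vent <- va > 1e-9
  cc_ideal <- sum(va[vent] * gas$cc_o2[vent]) / sum(va[vent])
  qs <- shunt_fraction(cc_ideal, arterial$o2_content, venous$o2_content)
  list(arterial = arterial, venous = venous, pao2 = gas$pao2,
       paco2 = gas$paco2, q = q, qs_qt = 100 * qs,
       cc_o2 = gas$cc_o2, cc_co2 = gas$cc_co2, iterations = it)
}
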