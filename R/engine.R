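#' Breath-by-breath simulation engine
#'
#' Orchestrates a virtual patient under a ventilation protocol. Within
#' each breath the square-wave airway pressure drives every open
#' compartment toward its phase equilibrium volume; because each
#' compartment is a first-order (resistance-compliance) element under a
#' piecewise-constant pressure, the engine integrates each phase with an
#' exponential update linearised at the phase equilibrium, which is exact
#' for the linear part of the pressure-volume law (explicit sub-stepped
#' integration is available separately via [step_mechanics()]).
#' Recruitment timers accumulate whenever the airway pressure exceeds a
#' collapsed compartment's TOP and reset when it does not; derecruitment
#' is evaluated once per breath at end-expiration. Gas exchange is
#' recomputed quasi-statically every breath, with the mixed venous pool
#' relaxing toward its Fick steady state with a configurable mixing time
#' constant, so that minute-scale PaO2/PaCO2 transients are resolved.
#' During CPAP (sustained inflation) segments there are no tidal breaths:
#' alveolar O2 is depleted and CO2 accumulates from per-compartment
#' stores under continuing perfusion.
#'
#' @name simulation-engine
NULL

# per-compartment resident gas volume (ml) behind the tidal excursion,
# used for alveolar store dynamics during breath-free CPAP holds
.v_store <- 15

# relax volumes toward the equilibrium for a constant airway pressure
# phase; exact for a linear PV law, locally linearised for the cubic term
phase_relax <- function(v, open, p_aw, dur, k, k3, pe, raw, rvc = 0) {
  veq <- pmax((p_aw - pe) / k, 0)
  if (any(k3 > 0)) {
    for (i in 1:20) {
      f <- pe + k * veq + k3 * veq^3 - p_aw
      veq <- pmax(veq - f / (k + 3 * k3 * veq^2), 0)
    }
  }
  keff <- k + 3 * k3 * veq^2
  raw_eff <- raw * (1 + rvc * (v / 24)^2)
  vnew <- veq + (v - veq) * exp(-dur * keff / raw_eff)
  ifelse(open, vnew, v)
}

# cycle-steady end-expiratory/end-inspiratory volumes under fixed
# settings: fixed point of the two-phase exponential map
cycle_volumes <- function(comps, open, peep, dp, ti, te, n_iter = 6) {
  k <- comps$k; k3 <- comps$k3; pe <- comps$p_ext; raw <- comps$r_aw
  rvc <- comps$raw_vol_coef
  v <- pmax((peep - pe) / k, 0) * open
  for (i in seq_len(n_iter)) {
    v_ei <- phase_relax(v, open, peep + dp, ti, k, k3, pe, raw, rvc)
    v <- phase_relax(v_ei, open, peep, te, k, k3, pe, raw, rvc)
  }
  list(v_ee = v, v_ei = v_ei)
}

# alveolar ventilation split: total fresh-gas alveolar ventilation after
# the shared series dead space, distributed in proportion to tidal volume
split_ventilation <- function(vt_i, vr, dead_space) {
  vt <- sum(vt_i)
  va_tot <- max(vr * (vt - dead_space), 0)
  if (vt <= 0) return(rep(0, length(vt_i)))
  va_tot * vt_i / vt
}

#' Whole-patient steady state at fixed ventilator settings
#'
#' Computes the cycle-steady mechanics and converged gas exchange of a
#' patient ventilated indefinitely at one set of pressure-controlled
#' settings, with the open compartment set taken as the compartments
#' maintainable at the given PEEP (closing pressure at or below PEEP)
#' plus those openable within a breath. This is the evaluator used by the
#' static calibration objective and for initialising protocol runs.
#'
#' @param patient An `ards_patient`.
#' @param peep PEEP (cm H2O).
#' @param dp Driving pressure (cm H2O).
#' @param hpv Apply hypoxic vasoconstriction.
#' @param init Optional warm-start list for the gas fixed point.
#' @return List: blood gases (`pao2`, `paco2`, `pvo2`, `pvco2`),
#'   `qs_qt` (%), `pf_ratio` (mmHg), `vt` (ml), `cdyn` (ml/mbar),
#'   `pct_open` (%), `open`, plus the full `gas` solution.
#' @export
patient_steady_state <- function(patient, peep, dp, hpv = TRUE, init = NULL) {
  comps <- patient$comps
  ie <- patient$vent$ie; vr <- patient$vent$vr
  cycle <- 60 / vr; ti <- ie * cycle; te <- cycle - ti
  # maintainable at this PEEP, or already open at the calibration
  # baseline; plus units whose TOP is cleared long enough within a breath
  closing <- pmax(comps$top - comps$d_close, 0)
  open <- closing <= peep &
    (comps$top <= .peep_baseline + comps$d_close |
       comps$top < peep + dp & (comps$top <= peep | comps$tau_c <= ti))
  cyc <- cycle_volumes(comps, open, peep, dp, ti, te)
  vt_i <- cyc$v_ei - cyc$v_ee
  va <- split_ventilation(vt_i, vr, patient$dead_space)
  metab <- metabolic_params(patient$metabolic$hb, patient$metabolic$co,
                            patient$metabolic$vo2, patient$metabolic$rq,
                            patient$metabolic$fio2, patient$metabolic$temp,
                            patient$metabolic$pb)
  v_mean <- cyc$v_ee + vt_i / 2
  gas <- steady_state_gas(va, comps, v_mean, metab,
                          cd = patient$hyper$cd, hpv = hpv, init = init)
  vt <- sum(vt_i)
  list(pao2 = gas$arterial$po2, paco2 = gas$arterial$pco2,
       pvo2 = gas$venous$po2, pvco2 = gas$venous$pco2,
       qs_qt = gas$qs_qt, pf_ratio = gas$arterial$po2 / metab$fio2,
       vt = vt, cdyn = vt / dp, pct_open = 100 * mean(open),
       open = open, gas = gas, v_ee = cyc$v_ee, v_ei = cyc$v_ei)
}

#' Run a ventilation protocol on a virtual patient
#'
#' Simulates the patient breath by breath (or in 1-second slices during
#' CPAP holds) through every protocol segment, starting from the
#' calibration-baseline recruitment state and the steady state of the
#' first segment. Deterministic: the patient's compartments are fixed at
#' construction and the engine adds no randomness.
#'
#' @param patient An `ards_patient`.
#' @param protocol An `ards_protocol`.
#' @param hpv Apply hypoxic vasoconstriction.
#' @param tau_venous Mixed venous pool mixing time constant (s).
#' @return An `ards_sim` object: breath-indexed series (`$series` data
#'   frame with time, blood gases, PaO2/FiO2, tidal volume, dynamic
#'   compliance, percent recruited), per-compartment pressure maxima
#'   (`$max_p`), and maneuver metrics `$p_peak`, `$delta_po2`,
#'   `$baseline_pf`.
#' @export
run_protocol <- function(patient, protocol, hpv = TRUE, tau_venous = 30) {
  comps <- patient$comps
  n <- nrow(comps)
  k <- comps$k; k3 <- comps$k3; pe <- comps$p_ext; raw <- comps$r_aw
  rvc <- comps$raw_vol_coef
  top <- comps$top; tau <- comps$tau_c
  closing <- pmax(comps$top - comps$d_close, 0)
  hb <- patient$metabolic$hb
  metab <- metabolic_params(hb, patient$metabolic$co, patient$metabolic$vo2,
                            patient$metabolic$rq, patient$metabolic$fio2,
                            patient$metabolic$temp, patient$metabolic$pb)
  cd <- patient$hyper$cd
  pio2 <- metab$fio2 * (metab$pb - 47)

  # initial recruitment state: what the calibration baseline maintains
  open <- top <= .peep_baseline + comps$d_close
  timer <- rep(0, n)
  seg1 <- protocol$segments[[1]]$settings
  ss <- patient_steady_state(patient, seg1$peep,
                             if (seg1$mode == "cpap") 0 else seg1$dp,
                             hpv = hpv)
  cv_o2 <- ss$gas$venous$o2_content; cv_co2 <- ss$gas$venous$co2_content
  pvo2 <- ss$gas$venous$po2; pvco2 <- ss$gas$venous$pco2
  pao2_alv <- ss$gas$pao2; paco2_alv <- ss$gas$paco2
  pa_po2 <- ss$gas$arterial$po2; pa_pco2 <- ss$gas$arterial$pco2
  so2g <- 0.95
  v <- ss$v_ee
  max_p <- ifelse(open, pe + k * v + k3 * v^3, pe)

  n_slices <- sum(vapply(protocol$segments, function(s)
    if (s$settings$mode == "cpap") ceiling(s$duration)
    else max(1, round(s$duration * s$settings$vr / 60)), 0))
  rec <- matrix(NA_real_, nrow = n_slices, ncol = 12)
  colnames(rec) <- c("time_s", "peep", "p_insp", "pao2", "paco2", "pf_ratio",
                     "pvo2", "pvco2", "sao2", "qs_qt", "vt", "pct_open")
  stage <- character(n_slices)
  row <- 0L; t_now <- 0
  prev_key <- c(NA, NA); mech_ok <- FALSE
  v_ei <- v; p_ee <- ifelse(open, pe + k * v + k3 * v^3, pe); vt_i <- rep(0, n)

  fick_o2 <- metab$vo2 / (10 * metab$co)
  fick_co2 <- metab$rq * metab$vo2 / (10 * metab$co)

  gas_breath <- function(va, v_mean, dt_s) {
    q <- distribute_perfusion(comps$r_vasc, pao2_alv, v_mean, cd = cd, hpv = hpv)
    vlite <- list(po2 = pvo2, pco2 = pvco2,
                  o2_content = cv_o2, co2_content = cv_co2)
    gas <- compartment_alveolar_gas(va, q, vlite, metab, so2_guess = so2g)
    pao2_alv <<- gas$pao2; paco2_alv <<- gas$paco2
    ca_o2 <- sum(q * gas$cc_o2); ca_co2 <- sum(q * gas$cc_co2)
    finish_gas(ca_o2, ca_co2, va, gas$pao2, gas$paco2, dt_s)
  }

  finish_gas <- function(ca_o2, ca_co2, va, p_o2, p_co2, dt_s) {
    t_o2 <- ca_o2 - fick_o2; t_co2 <- ca_co2 + fick_co2
    if (t_o2 <= 0)
      stop("non-physical state at t = ", round(t_now, 1),
           " s: venous O2 content <= 0 (patient desaturating beyond model validity)")
    rel <- 1 - exp(-dt_s / tau_venous)
    cv_o2 <<- cv_o2 + rel * (t_o2 - cv_o2)
    cv_co2 <<- cv_co2 + rel * (t_co2 - cv_co2)
    pvo2 <<- po2_from_content(cv_o2, hb, pco2 = pvco2)
    pvco2 <<- pco2_from_content(cv_co2, o2_saturation(pvo2, pvco2), hb)
    pa_po2 <<- po2_from_content(ca_o2, hb, pco2 = pa_pco2)
    sa <- o2_saturation(pa_po2, pa_pco2)
    pa_pco2 <<- pco2_from_content(ca_co2, sa, hb)
    vent_i <- va > 1e-9
    if (any(vent_i)) so2g <<- mean(o2_saturation(p_o2[vent_i], p_co2[vent_i]))
    sa
  }

  for (si in seq_along(protocol$segments)) {
    seg <- protocol$segments[[si]]
    st <- seg$settings

    if (st$mode == "cpap") {
      p_hold <- st$peep
      n_sl <- ceiling(seg$duration)
      for (sl in seq_len(n_sl)) {
        dt_s <- min(1, seg$duration - (sl - 1))
        r <- recruit_tick(timer, open, top, tau, p_hold, dt_s)
        timer <- r$timer
        if (any(r$opened)) {
          open <- r$open
          pao2_alv[r$opened] <- pio2
          paco2_alv[r$opened] <- 5
        }
        v <- phase_relax(v, open, p_hold, dt_s, k, k3, pe, raw, rvc)
        p_alv <- ifelse(open, pe + k * v + k3 * v^3, pe)
        max_p <- pmax(max_p, p_alv)
        # alveolar store depletion under ongoing perfusion (no breaths)
        q <- distribute_perfusion(comps$r_vasc, pao2_alv, v, cd = cd, hpv = hpv)
        ph_alv <- ph_from_pco2(paco2_alv)
        so2_alv <- o2_saturation(pao2_alv, paco2_alv, ph_alv)
        cc_o2 <- ifelse(open, o2_content(pao2_alv, so2_alv, hb), cv_o2)
        cc_co2 <- ifelse(open, co2_content(paco2_alv, so2_alv, hb), cv_co2)
        upt_o2 <- 10 * q * metab$co * (cc_o2 - cv_o2) / 1000   # l/min STPD
        upt_co2 <- 10 * q * metab$co * (cv_co2 - cc_co2) / 1000
        vs_l <- (v + .v_store) / 1000
        pao2_alv <- ifelse(open,
          pmax(pao2_alv - .k_vent * 1000 * upt_o2 / vs_l * dt_s / 60, 1), pvo2)
        paco2_alv <- ifelse(open,
          pmin(paco2_alv + .k_vent * 1000 * upt_co2 / vs_l * dt_s / 60, pvco2 + 30),
          pvco2)
        ca_o2 <- sum(q * cc_o2); ca_co2 <- sum(q * cc_co2)
        sa <- finish_gas(ca_o2, ca_co2, rep(0, n), pao2_alv, paco2_alv, dt_s)
        t_now <- t_now + dt_s
        row <- row + 1L
        rec[row, ] <- c(t_now, p_hold, p_hold, pa_po2, pa_pco2,
                        pa_po2 / metab$fio2, pvo2, pvco2, sa, NA, 0,
                        100 * mean(open))
        stage[row] <- seg$stage
      }
      mech_ok <- FALSE
      next
    }

    cycle <- 60 / st$vr
    ti <- st$ie * cycle; te <- cycle - ti
    p_pk <- st$peep + st$dp
    n_br <- max(1L, as.integer(round(seg$duration * st$vr / 60)))
    for (br in seq_len(n_br)) {
      r <- recruit_tick(timer, open, top, tau, p_pk, ti)
      timer <- r$timer
      events <- any(r$opened)
      just_opened <- r$opened
      open <- r$open
      key <- c(st$peep, st$dp)
      if (!events && mech_ok && identical(key, prev_key)) {
        # cycle-steady: reuse cached volumes; pressures repeat
        max_p <- pmax(max_p, ifelse(open, p_ei_cache, pe))
      } else {
        v_ei <- phase_relax(v, open, p_pk, ti, k, k3, pe, raw, rvc)
        p_ei_cache <- pe + k * v_ei + k3 * v_ei^3
        max_p <- pmax(max_p, ifelse(open, p_ei_cache, pe))
        v_new <- phase_relax(v_ei, open, st$peep, te, k, k3, pe, raw, rvc)
        mech_ok <- max(abs(v_new - v)) < 1e-5
        v <- v_new
        vt_i <- pmax(v_ei - v, 0) * open
        p_ee <- ifelse(open, pe + k * v + k3 * v^3, pe)
      }
      prev_key <- key
      # expiratory-phase recruitment bookkeeping (PEEP above TOP counts)
      r <- recruit_tick(timer, open, top, tau, st$peep, te)
      timer <- r$timer
      if (any(r$opened)) {
        open <- r$open
        just_opened <- just_opened | r$opened
        events <- TRUE
      }
      # cliff-edge derecruitment at end-expiration; compartments that
      # opened within this breath have not completed an expiration yet
      # and are exempt until they fill
      fall <- open & !just_opened & (p_ee < closing)
      if (any(fall)) {
        open[fall] <- FALSE
        v[fall] <- 0
        vt_i[fall] <- 0
        events <- TRUE
      }
      if (events) mech_ok <- FALSE
      va <- split_ventilation(vt_i, st$vr, patient$dead_space)
      sa <- gas_breath(va, v + vt_i / 2, cycle)
      t_now <- t_now + cycle
      row <- row + 1L
      rec[row, ] <- c(t_now, st$peep, p_pk, pa_po2, pa_pco2,
                      pa_po2 / st$fio2, pvo2, pvco2, sa, NA,
                      sum(vt_i), 100 * mean(open))
      stage[row] <- seg$stage
    }
  }

  series <- as.data.frame(rec[seq_len(row), , drop = FALSE])
  series$stage <- stage[seq_len(row)]
  series$cdyn <- ifelse(series$p_insp > series$peep,
                        series$vt / (series$p_insp - series$peep), NA)
  pre <- series$stage == "pre"
  baseline_pf <- if (any(pre)) {
    t_end <- max(series$time_s[pre])
    mean(series$pf_ratio[pre & series$time_s > t_end - 60])
  } else NA_real_
  structure(list(
    series = series, max_p = max_p, open = open,
    patient = patient$label, protocol = protocol$label,
    baseline_pf = baseline_pf,
    delta_po2 = max(series$pf_ratio) - baseline_pf,
    p_peak = p_peak_top20(max_p),
    final_pct_open = series$pct_open[row],
    final_pf = series$pf_ratio[row]
  ), class = "ards_sim")
}

#' @export
print.ards_sim <- function(x, ...) {
  cat(sprintf("ards_sim: patient %s under %s (%.1f min)\n",
              x$patient, x$protocol, max(x$series$time_s) / 60))
  cat(sprintf("  baseline PaO2/FiO2 %.1f mmHg, max %.1f, final %.1f\n",
              x$baseline_pf, max(x$series$pf_ratio), x$final_pf))
  cat(sprintf("  dPO2 %.1f mmHg, P_peak %.2f cm H2O, final recruitment %.0f%%\n",
              x$delta_po2, x$p_peak, x$final_pct_open))
  invisible(x)
}
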