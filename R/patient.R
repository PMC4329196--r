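#' Virtual ARDS patients
#'
#' A virtual patient couples a sampled 100-compartment parameter table to
#' whole-body metabolic/circulatory constants (haemoglobin, fixed cardiac
#' output, oxygen consumption, respiratory quotient) and default ventilator
#' settings. Per-compartment heterogeneity is described by a small set of
#' distribution hyper-parameters rather than 100 free values: threshold
#' opening pressures follow a truncated Gaussian whose mean is solved so
#' that the fraction of compartments with TOP above the baseline peak
#' airway pressure (20 cm H2O: PEEP 5 + driving pressure 15) equals the
#' patient's collapsed fraction; stiffness, extrinsic pressure and
#' resistances are sampled around their means with fixed relative spreads;
#' opening time-constants are log-normal. Sampling is quantile-stratified
#' under a fixed seed, so a given hyper-parameter vector always produces
#' the same lung and the collapsed percentage is exact.
#'
#' @name virtual-patient
NULL

# calibration-baseline PEEP (cm H2O): the TOP distribution is anchored so
# that the set of compartments maintainable at this PEEP (those with
# closing pressure TOP - d_close at or below it) has exactly the fitted
# open fraction; patients arrive at the baseline ventilated at PEEP 5
.peep_baseline <- 5
# volume scale (ml) of the cubic stiffening term: k3 = k/(3 * v_s^2),
# giving an effective stiffness k * (1 + (V/v_s)^2); v_s chosen so that
# dynamic compliance falls from about 30 to the low twenties (ml/mbar)
# over a PEEP staircase to 40-45 cm H2O, the decline a recruitable ARDS
# lung shows when driven to those pressures
.v_stiff <- 18

# truncated-normal quantile
qtnorm <- function(p, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + p * (phi - plo), mean, sd)
}

# mean of a [0,60]-truncated Gaussian TOP distribution such that
# P(TOP > p_ref) = frac
top_mean_for_fraction <- function(frac, sd, p_ref = 20) {
  stopifnot(frac > 0, frac < 1)
  f <- function(m) {
    plo <- stats::pnorm(0, m, sd); phi <- stats::pnorm(60, m, sd)
    (phi - stats::pnorm(p_ref, m, sd)) / (phi - plo) - frac
  }
  stats::uniroot(f, c(-40, 59), tol = 1e-10)$root
}

#' Default heterogeneity hyper-parameters
#'
#' @return Named list of hyper-parameters with documented defaults:
#'   `collapsed_frac` (fraction of compartments collapsed at baseline),
#'   `top_sd` (cm H2O), `k_mean` (cm H2O/ml), `pext_mean` (cm H2O),
#'   `raw_mean` (cm H2O s/ml), `cd` (vascular distension coefficient),
#'   `tau_logmean`/`tau_logsd` (log seconds) and `d_close` (cm H2O).
#' @export
default_hyper <- function() {
  list(collapsed_frac = 0.25, top_sd = 8, k_mean = 2.5,
       pext_mean = 2, raw_mean = 1, cd = 0.8, q_grad = 0.5,
       tau_logmean = log(30), tau_logsd = 1.0, d_close = 15)
}

#' Bounds for the fitted hyper- and patient parameters
#'
#' Physiological box constraints used by the calibration routines.
#'
#' @return Data frame with columns `lower`, `upper`, row names the
#'   parameter names.
#' @export
hyper_bounds <- function() {
  b <- rbind(
    vr             = c(8, 25),
    ie             = c(0.2, 0.5),
    rq             = c(0.5, 1.1),
    vo2            = c(120, 420),
    collapsed_frac = c(0.02, 0.6),
    top_sd         = c(6, 10),
    k_mean         = c(1.2, 8),
    pext_mean      = c(0, 5),
    raw_mean       = c(0.4, 3),
    cd             = c(0, 4),
    q_grad         = c(0, 2),
    tau_logmean    = c(log(1), log(300)),
    tau_logsd      = c(0.3, 1.5),
    d_close        = c(10, 18)
  )
  data.frame(lower = b[, 1], upper = b[, 2])
}

#' Sample a compartment parameter table from hyper-parameters
#'
#' Quantile-stratified draws: each marginal uses the N mid-point
#' probabilities (i - 0.5)/N run through the relevant quantile function,
#' then seeded permutations decorrelate the marginals. Deterministic for a
#' given (hyper, n, seed).
#'
#' @param hyper Hyper-parameter list, see [default_hyper()].
#' @param n Number of compartments, default 100.
#' @param seed Integer seed controlling the pairing permutations.
#' @return A `compartment_params` table.
#' @export
build_compartments <- function(hyper, n = 100, seed = 1L) {
  h <- utils::modifyList(default_hyper(), hyper)
  p <- (seq_len(n) - 0.5) / n
  top_mean <- top_mean_for_fraction(h$collapsed_frac, h$top_sd,
                                    p_ref = .peep_baseline + h$d_close)
  top <- qtnorm(p, top_mean, h$top_sd, 0, 60)
  set.seed(seed)
  k <- qtnorm(p, h$k_mean, 0.25 * h$k_mean, 0.3 * h$k_mean, 3 * h$k_mean)[sample.int(n)]
  pext <- qtnorm(p, h$pext_mean, 1, -3, 8)[sample.int(n)]
  raw <- stats::qlnorm(p, log(h$raw_mean), 0.3)[sample.int(n)]
  # vascular resistance: log-normal scatter with a conductance gradient
  # toward high-TOP (dependent, atelectasis-prone) regions, which in ARDS
  # receive a disproportionate share of pulmonary blood flow
  z_top <- (top - mean(top)) / stats::sd(top)
  rvasc <- stats::qlnorm(p, 0, 0.4)[sample.int(n)] * exp(-h$q_grad * z_top)
  tau <- stats::qlnorm(p, h$tau_logmean, h$tau_logsd)[sample.int(n)]
  # stiffening volume scale refers to the standard 100-compartment lung;
  # rescale for other n so the dimensionless stiffening is unchanged
  v_s <- .v_stiff * 100 / n
  compartment_params(k = k, k3 = k / (3 * v_s^2), p_ext = pext,
                     top = top, d_close = h$d_close, r_aw = raw,
                     r_vasc = rvasc, tau_c = tau)
}

#' Construct a virtual patient
#'
#' @param hyper Hyper-parameter list (see [default_hyper()]); entries
#'   missing from the list take defaults.
#' @param metabolic List with `hb` (g/dl), `co` (l/min), `vo2` (ml/min),
#'   `rq`, `fio2`, and optionally `temp` (C) and `pb` (mmHg).
#' @param vent List with `vr` (breaths/min), `ie` (inspiratory fraction
#'   of the cycle, I/(I+E)) and `fio2`.
#' @param label Patient label.
#' @param n Number of compartments.
#' @param seed Sampling seed.
#' @param dead_space Series dead space (ml).
#' @return An object of class `ards_patient`.
#' @export
virtual_patient <- function(hyper, metabolic, vent, label = "custom",
                            n = 100, seed = 1L, dead_space = 150) {
  metabolic <- utils::modifyList(list(temp = 37, pb = 760), metabolic)
  stopifnot(metabolic$hb > 0, metabolic$co > 0, metabolic$vo2 > 0,
            metabolic$rq >= 0.5, metabolic$rq <= 1.1,
            metabolic$fio2 > 0, metabolic$fio2 <= 1,
            vent$vr > 0, vent$ie > 0, vent$ie < 1)
  comps <- build_compartments(hyper, n = n, seed = seed)
  structure(list(label = label, hyper = utils::modifyList(default_hyper(), hyper),
                 metabolic = metabolic, vent = vent, comps = comps,
                 n = n, seed = seed, dead_space = dead_space),
            class = "ards_patient")
}

#' @export
print.ards_patient <- function(x, ...) {
  cat(sprintf("ards_patient '%s': %d compartments, %.0f%% collapsed at baseline\n",
              x$label, x$n, 100 * x$hyper$collapsed_frac))
  cat(sprintf("  Hb %.1f g/dl, CO %.1f l/min, VO2 %.1f ml/min, RQ %.2f, FiO2 %.2f\n",
              x$metabolic$hb, x$metabolic$co, x$metabolic$vo2,
              x$metabolic$rq, x$metabolic$fio2))
  cat(sprintf("  VR %.2f /min, IE %.2f\n", x$vent$vr, x$vent$ie))
  invisible(x)
}

# static patient records: measured inputs, optimizer-reported parameter
# values, calibration conditions and blood-gas targets for patients A-E
.patient_records <- data.frame(
  label = c("A", "B", "C", "D", "E"),
  hb    = c(10.5, 10.8, 11.5, 9.8, 9),
  co    = c(11.1, 7.2, 5.6, 7.7, 5.9),
  fio2  = c(0.8, 0.9, 0.5, 0.8, 1),
  vr    = c(12.25, 12.14, 16.04, 17.68, 17.0),
  ie    = c(0.28, 0.25, 0.38, 0.38, 0.43),
  rq    = c(0.6, 0.6, 0.9, 0.7, 0.61),
  vo2   = c(294.3, 300, 200, 257.2, 246.8),
  collapsed_pct = c(26, 29, 12, 20, 21),
  pv    = 15, peep = 5,
  pvo2  = c(47.3, 38.3, 48, 42.83, 34.5),
  pvco2 = c(44.4, 55.5, 47.6, 51, 33.82),
  qs_qt = c(28.6, 31.7, 22.6, 32.3, 43.1),
  pao2  = c(153.7, 85.5, 130.5, 110.3, 64.5),
  # published model-fit outputs, kept for regression comparison
  pvo2_model  = c(49.5, 39.4, 45.4, 42.2, 30.3),
  pvco2_model = c(46.2, 54.4, 49.9, 48.8, 36.07),
  qs_qt_model = c(31.8, 33.9, 19.4, 31.4, 39.14),
  pao2_model  = c(149.9, 87.9, 129.6, 109.6, 64.95),
  stringsAsFactors = FALSE
)

#' Static patient records (five ARDS patients)
#'
#' Returns the embedded static records of the five reference ARDS
#' patients: measured inputs (Hb, cardiac output, FiO2), ventilation
#' parameters, the calibration ventilator conditions (inspiratory pressure
#' 15 cm H2O above a PEEP of 5 cm H2O), and the blood-gas calibration
#' targets (PvO2, PvCO2, Qs/Qt, PaO2).
#'
#' @param label Optional patient label "A".."E"; if omitted all five
#'   records are returned.
#' @return A data frame of class `static_patient_record` (one row per
#'   patient).
#' @export
load_patient_records <- function(label = NULL) {
  out <- .patient_records
  if (!is.null(label)) {
    if (!all(label %in% out$label)) stop("unknown patient label: ", label)
    out <- out[match(label, out$label), , drop = FALSE]
  }
  class(out) <- c("static_patient_record", "data.frame")
  out
}

#' Baseline PaO2/FiO2 severity index from a static record
#'
#' @param record One or more rows of [load_patient_records()].
#' @return PaO2/FiO2 in mmHg.
#' @export
pf_ratio <- function(record) record$pao2 / record$fio2
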