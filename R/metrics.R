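#' Maneuver comparison and PEEP sweeps
#'
#' Experiment drivers over the simulation engine: side-by-side evaluation
#' of the three recruitment maneuvers at a common final PEEP, and sweeps
#' of the MRS staircase peak (PEEP_max) and the titration end point
#' (PEEP_end) measuring how much of the lung is recruited and retained.
#'
#' @name maneuver-metrics
NULL

#' Compare the three recruitment maneuvers on one patient
#'
#' Runs MRS, SI and PRM with the same final PEEP and reports the
#' oxygenation benefit (maximum PaO2/FiO2 above the pre-RM baseline) and
#' the barotrauma surrogate P_peak for each.
#'
#' @param patient An `ards_patient`.
#' @param peep_end Final PEEP (cm H2O), default 10.
#' @param hpv Apply hypoxic vasoconstriction.
#' @return Data frame with columns `rm`, `delta_po2` (mmHg),
#'   `p_peak` (cm H2O), `final_pf` (mmHg), `final_pct_open` (%).
#' @export
compare_rms <- function(patient, peep_end = 10, hpv = TRUE) {
  protos <- list(build_mrs(patient, peep_end = peep_end),
                 build_si(patient, peep_end = peep_end),
                 build_prm(patient, peep_end = peep_end))
  do.call(rbind, lapply(protos, function(p) {
    sim <- run_protocol(patient, p, hpv = hpv)
    data.frame(rm = p$label, delta_po2 = sim$delta_po2, p_peak = sim$p_peak,
               final_pf = sim$final_pf, final_pct_open = sim$final_pct_open)
  }))
}

#' Recruitment achieved versus staircase peak PEEP
#'
#' For each candidate PEEP_max, runs the pre-RM stage plus the MRS
#' recruitment staircase up to that peak and reports the percentage of
#' compartments open at the final breath of the peak step.
#'
#' @param patient An `ards_patient`.
#' @param values PEEP_max values (cm H2O, multiples of 5), ascending.
#' @param hpv Apply hypoxic vasoconstriction.
#' @return Data frame `peep_max`, `pct_recruited`.
#' @export
sweep_peep_max <- function(patient, values = seq(15, 45, by = 5),
                           hpv = TRUE) {
  stopifnot(!is.unsorted(values))
  do.call(rbind, lapply(values, function(pm) {
    segs <- list(build_baseline(10, 300, patient))
    for (p in seq(5, pm, by = 5))
      segs <- c(segs, list(protocol_segment(120, .tidal(p, 15, patient), "rm")))
    proto <- new_protocol(segs, sprintf("MRS-staircase-%g", pm))
    sim <- run_protocol(patient, proto, hpv = hpv)
    data.frame(peep_max = pm, pct_recruited = sim$final_pct_open)
  }))
}

#' Recruitment retained versus titration end PEEP
#'
#' For each candidate PEEP_end, runs the full MRS (staircase to
#' `peep_max`, titration down to PEEP_end) plus the post-RM stage at
#' PEEP_end and reports the percentage of compartments still open at the
#' end.
#'
#' @param patient An `ards_patient`.
#' @param values PEEP_end values (cm H2O), ascending.
#' @param peep_max Staircase peak, default 45.
#' @param hpv Apply hypoxic vasoconstriction.
#' @return Data frame `peep_end`, `pct_open`.
#' @export
sweep_peep_end <- function(patient, values = c(5, 10, 16, 20, 25),
                           peep_max = 45, hpv = TRUE) {
  stopifnot(!is.unsorted(values))
  do.call(rbind, lapply(values, function(pe) {
    sim <- run_protocol(patient,
                        build_mrs(patient, peep_end = pe, peep_max = peep_max),
                        hpv = hpv)
    data.frame(peep_end = pe, pct_open = sim$final_pct_open)
  }))
}
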