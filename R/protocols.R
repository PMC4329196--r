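#' Ventilator protocols
#'
#' Protocols are ordered lists of segments, each holding a duration and a
#' set of pressure-controlled ventilator settings (PEEP, driving pressure
#' above PEEP, ventilation rate, inspiratory fraction, mode). The airway
#' pressure waveform is a square wave: PEEP + driving pressure during the
#' inspiratory fraction of each breath cycle, PEEP during expiration; CPAP
#' segments hold a constant pressure with no tidal breaths. Builders are
#' provided for baseline ventilation and for the three recruitment
#' maneuvers: the maximal recruitment strategy (MRS, a PEEP staircase
#' followed by downward PEEP titration), sustained inflation (SI, a single
#' CPAP hold) and the prolonged recruitment maneuver (PRM, stepwise
#' increases of driving pressure over a fixed raised PEEP).
#'
#' @name ventilator-protocols
NULL

#' Ventilator settings for one protocol segment
#'
#' @param peep End-expiratory pressure (cm H2O).
#' @param dp Driving pressure above PEEP (cm H2O); for CPAP segments the
#'   held pressure is `peep` and `dp` must be 0.
#' @param vr Ventilation rate (breaths/min); required for tidal mode.
#' @param ie Inspiratory fraction of the breath cycle, I/(I+E), in (0,1).
#' @param fio2 Inspired oxygen fraction.
#' @param mode `"tidal"` or `"cpap"`.
#' @return A `vent_settings` list.
#' @export
vent_settings <- function(peep, dp = 15, vr = 12, ie = 0.33, fio2 = 0.21,
                          mode = c("tidal", "cpap")) {
  mode <- match.arg(mode)
  stopifnot(peep >= 0, dp >= 0, fio2 > 0, fio2 <= 1)
  if (mode == "tidal") stopifnot(vr > 0, ie > 0, ie < 1)
  structure(list(peep = peep, dp = dp, vr = vr, ie = ie,
                 fio2 = fio2, mode = mode), class = "vent_settings")
}

#' Protocol segment
#'
#' @param duration Segment duration (s), must be positive.
#' @param settings A [vent_settings()] object.
#' @param stage Stage label ("pre", "rm", "titration", "post", ...).
#' @return A `protocol_segment` list.
#' @export
protocol_segment <- function(duration, settings, stage = "rm") {
  if (!is.numeric(duration) || duration <= 0) stop("segment duration must be positive")
  structure(list(duration = duration, settings = settings, stage = stage),
            class = "protocol_segment")
}

new_protocol <- function(segments, label) {
  structure(list(segments = segments, label = label,
                 total_duration = sum(vapply(segments, `[[`, 0, "duration"))),
            class = "ards_protocol")
}

#' @export
print.ards_protocol <- function(x, ...) {
  cat(sprintf("protocol %s: %d segments, %.1f min total\n",
              x$label, length(x$segments), x$total_duration / 60))
  for (s in x$segments) {
    st <- s$settings
    if (st$mode == "cpap")
      cat(sprintf("  [%-9s] %5.1f min CPAP %g cm H2O\n", s$stage,
                  s$duration / 60, st$peep))
    else
      cat(sprintf("  [%-9s] %5.1f min PEEP %g + dP %g cm H2O, VR %.2f, IE %.2f\n",
                  s$stage, s$duration / 60, st$peep, st$dp, st$vr, st$ie))
  }
  invisible(x)
}

#' Summary table of a protocol
#'
#' @param object An `ards_protocol`.
#' @param ... Ignored.
#' @return Data frame with one row per segment: stage, duration_s, peep,
#'   dp, p_peak (PEEP + dP, the ventilator peak pressure), mode.
#' @export
summary.ards_protocol <- function(object, ...) {
  do.call(rbind, lapply(object$segments, function(s) {
    data.frame(stage = s$stage, duration_s = s$duration,
               peep = s$settings$peep, dp = s$settings$dp,
               p_peak = s$settings$peep +
                 if (s$settings$mode == "cpap") 0 else s$settings$dp,
               mode = s$settings$mode)
  }))
}

#' Baseline tidal ventilation segment
#'
#' Pressure-controlled tidal ventilation at a stated PEEP with the
#' standard driving pressure of 15 cm H2O above PEEP.
#'
#' @param peep PEEP (cm H2O).
#' @param duration Duration (s).
#' @param patient An `ards_patient` supplying VR, IE and FiO2.
#' @param dp Driving pressure, default 15 cm H2O.
#' @param stage Stage label.
#' @return A `protocol_segment`.
#' @export
build_baseline <- function(peep, duration, patient, dp = 15, stage = "pre") {
  protocol_segment(duration, vent_settings(
    peep = peep, dp = dp, vr = patient$vent$vr, ie = patient$vent$ie,
    fio2 = patient$metabolic$fio2), stage = stage)
}

.tidal <- function(peep, dp, patient, fio2 = NULL) {
  vent_settings(peep = peep, dp = dp, vr = patient$vent$vr,
                ie = patient$vent$ie,
                fio2 = if (is.null(fio2)) patient$metabolic$fio2 else fio2)
}

#' Maximal recruitment strategy (MRS)
#'
#' Recruitment phase: 2-minute steps of tidal ventilation with fixed
#' driving pressure 15 cm H2O while PEEP climbs 5, 10, ..., `peep_max`.
#' Titration phase: PEEP set to `min(25, peep_max - 5)` and reduced in
#' 5 cm H2O steps of 5 minutes each down to `peep_end`; a `peep_end` off
#' the 5-grid (e.g. 16) is appended as a final exact step. Wrapped in a
#' pre-RM stage (PEEP 10) and a post-RM stage at `peep_end`.
#'
#' @param patient An `ards_patient`.
#' @param peep_end Final PEEP (cm H2O), e.g. 10 (MRS-10) or 5 (MRS-5).
#' @param peep_max Peak PEEP of the staircase (cm H2O), multiple of 5
#'   between 10 and 45; default 45.
#' @param dp Driving pressure (cm H2O), default 15.
#' @param pre_min,post_min Pre-/post-RM stage durations (minutes).
#' @return An `ards_protocol`.
#' @export
build_mrs <- function(patient, peep_end = 10, peep_max = 45, dp = 15,
                      pre_min = 5, post_min = 20) {
  if (peep_max %% 5 != 0 || peep_max < 10 || peep_max > 45)
    stop("peep_max must be a multiple of 5 in [10, 45]")
  titr_start <- min(25, peep_max - 5)
  if (peep_end < 5 || peep_end > titr_start)
    stop("peep_end must lie in [5, ", titr_start, "]")
  segs <- list(build_baseline(10, pre_min * 60, patient, dp = dp))
  for (p in seq(5, peep_max, by = 5))
    segs <- c(segs, list(protocol_segment(120, .tidal(p, dp, patient), "rm")))
  titr <- seq(titr_start, peep_end, by = -5)
  if (titr[length(titr)] != peep_end) titr <- c(titr, peep_end)
  for (p in titr)
    segs <- c(segs, list(protocol_segment(300, .tidal(p, dp, patient), "titration")))
  segs <- c(segs, list(build_baseline(peep_end, post_min * 60, patient,
                                      dp = dp, stage = "post")))
  new_protocol(segs, sprintf("MRS-%g", peep_end))
}

#' Sustained inflation (SI)
#'
#' A single continuous-pressure (CPAP) hold, by default 40 cm H2O for
#' 40 seconds, with no tidal breaths, preceded by a pre-RM stage at PEEP
#' 10 and followed by a post-RM tidal stage at `peep_end`.
#'
#' @param patient An `ards_patient`.
#' @param peep_end Final PEEP (cm H2O).
#' @param pressure Hold pressure (cm H2O), default 40.
#' @param hold Hold duration (s), default 40; must be positive.
#' @param pre_min,post_min Stage durations (minutes).
#' @return An `ards_protocol`.
#' @export
build_si <- function(patient, peep_end = 10, pressure = 40, hold = 40,
                     pre_min = 5, post_min = 20) {
  if (hold <= 0) stop("hold duration must be positive")
  segs <- list(
    build_baseline(10, pre_min * 60, patient),
    protocol_segment(hold, vent_settings(
      peep = pressure, dp = 0, vr = patient$vent$vr, ie = patient$vent$ie,
      fio2 = patient$metabolic$fio2, mode = "cpap"), "rm"),
    build_baseline(peep_end, post_min * 60, patient, stage = "post"))
  new_protocol(segs, sprintf("SI-%g", peep_end))
}

#' Prolonged recruitment maneuver (PRM)
#'
#' Tidal ventilation over a fixed raised PEEP (default 15 cm H2O) while
#' the driving pressure climbs from `dp_start` to `dp_end` in `dp_step`
#' increments, each held `step_duration` seconds; then a post-RM tidal
#' stage at `peep_end`.
#'
#' @param patient An `ards_patient`.
#' @param peep_end Final PEEP (cm H2O).
#' @param peep Fixed PEEP during the maneuver, default 15.
#' @param dp_start,dp_end,dp_step Driving-pressure ramp (cm H2O),
#'   defaults 15 to 25 in steps of 5; `dp_step` must be positive.
#' @param step_duration Step length (s), default 120.
#' @param pre_min,post_min Stage durations (minutes).
#' @return An `ards_protocol`.
#' @export
build_prm <- function(patient, peep_end = 10, peep = 15, dp_start = 15,
                      dp_end = 25, dp_step = 5, step_duration = 120,
                      pre_min = 5, post_min = 20) {
  if (dp_step <= 0) stop("dp_step must be positive")
  if (dp_end < dp_start) stop("dp_end must be >= dp_start")
  segs <- list(build_baseline(10, pre_min * 60, patient))
  for (dp in seq(dp_start, dp_end, by = dp_step))
    segs <- c(segs, list(protocol_segment(step_duration,
                                          .tidal(peep, dp, patient), "rm")))
  segs <- c(segs, list(build_baseline(peep_end, post_min * 60, patient,
                                      stage = "post")))
  new_protocol(segs, sprintf("PRM-%g", peep_end))
}

# segment index and within-segment offset for a time t
segment_at <- function(protocol, t) {
  if (t < 0 || t >= protocol$total_duration) stop("t outside protocol duration")
  for (i in seq_along(protocol$segments)) {
    d <- protocol$segments[[i]]$duration
    if (t < d) return(list(i = i, offset = t))
    t <- t - d
  }
}

#' Airway pressure waveform of a protocol
#'
#' Evaluates the square-wave ventilator pressure at time `t`: PEEP plus
#' driving pressure during the inspiratory fraction of each breath cycle,
#' PEEP during expiration; constant pressure in CPAP segments.
#'
#' @param protocol An `ards_protocol`.
#' @param t Time since protocol start (s), in `[0, total duration)`;
#'   vectorised.
#' @return Airway pressure (cm H2O).
#' @export
pressure_at <- function(protocol, t) {
  vapply(t, function(tt) {
    loc <- segment_at(protocol, tt)
    st <- protocol$segments[[loc$i]]$settings
    if (st$mode == "cpap") return(st$peep)
    cycle <- 60 / st$vr
    phase <- loc$offset %% cycle
    if (phase < st$ie * cycle) st$peep + st$dp else st$peep
  }, 0)
}
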