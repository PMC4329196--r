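#' Per-compartment lung mechanics
#'
#' The lung is divided into `N` (default 100) alveolar compartments in
#' parallel behind a shared series dead space. Each compartment has a
#' pressure-volume law
#' \deqn{P_{alv} = P_{ext} + k V + k_3 V^3}
#' (stiffness `k`, cubic stiffening `k3`, extrinsic pressure `P_ext`),
#' an airway resistance `R_aw` governing flow, a threshold opening
#' pressure `TOP` with opening time-constant `tau_c`, and a closing
#' pressure `TOP - d_close` strictly below `TOP` (hysteresis). A collapsed
#' compartment holds zero volume and admits no flow; it opens after the
#' airway pressure has exceeded its TOP continuously for `tau_c` seconds,
#' and an open compartment collapses when its end-expiratory alveolar
#' pressure falls below its closing pressure.
#'
#' @name lung-mechanics
NULL

#' Compartment parameter table
#'
#' Validates and assembles per-compartment mechanical parameters.
#'
#' @param k Stiffness (cm H2O per ml), length N.
#' @param k3 Cubic stiffening coefficient (cm H2O per ml^3).
#' @param p_ext Extrinsic pressure (cm H2O).
#' @param top Threshold opening pressure (cm H2O).
#' @param d_close Closing-pressure offset (cm H2O); closing pressure is
#'   `top - d_close`, floored at zero.
#' @param r_aw Airway resistance (cm H2O s per ml).
#' @param r_vasc Relative vascular resistance (dimensionless, > 0).
#' @param tau_c Opening time-constant (s).
#' @param v0 Unstressed volume (ml), default 0.
#' @param raw_vol_coef Optional volume dependence of airway resistance:
#'   the effective resistance is `r_aw (1 + raw_vol_coef (V/24)^2)`,
#'   slowing flow out of (and into) distended compartments; 0 (default)
#'   disables the mechanism.
#' @return A `data.frame` with one row per compartment, class
#'   `compartment_params`.
#' @export
compartment_params <- function(k, k3 = 0, p_ext = 0, top = 0,
                               d_close = 1, r_aw = 1, r_vasc = 1,
                               tau_c = 0, v0 = 0, raw_vol_coef = 0) {
  n <- max(length(k), length(top))
  df <- data.frame(
    k = rep_len(k, n), k3 = rep_len(k3, n), p_ext = rep_len(p_ext, n),
    top = rep_len(top, n), d_close = rep_len(d_close, n),
    r_aw = rep_len(r_aw, n), r_vasc = rep_len(r_vasc, n),
    tau_c = rep_len(tau_c, n), v0 = rep_len(v0, n),
    raw_vol_coef = rep_len(raw_vol_coef, n)
  )
  stopifnot(all(df$k > 0), all(df$r_aw > 0), all(df$tau_c >= 0),
            all(df$r_vasc > 0), all(df$v0 >= 0), all(df$k3 >= 0),
            all(df$d_close > 0), all(df$d_close <= pmax(df$top, df$d_close)))
  class(df) <- c("compartment_params", "data.frame")
  df
}

#' Alveolar pressure from compartment volume
#'
#' Evaluates the compartmental pressure-volume law
#' `P_ext + k V + k3 V^3`; strictly increasing and convex in V.
#'
#' @param v Volume above unstressed volume (ml), vectorised.
#' @param params A `compartment_params` row set (or list with `k`, `k3`,
#'   `p_ext`).
#' @return Alveolar pressure (cm H2O).
#' @export
alveolar_pressure <- function(v, params) {
  if (any(v < 0)) stop("compartment volume must be non-negative")
  params$p_ext + params$k * v + params$k3 * v^3
}

# volume at which the PV law equals pressure p (vectorised Newton;
# the law is strictly increasing so the iteration is safe from v >= 0)
equilibrium_volume <- function(p, params) {
  v <- pmax((p - params$p_ext) / params$k, 0)
  if (any(params$k3 > 0)) {
    for (i in 1:30) {
      f <- params$p_ext + params$k * v + params$k3 * v^3 - p
      v <- pmax(v - f / (params$k + 3 * params$k3 * v^2), 0)
    }
  }
  v
}

#' Create a lung state
#'
#' @param params `compartment_params` table.
#' @param open Logical vector: initially open compartments.
#' @param v Initial volumes (ml above unstressed volume).
#' @param dead_space Shared series dead-space volume (ml), default 150.
#' @return A `lung_state` list with vectors `v`, `open`, `timer`,
#'   `p_alv`, `max_p`, plus `params` and `dead_space`.
#' @export
lung_state <- function(params, open = rep(TRUE, nrow(params)),
                       v = rep(0, nrow(params)), dead_space = 150) {
  stopifnot(length(open) == nrow(params), dead_space >= 0)
  v <- rep_len(v, nrow(params))
  v[!open] <- 0
  p <- alveolar_pressure(v, params)
  p[!open] <- params$p_ext[!open]
  structure(list(params = params, v = v, open = open,
                 timer = rep(0, nrow(params)), p_alv = p,
                 max_p = p, dead_space = dead_space),
            class = "lung_state")
}

#' Advance compartment volumes under an airway pressure
#'
#' Explicit fixed-step integration of `dV/dt = (P_aw - P_alv)/R_aw` for
#' every open compartment over a total interval `duration`, sub-stepped at
#' `dt`. Collapsed compartments admit no flow. Updates alveolar pressures
#' and the running per-compartment pressure maxima.
#'
#' @param state A `lung_state`.
#' @param p_aw Airway opening pressure (cm H2O), held constant over the
#'   interval (square-wave ventilation).
#' @param duration Interval length (s).
#' @param dt Sub-step (s), default 0.01.
#' @return Updated `lung_state`.
#' @export
step_mechanics <- function(state, p_aw, duration, dt = 0.01) {
  stopifnot(is.finite(p_aw), duration >= 0)
  pr <- state$params
  v <- state$v; open <- state$open
  k <- pr$k; k3 <- pr$k3; pe <- pr$p_ext; raw <- pr$r_aw
  rvc <- pr$raw_vol_coef
  n_steps <- max(1L, as.integer(round(duration / dt)))
  h <- duration / n_steps
  pmax_run <- state$max_p
  p <- pe + k * v + k3 * v^3
  for (s in seq_len(n_steps)) {
    dv <- (p_aw - p) / (raw * (1 + rvc * (v / 24)^2)) * h
    v <- ifelse(open, pmax(v + dv, 0), v)
    p <- pe + k * v + k3 * v^3
    pmax_run <- pmax(pmax_run, ifelse(open, p, pe))
  }
  state$v <- v
  state$p_alv <- ifelse(open, p, pe)
  state$max_p <- pmax_run
  state
}

#' Update recruitment timers and open compartments
#'
#' For each collapsed compartment: while the airway pressure exceeds its
#' TOP the opening timer accumulates; once the timer reaches `tau_c` the
#' compartment opens (volume starts at zero and fills through
#' [step_mechanics()]). If the airway pressure drops to or below the TOP
#' the timer resets to zero.
#'
#' @param state A `lung_state`.
#' @param p_aw Airway pressure held over the interval (cm H2O).
#' @param dt Interval over which `p_aw` was held (s).
#' @return Updated `lung_state`.
#' @export
update_recruitment <- function(state, p_aw, dt) {
  r <- recruit_tick(state$timer, state$open, state$params$top,
                    state$params$tau_c, p_aw, dt)
  state$timer <- r$timer
  state$open <- r$open
  state
}

# internal, vectorised recruitment bookkeeping used by the engine
recruit_tick <- function(timer, open, top, tau_c, p_aw, dt) {
  closed <- !open
  above <- closed & (p_aw > top)
  timer[closed & !above] <- 0
  timer[above] <- timer[above] + dt
  opens <- above & (timer >= tau_c)
  open[opens] <- TRUE
  timer[opens] <- 0
  list(timer = timer, open = open, opened = opens)
}

#' Collapse compartments below their closing pressure
#'
#' Evaluated once per breath at end-expiration: any open compartment whose
#' end-expiratory alveolar pressure is below `TOP - d_close` collapses
#' instantly (cliff-edge derecruitment); its volume is discarded.
#'
#' @param state A `lung_state`; `p_alv` must hold end-expiratory pressures.
#' @return Updated `lung_state`.
#' @export
update_derecruitment <- function(state) {
  closing <- pmax(state$params$top - state$params$d_close, 0)
  fall <- state$open & (state$p_alv < closing)
  state$open[fall] <- FALSE
  state$v[fall] <- 0
  state$p_alv[fall] <- state$params$p_ext[fall]
  state
}

#' Dynamic compliance
#'
#' Tidal volume divided by driving pressure, reported in ml per mbar with
#' the working convention 1 mbar = 1 cm H2O (a ~2% unit approximation).
#'
#' @param vt Tidal volume (ml).
#' @param p_peak Peak inspiratory airway pressure (cm H2O).
#' @param peep Positive end-expiratory pressure (cm H2O).
#' @return Compliance in ml/mbar.
#' @export
dynamic_compliance <- function(vt, p_peak, peep) {
  if (any(p_peak <= peep)) stop("driving pressure must be positive")
  vt / (p_peak - peep)
}

#' Peak-pressure barotrauma index
#'
#' Mean of the per-compartment maximum alveolar pressures over the most
#' highly pressurised 20% of compartments, taken over an entire maneuver.
#'
#' @param max_p Vector of per-compartment running pressure maxima
#'   (cm H2O), or a `lung_state`.
#' @param frac Fraction of compartments to average, default 0.2.
#' @return P_peak (cm H2O).
#' @export
p_peak_top20 <- function(max_p, frac = 0.2) {
  if (inherits(max_p, "lung_state")) max_p <- max_p$max_p
  if (length(max_p) == 0) stop("empty lung")
  n_top <- ceiling(frac * length(max_p))
  mean(sort(max_p, decreasing = TRUE)[seq_len(n_top)])
}

#' Percentage of compartments recruited
#'
#' @param open Logical vector of open flags, or a `lung_state`.
#' @return Percentage open, in \[0, 100\].
#' @export
percent_recruited <- function(open) {
  if (inherits(open, "lung_state")) open <- open$open
  100 * mean(open)
}
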