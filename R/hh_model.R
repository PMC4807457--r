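# Hodgkin-Huxley membrane and conductance model.
#
# All voltages use the original HH sign convention: V is the displacement of
# the membrane potential from rest, rest is V = 0, and a depolarization of
# d mV corresponds to V = -d.  Time is in ms, conductances in mS/cm^2,
# currents in uA/cm^2, capacitance in uF/cm^2.

.K_NAMES <- c("k_an1", "k_an2", "k_an3", "k_bn1", "k_bn2",
              "k_am1", "k_am2", "k_am3", "k_bm1", "k_bm2",
              "k_ah1", "k_ah2", "k_bh1", "k_bh2")
.RATE_NAMES <- c("alpha_n", "beta_n", "alpha_m", "beta_m", "alpha_h", "beta_h")
.K_SPECIES <- list(K = .K_NAMES[1:5], Na = .K_NAMES[6:14])
# exponent-denominator parameters that must stay positive
.K_DENOM <- c("k_an3", "k_bn2", "k_am3", "k_bm2", "k_ah2", "k_bh2")

#' Reported voltage-dependency parameters
#'
#' The canonical 1952 parametrization of the six gating-rate functions,
#' expressed as the 14 free constants of the voltage-dependent model:
#' \deqn{\alpha_n(V) = k_{\alpha n1}(V + k_{\alpha n2}) /
#'   (e^{(V + k_{\alpha n2})/k_{\alpha n3}} - 1)}
#' \deqn{\beta_n(V) = k_{\beta n1} e^{V/k_{\beta n2}}}
#' and analogously for the sodium activation (m) and inactivation (h) gates,
#' with \eqn{\beta_h(V) = 1/(e^{(V + k_{\beta h1})/k_{\beta h2}} + 1)}.
#'
#' @return Named numeric vector of length 14 (class `hh_vparams`).
#' @export
#' @examples
#' k <- hh_default_params()
#' rates_from_voltage(k, 0)  # beta_n = 0.125, alpha_h = 0.07
hh_default_params <- function() {
  k <- c(k_an1 = 0.01, k_an2 = 10, k_an3 = 10, k_bn1 = 0.125, k_bn2 = 80,
         k_am1 = 0.1, k_am2 = 25, k_am3 = 10, k_bm1 = 4, k_bm2 = 18,
         k_ah1 = 0.07, k_ah2 = 20, k_bh1 = 30, k_bh2 = 10)
  structure(k, class = "hh_vparams")
}

#' Construct or validate a voltage-dependency parameter vector
#'
#' @param k Named numeric vector; any subset of the 14 parameter names, the
#'   rest taken from [hh_default_params()].
#' @return Named numeric vector of length 14 (class `hh_vparams`).
#' @export
voltage_params <- function(k = NULL) {
  out <- unclass(hh_default_params())
  if (!is.null(k)) {
    if (is.null(names(k)) || !all(names(k) %in% .K_NAMES))
      stop("voltage parameters must be named with the k_* names: ",
           paste(.K_NAMES, collapse = ", "))
    out[names(k)] <- as.numeric(k)
  }
  if (!all(is.finite(out))) stop("voltage parameters must be finite")
  if (any(out[.K_DENOM] <= 0))
    stop("exponent-denominator parameters (", paste(.K_DENOM, collapse = ", "),
         ") must be > 0")
  structure(out, class = "hh_vparams")
}

#' Membrane circuit constants
#'
#' Capacitance, maximum conductances, leak conductance and reversal
#' potentials.  Defaults are the values reported with the original squid-axon
#' model (HH sign convention: \eqn{V_{Na} = -115} mV, \eqn{V_K = +12} mV,
#' \eqn{V_l = -10.613} mV, the leak reversal chosen so that V = 0 is the
#' resting fixed point).  These are configuration, not fitted quantities.
#'
#' @param C_M Membrane capacitance, uF/cm^2.
#' @param gbar_K,gbar_Na Maximum potassium / sodium conductances, mS/cm^2.
#' @param g_l Leak conductance, mS/cm^2.
#' @param V_Na,V_K,V_l Reversal potentials, mV (HH sign convention).
#' @return Named numeric vector (class `hh_constants`).
#' @export
membrane_constants <- function(C_M = 1, gbar_K = 36, gbar_Na = 120,
                               g_l = 0.3, V_Na = -115, V_K = 12,
                               V_l = -10.613) {
  if (C_M <= 0) stop("C_M must be > 0")
  if (gbar_K < 0 || gbar_Na < 0 || g_l < 0)
    stop("conductances must be >= 0")
  structure(c(C_M = C_M, gbar_K = gbar_K, gbar_Na = gbar_Na, g_l = g_l,
              V_Na = V_Na, V_K = V_K, V_l = V_l),
            class = "hh_constants")
}

.consts_vec <- function(consts) {
  as.numeric(consts[c("C_M", "gbar_K", "gbar_Na", "g_l", "V_Na", "V_K",
                      "V_l")])
}

#' Gating rates from membrane voltage
#'
#' Evaluates the six voltage-dependent rate functions at voltage `V`.  The
#' removable singularity of the \eqn{(V + k_2)/(e^{(V+k_2)/k_3} - 1)} form at
#' \eqn{V = -k_2} is replaced by its analytic limit \eqn{k_1 k_3} inside a
#' guard band of width \eqn{10^{-7} k_3}; exponential arguments are clamped
#' to \eqn{\pm 500} to preclude overflow.
#'
#' @param k Voltage-dependency parameters ([voltage_params()]).
#' @param V Membrane voltage(s), mV, HH convention.
#' @return For scalar `V` a named rate vector (class `hh_rates`); for vector
#'   `V` a `length(V) x 6` matrix with one row per voltage.
#' @export
#' @examples
#' rates_from_voltage(hh_default_params(), -10)[["alpha_n"]]  # limit 0.1
rates_from_voltage <- function(k, V) {
  k <- voltage_params(k)
  if (!all(is.finite(V))) stop("V must be finite")
  if (length(V) == 1L) {
    r <- .hh_rates_cpp(as.numeric(k), V)
    names(r) <- .RATE_NAMES
    return(structure(r, class = "hh_rates"))
  }
  out <- t(vapply(V, function(v) .hh_rates_cpp(as.numeric(k), v),
                  numeric(6)))
  colnames(out) <- .RATE_NAMES
  rownames(out) <- NULL
  out
}

#' Fixed gating rates
#'
#' Constructor for the simplified-model parameter vector: the six rate
#' constants, each in 1/ms, held fixed (voltage-independent).
#'
#' @param alpha_n,beta_n,alpha_m,beta_m,alpha_h,beta_h Rates, 1/ms, all >= 0.
#' @return Named numeric vector (class `hh_rates`).
#' @export
gating_rates <- function(alpha_n, beta_n, alpha_m = 0, beta_m = 0,
                         alpha_h = 0, beta_h = 0) {
  r <- c(alpha_n = alpha_n, beta_n = beta_n, alpha_m = alpha_m,
         beta_m = beta_m, alpha_h = alpha_h, beta_h = beta_h)
  if (any(!is.finite(r)) || any(r < 0))
    stop("rates must be finite and >= 0")
  structure(r, class = "hh_rates")
}

#' Gating-variable time derivatives
#'
#' \eqn{dx/dt = \alpha_x (1 - x) - \beta_x x} for each gate x in (n, m, h).
#'
#' @param state Named vector or list with elements `n`, `m`, `h` in [0, 1].
#' @param rates Rate vector as returned by [gating_rates()] or
#'   [rates_from_voltage()].
#' @return Named numeric vector `c(dn, dm, dh)` (1/ms).
#' @export
gating_derivatives <- function(state, rates) {
  x <- c(state[["n"]], state[["m"]], state[["h"]])
  if (any(x < 0) || any(x > 1)) stop("gating variables must lie in [0, 1]")
  a <- as.numeric(rates[c("alpha_n", "alpha_m", "alpha_h")])
  b <- as.numeric(rates[c("beta_n", "beta_m", "beta_h")])
  d <- a * (1 - x) - b * x
  c(dn = d[1], dm = d[2], dh = d[3])
}

#' Ionic conductances from gating state
#'
#' \eqn{g_K = \bar g_K n^4}, \eqn{g_{Na} = \bar g_{Na} m^3 h}.
#'
#' @param state Named vector or list with elements `n`, `m`, `h` in [0, 1].
#' @param consts [membrane_constants()].
#' @return Named numeric vector `c(g_K, g_Na)` in mS/cm^2.
#' @export
conductances <- function(state, consts = membrane_constants()) {
  n <- state[["n"]]; m <- state[["m"]]; h <- state[["h"]]
  if (any(c(n, m, h) < 0) || any(c(n, m, h) > 1))
    stop("gating variables must lie in [0, 1]")
  c(g_K = unname(consts[["gbar_K"]]) * n^4,
    g_Na = unname(consts[["gbar_Na"]]) * m^3 * h)
}

#' Steady-state gating values
#'
#' Fixed point of the gating ODEs at constant rates:
#' \eqn{x_\infty = \alpha_x / (\alpha_x + \beta_x)}.
#'
#' @param rates Rate vector (six rates).
#' @return Named numeric vector `c(n_inf, m_inf, h_inf)`.
#' @export
steady_state_gating <- function(rates) {
  a <- as.numeric(rates[c("alpha_n", "alpha_m", "alpha_h")])
  b <- as.numeric(rates[c("beta_n", "beta_m", "beta_h")])
  if (any(a + b <= 0))
    stop("degenerate gate: alpha + beta must be > 0 for every gate")
  x <- a / (a + b)
  c(n_inf = x[1], m_inf = x[2], h_inf = x[3])
}

#' Membrane currents
#'
#' Component ionic currents and their sum under the membrane circuit
#' equations: \eqn{I_x = g_x (V - V_x)} per species, \eqn{I_i = I_{Na} +
#' I_K + I_l}, and total \eqn{I = C_M dV/dt + I_i}.
#'
#' @param state Named vector or list with `V`, `n`, `m`, `h`.
#' @param consts [membrane_constants()].
#' @param I_applied Externally applied current, uA/cm^2.
#' @return List with `I`, `I_i`, `I_Na`, `I_K`, `I_l` (uA/cm^2) and `dVdt`
#'   (mV/ms).
#' @export
membrane_currents <- function(state, consts = membrane_constants(),
                              I_applied = 0) {
  g <- conductances(state, consts)
  V <- state[["V"]]
  I_Na <- unname(g[["g_Na"]]) * (V - unname(consts[["V_Na"]]))
  I_K <- unname(g[["g_K"]]) * (V - unname(consts[["V_K"]]))
  I_l <- unname(consts[["g_l"]]) * (V - unname(consts[["V_l"]]))
  I_i <- I_Na + I_K + I_l
  dVdt <- (I_applied - I_i) / unname(consts[["C_M"]])
  list(I = I_applied, I_i = I_i, I_Na = I_Na, I_K = I_K, I_l = I_l,
       dVdt = dVdt)
}

#' Membrane-voltage derivative
#'
#' @inheritParams membrane_currents
#' @return dV/dt in mV/ms.
#' @export
membrane_derivative <- function(state, consts = membrane_constants(),
                                I_applied = 0) {
  membrane_currents(state, consts, I_applied)$dVdt
}

#' Resting membrane state
#'
#' The configured initial state used by the voltage-clamp protocol: V = 0
#' with the gating variables at their reported resting values (the steady
#' state of the reported rates at V = 0).  With `self_consistent = TRUE` the
#' gates are instead recomputed as the steady state of the *given* parameter
#' vector at V = 0.
#'
#' @param k Voltage-dependency parameters (used only when
#'   `self_consistent = TRUE`).
#' @param self_consistent Recompute gates from `k` rather than using the
#'   fixed configured values.
#' @return Named numeric vector `c(V, n, m, h)`.
#' @export
resting_state <- function(k = hh_default_params(), self_consistent = FALSE) {
  if (self_consistent) {
    x <- steady_state_gating(rates_from_voltage(k, 0))
  } else {
    x <- steady_state_gating(rates_from_voltage(hh_default_params(), 0))
  }
  c(V = 0, n = unname(x[["n_inf"]]), m = unname(x[["m_inf"]]),
    h = unname(x[["h_inf"]]))
}

#' Build a piecewise drive schedule
#'
#' A schedule is a data frame of contiguous segments.  Each segment holds the
#' membrane either voltage-clamped (`kind = "clamp_V"`, `value` = clamp
#' voltage in mV), current-clamped (`kind = "clamp_I"`, `value` = applied
#' current in uA/cm^2) or free-running (`kind = "free"`).  `v_set` (absolute)
#' and `v_add` (additive) apply an instantaneous voltage reset at segment
#' start, modelling an instantaneous depolarization.
#'
#' @param t0,t1 Segment start/end times (ms); must be contiguous.
#' @param kind Character vector of segment kinds.
#' @param value Drive value per segment (clamp voltage or current).
#' @param v_set,v_add Optional instantaneous voltage resets at segment start
#'   (NA = none).
#' @return Data frame with class `hh_schedule`.
#' @export
drive_schedule <- function(t0, t1, kind, value = 0, v_set = NA_real_,
                           v_add = NA_real_) {
  n <- length(t0)
  sched <- data.frame(t0 = t0, t1 = t1,
                      kind = rep_len(kind, n),
                      value = rep_len(value, n),
                      v_set = rep_len(v_set, n),
                      v_add = rep_len(v_add, n))
  if (!all(sched$kind %in% c("clamp_V", "clamp_I", "free")))
    stop("segment kind must be one of clamp_V, clamp_I, free")
  if (any(sched$t1 <= sched$t0)) stop("segments must have t1 > t0")
  if (n > 1 && any(abs(sched$t0[-1] - sched$t1[-n]) > 1e-9))
    stop("segments must be contiguous and non-overlapping")
  class(sched) <- c("hh_schedule", "data.frame")
  sched
}

.schedule_matrix <- function(schedule) {
  mode <- match(schedule$kind, c("clamp_V", "clamp_I", "free")) - 1L
  cbind(schedule$t0, schedule$t1, mode, schedule$value,
        ifelse(is.na(schedule$v_set), NaN, schedule$v_set),
        ifelse(is.na(schedule$v_add), NaN, schedule$v_add))
}

#' Simulate the Hodgkin-Huxley system over a drive schedule
#'
#' Integrates the four-state system (V, n, m, h) with an adaptive
#' Dormand-Prince 5(4) solver (relative tolerance 1e-6, absolute 1e-8 by
#' default) and dense output evaluated exactly at `t_grid`.  During
#' voltage-clamped segments V is held at the clamp value exactly and only the
#' gates are integrated.
#'
#' @param params Either a 14-element [voltage_params()] vector (full model)
#'   or a six-element [gating_rates()] vector (simplified model, rates held
#'   fixed regardless of voltage).
#' @param consts [membrane_constants()].
#' @param schedule [drive_schedule()].
#' @param t_grid Strictly increasing sample times (ms) within the schedule's
#'   time span.
#' @param init Initial state `c(V, n, m, h)`; default [resting_state()].
#' @param rtol,atol Solver tolerances.
#' @return Data frame with columns `t`, `V`, `n`, `m`, `h`, `g_K`, `g_Na`.
#'   Solver failure signals an error of class `hh_integration_error`.
#' @export
simulate_hh <- function(params, consts = membrane_constants(), schedule,
                        t_grid, init = resting_state(), rtol = 1e-6,
                        atol = 1e-8) {
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  if (inherits(params, "hh_rates") || length(params) == 6L) {
    pvec <- as.numeric(params)
    mode <- 1L
  } else {
    pvec <- as.numeric(voltage_params(params))
    mode <- 0L
  }
  segm <- .schedule_matrix(schedule)
  y <- tryCatch(
    .hh_simulate_cpp(pvec, mode, .consts_vec(consts), segm,
                     as.numeric(t_grid), as.numeric(init), rtol, atol),
    error = function(e) {
      stop(structure(class = c("hh_integration_error", "error", "condition"),
                     list(message = conditionMessage(e),
                          call = sys.call(-1), params = pvec)))
    })
  data.frame(t = t_grid, V = y[, 1], n = y[, 2], m = y[, 3], h = y[, 4],
             g_K = unname(consts[["gbar_K"]]) * y[, 2]^4,
             g_Na = unname(consts[["gbar_Na"]]) * y[, 3]^3 * y[, 4])
}

#' Convert HH-convention voltage to modern membrane potential
#'
#' The package works throughout in the original sign convention (V =
#' displacement from rest, depolarization negative).  For presentation in
#' the modern convention, \eqn{V_m = V_{rest} - V}.
#'
#' @param V Voltage(s) in HH convention (mV).
#' @param rest Resting membrane potential in the modern convention (mV).
#' @return Membrane potential(s) in mV, modern convention.
#' @export
hh_to_modern <- function(V, rest = -65) rest - V
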