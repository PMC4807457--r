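# The five experimental drive protocols.
#
# The voltage-clamp protocol starts from fixed configured initial conditions
# and clamps immediately; the four advanced protocols first let the model
# free-run for a settle period (default 1000 ms) so all state variables reach
# steady state for the candidate parametrization before the stimulus at t = 0.

.voltage_trace <- function(t, V, protocol) {
  structure(data.frame(time_ms = t, V_mV = V),
            protocol = protocol, class = c("hh_voltage_trace", "data.frame"))
}

.conductance_trace <- function(t, g, species, depolarization) {
  data.frame(time_ms = t, g = g, species = species,
             depolarization_mV = depolarization)
}

#' Voltage-clamp conductance protocol
#'
#' Clamps the membrane at \eqn{V = -d} (a depolarization of d mV) for 12 ms
#' from the configured resting initial state and records both ionic
#' conductances every 0.1 ms (121 samples).
#'
#' @param k [voltage_params()] vector, or a six-element [gating_rates()]
#'   vector for the simplified fixed-rate model.
#' @param depolarization Depolarization magnitude d in mV (clamp V = -d).
#' @param consts [membrane_constants()].
#' @param duration_ms,sample_interval_ms Clamp duration and sampling period.
#' @param init Initial state; default the fixed configured resting state.
#' @param self_consistent_init Recompute initial gates as the steady state of
#'   `k` at V = 0 instead of the fixed configured values.
#' @param rtol,atol Solver tolerances.
#' @return List with elements `K` and `Na`, each a conductance-trace data
#'   frame (`time_ms`, `g`, `species`, `depolarization_mV`).
#' @export
run_voltage_clamp <- function(k, depolarization,
                              consts = membrane_constants(),
                              duration_ms = 12, sample_interval_ms = 0.1,
                              init = NULL, self_consistent_init = FALSE,
                              rtol = 1e-6, atol = 1e-8) {
  if (!is.finite(depolarization)) stop("depolarization must be finite")
  if (is.null(init)) {
    init <- if (self_consistent_init && !(length(k) == 6L))
      resting_state(k, self_consistent = TRUE) else resting_state()
  }
  t_grid <- seq(0, duration_ms, by = sample_interval_ms)
  sched <- drive_schedule(0, duration_ms, "clamp_V", -depolarization)
  out <- simulate_hh(k, consts, sched, t_grid, init, rtol, atol)
  list(K = .conductance_trace(out$t, out$g_K, "K", depolarization),
       Na = .conductance_trace(out$t, out$g_Na, "Na", depolarization))
}

.settle_then <- function(k, consts, settle_ms, segments, t_grid, rtol, atol) {
  sched <- rbind(drive_schedule(-settle_ms, 0, "free"), segments)
  class(sched) <- c("hh_schedule", "data.frame")
  simulate_hh(k, consts, sched, t_grid, resting_state(), rtol, atol)
}

#' Anode-break excitation protocol
#'
#' After settling, the membrane is voltage-clamped 30 mV below resting
#' potential (V = +30, a hyperpolarization) for 200 ms; the clamp is then
#' released and the free-running voltage recorded every 0.1 ms for 30 ms.
#' Under the reported parametrization, release of the clamp triggers a full
#' action potential.
#'
#' @inheritParams run_voltage_clamp
#' @param clamp_mV Hyperpolarizing clamp level in HH convention (+30 =
#'   30 mV below rest).
#' @param clamp_ms,record_ms Clamp and post-release recording durations.
#' @param settle_ms Pre-stimulus free-run settle duration.
#' @return An `hh_voltage_trace` data frame covering the recording window
#'   (t = 0 at clamp release).
#' @export
run_anode_break <- function(k, consts = membrane_constants(),
                            settle_ms = 1000, clamp_mV = 30, clamp_ms = 200,
                            sample_interval_ms = 0.1, record_ms = 30,
                            rtol = 1e-6, atol = 1e-8) {
  segs <- drive_schedule(c(-clamp_ms, 0), c(0, record_ms),
                         c("clamp_V", "free"), c(clamp_mV, 0))
  sched <- rbind(drive_schedule(-settle_ms - clamp_ms, -clamp_ms, "free"),
                 segs)
  class(sched) <- c("hh_schedule", "data.frame")
  t_grid <- seq(0, record_ms, by = sample_interval_ms)
  out <- simulate_hh(k, consts, sched, t_grid, resting_state(), rtol, atol)
  .voltage_trace(out$t, out$V, "anode_break")
}

#' Threshold-excitation protocol
#'
#' After settling, the membrane voltage is stepped instantaneously by a
#' depolarization of d mV (V jumps to -d; d = -10 is a 10 mV
#' hyperpolarization) and then free-runs for 10 ms, recorded every 0.01 ms.
#' Under the reported parametrization only the 7 mV step in the canonical
#' set (-10, 2, 5, 6, 7) triggers an action potential.
#'
#' @inheritParams run_anode_break
#' @param depolarization Instantaneous step magnitude d in mV.
#' @param record_ms Post-step recording duration.
#' @return An `hh_voltage_trace` (t = 0 at the step).
#' @export
run_threshold_excitation <- function(k, depolarization,
                                     consts = membrane_constants(),
                                     settle_ms = 1000,
                                     sample_interval_ms = 0.01,
                                     record_ms = 10, rtol = 1e-6,
                                     atol = 1e-8) {
  segs <- drive_schedule(0, record_ms, "free", 0, v_add = -depolarization)
  t_grid <- seq(0, record_ms, by = sample_interval_ms)
  out <- .settle_then(k, consts, settle_ms, segs, t_grid, rtol, atol)
  .voltage_trace(out$t, out$V, "threshold_excitation")
}

#' Positive-phase depolarization protocol
#'
#' After settling, a 15 mV instantaneous depolarization is applied; after
#' `delay_ms` (5, 6 or 8 ms) of free running, an additional 90 mV
#' depolarization is applied, and the simulation continues to 15 ms total
#' after the first step, recorded every 0.01 ms.
#'
#' @inheritParams run_anode_break
#' @param delay_ms Delay between the two depolarizations (ms).
#' @param first_step_mV,second_step_mV Step magnitudes (depolarizations, mV).
#' @param total_ms Total recorded duration after the first step.
#' @return An `hh_voltage_trace` (t = 0 at the first step; 1501 samples at
#'   the defaults).
#' @export
run_positive_phase <- function(k, delay_ms, consts = membrane_constants(),
                               settle_ms = 1000, first_step_mV = 15,
                               second_step_mV = 90, total_ms = 15,
                               sample_interval_ms = 0.01, rtol = 1e-6,
                               atol = 1e-8) {
  if (delay_ms <= 0 || delay_ms >= total_ms)
    stop("delay_ms must lie in (0, total_ms)")
  segs <- drive_schedule(c(0, delay_ms), c(delay_ms, total_ms), "free", 0,
                         v_add = c(-first_step_mV, -second_step_mV))
  t_grid <- seq(0, total_ms, by = sample_interval_ms)
  out <- .settle_then(k, consts, settle_ms, segs, t_grid, rtol, atol)
  .voltage_trace(out$t, out$V, "positive_phase")
}

#' Oscillation-induction protocol
#'
#' After settling, the membrane current is clamped to a fixed amplitude for
#' 15 ms; the clamp is then released and the model free-runs for a further
#' 10 ms, with voltage recorded every 0.1 ms over the whole 25 ms.
#'
#' The default amplitude is the printed value -1.49 mA/cm^2; the magnitude
#' is physiologically anomalous for this preparation (classic sustained
#' currents are of order uA/cm^2), so the unit is exposed rather than
#' silently corrected: set `units = "uA"` to interpret `amplitude` in
#' uA/cm^2.
#'
#' @inheritParams run_anode_break
#' @param amplitude Applied current amplitude during the clamp.
#' @param units `"mA"` (printed convention; converted to uA/cm^2 internally)
#'   or `"uA"`.
#' @param clamp_ms,post_ms Current-clamp and post-release durations.
#' @return An `hh_voltage_trace` over [0, clamp_ms + post_ms], t = 0 at
#'   clamp onset.
#' @export
run_oscillation_induction <- function(k, consts = membrane_constants(),
                                      amplitude = -1.49,
                                      units = c("mA", "uA"),
                                      settle_ms = 1000, clamp_ms = 15,
                                      post_ms = 10,
                                      sample_interval_ms = 0.1,
                                      rtol = 1e-6, atol = 1e-8) {
  units <- match.arg(units)
  amp_uA <- if (units == "mA") amplitude * 1000 else amplitude
  segs <- drive_schedule(c(0, clamp_ms), c(clamp_ms, clamp_ms + post_ms),
                         c("clamp_I", "free"), c(amp_uA, 0))
  t_grid <- seq(0, clamp_ms + post_ms, by = sample_interval_ms)
  out <- .settle_then(k, consts, settle_ms, segs, t_grid, rtol, atol)
  .voltage_trace(out$t, out$V, "oscillation_induction")
}

#' Detect an action potential in a voltage trace
#'
#' Responses of the model are bimodal: either a full spike (peak
#' depolarization displacement of roughly 90-100 mV) or a few-mV
#' subthreshold decay, so any mid-range displacement cut separates the two
#' robustly; the default is 50 mV.
#'
#' @param trace An `hh_voltage_trace` (or data frame with `V_mV`), HH sign
#'   convention (depolarization negative).
#' @param threshold_mV Peak-displacement threshold (mV).
#' @return `TRUE` iff the peak depolarization displacement max(-V) exceeds
#'   `threshold_mV` anywhere in the trace.
#' @export
detect_ap <- function(trace, threshold_mV = 50) {
  V <- if (is.data.frame(trace)) trace$V_mV else as.numeric(trace)
  if (length(V) == 0) stop("empty voltage trace")
  max(-V) > threshold_mV
}
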