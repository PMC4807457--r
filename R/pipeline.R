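# Orchestration: the three studies (simplified fits per depolarization,
# full-model fits per species, posterior protocol ensembles) plus the
# ABC simulator builders that tie the sampler to the clamp protocol.

#' Build a voltage-clamp simulator for ABC fitting
#'
#' Returns a closure `theta -> list of conductance vectors`, one per
#' depolarization, sampled on the observed time grid — the forward model
#' handed to [run_abc_smc()].  Simplified-model closures treat `theta` as
#' fixed gating rates for one species; full-model closures embed `theta`
#' (5 potassium or 9 sodium k-parameters) into a full vector.
#'
#' @param model `"simplified"` or `"full"`.
#' @param species `"K"` or `"Na"`.
#' @param depolarizations Depolarization magnitudes (mV) matching the
#'   observed traces, in order.
#' @param t_grid Sample times (ms) of the observed traces.
#' @param consts [membrane_constants()].
#' @param base Full parameter vector for the non-fitted species (full model
#'   only).
#' @param init Initial state; default the configured resting state.
#' @param rtol,atol Solver tolerances.
#' @return Function mapping a named parameter vector to a list of numeric
#'   conductance vectors.
#' @export
clamp_simulator <- function(model = c("simplified", "full"),
                            species = c("K", "Na"), depolarizations,
                            t_grid, consts = membrane_constants(),
                            base = hh_default_params(), init = NULL,
                            rtol = 1e-6, atol = 1e-8) {
  model <- match.arg(model)
  species <- match.arg(species)
  if (is.null(init)) init <- resting_state()
  cvec <- .consts_vec(consts)
  M <- length(depolarizations)
  cols <- if (species == "K") seq_len(M) else M + seq_len(M)
  base <- as.numeric(voltage_params(base))
  names(base) <- .K_NAMES
  kidx <- match(.K_SPECIES[[species]], .K_NAMES)
  function(theta) {
    if (model == "simplified") {
      rates <- c(0, 0, 0, 0, 0, 0)
      names(rates) <- .RATE_NAMES
      if (species == "K") rates[c("alpha_n", "beta_n")] <- theta
      else rates[c("alpha_m", "beta_m", "alpha_h", "beta_h")] <- theta
      g <- .hh_clamp_batch_cpp(as.numeric(rates), 1L, cvec,
                               as.numeric(depolarizations),
                               as.numeric(t_grid), as.numeric(init), rtol,
                               atol)
    } else {
      k <- base
      k[kidx] <- as.numeric(theta)
      g <- .hh_clamp_batch_cpp(k, 0L, cvec, as.numeric(depolarizations),
                               as.numeric(t_grid), as.numeric(init), rtol,
                               atol)
    }
    lapply(cols, function(j) g[, j])
  }
}

.trace_depol <- function(tr) tr$depolarization_mV[1]

#' Simplified-model study: per-depolarization rate fits
#'
#' For each depolarization present in the dataset, fits the species' fixed
#' gating rates to that single clamp trace with ABC-SMC (potassium: alpha_n,
#' beta_n against the g_K trace; sodium: alpha_m, beta_m, alpha_h, beta_h
#' against the g_Na trace) and tabulates posterior mean and s.d. per rate,
#' the per-depolarization analogue of the published rate-versus-voltage
#' summaries.
#'
#' @param dataset An `hh_synth_dataset` (or compatible list of traces).
#' @param species Species to fit (default both present).
#' @param N,max_draws,tau,max_generations ABC-SMC settings (see
#'   [run_abc_smc()]).
#' @param seed Integer seed (set once; fits run sequentially).
#' @param consts [membrane_constants()].
#' @param keep_fits Retain full `hh_abc_fit` objects in the result.
#' @param verbose Progress messages.
#' @return List with `table` (data frame: species, depolarization,
#'   parameter, truth, mean, sd, p5, p95, epsilon) and, if `keep_fits`,
#'   `fits` (named list).
#' @export
run_simplified_study <- function(dataset, species = c("K", "Na"), N = 100,
                                 max_draws = 10000, tau = 0.003,
                                 max_generations = 60, seed = 1,
                                 consts = membrane_constants(),
                                 keep_fits = FALSE, verbose = FALSE) {
  set.seed(seed)
  rows <- list()
  fits <- list()
  for (sp in species) {
    trs <- dataset_species(dataset, sp)
    if (length(trs) == 0) {
      warning("no ", sp, " traces in dataset; skipping")
      next
    }
    settings <- default_abc_settings("simplified", sp)
    for (nm in names(trs)) {
      tr <- trs[[nm]]
      d <- .trace_depol(tr)
      sim <- clamp_simulator("simplified", sp, d, tr$time_ms, consts)
      fit <- run_abc_smc(sim, list(tr$g), settings$prior, settings$kernel,
                         N = N, max_draws = max_draws, tau = tau,
                         max_generations = max_generations,
                         verbose = verbose)
      pop <- final_population(fit)
      truth <- rates_from_voltage(dataset$truth$params, -d)
      smry <- summarize_population(pop, settings$prior)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, depolarization_mV = d, parameter = smry$parameter,
        truth = as.numeric(truth[smry$parameter]), mean = smry$mean,
        sd = sqrt(smry$variance), p5 = smry$p5, p95 = smry$p95,
        epsilon = pop$epsilon)
      if (keep_fits) fits[[nm]] <- fit
    }
  }
  if (length(rows) == 0) stop("dataset contains no traces for ",
                              paste(species, collapse = "/"))
  out <- list(table = do.call(rbind, rows))
  if (keep_fits) out$fits <- fits
  out
}

#' Full-model study: voltage-dependency fits per species
#'
#' Fits all of a species' voltage-dependency parameters (5 for potassium, 9
#' for sodium) against all of that species' clamp traces at once with the
#' multi-trace averaged distance, then summarizes the posterior and applies
#' the identifiability classifier.
#'
#' @inheritParams run_simplified_study
#' @param s0,v0,c0 Identifiability thresholds
#'   (see [classify_identifiability()]).
#' @return Named list per species, each with `fit` (`hh_abc_fit`),
#'   `summary` (with reported values), and `report`
#'   (`hh_identifiability_report`).
#' @export
run_full_study <- function(dataset, species = c("K", "Na"), N = 100,
                           max_draws = 10000, tau = 0.003,
                           max_generations = 60, seed = 1,
                           consts = membrane_constants(), s0 = 0.18,
                           v0 = 0.1, c0 = 0.9, verbose = FALSE) {
  set.seed(seed)
  out <- list()
  for (sp in species) {
    trs <- dataset_species(dataset, sp)
    if (length(trs) == 0) {
      warning("no ", sp, " traces in dataset; skipping")
      next
    }
    depols <- vapply(trs, .trace_depol, numeric(1))
    t_grid <- trs[[1]]$time_ms
    settings <- default_abc_settings("full", sp)
    sim <- clamp_simulator("full", sp, depols, t_grid, consts,
                           base = dataset$truth$params)
    fit <- run_abc_smc(sim, lapply(trs, function(tr) tr$g),
                       settings$prior, settings$kernel, N = N,
                       max_draws = max_draws, tau = tau,
                       max_generations = max_generations,
                       verbose = verbose)
    pop <- final_population(fit)
    reported <- unclass(hh_default_params())[.K_SPECIES[[sp]]]
    smry <- summarize_population(pop, settings$prior, reported = reported)
    rep <- identifiability_report(pop, settings$prior,
                                  base = dataset$truth$params, s0 = s0,
                                  v0 = v0, c0 = c0)
    out[[sp]] <- list(fit = fit, summary = smry, report = rep)
  }
  if (length(out) == 0) stop("dataset contains no traces")
  out
}

#' Protocol study over fitted posteriors
#'
#' Runs the advanced protocols over every particle of a fitted posterior
#' population (one species varying, the other at base values) and tabulates
#' the firing fractions.
#'
#' @param pop An `hh_population` of species-level k-parameter particles.
#' @param protocols Named list mapping protocol names to argument lists,
#'   e.g. `list(threshold_excitation = list(depolarization = 7))`; defaults
#'   cover all four advanced protocols.
#' @param base Full parameter vector for the non-varying species.
#' @param consts [membrane_constants()].
#' @param settle_ms Settle duration passed to each protocol.
#' @param threshold_mV AP-detection threshold.
#' @return List with `table` (protocol, fraction_firing, failures) and
#'   `responses` (per-protocol [ensemble_protocol_response()] results).
#' @export
run_protocol_study <- function(pop,
                               protocols = list(
                                 anode_break = list(),
                                 threshold_excitation =
                                   list(depolarization = 7),
                                 positive_phase = list(delay_ms = 5),
                                 oscillation_induction = list()),
                               base = hh_default_params(),
                               consts = membrane_constants(),
                               settle_ms = 1000, threshold_mV = 50) {
  responses <- list()
  rows <- list()
  for (nm in names(protocols)) {
    args <- c(list(pop = pop, protocol = nm, base = base, consts = consts,
                   threshold_mV = threshold_mV, settle_ms = settle_ms),
              protocols[[nm]])
    resp <- do.call(ensemble_protocol_response, args)
    responses[[nm]] <- resp
    rows[[nm]] <- data.frame(protocol = nm,
                             fraction_firing = resp$fraction_firing,
                             failures = resp$failures)
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       responses = responses)
}
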