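# Synthetic voltage-clamp datasets emulating sparsely digitized recordings:
# clamp traces simulated under known parameters, optionally decimated, with
# seeded additive Gaussian noise and negative conductances clipped at zero.
# Ground truth always travels with the dataset so recovery tests are
# self-contained.

#' Default per-species depolarization sets
#'
#' Representative sets of clamp depolarizations spanning roughly 6-109 mV
#' (the historical recordings' range; the exact magnitudes are configurable,
#' not asserted as historical values).  The 6 mV potassium trace is flagged
#' excluded by default, mirroring the published exclusion of the smallest
#' potassium plot, leaving M = 11 potassium and M = 12 sodium traces.
#'
#' @param K,Na Optional user-supplied depolarization vectors (mV), passed
#'   through unchanged.
#' @param exclude_K Potassium depolarizations to flag as excluded.
#' @return List with `K`, `Na` (active sets) and `excluded` (data frame of
#'   flagged traces).
#' @export
default_depolarization_sets <- function(K = NULL, Na = NULL,
                                        exclude_K = 6) {
  base <- c(109, 100, 88, 76, 63, 51, 38, 32, 26, 19, 10, 6)
  if (is.null(K)) K <- setdiff(base, exclude_K)
  if (is.null(Na)) Na <- base
  excl <- if (length(exclude_K))
    data.frame(species = "K", depolarization_mV = exclude_K)
  else data.frame(species = character(), depolarization_mV = numeric())
  list(K = K, Na = Na, excluded = excl)
}

#' Specification of a synthetic voltage-clamp dataset
#'
#' @param true_params Generating [voltage_params()] vector.
#' @param depolarizations List with `K` and `Na` depolarization vectors
#'   (mV); default [default_depolarization_sets()].
#' @param duration_ms Clamp duration (default 12).
#' @param sample_interval_ms Simulation sampling period (default 0.1).
#' @param subsample Keep every `subsample`-th sample (decimation emulating
#'   sparse digitization; 1 = none).
#' @param noise_sd Additive Gaussian noise s.d.: absolute mS/cm^2
#'   (`noise_mode = "absolute"`) or a fraction of each trace's amplitude
#'   (`"relative"`, default 0.02, i.e. 2 percent of the per-trace maximum).
#' @param noise_mode `"relative"` or `"absolute"`.
#' @param seed Integer seed for the noise stream.
#' @param consts [membrane_constants()].
#' @return List with class `hh_synth_spec`.
#' @export
synthetic_dataset_spec <- function(true_params = hh_default_params(),
                                   depolarizations =
                                     default_depolarization_sets(),
                                   duration_ms = 12,
                                   sample_interval_ms = 0.1, subsample = 1,
                                   noise_sd = 0.02,
                                   noise_mode = c("relative", "absolute"),
                                   seed = 1,
                                   consts = membrane_constants()) {
  noise_mode <- match.arg(noise_mode)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (duration_ms <= 0) stop("duration_ms must be > 0")
  if (length(depolarizations$K) == 0 && length(depolarizations$Na) == 0)
    stop("depolarization lists are empty")
  structure(list(true_params = voltage_params(true_params),
                 depolarizations = depolarizations,
                 duration_ms = duration_ms,
                 sample_interval_ms = sample_interval_ms,
                 subsample = as.integer(subsample), noise_sd = noise_sd,
                 noise_mode = noise_mode, seed = as.integer(seed),
                 consts = consts),
            class = "hh_synth_spec")
}

#' Generate a synthetic voltage-clamp conductance dataset
#'
#' For each species and depolarization, simulates the clamp under the true
#' parameters, decimates, adds seeded Gaussian noise and clips negative
#' conductances to zero.
#'
#' @param spec [synthetic_dataset_spec()].
#' @return List (class `hh_synth_dataset`) with `traces` (list of
#'   conductance-trace data frames named `"K_109"` etc.), `clean` (the
#'   noiseless counterparts) and `truth` (generating parameters and spec).
#' @export
generate_clamp_dataset <- function(spec) {
  stopifnot(inherits(spec, "hh_synth_spec"))
  set.seed(spec$seed)
  traces <- list()
  clean <- list()
  for (sp in c("K", "Na")) {
    for (d in spec$depolarizations[[sp]]) {
      sim <- run_voltage_clamp(spec$true_params, d, spec$consts,
                               spec$duration_ms, spec$sample_interval_ms)
      tr <- sim[[sp]]
      if (spec$subsample > 1)
        tr <- tr[seq(1, nrow(tr), by = spec$subsample), , drop = FALSE]
      sd_abs <- if (spec$noise_mode == "relative")
        spec$noise_sd * max(tr$g) else spec$noise_sd
      noisy <- tr
      noisy$g <- pmax(0, tr$g + rnorm(nrow(tr), 0, sd_abs))
      nm <- paste0(sp, "_", d)
      traces[[nm]] <- noisy
      clean[[nm]] <- tr
    }
  }
  structure(list(traces = traces, clean = clean,
                 truth = list(params = spec$true_params, spec = spec)),
            class = "hh_synth_dataset")
}

#' Select the traces of one species from a synthetic dataset
#'
#' @param dataset An `hh_synth_dataset`.
#' @param species `"K"` or `"Na"`.
#' @param clean Return the noiseless traces instead.
#' @return Named list of conductance-trace data frames.
#' @export
dataset_species <- function(dataset, species = c("K", "Na"),
                            clean = FALSE) {
  species <- match.arg(species)
  src <- if (clean) dataset$clean else dataset$traces
  src[grepl(paste0("^", species, "_"), names(src))]
}
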