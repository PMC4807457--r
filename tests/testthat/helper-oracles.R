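# Shared oracles and fixture builders (all fixtures generated in code).

# cache letting the acceptance invariants criterion reuse the fits computed
# by the recovery criteria instead of re-running them
.acc_cache <- new.env(parent = emptyenv())

# Analytic solution of a gate under constant rates:
# x(t) = xinf - (xinf - x0) exp(-(alpha + beta) t)
gate_closed_form <- function(alpha, beta, x0, t) {
  xinf <- alpha / (alpha + beta)
  xinf - (xinf - x0) * exp(-(alpha + beta) * t)
}

# The reported rate functions written out directly (independent of the
# package's parametrized evaluator).
reference_rates <- function(V) {
  c(alpha_n = 0.01 * (V + 10) / (exp((V + 10) / 10) - 1),
    beta_n = 0.125 * exp(V / 80),
    alpha_m = 0.1 * (V + 25) / (exp((V + 25) / 10) - 1),
    beta_m = 4 * exp(V / 18),
    alpha_h = 0.07 * exp(V / 20),
    beta_h = 1 / (exp((V + 30) / 10) + 1))
}

# Exhaustive weighted-CDF quantile (independent of weighted_quantile):
# walk the sorted values accumulating weight until >= p.
brute_weighted_quantile <- function(x, w, p) {
  ord <- order(x)
  xs <- x[ord]
  ws <- w[ord] / sum(w)
  acc <- 0
  for (i in seq_along(xs)) {
    acc <- acc + ws[i]
    if (acc >= p - 1e-12) return(xs[i])
  }
  xs[length(xs)]
}

# Small noiseless single-trace potassium dataset for fit tests.
tiny_k_dataset <- function(depol = 100, noise_sd = 0, seed = 1,
                           duration_ms = 12, sample_interval_ms = 0.1) {
  spec <- synthetic_dataset_spec(
    depolarizations = list(K = depol, Na = numeric(0)),
    duration_ms = duration_ms, sample_interval_ms = sample_interval_ms,
    noise_sd = noise_sd,
    noise_mode = if (noise_sd > 0) "relative" else "absolute", seed = seed)
  generate_clamp_dataset(spec)
}

# 1-parameter toy: fit alpha_n to a single noiseless clamped potassium gate
# with beta_n fixed at truth.
toy_fit <- function(seed, N = 50, max_draws = 2000) {
  ds <- tiny_k_dataset(depol = 100)
  tr <- ds$traces$K_100
  truth <- rates_from_voltage(hh_default_params(), -100)
  base_sim <- clamp_simulator("simplified", "K", 100, tr$time_ms)
  sim1 <- function(theta) base_sim(c(theta[["alpha_n"]],
                                     truth[["beta_n"]]))
  pr <- prior_spec(c(alpha_n = 0), c(alpha_n = 1))
  kern <- kernel_spec(c(alpha_n = 0.1))
  list(fit = run_abc_smc(sim1, list(tr$g), pr, kern, N = N,
                         max_draws = max_draws, seed = seed),
       truth = truth[["alpha_n"]])
}

# Hand-built population helper.
make_population <- function(theta, weight = NULL, distance = NULL,
                            epsilon = 1, generation = 1L) {
  N <- nrow(theta)
  if (is.null(weight)) weight <- rep(1 / N, N)
  if (is.null(distance)) distance <- rep(0, N)
  hhabc:::.new_population(theta, weight, distance, epsilon, generation, N)
}
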