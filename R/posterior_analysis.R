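# Posterior summarization and identifiability diagnostics.

#' Weighted quantile (left-continuous inverse CDF)
#'
#' The smallest observed value x with weighted CDF F(x) >= p.
#'
#' @param x Numeric values.
#' @param w Non-negative weights (normalized internally).
#' @param p Probabilities in [0, 1].
#' @return Quantile(s) of the weighted empirical distribution.
#' @export
weighted_quantile <- function(x, w, p) {
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(p, function(pp) x[which(cw >= pp - 1e-12)[1]], numeric(1))
}

.weighted_moments <- function(x, w) {
  w <- w / sum(w)
  mu <- sum(w * x)
  c(mean = mu, variance = sum(w * (x - mu)^2))
}

#' Summarize a posterior population
#'
#' Per-parameter weighted mean, weighted variance and weighted 5th/95th
#' percentiles (the published tables' layout), plus a distance summary.
#' Weighted statistics are primary; `weighted = FALSE` gives the unweighted
#' versions.
#'
#' @param pop An `hh_population`.
#' @param prior Optional [prior_spec()]; when given, relative spread
#'   ((p95 - p5) / prior width) is included.
#' @param weighted Use particle weights (default) or uniform weights.
#' @param reported Optional named vector of reference parameter values to
#'   carry alongside (the "reported value" column).
#' @return Data frame, one row per parameter, with attribute
#'   `distance_summary` (min/max particle distance and the tolerance met).
#' @export
summarize_population <- function(pop, prior = NULL, weighted = TRUE,
                                 reported = NULL) {
  if (is.null(pop$theta) || nrow(pop$theta) == 0) stop("empty population")
  w <- if (weighted) pop$weight else rep(1 / nrow(pop$theta),
                                         nrow(pop$theta))
  rows <- lapply(colnames(pop$theta), function(p) {
    x <- pop$theta[, p]
    mo <- .weighted_moments(x, w)
    q <- weighted_quantile(x, w, c(0.05, 0.95))
    data.frame(parameter = p, mean = mo[["mean"]],
               variance = mo[["variance"]], p5 = q[1], p95 = q[2])
  })
  out <- do.call(rbind, rows)
  if (!is.null(reported))
    out$reported <- as.numeric(reported[out$parameter])
  if (!is.null(prior)) {
    width <- prior$upper[out$parameter] - prior$lower[out$parameter]
    out$relative_spread <- (out$p95 - out$p5) / as.numeric(width)
  }
  attr(out, "distance_summary") <- c(min_distance = min(pop$distance),
                                     max_distance = max(pop$distance),
                                     epsilon = pop$epsilon)
  out
}

# map each parameter to the rate curve it parametrizes
.PARAM_CURVE <- c(k_an1 = "alpha_n", k_an2 = "alpha_n", k_an3 = "alpha_n",
                  k_bn1 = "beta_n", k_bn2 = "beta_n",
                  k_am1 = "alpha_m", k_am2 = "alpha_m", k_am3 = "alpha_m",
                  k_bm1 = "beta_m", k_bm2 = "beta_m",
                  k_ah1 = "alpha_h", k_ah2 = "alpha_h",
                  k_bh1 = "beta_h", k_bh2 = "beta_h")

.embed_theta <- function(theta, base = hh_default_params()) {
  k <- unclass(base)
  k[names(theta)] <- as.numeric(theta)
  voltage_params(k)
}

#' Embed species-level parameters into a full parameter vector
#'
#' Posterior particles for one species (5 potassium or 9 sodium parameters)
#' are completed to a full 14-parameter vector with the other species held
#' at `base` values.
#'
#' @param theta Named parameter subset.
#' @param base Full parameter vector supplying the remaining values.
#' @return An `hh_vparams` vector.
#' @export
embed_species_params <- function(theta, base = hh_default_params()) {
  if (is.null(names(theta)) || !all(names(theta) %in% .K_NAMES))
    stop("theta must be named with k_* parameter names")
  .embed_theta(theta, base)
}

#' Rate-curve ensemble over a posterior population
#'
#' Evaluates the six voltage-dependent rates for every particle on a voltage
#' grid, returning the per-particle curves and pointwise weighted quantile
#' bands.
#'
#' @param pop An `hh_population` of full-model (k_*) particles.
#' @param V_grid Voltages (mV, HH convention).
#' @param base Full parameter vector completing partial particles.
#' @param probs Band quantiles (default 5th/95th).
#' @return List with `curves` (array particle x voltage x rate), `bands`
#'   (array quantile x voltage x rate) and `V_grid`.
#' @export
rate_curve_ensemble <- function(pop, V_grid, base = hh_default_params(),
                                probs = c(0.05, 0.95)) {
  if (!all(colnames(pop$theta) %in% .K_NAMES))
    stop("rate_curve_ensemble needs full-model (k_*) particles")
  N <- nrow(pop$theta)
  curves <- array(NA_real_, c(N, length(V_grid), 6),
                  dimnames = list(NULL, NULL, .RATE_NAMES))
  for (i in seq_len(N)) {
    kk <- .embed_theta(pop$theta[i, ], base)
    curves[i, , ] <- rates_from_voltage(kk, V_grid)
  }
  bands <- array(NA_real_, c(length(probs), length(V_grid), 6),
                 dimnames = list(paste0("p", probs * 100), NULL,
                                 .RATE_NAMES))
  for (r in seq_len(6)) for (v in seq_along(V_grid))
    bands[, v, r] <- weighted_quantile(curves[, v, r], pop$weight, probs)
  list(curves = curves, bands = bands, V_grid = V_grid)
}

#' Weighted pairwise parameter correlations
#'
#' Weighted Pearson correlations for all parameter pairs plus marginal
#' histogram bins for biplot-style visualization.  Parameters with zero
#' weighted variance (or an effectively degenerate weight vector) yield `NA`
#' correlations.
#'
#' @param pop An `hh_population` with at least 3 distinct particles.
#' @param bins Histogram bin count for the marginals.
#' @return List with `correlation` (d x d matrix) and `marginals` (list of
#'   per-parameter histogram data frames).
#' @export
pairwise_correlations <- function(pop, bins = 20) {
  th <- pop$theta
  if (nrow(unique(th)) < 3)
    stop("need at least 3 distinct particles")
  w <- pop$weight / sum(pop$weight)
  d <- ncol(th)
  mu <- colSums(th * w)
  cen <- sweep(th, 2, mu)
  cov <- t(cen * w) %*% cen
  sdv <- sqrt(diag(cov))
  corr <- matrix(NA_real_, d, d, dimnames = list(colnames(th),
                                                 colnames(th)))
  ess_ok <- 1 / sum(w^2) > 1.5  # weight mass not concentrated on one point
  for (i in seq_len(d)) for (j in seq_len(d)) {
    if (ess_ok && sdv[i] > 1e-12 && sdv[j] > 1e-12)
      corr[i, j] <- cov[i, j] / (sdv[i] * sdv[j])
  }
  marginals <- lapply(colnames(th), function(p) {
    h <- hist(th[, p], breaks = bins, plot = FALSE)
    data.frame(mid = h$mids, count = h$counts)
  })
  names(marginals) <- colnames(th)
  list(correlation = corr, marginals = marginals)
}

#' Per-parameter output-variation scores
#'
#' For each parameter, particles in the bottom and top weighted terciles of
#' that parameter are pooled and the weighted coefficient of variation of
#' the rate curve the parameter enters is averaged over the voltage grid.
#' A parameter whose span leaves the output unchanged (the structural
#' signature) scores near zero; a parameter whose span moves the output
#' scores high.
#'
#' @inheritParams rate_curve_ensemble
#' @return Named numeric vector of scores, one per parameter.
#' @export
output_variation_scores <- function(pop, V_grid = seq(-110, 10, by = 5),
                                    base = hh_default_params()) {
  ens <- rate_curve_ensemble(pop, V_grid, base)
  w <- pop$weight / sum(pop$weight)
  vapply(colnames(pop$theta), function(p) {
    crv <- matrix(ens$curves[, , .PARAM_CURVE[[p]]],
                  nrow = nrow(pop$theta))
    x <- pop$theta[, p]
    q <- weighted_quantile(x, w, c(1 / 3, 2 / 3))
    sel <- x <= q[1] | x >= q[2]
    if (sum(sel) < 2) return(0)
    ws <- w[sel] / sum(w[sel])
    cvs <- vapply(seq_along(V_grid), function(v) {
      y <- crv[sel, v]
      mo <- .weighted_moments(y, ws)
      sqrt(mo[["variance"]]) / (abs(mo[["mean"]]) + 1e-12)
    }, numeric(1))
    mean(cvs)
  }, numeric(1))
}

#' Classify parameter identifiability
#'
#' Documented rule applied per parameter:
#' * relative spread < `s0` -> `"identifiable"`;
#' * spread >= `s0`, output variation >= `v0` and max absolute pairwise
#'   correlation < `c0` -> `"practical-unidentifiable"` (output still
#'   responds to the parameter, no compensating relationship);
#' * spread >= `s0` with output variation < `v0` or max correlation >=
#'   `c0` -> `"structural-candidate"`.
#'
#' @param summary Output of [summarize_population()] (with
#'   `relative_spread`, i.e. called with a prior).
#' @param correlations Output of [pairwise_correlations()].
#' @param output_variation Output of [output_variation_scores()].
#' @param s0,v0,c0 Classification thresholds.
#' @return Data frame (class `hh_identifiability_report`) with the raw
#'   diagnostics and a `label` per parameter.
#' @export
classify_identifiability <- function(summary, correlations,
                                     output_variation, s0 = 0.18, v0 = 0.1,
                                     c0 = 0.9) {
  cm <- correlations$correlation
  diag(cm) <- NA
  rows <- lapply(seq_len(nrow(summary)), function(i) {
    p <- summary$parameter[i]
    spread <- summary$relative_spread[i]
    if (is.null(spread)) stop("summary must carry relative_spread; ",
                              "call summarize_population with a prior")
    ov <- unname(output_variation[[p]])
    mc <- suppressWarnings(max(abs(cm[p, ]), na.rm = TRUE))
    if (!is.finite(mc)) mc <- NA_real_
    label <- if (spread < s0) "identifiable"
    else if (ov >= v0 && (is.na(mc) || mc < c0)) "practical-unidentifiable"
    else "structural-candidate"
    data.frame(parameter = p, relative_spread = spread,
               output_variation = ov, max_abs_correlation = mc,
               label = label)
  })
  out <- do.call(rbind, rows)
  attr(out, "thresholds") <- c(s0 = s0, v0 = v0, c0 = c0)
  class(out) <- c("hh_identifiability_report", "data.frame")
  out
}

#' Full identifiability report for a population
#'
#' Convenience wrapper computing the posterior summary, pairwise
#' correlations and output-variation scores from one population and
#' applying [classify_identifiability()].
#'
#' @param pop An `hh_population` of full-model particles.
#' @param prior [prior_spec()] used for the fit.
#' @param V_grid Voltage grid for the output-variation diagnostics.
#' @param base Full parameter vector completing partial particles.
#' @param s0,v0,c0 Classification thresholds.
#' @return An `hh_identifiability_report` with attribute `summary`.
#' @export
identifiability_report <- function(pop, prior,
                                   V_grid = seq(-110, 10, by = 5),
                                   base = hh_default_params(), s0 = 0.18,
                                   v0 = 0.1, c0 = 0.9) {
  smry <- summarize_population(pop, prior)
  corr <- pairwise_correlations(pop)
  ov <- output_variation_scores(pop, V_grid, base)
  rep <- classify_identifiability(smry, corr, ov, s0, v0, c0)
  attr(rep, "summary") <- smry
  rep
}

#' Posterior-ensemble protocol responses
#'
#' Runs one of the advanced protocols for every particle in a posterior
#' population (the particle's species parameters embedded into a full
#' vector, the other species held at `base` values) and summarizes firing
#' behaviour.
#'
#' @param pop An `hh_population` of species-level full-model particles.
#' @param protocol One of `"anode_break"`, `"threshold_excitation"`,
#'   `"positive_phase"`, `"oscillation_induction"`.
#' @param base Full parameter vector for the non-varying species.
#' @param consts [membrane_constants()].
#' @param threshold_mV AP-detection threshold.
#' @param ... Protocol-specific arguments (e.g. `depolarization` for
#'   threshold excitation, `delay_ms` for positive phase, `settle_ms`).
#' @return List with `traces` (one `hh_voltage_trace` or `NULL` per
#'   particle), `fired` (logical, `NA` where integration failed),
#'   `fraction_firing` (over successful runs), `failures` (count) and
#'   `envelope` (pointwise min/max voltage across successful traces).
#' @export
ensemble_protocol_response <- function(pop,
                                       protocol = c("anode_break",
                                                    "threshold_excitation",
                                                    "positive_phase",
                                                    "oscillation_induction"),
                                       base = hh_default_params(),
                                       consts = membrane_constants(),
                                       threshold_mV = 50, ...) {
  protocol <- match.arg(protocol)
  runner <- switch(protocol,
    anode_break = run_anode_break,
    threshold_excitation = run_threshold_excitation,
    positive_phase = run_positive_phase,
    oscillation_induction = run_oscillation_induction)
  N <- nrow(pop$theta)
  traces <- vector("list", N)
  fired <- rep(NA, N)
  for (i in seq_len(N)) {
    kk <- .embed_theta(pop$theta[i, ], base)
    tr <- tryCatch(runner(kk, consts = consts, ...),
                   hh_integration_error = function(e) NULL,
                   error = function(e) NULL)
    traces[[i]] <- tr
    if (!is.null(tr)) fired[i] <- detect_ap(tr, threshold_mV)
  }
  ok <- !vapply(traces, is.null, logical(1))
  envelope <- NULL
  if (any(ok)) {
    Vs <- vapply(traces[ok], function(tr) tr$V_mV,
                 numeric(nrow(traces[which(ok)[1]][[1]])))
    Vs <- matrix(Vs, ncol = sum(ok))
    envelope <- data.frame(time_ms = traces[[which(ok)[1]]]$time_ms,
                           V_min = apply(Vs, 1, min),
                           V_max = apply(Vs, 1, max))
  }
  list(traces = traces, fired = fired,
       fraction_firing = mean(fired[ok]),
       failures = sum(!ok), envelope = envelope)
}
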