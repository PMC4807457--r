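test_that("summaries of a delta population reproduce its point", {
  th <- matrix(rep(c(0.3, 7), each = 5), 5,
               dimnames = list(NULL, c("k_an1", "k_an2")))
  pop <- make_population(th)
  sm <- summarize_population(pop)
  expect_equal(sm$mean, c(0.3, 7))
  expect_equal(sm$variance, c(0, 0))
  expect_equal(sm$p5, sm$p95)
})

test_that("weighted percentiles agree with the brute-force CDF oracle", {
  # uniform weights over 1..100: p5 = 5, p95 = 95 under the step convention
  x <- 1:100
  w <- rep(1, 100)
  expect_equal(weighted_quantile(x, w, c(0.05, 0.95)), c(5, 95))
  # randomized cross-check on small populations
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:20, 1)
    x <- rnorm(n)
    w <- runif(n)
    for (p in c(0.05, 0.33, 0.5, 0.95)) {
      expect_equal(weighted_quantile(x, w, p),
                   brute_weighted_quantile(x, w, p))
    }
  }
})

test_that("two-point equal-weight population has mean 0.5, variance 0.25", {
  th <- matrix(c(0, 1), 2, dimnames = list(NULL, "k_an1"))
  sm <- summarize_population(make_population(th))
  expect_equal(sm$mean, 0.5)
  expect_equal(sm$variance, 0.25)
  expect_error(summarize_population(make_population(th[0, , drop = FALSE])),
               "empty")
})

test_that("rate-curve ensembles collapse for degenerate populations", {
  Vg <- seq(-100, 0, by = 10)
  k0 <- hh_default_params()
  th1 <- matrix(unclass(k0)[1:5], 1,
                dimnames = list(NULL, names(unclass(k0))[1:5]))
  ens1 <- rate_curve_ensemble(make_population(th1), Vg)
  expect_equal(ens1$bands["p5", , "alpha_n"], ens1$bands["p95", , "alpha_n"])
  # a population of reported-parameter copies equals the reported curves
  th5 <- th1[rep(1, 5), , drop = FALSE]
  ens5 <- rate_curve_ensemble(make_population(th5), Vg)
  ref <- rates_from_voltage(k0, Vg)
  for (i in 1:5)
    expect_equal(ens5$curves[i, , "beta_n"], unname(ref[, "beta_n"]))
})

test_that("band width at negative V grows with k_bn2 posterior spread", {
  # two synthetic populations differing only in k_bn2 spread; beta_n at
  # strongly negative V is dominated by the exponential argument V/k_bn2
  base <- unclass(hh_default_params())[1:5]
  mk <- function(spread) {
    th <- matrix(rep(base, each = 40), 40,
                 dimnames = list(NULL, names(base)))
    set.seed(9)
    th[, "k_bn2"] <- pmax(1, 80 + rnorm(40, 0, spread))
    make_population(th)
  }
  Vg <- c(-100)
  narrow <- rate_curve_ensemble(mk(2), Vg)
  wide <- rate_curve_ensemble(mk(25), Vg)
  width <- function(e) e$bands["p95", 1, "beta_n"] -
    e$bands["p5", 1, "beta_n"]
  expect_gt(width(wide), 3 * width(narrow))
})

test_that("pairwise correlations behave on null, collinear and degenerate
           populations", {
  set.seed(5)
  N <- 400
  th <- cbind(k_an1 = runif(N), k_an2 = runif(N, 0, 100))
  pc <- pairwise_correlations(make_population(th))
  expect_lt(abs(pc$correlation["k_an1", "k_an2"]), 3 / sqrt(N))
  expect_equal(diag(pc$correlation), c(k_an1 = 1, k_an2 = 1))
  # exact linear relation
  th2 <- cbind(k_an1 = seq(0.1, 0.9, length.out = 20))
  th2 <- cbind(th2, k_an2 = 2 * th2[, 1])
  colnames(th2) <- c("k_an1", "k_an2")
  pc2 <- pairwise_correlations(make_population(th2))
  expect_equal(pc2$correlation["k_an1", "k_an2"], 1)
  # weights concentrated on one particle: degenerate, NA reported
  w <- c(1 - 1e-9, rep(1e-9 / 19, 19))
  pc3 <- pairwise_correlations(make_population(th2, weight = w))
  expect_true(is.na(pc3$correlation["k_an1", "k_an2"]))
  expect_error(pairwise_correlations(
    make_population(th2[c(1, 1, 1), , drop = FALSE])), "distinct")
})

test_that("classifier separates identifiable, practical and structural", {
  base <- unclass(hh_default_params())[1:5]
  pr <- default_abc_settings("full", "K")$prior
  nm <- names(base)
  jitter_mat <- function(N, sds) {
    set.seed(31)
    th <- matrix(rep(base, each = N), N, dimnames = list(NULL, nm))
    for (p in nm) th[, p] <- pmax(pr$lower[p] + 1e-6,
                                  pmin(pr$upper[p] - 1e-6,
                                       th[, p] + rnorm(N, 0, sds[p])))
    th
  }
  # (a) near-zero-variance posterior: everything identifiable
  tight <- jitter_mat(30, c(k_an1 = 1e-4, k_an2 = 0.01, k_an3 = 0.01,
                            k_bn1 = 1e-4, k_bn2 = 0.01))
  pop <- make_population(tight)
  rep_a <- identifiability_report(pop, pr)
  expect_true(all(rep_a$label == "identifiable"))

  # (b) wide, uncorrelated k_bn2 with output response at negative V:
  # practical unidentifiability
  wide <- jitter_mat(60, c(k_an1 = 1e-4, k_an2 = 0.01, k_an3 = 0.01,
                           k_bn1 = 1e-4, k_bn2 = 1e-6))
  set.seed(32)
  wide[, "k_bn2"] <- runif(60, 20, 99)
  rep_b <- identifiability_report(make_population(wide), pr,
                                  V_grid = seq(-110, 0, by = 10))
  expect_equal(rep_b$label[rep_b$parameter == "k_bn2"],
               "practical-unidentifiable")

  # (c) constant-product pair evaluated where output depends only on the
  # product: structural candidate (flat output, strong dependence)
  set.seed(33)
  th <- jitter_mat(60, c(k_an1 = 0, k_an2 = 0, k_an3 = 0, k_bn1 = 0,
                         k_bn2 = 0))
  k1 <- runif(60, 0.002, 0.9)
  th[, "k_an1"] <- k1
  th[, "k_an3"] <- pmin(99.9, 0.1 / k1)   # k_an1 * k_an3 = 0.1
  # V = -k_an2 puts alpha_n exactly at its removable-singularity limit
  # k_an1 * k_an3, so the output is flat across the population
  rep_c <- identifiability_report(make_population(th), pr, V_grid = -10)
  expect_equal(rep_c$label[rep_c$parameter == "k_an1"],
               "structural-candidate")
})

test_that("classification is deterministic and auditable", {
  sm <- data.frame(parameter = c("a", "b"),
                   relative_spread = c(0.05, 0.6))
  corr <- list(correlation = matrix(c(1, 0.2, 0.2, 1), 2,
                                    dimnames = list(c("a", "b"),
                                                    c("a", "b"))))
  ov <- c(a = 0.5, b = 0.5)
  r1 <- classify_identifiability(sm, corr, ov)
  r2 <- classify_identifiability(sm, corr, ov)
  expect_identical(r1, r2)
  expect_equal(r1$label, c("identifiable", "practical-unidentifiable"))
  # with a high-correlation pair the wide parameter becomes structural
  corr$correlation[1, 2] <- corr$correlation[2, 1] <- 0.95
  r3 <- classify_identifiability(sm, corr, ov)
  expect_equal(r3$label[2], "structural-candidate")
  expect_equal(unname(attr(r3, "thresholds")["s0"]), 0.18)
})

test_that("ensemble protocol responses collapse for clone populations", {
  k0 <- hh_default_params()
  th <- matrix(rep(unclass(k0)[1:5], each = 3), 3,
               dimnames = list(NULL, names(unclass(k0))[1:5]))
  pop <- make_population(th)
  resp <- ensemble_protocol_response(pop, "threshold_excitation",
                                     depolarization = 7,
                                     settle_ms = 200)
  expect_equal(resp$fraction_firing, 1)
  expect_equal(resp$failures, 0)
  ref <- run_threshold_excitation(k0, 7, settle_ms = 200)
  expect_equal(resp$traces[[1]]$V_mV, ref$V_mV)
  expect_equal(resp$traces[[2]]$V_mV, resp$traces[[3]]$V_mV)
  # permutation invariance of the firing fraction
  perm <- make_population(th[c(3, 1, 2), , drop = FALSE])
  resp2 <- ensemble_protocol_response(perm, "threshold_excitation",
                                      depolarization = 7,
                                      settle_ms = 200)
  expect_equal(resp2$fraction_firing, resp$fraction_firing)
})

test_that("ensemble responses never mutate the population", {
  th <- matrix(rep(unclass(hh_default_params())[1:5], each = 2), 2,
               dimnames = list(NULL, names(unclass(hh_default_params()))[1:5]))
  pop <- make_population(th)
  snapshot <- serialize(pop, NULL)
  invisible(ensemble_protocol_response(pop, "threshold_excitation",
                                       depolarization = 2,
                                       settle_ms = 100))
  expect_identical(serialize(pop, NULL), snapshot)
})
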