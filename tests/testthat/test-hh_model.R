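k0 <- hh_default_params()
consts0 <- membrane_constants()

test_that("rate functions reproduce the reported parametrization", {
  r0 <- rates_from_voltage(k0, 0)
  expect_equal(r0[["beta_n"]], 0.125)
  expect_equal(r0[["alpha_h"]], 0.07)
  expect_equal(r0[["beta_m"]], 4)
  # pointwise agreement with the directly coded rate formulas on a V grid
  for (V in seq(-115, 55, by = 7.3)) {
    expect_equal(unclass(rates_from_voltage(k0, V)), reference_rates(V),
                 tolerance = 1e-12)
  }
})

test_that("removable singularities take the analytic limit", {
  # alpha_n at V = -k_an2: limit k_an1 * k_an3 = 0.1
  expect_equal(rates_from_voltage(k0, -10)[["alpha_n"]], 0.1)
  expect_equal(rates_from_voltage(k0, -25)[["alpha_m"]], 1.0)
  # continuity: evaluation just off the singularity agrees with the limit
  for (eps in c(-1e-6, 1e-6)) {
    expect_equal(rates_from_voltage(k0, -10 + eps)[["alpha_n"]], 0.1,
                 tolerance = 1e-6)
  }
  # rates stay finite and non-negative over the physiological range
  rr <- rates_from_voltage(k0, seq(-120, 60, by = 1))
  expect_true(all(is.finite(rr)))
  expect_true(all(rr >= 0))
})

test_that("rate evaluation validates input", {
  expect_error(rates_from_voltage(k0, NaN), "finite")
  expect_error(voltage_params(c(k_an3 = -1)), "denominator")
  expect_error(voltage_params(c(bogus = 1)), "named")
})

test_that("gating derivatives follow alpha(1-x) - beta x", {
  st <- c(n = 1, m = 0.5, h = 0)
  r <- gating_rates(alpha_n = 0.7, beta_n = 0, alpha_m = 0.3, beta_m = 0.3,
                    alpha_h = 0.5, beta_h = 0.1)
  d <- gating_derivatives(st, r)
  expect_equal(d[["dn"]], 0)        # fully open, no closing rate
  expect_equal(d[["dm"]], 0)        # alpha = beta at x = 0.5
  expect_equal(d[["dh"]], 0.5)      # alpha (1 - 0) - beta * 0
  expect_error(gating_derivatives(c(n = 1.5, m = 0, h = 0), r), "0, 1")
})

test_that("conductances follow n^4 and m^3 h", {
  expect_equal(conductances(c(n = 1, m = 0, h = 0))[["g_K"]],
               unname(consts0[["gbar_K"]]))
  expect_equal(conductances(c(n = 0, m = 1, h = 0))[["g_Na"]], 0)
  cg <- conductances(c(n = 0.5, m = 0.3, h = 0.7),
                     membrane_constants(gbar_K = 16, gbar_Na = 120))
  expect_equal(cg[["g_K"]], 16 * 0.5^4)  # = 1.0
  expect_equal(cg[["g_Na"]], 120 * 0.3^3 * 0.7)
})

test_that("steady-state gating is the fixed point", {
  r <- gating_rates(alpha_n = 0.2, beta_n = 0.2, alpha_m = 0, beta_m = 1,
                    alpha_h = 0.4, beta_h = 0.1)
  ss <- steady_state_gating(r)
  expect_equal(ss[["n_inf"]], 0.5)
  expect_equal(ss[["m_inf"]], 0)
  d <- gating_derivatives(c(n = ss[["n_inf"]], m = ss[["m_inf"]],
                            h = ss[["h_inf"]]), r)
  expect_equal(unname(d), c(0, 0, 0))
  expect_error(steady_state_gating(gating_rates(0, 0)), "degenerate")
  # resting n_inf at V = 0 cross-checked by long clamped integration
  r0 <- rates_from_voltage(k0, 0)
  ninf <- r0[["alpha_n"]] / (r0[["alpha_n"]] + r0[["beta_n"]])
  sim <- simulate_hh(k0, consts0, drive_schedule(0, 400, "clamp_V", 0),
                     c(0, 400), init = c(V = 0, n = 0.9, m = 0.1, h = 0.5))
  expect_equal(sim$n[2], ninf, tolerance = 1e-6)
})

test_that("membrane derivative implements the circuit equation", {
  # leak only: dV/dt = -(g_l (V - V_l))/C_M = -3
  cc <- membrane_constants(gbar_K = 0, gbar_Na = 0, g_l = 0.3, V_l = 0)
  st <- c(V = 10, n = 0, m = 0, h = 0)
  expect_equal(membrane_derivative(st, cc), -3)
  # at the reversal potential with only that species conducting: no force
  cc2 <- membrane_constants(gbar_K = 36, gbar_Na = 0, g_l = 0)
  expect_equal(membrane_derivative(c(V = 12, n = 1, m = 0, h = 0), cc2), 0)
  # applied current equal to the ionic current: no net change
  cur <- membrane_currents(c(V = -30, n = 0.4, m = 0.3, h = 0.5), consts0)
  expect_equal(membrane_derivative(c(V = -30, n = 0.4, m = 0.3, h = 0.5),
                                   consts0, I_applied = cur$I_i), 0)
  # component sum invariant
  expect_equal(cur$I_i, cur$I_Na + cur$I_K + cur$I_l)
})

test_that("clamped simulation matches the analytic gate solution", {
  tg <- seq(0, 12, by = 0.1)
  x0 <- resting_state()
  for (d in c(6, 25, 63, 109)) {
    r <- rates_from_voltage(k0, -d)
    sim <- simulate_hh(k0, consts0, drive_schedule(0, 12, "clamp_V", -d),
                       tg, x0)
    n_ref <- gate_closed_form(r[["alpha_n"]], r[["beta_n"]], x0[["n"]], tg)
    m_ref <- gate_closed_form(r[["alpha_m"]], r[["beta_m"]], x0[["m"]], tg)
    h_ref <- gate_closed_form(r[["alpha_h"]], r[["beta_h"]], x0[["h"]], tg)
    expect_lt(max(abs(sim$n - n_ref)), 1e-5)
    expect_lt(max(abs(sim$m - m_ref)), 1e-5)
    expect_lt(max(abs(sim$h - h_ref)), 1e-5)
    expect_equal(sim$V, rep(-d, length(tg)))  # clamp is exact
  }
})

test_that("clamping at the resting fixed point leaves the state constant", {
  tg <- seq(0, 12, by = 0.5)
  sim <- simulate_hh(k0, consts0, drive_schedule(0, 12, "clamp_V", 0), tg)
  for (col in c("V", "n", "m", "h", "g_K", "g_Na"))
    expect_lt(diff(range(sim[[col]])), 1e-7)
})

test_that("simulation output is invariant to sampling-grid refinement", {
  sched <- drive_schedule(0, 12, "clamp_V", -25)
  t1 <- seq(0, 12, by = 0.1)
  t2 <- seq(0, 12, by = 0.05)
  s1 <- simulate_hh(k0, consts0, sched, t1)
  s2 <- simulate_hh(k0, consts0, sched, t2)
  idx <- seq(1, length(t2), by = 2)
  rel <- abs(s2$g_K[idx] - s1$g_K) / pmax(abs(s1$g_K), 1e-9)
  expect_lt(max(rel), 1e-6)
})

test_that("free-running dynamics show the clamp-25 conductance shapes", {
  vc <- run_voltage_clamp(k0, 25)
  gna <- vc$Na$g
  peak <- which.max(gna)
  expect_gt(peak, 1)                     # rises ...
  expect_lt(peak, length(gna))           # ... then decays
  expect_lt(gna[length(gna)] , 0.25 * max(gna))
  expect_true(all(diff(vc$K$g) >= -1e-9))  # g_K monotone to plateau
})

test_that("gating bounds hold for prior-drawn parameters (property)", {
  set.seed(7)
  settings <- default_abc_settings("full", "K")
  sNa <- default_abc_settings("full", "Na")
  for (i in 1:8) {
    kk <- c(sample_prior(settings$prior, 1)[1, ],
            sample_prior(sNa$prior, 1)[1, ])
    sim <- simulate_hh(voltage_params(kk), consts0,
                       drive_schedule(0, 12, "clamp_V",
                                      -sample(c(6, 40, 109), 1)),
                       seq(0, 12, by = 0.2))
    g <- as.matrix(sim[, c("n", "m", "h")])
    expect_gt(min(g), -1e-6)
    expect_lt(max(g), 1 + 1e-6)
  }
})

test_that("steady-state-initialized clamp stays fixed over 1000 ms", {
  V <- -40
  ss <- steady_state_gating(rates_from_voltage(k0, V))
  init <- c(V = V, n = ss[["n_inf"]], m = ss[["m_inf"]], h = ss[["h_inf"]])
  sim <- simulate_hh(k0, consts0, drive_schedule(0, 1000, "clamp_V", V),
                     c(0, 250, 500, 1000), init)
  drift_K <- diff(range(sim$g_K)) / max(sim$g_K)
  drift_Na <- diff(range(sim$g_Na)) / max(sim$g_Na)
  expect_lt(drift_K, 1e-5)
  expect_lt(drift_Na, 1e-5)
})

test_that("schedule construction is validated", {
  expect_error(drive_schedule(0, 1, "warp"), "kind")
  expect_error(drive_schedule(c(0, 2), c(1, 3), "free"), "contiguous")
  expect_error(simulate_hh(k0, consts0, drive_schedule(0, 1, "free"),
                           c(0.5, 0.2)), "increasing")
})

test_that("voltage-convention converter maps displacement to modern V_m", {
  expect_equal(hh_to_modern(0), -65)       # rest
  expect_equal(hh_to_modern(-90), 25)      # 90 mV depolarized
  expect_equal(hh_to_modern(30), -95)      # 30 mV hyperpolarized
})
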