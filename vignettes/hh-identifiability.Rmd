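---
title: "Methods: ABC-SMC identifiability analysis of the Hodgkin-Huxley model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ABC-SMC identifiability analysis of the Hodgkin-Huxley model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the model and its assumptions, the inference algorithm, the synthetic-data
generator, and the design choices made where the design was genuinely open.
It states no empirical result that the test suite or the acceptance script
does not itself compute.

## The model

The membrane is an electrical circuit: capacitive current plus three ionic
currents (sodium, potassium, leak), each ohmic with respect to its reversal
potential. Potassium conductance is gated as $g_K = \bar g_K n^4$ and
sodium as $g_{Na} = \bar g_{Na} m^3 h$, with each dimensionless gate $x$
relaxing as $dx/dt = \alpha_x(1-x) - \beta_x x$. The package implements two
forms:

* **simplified** — the six rates $\alpha_n \dots \beta_h$ are constants
  (1/ms). Under a clamped voltage this is exact: each gate follows
  $x(t) = x_\infty - (x_\infty - x_0)e^{-(\alpha+\beta)t}$, which the test
  suite uses as an independent analytic oracle against the numerical
  integrator.
* **full** — the rates are voltage-dependent with 14 constants: three
  `(V + k_2)/(\exp((V+k_2)/k_3)-1)`-type activation forms, three
  exponential forms, and a logistic inactivation form. The defaults are the
  canonical 1952 values (`hh_default_params()`).

**Sign convention.** $V$ is the displacement of membrane potential from
rest; rest is $V=0$ and a depolarization of $d$ mV sets $V=-d$. The printed
rate functions are only physiological under this convention. A converter to
the modern convention (`hh_to_modern()`, $V_m = V_{rest} - V$) is provided
for presentation only.

**Constants.** Membrane constants are configuration, not fitted: defaults
$C_M = 1\,\mu F/cm^2$, $\bar g_K = 36$, $\bar g_{Na} = 120$,
$g_l = 0.3\ mS/cm^2$, $V_{Na} = -115$, $V_K = +12$, $V_l = -10.613$ mV.
These are the values the original squid-axon work reports; the leak
reversal was chosen there so that $V=0$ is (very nearly) the resting fixed
point — the true equilibrium of the default parametrization sits about
0.004 mV away, which is why settled protocol traces start within a few
thousandths of a millivolt of zero rather than exactly at it. The resting
gate values $n_0=0.3177$, $m_0=0.0529$, $h_0=0.5961$ are the steady state
of the reported rates at $V=0$.

## Numerics

No ODE-solver package ships with the supported environment, so the package
carries a Dormand–Prince 5(4) adaptive integrator with fifth-order dense
output in compiled code (`src/hh_ode.cpp`). Choices that matter:

* relative tolerance $10^{-6}$, absolute $10^{-8}$; dense output means the
  0.01–0.1 ms sampling grids never constrain step size. ABC-SMC needs of
  order $10^5$ trace simulations per fit, which is why the dynamics are
  compiled.
* the removable singularity of the activation form at $V = -k_2$ is
  replaced by its analytic limit $k_1 k_3$ inside a guard band
  $|V + k_2| < 10^{-7} k_3$, for reproducibility across platforms.
* exponential arguments are clamped to $\pm 500$ (overflow begins near
  709); nothing a Table-1 prior can produce on $V \in [-120, 60]$ comes
  near the bound.
* voltage-clamped segments hold $V$ exactly (the gate subsystem is
  integrated; $V$ is pinned), and "instantaneous depolarization" is a
  discontinuous state reset at a segment boundary, not a brief clamp.
  A sample time falling exactly on a boundary reports the post-reset state.
* solver failure raises a condition of class `hh_integration_error`; the
  ABC layer treats it as a rejection, and ensemble protocol runs record it
  per particle without aborting.

## Protocols

The voltage-clamp protocol starts from the fixed configured resting state
(a flag switches to self-consistent steady-state initialization) and clamps
immediately for 12 ms, recording both conductances every 0.1 ms. The four
advanced protocols settle 1000 ms first, so each candidate parametrization
reaches its own steady state before the stimulus; the settle is
configurable because tests shorten it for speed.

The oscillation-induction current amplitude is stored as printed,
$-1.49\ mA/cm^2$. That magnitude is physiologically anomalous for this
preparation (classic sustained currents are of order $\mu A/cm^2$), so the
unit system is exposed (`units = "uA"`) rather than silently corrected;
the default follows the printed text. Under it the membrane spikes
repetitively during the clamp, which satisfies the damped-oscillation
predicate (at least two sign changes of $dV/dt$), but the trace is still
about 4 mV from rest at the 25 ms mark — a "returns within 1 mV of rest"
expectation does not hold under the printed amplitude and is not asserted.

The threshold-excitation entry "−10 mV depolarization" is read under the
sign convention as a 10 mV hyperpolarization.

Action-potential detection is a peak-displacement threshold, default
50 mV: responses are bimodal (few-mV subthreshold decay vs ~90–100 mV
spike), so any mid-range cut is robust, and the test suite sweeps the
threshold over 30–80 mV to show the verdict for the 6-vs-7 mV pair does
not move.

## ABC-SMC and the adaptive tolerance schedule

Generation 0 is $N$ unconditioned prior draws with uniform weights $1/N$.
Each later generation resamples the previous population by weight,
perturbs each draw with a zero-mean Gaussian kernel (redrawing until the
result is inside the prior box), simulates, and accepts when the distance
is at most $\epsilon_t$. Weights follow the standard SMC importance form
$w_i \propto \pi(\theta_i) / \sum_j w_j K(\theta_i - \theta_j)$, which
under uniform priors reduces to the "probability of obtaining the particle
as a perturbed draw from the previous estimate" up to a constant.

The distance is the RMSE between observed and simulated conductance at the
observed sample times (the printed formula is a mean of squares, but the
surrounding text and result tables call the metric RMSE; `type = "mse"` is
available). Multi-trace fits average the per-trace RMSE over the $M$
traces. Grids must match exactly; the package never interpolates silently.

The tolerance schedule: $\epsilon_0$ is the maximum distance in generation
0 (the schedule's "initial 0.5 quantile" then corresponds to the first
halving); each generation first attempts $\epsilon_t = 0.5\,
\epsilon_{t-1}$; if the population cannot be filled within `max_draws`
proposals (default 10 000, counted per generation attempt, with the
partial population discarded on failure), the deficit is halved,
$\epsilon_t \leftarrow \epsilon_{t-1} + 0.5(\epsilon_t - \epsilon_{t-1})$,
and the run terminates when the attempted improvement falls below
$\tau = 0.003$.

**Priors and kernels.** Priors are the published table: uniform, roughly an
order of magnitude wider than each reported value. The kernel table admits
two readings — "N(0, 0.1)" as variance 0.1 or as standard deviation 0.1 —
and the package default is the standard-deviation reading (0.1 on a
unit-width prior, 10 on a 99-wide prior: each 10 % of the width, and the
scale convention of most sampling libraries, including the one the
original analysis was implemented in). The readings are distinguishable on
published numbers alone: a posterior with standard deviation $\sim 0.002$
on a unit-width prior, maintained by 100 particles within 10 000 proposals
per generation, implies a per-proposal acceptance rate of order $10^{-2}$
under sd-0.1 jumps but of order $10^{-4}$ under sd-0.32 (variance 0.1)
jumps — the latter cannot fill a population inside the stated budget, so
fits under the variance reading stall at visibly larger tolerances with
inflated posterior widths. Any other scaling is one `kernel_spec()` call
away (it takes variances).

**Fitting granularity.** Under clamped voltage the two conductances are
decoupled, so simplified-model fits are per depolarization — $(\alpha_n,
\beta_n)$ against the potassium trace, $(\alpha_m, \beta_m, \alpha_h,
\beta_h)$ against the sodium trace — and full-model fits are per species:
5 potassium parameters against all potassium traces, 9 sodium parameters
against all sodium traces.

## Synthetic data

The historical conductance recordings exist only as printed figures, so
the generator emulates them rather than reproducing them: for each
depolarization it simulates the clamp under known true parameters,
optionally decimates (sparse digitization), adds seeded Gaussian noise and
clips negative conductances to zero. Defaults state the emulated world
once:

* depolarization sets 109…6 mV (twelve values spanning the historical
  range; the exact magnitudes are representative, not asserted as
  historical), with the 6 mV potassium trace excluded by default —
  mirroring the published exclusion of the smallest potassium plot for
  lack of a reliable axis scale — leaving $M = 11$ potassium and $M = 12$
  sodium traces;
* 12 ms traces sampled every 0.1 ms;
* noise s.d. 2 % of each trace's maximum (digitization error is
  uncharacterized; an absolute mode exists). Ground truth always travels
  with the dataset.

What a green recovery test establishes is therefore limited: the generator
shares the simulator's model family (no model mismatch), its noise is
i.i.d. Gaussian (digitization error is not), and the depolarization grid
is idealized. Green means the inference machinery recovers parameters in a
well-specified world, not that the historical analysis is validated.

For the single-clamp recovery experiment the acceptance suite uses the
100 mV trace: it is the largest default-set depolarization whose
generating rates lie strictly inside the prior box. At 109 mV the
generating $\alpha_n = 0.990$ sits essentially on the U(0, 1) prior
boundary, and any finite-tolerance posterior mean is then biased downward
by truncation alone — a property of the prior, not of the sampler under
test.

## Posterior analysis and the identifiability rule

Summaries are weighted: means, variances and 5th/95th percentiles from the
left-continuous inverse of the weighted empirical CDF (the published
tables do not state their estimator; unweighted versions are a flag away).
Relative spread is the 90-percentile width divided by the prior width.
Rate-curve ensembles evaluate the six rate functions per particle on a
voltage grid with pointwise weighted bands; correlations are weighted
Pearson, with degenerate cases (zero variance, weight mass on one
particle) reported as `NA` rather than numbers.

The classifier encodes the verbal argument of the source analysis as an
auditable rule. Per parameter: relative spread below $s_0$ —
*identifiable*; spread at least $s_0$ with output variation at least $v_0$
and maximum absolute pairwise correlation below $c_0$ —
*practical-unidentifiable* (the output still responds to the parameter and
no compensating relationship exists); otherwise *structural-candidate*.
The output-variation score isolates a parameter's contribution by pooling
the bottom and top weighted terciles of that parameter and averaging, over
the voltage grid, the weighted coefficient of variation of the rate curve
the parameter enters.

Thresholds: $v_0 = 0.1$ and $c_0 = 0.9$ are conventional cuts. For $s_0$
the published potassium posterior itself is the calibration: its
90-percentile spreads over prior widths are 0.007 and 0.154 for the two
parameters judged well constrained, and 0.189, 0.35, 0.47 for the three
judged unidentifiable, so the default is the separating value
$s_0 = 0.18$. (An initially considered $s_0 = 0.5$ would label all five
potassium parameters identifiable, contradicting the published verdict; a
single global threshold also cannot reproduce the sodium-side judgement on
its 0.12-spread inactivation parameter — thresholds are configurable and
every report carries the raw diagnostics so labels are auditable.)

## Known limitations

* The adaptive schedule with fixed kernels stalls at a tolerance set by
  the kernel-to-posterior width ratio, not by the data; posterior widths
  near the stall should be read as upper bounds on what the data allow.
* No temperature correction, no propagating-axon geometry, no stochastic
  channel noise, no joint potassium-plus-sodium fitting with a combined
  distance, and no re-tuning of the leak conductance per posterior (the
  leak is a catch-all set after the conductance fits in the original
  work; ensemble protocol responses inherit whatever mismatch that
  implies).
* Identifiability labels are heuristic classifications of diagnostics, not
  formal profile-likelihood or Fisher-information statements.
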