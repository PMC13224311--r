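---
title: "Dynamics-informed priors for neural mass spectral inference: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamics-informed priors for neural mass spectral inference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipdcm)
```

## The inference problem

Resting and task M/EEG power spectra are shaped by the lumped synaptic
physiology of cortical circuits: how strongly excitatory and inhibitory
populations couple, how quickly their post-synaptic potentials decay, how
steeply membrane potential converts to firing. Neural mass models encode
these quantities as parameters of a small differential-equation system, and
fitting the model's predicted spectrum to a measured one turns spectral
differences between conditions (drug vs. baseline, patients vs. controls)
into mechanistic statements about synaptic time constants or gains.

The catch is that the map from parameters to spectra is many-to-one.
Distinct parameter configurations can produce spectra that differ by less
than the measurement noise, so a local Bayesian fit started from one prior
finds one of the explanations and silently ignores the others. This package
implements a two-step hybrid estimator that addresses exactly that failure
mode: a multi-objective genetic algorithm first maps the bounded parameter
space to model dynamics, and its best solutions then seed a family of
variational-Laplace inversions whose Gaussian posteriors are averaged into
an equal-weight mixture. The mixture retains every parameter regime the data
support, including multimodal ones a single Gaussian posterior cannot
express.

## The neural mass model

`nmm_params()` parameterises a three-population cortical column: spiny
stellate cells (the input layer), inhibitory interneurons, and pyramidal
cells (the observed output). Each of the five synaptic channels (stellate
excitatory; interneuron excitatory and self-inhibitory; pyramidal excitatory
and inhibitory) obeys the critically damped second-order kernel

$$\ddot v = \frac{H}{\tau}\,u(t) - \frac{2}{\tau}\dot v - \frac{v}{\tau^2},$$

with excitatory channels sharing $(H_e, \tau_e)$ and inhibitory channels
$(H_i, \tau_i)$. Drives are sigmoid-transformed membrane potentials weighted
by the intrinsic gains $G_1$–$G_5$ (pyramidal→stellate, stellate→pyramidal,
pyramidal→interneuron, interneuron→pyramidal, interneuron self), delayed by
the intrinsic conduction delay $D_i$. The wave-to-pulse sigmoid
$S(v) = \sigma(R_1(v - R_2)) - \sigma(-R_1 R_2)$ is baseline-subtracted so
that the resting state $v = 0$ is an exact equilibrium for any parameter
values; slow adaptation currents present in some published variants are
deliberately omitted — the state vector holds only the five second-order
synaptic pairs (10 states), which is sufficient for the spectral
observations this package targets.

All parameters are estimated on the log scale: the physical value of entry
$i$ is $s_i e^{\theta_i}$ with fixed positive scale factors $s_i$
(`default_param_table()`), which enforces positivity and gives every
parameter comparable numerical magnitude. Default scales are
$\tau_e = 4$ ms, $\tau_i = 16$ ms, $H_e = 8$ mV, $H_i = 32$ mV, gains
$128 \cdot \{1, 0.8, 0.5, 0.5, 0.25\}$, $R_1 = 0.5$ mV$^{-1}$, $R_2 = 3$ mV
and $D_i = 10$ ms. The inhibitory-loop gains were chosen so that the default
operating point is stable and exhibits an alpha-band (≈10.5 Hz) spectral
peak on the 2–45 Hz analysis grid, the qualitative regime of resting-state
recordings; the editable parameter table lets a user substitute any other
published calibration.

## The observation function

The shared forward model of every estimator is the log power spectral
density of the linearised circuit. Because the rest state is an exact
equilibrium at zero mean input, linearisation is exact at the origin:
`observe_log_psd()` evaluates the closed-loop transfer function from the
stochastic input to the pyramidal potential,

$$T(\omega) = \frac{k_e^2\, c_2\, d}{1 - k_e^2 c_1 c_2 d^2 +
  \frac{k_e k_i c_3 c_4 d^2}{1 + k_i c_5 d}},$$

where $k_e, k_i$ are the synaptic kernel responses, $c_j = G_j S'(0)$ the
linearised coupling gains and $d = e^{-i\omega D_i}$ the exact delay phase
factor applied to every sigmoid-mediated coupling (a delay outside the
feedback loops would cancel in the squared magnitude and is therefore
spectrally meaningless). The PSD $|T|^2 g_u(\omega)$ uses a white innovation
spectrum by default; a $1/f^{\nu}$ component can be switched on, with the
exponent exposed as a model parameter. The PSD is normalised to unit area
over the frequency grid by the rectangular rule — the same convention applied
to data — and log-transformed, which removes overall gain
(`obs_gain`, `input_gain`) from the normalised observation.

Two independent routes to this quantity are kept in the test suite: the
closed-form loop reduction above and a per-frequency matrix resolvent
$C(i\omega I - A_0 - A_d e^{-i\omega D_i})^{-1}B$ built from the analytic
state Jacobian, which agree to machine precision. A third, fully independent
oracle is the stochastic simulator (`simulate_timeseries()`): each channel
is advanced by its exact zero-order-hold propagator (a first-order Euler
scheme adds artificial damping at beta frequencies with millisecond steps),
and the Welch spectrum of a 200 s run matches the transfer-function spectrum
to better than 0.1 RMSE in log units over 4–40 Hz.

Stability screening in the optimisation hot path uses a Routh–Hurwitz test
on the degree-6 closed-loop characteristic polynomial of the zero-delay
linearisation, vectorised across whole populations; it agrees with the
eigenvalues of the full 10×10 Jacobian on randomised draws. Delay effects on
stability are neglected for screening (the delays here are ~10 ms against
kernel time constants of 4–16 ms); an unstable set is flagged, not an error,
and receives the penalty objective value $10^6$ so that dominance sorting in
the genetic search remains well defined while the search traverses unstable
regions.

## Step 1: multi-objective genetic search

`nsga2_evolve()` minimises two band-limited squared-error objectives
$J_1 = \sum_{\omega \in \Omega_1}(y - \hat y)^2$ and
$J_2 = \sum_{\omega \in \Omega_2}(y - \hat y)^2$ over closed log-scale
bounds ($[-1, 0.85]$ per parameter by default), using NSGA-II: fast
non-dominated sorting, crowding-distance selection, simulated-binary
crossover (probability 0.9, index 15) and polynomial mutation (probability
$1/d$, index 20), population 60. The two bands are study presets
(`study_preset()`): alpha/beta 6.5–12.5 and 11.5–30 Hz for resting EEG,
10.7–65.8 and 35.6–85 Hz for gamma-band MEG. Band membership is
closed-interval inclusion of grid points; objective-space distances are
computed on raw (unnormalised) $J$ values, with a min–max option for fronts
with very different objective scales.

From each realisation's Pareto front the solution nearest the objective
origin ($\min \sqrt{J_1^2 + J_2^2}$, ties to the lowest index) is selected,
and `ga_realisations()` repeats the whole search under fresh Latin-hypercube
initialisations (one sample per equal-width bin in every free dimension),
seeds `seed0 … seed0 + n − 1`, recording each selected solution with its
whole-band RMSE over the union span of the two bands. Every source of
randomness flows from these explicit seeds; a forked parallel run is
bit-identical to the serial one.

## Step 2: dynamics-informed priors and variational Laplace

`rank_and_select()` orders the realisations by whole-band RMSE (ties by
$J_1^2 + J_2^2$, then row order) and keeps the top $m$; duplicates are kept
deliberately, since all retained estimates are treated as equally plausible.
Each estimate becomes the mean of a Gaussian prior whose free-parameter
variances are all 1 on the log scale — wider than every "standard" prior
variance in the default table, so the subsequent inversion can actually move
every parameter.

`vl_invert()` maximises the negative variational free energy — Gaussian
log-likelihood of the log-PSD residuals (accuracy, with the Laplace
curvature correction $-\tfrac12\mathrm{tr}(\Sigma J^\top J e^{h})$) minus
the closed-form Gaussian KL complexity — by Levenberg–Marquardt-regularised
Gauss–Newton on central-difference sensitivities (step $10^{-4}$ in log
space). The regularisation is divided by 10 on accepted steps and multiplied
by 10 on rejections, so free energy over accepted iterations is
non-decreasing by construction. Residual noise is modelled with a single
shared log-precision hyperparameter $h$ with Gaussian prior
$\mathcal N(0, 16)$; its update solves the stationarity condition
$e^{h}\,\mathrm{ss}/2 = n/2 - (h - h_0)/v_h$ by safeguarded root finding and
is accepted only when it does not lower the free energy (a plain Newton step
overshoots catastrophically when residuals are near zero). Convergence:
$|\Delta F| < 10^{-2}$ on three consecutive accepted steps, at most 64
iterations, or a regularisation ceiling when no improving step remains. The
posterior covariance is the inverse curvature at the optimum; its diagonal
enters the mixture, the full matrix is retained as an attribute.

The $m$ posteriors are averaged into an equal-weight Gaussian mixture
(`average_posteriors()`); no evidence weighting is applied — the priors were
constructed to be equally plausible, so equal weights are the coherent
choice. Failed or unconverged inversions are dropped with a warning, and the
run errors out if more than 10% fail, which keeps the equal-weight scheme
honest. Marginal densities, CDFs, quantiles, mode counts and seeded sampling
are provided for downstream inference.

## Effect inference

`effect_table()` contrasts two conditions parameter by parameter:
independent draws (default $10^5$) from each condition's distribution — a
posterior mixture, a single Gaussian posterior, or the empirical table of GA
point estimates — are exponentiated and scaled to physical units before
differencing, so reported effects are in seconds or millivolts. The headline
effect is the signed mean difference (its absolute value and the mean
absolute difference are both reported, as the two readings of "mean absolute
difference" differ for multimodal marginals); uncertainty is the equal-tailed
95% credible interval, practical relevance is Cohen's $d$ with the pooled SD
taken as the root of the average variance. A parameter is selected only when
the interval excludes zero *and* $|d| \ge 0.2$. Draws are independent across
conditions — the posteriors are independent objects and no pairing exists.
No multiplicity correction is applied beyond the joint rule (a Bonferroni
switch exists for sensitivity analyses).

## Diagnostics: landscapes and profiles

`free_energy_profile()` scans one prior mean along a grid (the shipped
preset scans the stellate-coupling gain over $[-1, 0.85]$ in log space,
containing the standard prior at 0), runs a full inversion at each point,
and min–max scales the resulting free energies to $[0, 1]$ with the maximum
pinned at 1 (raw values retained; a single-point grid scales to 1 by
convention). `rmse_landscape()` maps band-restricted RMSE between a
reference spectrum and the model over a two-parameter grid and reports
strict 8-neighbourhood local minima, excluding penalty-marked unstable
cells; boundary cells are compared over their existing neighbours.

A structural feature of the model makes this diagnostic vivid: the sigmoid
rest slope $S'(0) = R_1\,\sigma_0(1-\sigma_0)$ is non-monotone in $R_1$
(it folds at $\log R_1 \approx 0.03$ under the default scales), so two
distinct $R_1$ values generate *identical* linearised spectra at the same
delay. A scan over $(R_1, D_i)$ from a reference at $\log R_1 = -0.5$ shows
two RMSE minima at $\log R_1 \approx -0.5$ and $\approx +0.44$ sharing the
delay coordinate. The two-step pipeline recovers both modes in the mixture
marginal while a single standard-prior inversion reports whichever basin its
prior falls into — the motivating failure case for dynamics-informed priors.

## The synthetic-data generator

`generate_spectrum()` adds independent Gaussian noise (default sd 0.1) on
the log scale to the model's unit-area log PSD at a known ground truth —
log-additive noise matches the scale on which objectives and likelihood
operate. `generate_condition_pair()` derives a second condition by log-space
shifts (`delta_map`), with independent noise and derived seeds; an empty map
yields the placebo-style null pair. `preprocess_epochs()` reduces raw epoch
series the way grand-average studies do: per-epoch PSD (rectangular-window
FFT periodogram at the epoch's native resolution, or Welch with a 512-sample
Hamming window and 50% overlap), unit-area normalisation per epoch,
arithmetic averaging *before* the log transform, re-normalisation, then log.

What the generator emulates — and what it does not. It reproduces
grand-average, unit-area, log-transformed spectra with homoscedastic
log-power noise at a realistic amplitude. Real spectra differ in ways that
matter for extrapolation: their noise is correlated across neighbouring
bins, subject averaging induces heavier tails, and above all the generating
process is *not* the fitted model. Passing recovery tests on realizable
synthetic data therefore demonstrates estimator correctness, not model
adequacy on real recordings. One consequence is measured honestly by the
acceptance suite: with a well-specified generator the genetic step already
attains the optimum of its own band objective (including the noise
component), so the variational refinement — which maximises whole-grid
evidence — cannot further reduce in-band RMSE, and the near-universal
RMSE improvement reported on real data reappears here only on noise-free
data (where the fraction is 1.0).

## Study designs used by the acceptance suite

*Parameter recovery* frees the synaptic time constants and conduction delay
$\{T_e, T_i, D_i\}$ at ground truth $(0.15, -0.1, 0.2)$ in log units, noise
sd 0.1, 100 GA realisations of 150 generations (population 60), top 20 as
priors, across 10 master seeds. The free set follows a power analysis: the
asymptotic (Cramér–Rao) per-parameter sd at this noise level is at most
0.085 log units for this set, whereas freeing the intrinsic gains pushes it
to ≈0.24 — near-flat likelihood ridges along which no estimator could meet a
0.15 recovery bound. Gains and sigmoid parameters are instead exercised by
the degeneracy study, which is designed to be ill-posed on purpose. The
150-generation budget is the reduced budget at which fit quality stabilises;
500 generations remain the package default for exploratory use.

*Degeneracy recovery* frees $(R_1, D_i)$ with the reference at
$(\log R_1, \log D_i) = (-0.5, 0.34)$, constructs the degenerate partner via
a 60×60 landscape scan (minima RMSE gap < 0.02), and checks that the mixture
marginal of $R_1$ is at least bimodal while the single inversion is
unimodal.

*Effect calibration* runs the full pipeline at reduced scale (16
realisations, 100 generations, population 40, 8 priors) on condition pairs:
null pairs must select no effect in ≥9/10 repetitions; a $-0.3$ log shift in
$T_e$ (≈26% faster excitatory decay, the direction of the anti-seizure-drug
effects the method was built to detect) must be selected as exactly
$\{T_e\}$ with the physical-scale mean difference within 25%.

Problem sizes throughout (200 s simulations, 60×60 scan grids, $10^5$
draws, the reduced-scale pipeline runs above) were chosen once as the
smallest sizes at which the corresponding asymptotics are comfortably
resolved.

## Numerical choices and limitations

- Unit-area normalisation uses the rectangular sum $\sum p_k\,\Delta f = 1$,
  not the trapezoid, so the normalisation identity holds bin-wise exactly;
  it is idempotent to $10^{-12}$.
- Fixed points for nonzero constant input use damped Newton iteration with
  up to 5 seeded random restarts, tolerance $10^{-9}$ on the derivative
  norm; at zero input the origin is exact.
- Finite-difference sensitivity steps ($10^{-4}$), the LM factor (10), the
  free-energy tolerance ($10^{-2}$ × 3 hits) and the mode-finding grid (512
  points, peaks ≥5% of the maximum) are fixed constants, documented here
  rather than exposed as tuning surfaces.
- Tie-breaks are deterministic everywhere: front selection takes the lowest
  index, ranking falls back to objective norm then row order, and a density
  peak landing exactly between two grid samples is reported once.
- The delay enters stability screening at zero delay; for delays large
  relative to the kernel time constants the Routh–Hurwitz screen could pass
  a delay-destabilised set (it would still be caught by the simulation
  oracle, not by the screen).
- Group-level inference operates on grand-average spectra, as in the studies
  this design follows; subject-level hierarchies, multi-region models with
  extrinsic connectivity, Bayesian model reduction and evidence-weighted
  model averaging are out of scope.
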