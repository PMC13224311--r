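# dipdcm

Hybrid global–local Bayesian estimation for neural mass models fitted to
M/EEG power spectra.

Neural mass models explain measured brain rhythms through lumped synaptic
parameters — excitatory/inhibitory time constants, intrinsic coupling gains,
firing thresholds. Fitting them is an ill-posed inverse problem: distinct
parameter regimes can generate indistinguishable spectra, so a local
Bayesian inversion started from one prior silently commits to one
explanation. `dipdcm` implements a two-step estimator that keeps all the
explanations the data support:

1. **Global search.** An NSGA-II multi-objective genetic algorithm minimises
   two band-limited squared-error objectives
   `J1 = Σ_{ω∈Ω1} (y(ω) − ŷ(ω))²`, `J2 = Σ_{ω∈Ω2} (y(ω) − ŷ(ω))²`
   between the data log PSD `y` and the model log PSD `ŷ` over closed
   log-scale bounds, repeated for `n` Latin-hypercube-initialised
   realisations; each run contributes the Pareto-front solution closest to
   the objective origin.
2. **Local exploitation.** The top `m` solutions (ranked by whole-band RMSE)
   become means of unit-variance Gaussian priors — *dynamics-informed
   priors* — each refined by a variational-Laplace inversion that maximises
   the negative free energy (accuracy − complexity). The `m` Gaussian
   posteriors are averaged into an equal-weight mixture that can be
   multimodal where the problem is degenerate.

Group-level effects between conditions are then summarised per parameter
from `1e5` mixture draws on the physical scale: mean difference, 95%
equal-tailed credible interval, and Cohen's *d*, with an effect selected
when the interval excludes zero and `|d| ≥ 0.2`.

The generative model is a three-population cortical column (spiny stellate,
inhibitory interneuron, pyramidal) with second-order synaptic kernels, five
intrinsic gains, a baseline-subtracted wave-to-pulse sigmoid and an
intrinsic conduction delay; its observation function is the
unit-area-normalised log PSD of the linearised circuit's transfer function.
Diagnostic tools map free-energy profiles along prior-mean axes and RMSE
landscapes over parameter pairs, with local-minimum detection for
identifying degenerate solution pairs.

## Worked example

Generate a synthetic spectrum at a known ground truth, run the two-step
pipeline at reduced scale, and inspect the recovered mixture:

```r
library(dipdcm)

p <- nmm_params(free_mask = c(Te = TRUE, Ti = TRUE, Di = TRUE,
                              He = FALSE, Hi = FALSE, G1 = FALSE, G2 = FALSE,
                              G3 = FALSE, G4 = FALSE, G5 = FALSE, R1 = FALSE,
                              R2 = FALSE, input_gain = FALSE))
truth <- set_theta(p, c(Te = 0.15, Ti = -0.1, Di = 0.2))
dat <- generate_spectrum(synthetic_spec(truth, noise_sd = 0.1, seed = 1))

res <- run_dip(dat, default_bounds(), study_preset("study1")$bands,
               params = p, n = 20, m = 8,
               control = ga_control(pop_size = 60, n_generations = 150),
               seed0 = 100)

round(sapply(c("Te", "Ti", "Di"), function(nm) {
  c(truth   = truth$theta_log[[nm]],
    mixture = mean(sapply(res$mixture$components, function(cc) cc$mean[[nm]])))
}), 3)
#>            Te     Ti   Di
#> truth   0.150 -0.100 0.20
#> mixture 0.143 -0.074 0.19
```

The mixture means land within a few hundredths of a log unit of the
generating values: on this identifiable three-parameter problem the genetic
step localises the optimum basin and the variational step sharpens it.
`res$report` records, per inversion, the GA seed's whole-band RMSE, the
posterior RMSE, the free energy and convergence; `mixture_quantile()`,
`mixture_modes()` and `effect_table()` take the analysis from there.

A thin command-line wrapper is installed under `inst/cli/dipdcm`
(subcommands `simulate`, `ga`, `invert`, `dip`, `effects`, `profile`,
`landscape`).

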