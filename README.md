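# ornmix

Biophysical and statistical modeling of mammalian olfactory receptor
neuron (ORN) responses to odorants and their mixtures, for computational
neuroscientists studying olfactory coding and for modelers who need a
tested, seed-reproducible mixture-response simulator.

Natural odors are mixtures, and mixture components interact at the very
first synapse-free stage of olfaction: they compete for receptors, and
some additionally *mask* the downstream transduction channels. `ornmix`
implements the full chain from channel kinetics to perception-level
read-outs:

* **Transduction kinetics** — a stiff ODE model of the ORN cascade
  (two-step receptor binding/activation, cAMP production, cooperative CNG
  channel gating, Ca²⁺ dynamics, Ca-calmodulin feedback) reproducing
  response latency, sigmoidal peak responses and slow adaptation.
* **Mixture algebra** — every odorant-receptor pair reduces to a
  sensitivity scale κ and an activation efficacy η, with the peak response
  `F(C) = Fmax / (1 + ((1 + C/κ)/(η C/κ))^n)` and exact effective mixture
  parameters `κ_mix⁻¹ = Σ βᵢ κᵢ⁻¹`, `η_mix = κ_mix Σ ηᵢ βᵢ κᵢ⁻¹`, plus the
  dominant-component approximation and its error analysis.
* **Masking** — competitive occupancy of membrane masking sites scales the
  efficacy by `χ_M = (1 − Σ μᵢ M̃ᵢ)^m`, producing synergy and inhibition
  that pure receptor competition cannot.
* **Population encoding** — ensembles of N = 250 receptor types with
  correlated log-normal sensitivities and efficacies; the antagonism
  factor ρ = Corr(log κ⁻¹, log η) tunes the code from an OR gate (ρ = 1)
  to a normalized, sparsity-preserving code (ρ = 0).
* **Information and decoding** — Monte-Carlo mutual information for
  figure-ground segregation (with an exact enumeration oracle), optimal-ρ
  scans, ridge-logistic classifier panels with generalized ROC curves,
  and noisy discrimination experiments.
* **Psychophysics** — concentration inference from glomerular
  recruitment, inhibition/synergy of perceived intensity, symmetric and
  asymmetric suppression, masking and overshadowing.

All inputs are synthetic and every stochastic experiment takes an integer
seed; identical seeds reproduce results bit for bit.

## A worked example

```r
library(ornmix)

# an odorant-receptor pair and its steady-state profile
kin <- or_kinetics(k1 = 100, k_neg1 = 100, k2 = 2, k_neg2 = 2)
params <- transduction_params()
kinetics_to_profile(kin, params)
#> <ss_profile> kappa = 0.5 (sensitivity 2), eta = 10

# simulate a 4-s odor pulse and summarize the transient
pulse <- stimulus_protocol(odorant = 1, conc = 1, onset = 1, offset = 5,
                           duration = 8)
ts <- simulate_orn(kin, params, pulse)
unlist(response_summary(ts))
#>       peak    latency
#> 0.01495379 0.26100000
```

The pulse elicits a transient that peaks at ~1.5% of the maximal rate 261
ms after odor onset and then adapts away — Ca-calmodulin feedback
terminates the response long before the cascade's feedback-free steady
state.

```r
# competitive mixture: the response stays between the component curves
mix <- mixture_spec(kappa = c(0.5, 0.5), eta = c(10, 1), conc = c(5, 5))
c(A_alone = single_odorant_rate(10, kappa = 0.5, eta = 10),
  mixture = mixture_rate(mix),
  B_alone = single_odorant_rate(10, kappa = 0.5, eta = 1))
#>   A_alone   mixture   B_alone
#> 0.9998785 0.9986734 0.4513641
```

The weak activator B drags the mixture response below A's curve
(competitive antagonism) but never below its own — synergy or inhibition
require masking (see `masked_mixture_curves()`).

```r
# antagonism normalizes the population response (fraction of active
# glomeruli for mixtures of 1, 10, 100 components, each alone activating
# 30% of the glomeruli)
cfg0 <- ensemble_config(rho = 0, p = 0.3)   # antagonistic
cfg1 <- ensemble_config(rho = 1, p = 0.3)   # no antagonism
rbind(antagonistic = fraction_active_vs_complexity(cfg0, c(1, 10, 100),
        trials = 10, seed = 1)$fraction_active,
      or_gate = fraction_active_vs_complexity(cfg1, c(1, 10, 100),
        trials = 10, seed = 1)$fraction_active)
#>                [,1]   [,2]   [,3]
#> antagonistic 0.3032 0.3232 0.3296
#> or_gate      0.3032 0.9492 1.0000

# ... which preserves information about a target odorant in a
# 64-odorant background
for (rho in c(0, 1)) {
  task <- segregation_task(ensemble_config(rho = rho, p = 0.5),
                           background_model(fixed = 64), seed = 11)
  est <- mutual_information(task, seed = 13)
  cat(sprintf("rho = %d: I(T; z) = %.3f +/- %.3f bits\n", rho, est$mi, est$se))
}
#> rho = 0: I(T; z) = 0.287 +/- 0.004 bits
#> rho = 1: I(T; z) = 0.000 +/- 0.000 bits
```

Without antagonism the glomerular code saturates under a complex
background and carries no information about the target; the antagonistic
code stays sparse and keeps about a third of a bit per sniff.

Config-driven experiments (tidy CSV outputs plus a JSON manifest) run
through `run_experiment()` or the thin CLI wrapper in `inst/cli/ornmix`:

```sh
Rscript inst/cli/ornmix mixture-error --config cfg.json --seed 1 --out out/
```

See the methods vignette (`vignettes/ornmix-methods.Rmd`) for the model's
assumptions, parameter meanings and defaults, numerical choices, and known
limitations.

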