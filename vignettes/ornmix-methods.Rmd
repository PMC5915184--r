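---
title: "Modeling olfactory receptor neuron responses to odor mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling olfactory receptor neuron responses to odor mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ornmix)
```

## The model

`ornmix` simulates how mammalian olfactory receptor neurons (ORNs) respond
to single odorants and to mixtures, and what receptor-level *antagonism* in
mixtures does to the population code carried by the glomeruli.

### Transduction kinetics

Each odorant binds its receptor in a two-step scheme, `R + X <-> RX <-> RX*`,
with forward/backward rates `k1, k_neg1` (binding) and `k2, k_neg2`
(activation). Activated receptors produce cAMP at rate `kC` (degraded at
`dC`); cAMP opens cyclic-nucleotide-gated (CNG) channels cooperatively, which
we treat as an instantaneous Hill function with coefficient `n = 4` (one per
cAMP binding site) and lumped half-activation constant `kG` — the
strong-cooperativity limit, in which channels are either unbound or fully
bound. Open channels admit Ca²⁺ (influx `kCa`, extrusion `dCa`); Ca²⁺ binds
calmodulin and the Ca-CaM complex feeds back on the channel,
`kG -> kG / (1 + (CaCaM/CaCaM0)^2)`, which terminates the response and
produces adaptation. The firing rate is taken proportional to the
Ca²⁺-gated Cl⁻ current with a linear current map, normalized so that the
feedback-free steady state of a saturating stimulus equals the closed-form
saturation `Fmax / (1 + eta^-n)`.

Two derived parameters fully characterize an odorant-receptor pair at the
level of peak responses:

* the **sensitivity scale** `kappa = kappa1 * kappa2 / (1 + kappa2)` with
  `kappa1 = k_neg1/k1`, `kappa2 = k_neg2/k2` (concentration units; the
  sensitivity proper is `1/kappa`), and
* the **activation efficacy**
  `eta = kC * kG * Rtot / (dC * (1 + kappa2))` (dimensionless), which caps
  the saturating rate at `Fmax / (1 + eta^-n)`.

The peak/steady response to a single odorant at concentration `C` is

```
F(C) = Fmax / (1 + ((1 + C/kappa) / (eta * C/kappa))^n)
```

and a competitive mixture behaves like a single odorant with effective
parameters

```
kappa_mix^-1 = sum_i beta_i / kappa_i
eta_mix      = kappa_mix * sum_i eta_i * beta_i / kappa_i
```

where `beta_i` are concentration fractions. Because the response at a given
total concentration is a weighted compromise between the components, a
purely competitive mixture curve always lies between the component curves —
a strongly binding but weakly activating component drags the response down
(competitive antagonism), but the mixture can never leave the envelope.

Reference transduction parameters: `kC = 2/s`, `dC = 1/s`, `kG = 10`,
`CNGtot = 1`, `n = 4`, `kCa = 20/s`, `dCa = 0.5/s`, `kCaCaM = 1/s`,
`CaCaM0 = 0.05`, with receptor and channel counts and `Fmax` rescaled to 1.
The backward Ca-CaM rate is not constrained by the steady-state algebra; we
model Ca-CaM dissociation as first order with `kCaCaM_back = 0.05/s`
(time constant 20 s), which places recovery from adaptation at a few tens
of seconds. Both the forward and backward rates are exposed as parameters.

Numerical choices: stiff-capable `deSolve::lsoda`, relative tolerance 1e-6,
absolute 1e-9, integrated piecewise across the square-pulse discontinuities
on a fixed 1 ms output grid (coarser grids are used for long adaptation
protocols, where millisecond latency precision is irrelevant). Receptor
conservation is enforced algebraically (`R = Rtot - sum(B + A)`), so the
invariant holds to solver precision.

Two phenomenological caveats, both visible in simulations:

* With the reference feedback strength, Ca-CaM terminates the transient
  well below `Fmax` (peaks reach about 2% of `Fmax` at saturating
  concentration). A latency criterion fixed at a fraction of `Fmax` would
  therefore never fire; `response_summary()` measures latency as the first
  crossing of 5% of the *trial's own peak* by default, with an absolute
  (`Fmax`-referenced) criterion available.
* Ca-CaM continues to accumulate for a few seconds after stimulus offset
  (Ca²⁺ outlives the pulse), so paired-pulse recovery is non-monotone for
  interpulse intervals below ~5 s and monotone beyond; the adaptation
  experiments use intervals of 5 s and longer.
  `adaptation_protocol()` baseline-corrects the second-pulse peak by
  subtracting the single-pulse response so that the decaying tail of the
  first pulse is not mistaken for recovery.

### Masking

Some odorants additionally act as masking agents: they bind a limited pool
of sites on the ciliary membrane and lower the effective affinity of cAMP
for the CNG channel. Agents compete for the sites,
`Mtilde_i = KM_i M_i / (1 + sum_j KM_j M_j)`, and the combined suppression
factor `chi_M = (1 - sum_i mu_i Mtilde_i)^m` (clipped at zero; `m = j/n`
when `j` of the `n` channel subunits are affected, default 1) multiplies
the mixture efficacy: `eta_mix -> chi_M * eta_mix`. The microscopic
site-density, disruption-radius and binding-energy parameters are lumped
into `mu` and are not separate model inputs. Masking acts at the channel,
downstream of receptor identity, which is why `chi_M` scales the
whole-mixture efficacy rather than per-component efficacies.

Masking breaks the competitive envelope in both directions:

* **Inhibition** — a strong activator that also strongly binds and
  suppresses the masking sites (`eta = 5`, `KM = 1`, `mu = 0.7`) mixed
  with a clean weak activator (`eta = 1`, `KM ~ 0`): at high total
  concentration the mixture falls below both single-odorant curves.
* **Synergy** — a strong activator whose masking sites are instead blocked
  by the companion: the strong component self-masks (`eta = 5`,
  `KM = 1e-5`, `mu = 0.7`) while the weak companion occupies the sites
  harmlessly (`KM = 0.1`, `mu = 0`); mixing relieves the strong
  component's self-suppression and the mixture exceeds both single curves
  at high concentration.

These two reference pairs (both with `kappa_A = kappa_B = 1`) are provided
by `generate_fixtures()` and exercised in the test suite.

### The encoding ensemble and the antagonism factor

An odorant is a pair of `N = 250`-dimensional vectors over receptor types:
`log kappa^-1 ~ N(0, sigma_kappa^2)` with `sigma_kappa = 4` (natural log —
about six orders of magnitude between the most and least sensitive
receptors) and `log eta ~ N(0, 1)` (an exponential efficacy distribution is
also available through a Gaussian copula). The **antagonism factor**
`rho` is the correlation between the two: a latent normal `u` sets the
efficacy and `log kappa^-1 = sigma_kappa * (rho * u + sqrt(1-rho^2) * omega)`.
At `rho = 1` the strongest binders are the strongest activators (no
antagonism; the ORN acts as an OR gate over mixture components); at
`rho = 0` binding and activation are independent and strong binders
routinely displace strong activators.

Saturating responses are `y = 1 / (1 + eta_mix^-n)`, binarized by the
threshold `tau = 1 / (1 + exp(-n * qnorm(1 - p)))` chosen so that a single
odorant activates a fraction `p` of the glomeruli (activation is the strict
inequality `y > tau`; ties have measure zero but the strict rule fixes
determinism). For general efficacy distributions the same construction uses
the `(1-p)`-quantile of `eta`.

**Exact versus dominant-component mixing.** Because sensitivities are
spread over many decades, the sum `sum_i beta_i kappa_i^-1` is typically
dominated by one component `M`, giving the approximation
`kappa_mix^-1 ~ beta_M kappa_M^-1`, `eta_mix ~ eta_M`. Its mean relative
error grows with mixture size and reaches roughly 40% for 128-component
equiproportionate mixtures (`approximation_error_experiment()`); variable
concentrations broaden the `beta_i kappa_i^-1` distribution and make the
approximation better, not worse. Several sharp statements about the
population code are exact only in the dominant-component regime, and
`saturating_response()`, `mixture_efficacy()`,
`fraction_active_vs_complexity()` and `eta_mix_distribution()` therefore
expose `method = "exact"` (default) and `method = "dominant"`:

* the OR-gate active fraction `1 - (1-p)^K` at `rho = 1` is exact for the
  dominant path; the exact algebra smooths `eta_mix` and sits below the
  formula by up to ~0.07 at `p = 0.1` for mid-sized mixtures;
* normalization at `rho = 0` (the `eta_mix` distribution is invariant to
  mixture size) is exact for the dominant path (Kolmogorov-Smirnov
  distance ~0.01 between 1- and 100-component mixtures at 1e4 samples);
  the exact path narrows the distribution slightly (KS ~0.2) while
  remaining far from the `rho = 1` behavior, whose median shifts tenfold.

The acceptance tests assert the sharp claims on the dominant path and pin
the exact-path deviations at measured tolerances; both behaviors are part
of the model's documented phenomenology.

### Figure-ground segregation

The mutual information `I(T; z) = H(T) - H(T | z)` between the presence
`T` of a known target odorant (prior 1/2, so `H(T) = 1` bit) and the binary
glomerular pattern `z` is estimated by Monte Carlo. Background complexity
`nb` is either fixed or drawn from a discrete truncated exponential on
`1..128` with pmf proportional to `exp(-nb/lambda)`, `lambda` solved so the
mean is 32. Receptor types are statistically independent, so
`Pr(z | T, nb)` factorizes into per-receptor activation probabilities
`q_i(T, nb)`; these are pre-computed by sampling saturating
equiproportionate backgrounds (800 draws per background size by default,
shared across receptors through the background's sufficient statistics,
which leaves each estimate unbiased), clipped to `[1e-12, 1 - 1e-12]`
(an estimator bias of order 1e-12). `H(T | z)` is then the average binary
entropy of the Bayes posterior over sampled patterns, with all
likelihood sums in the log domain. For ensembles of up to 20 receptors
`exact_mutual_information()` enumerates all `2^N` patterns and serves as
the oracle for the Monte-Carlo estimator.

At `p = 0.5` and 64 background odorants the antagonistic code (`rho = 0`)
retains a few tenths of a bit about the target while the non-antagonistic
code (`rho = 1`) saturates and retains essentially none; with fluctuating
backgrounds the information-maximizing `rho*` is interior (below 1) at the
sparsity levels `p = 0.1–0.3` observed experimentally.

### Decoders

Linear classifiers `sigmoid(theta . z + b)` are trained by ridge-penalized
IRLS (penalty 1e-3 unless stated, intercept unpenalized, convergence
tolerance 1e-6 on the penalized deviance, 50-iteration budget) — written
in-package because saturating binary codes routinely produce perfect
separation, where unpenalized ML diverges; the implementation is checked
against `glm` on a non-separable fixture. Component separation trains one
classifier per panel odorant against backgrounds of 1–10 other panel
odorants and sweeps a shared detection threshold on test mixtures of 1–20,
yielding generalized ROC curves (hit rate versus false-positive count).
Noisy figure-ground discrimination perturbs the per-receptor efficacy as
`eta_mix -> (1 + eps) * eta_mix` with `eps ~ N(0, epsilon0^2)` truncated at
-0.99 (the distribution of the effective transduction noise is not
otherwise constrained; zero-mean Gaussian is our choice), with component
concentrations log-uniform over three decades.

Classifier quality matters for the orderings: with a few hundred training
trials the classifiers are undertrained on 250 inputs and both codes sit
near chance. At ~1200 balanced trials the antagonistic code wins noisy
figure-ground discrimination against 50-odorant backgrounds at 40% noise
(accuracy ~0.65 vs ~0.53 in the test suite). For component separation the
antagonistic advantage reproduces robustly at `p = 0.3` (mean hit-rate
advantage ~+0.18 at matched false positives; panel of 100, 800 trials per
classifier). At `p = 0.1` the ordering *reverses* in this implementation
(about -0.1 to -0.19, including at a 500-odorant panel with 2000 training
trials per classifier): with saturating equiproportionate test mixtures the
non-antagonistic code's unions remain decodable at that sparsity. The
test-phase concentration statistics are a genuinely open choice, and the
ordering at `p = 0.1` appears sensitive to it; the suite asserts only the
`p = 0.3` ordering.

### Psychophysics

Perceived intensity is read out from glomerular recruitment: for a single
odorant, glomerulus `g_i` first crosses `tau` at concentration `c_i`
(`recruitment_table()`), and each active table glomerulus contributes the
log-increment `log c_i - log c_{i-1}` to the inferred log-concentration,
independently of the other glomeruli (a suppressed middle glomerulus
removes its own increment only; for a contiguous active prefix the sum
telescopes to `log c_k`). The estimator's resolution — the Weber ratio —
is `log10(cmax/c1) / (p N)` decades, about 0.05 for `p = 0.5`, `N = 250`
over six decades. The recruitment grid is 61 log-spaced points over six
decades: its 0.1-decade step matches the mean recruitment spacing, so the
upward rounding of recruitment thresholds cancels the downward
quantization of "last recruited glomerulus", making single-odorant
inference unbiased to well within half a grid step; a finer grid would
*increase* the bias (toward minus one full recruitment gap) while
pretending resolution the code does not have.

The suppression experiments deliver A at a fixed saturating concentration
and B at a concentration ratio; the receptor side is evaluated in the
saturating limit (fractions follow the ratio) while masking-site occupancy
uses B's absolute concentration. A glomerulus is *suppressed for A* when it
is active under A alone, inactive under B alone, and inactive in the
mixture; fractions are normalized by the conditioning-set size (the per-`N`
fraction is reported alongside), as per-trial fractions averaged over
odorant pairs. At `rho = 0`, `p = 0.5` and equal concentrations the
conditional suppressed fraction is ~0.44 for both odorants (the
dominant-component argument gives exactly 1/2; exact mixing lands slightly
below, and the suite checks the implementation against a brute-force
oracle) and is symmetric; at `rho = 1` it is ~0.02; a masking B suppresses
A's glomeruli far more than its own are suppressed (asymmetric
suppression).

Overshadowing trains per-odorant logistic detectors on the target alone at
concentrations spanning three decades. The negative trials are an even
mixture of blanks and single distractor odorants: blanks calibrate
presence-versus-absence of the target's signature, distractors discount
chance coverage of the target's glomeruli. This choice is load-bearing —
blank-only negatives put the decision boundary below any surviving
signature (the detector never releases its target), distractor-only
negatives penalize the union pattern of an equal-ratio mixture so heavily
that the non-antagonistic curve starts below threshold, and training on
mixtures lets the non-antagonistic detector read total pattern size, a cue
that normalization removes from the antagonistic code. With the mixed
negatives, A fixed at `cA = 100` and B diluted to `cA/ratio`, both
detection curves start near 1 and the antagonistic code loses B at a
roughly tenfold smaller ratio (~30 versus ~250 at `p = 0.5`).

## What the generator emulates — and what it does not

All inputs are synthetic. The ensemble generator reproduces the study
conditions: 250 receptor types, log-normal sensitivities spanning ~6
decades, unit-log-normal (or exponential) efficacies, tunable
binding-activation correlation, saturating equiproportionate mixtures, and
truncated-exponential background complexity. It does not emulate receptor
structure constraints on attainable `rho`, sniff-cycle temporal statistics
(stimuli are ideal square pulses), stochastic channel noise, spatial cilia
geometry, non-competitive PI3K-dependent inhibition, or correlations
between odorants (components are drawn independently). Passing tests
therefore validate the model's internal logic and its stated statistical
claims under these idealized conditions, not agreement with any particular
recording.

## Problem sizes

The test suite runs the full parameter sets where cheap (N = 250
ensembles, 1e4-sample distribution tests, 1e5-draw threshold checks) and
scaled-down Monte-Carlo sizes elsewhere: 100 trials for the
128-component approximation-error experiment; 800 background draws and
4000 pattern samples per mutual-information estimate (600/3000 in the
`rho*` scan over a 5-point grid); panels of 25–100 odorants with 200–800
training trials for ROC experiments and 1200 training trials for noisy
figure-ground; 10–60 odorant-pair draws for the psychophysics
experiments. Function defaults document the reference sizes; all
experiments accept explicit sizes and integer seeds, and scale linearly
in them.

## Known limitations

* The exact-mixing versus dominant-component distinction above: headline
  closed forms (`1 - (1-p)^K`, strict normalization, the 1/2 suppression
  fraction) are exact only in the dominant regime.
* The component-separation advantage of antagonism is not reproduced at
  `p = 0.1` under saturating equiproportionate test mixtures.
* Masking parameters (`KM`, `mu`, `m`) are phenomenological; the fitter
  (`fit_masking_profile()`) recovers them from clean suppression curves
  but real masking data were not used.
* The concentration-inference experiments floor the inferred value at the
  bottom of the recruitment grid; near-total suppression is reported at
  that floor.
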