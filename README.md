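# modlabel

Tools for studying **targeted stochastic gain modulation** in spiking
neural populations — the idea that a shared, rapidly fluctuating
multiplicative gain signal, coupled preferentially to task-informative
neurons, can act as a *label* that tells downstream circuits which neurons
to read out after a task switch.

The package is written for computational neuroscientists who want to
simulate, fit and decode modulated-Poisson population activity, and to
probe modulator-based information routing in a small hierarchical network.

## The models

**Encoding.** Binned spike counts follow a modulated Poisson model

```
k_{n,t}(s) ~ Poisson( lambda_n(s) * exp(c_n m_t - sigma_m^2 c_n^2 / 2) )
```

with stimulus-dependent rates `lambda_n(s)`, a shared modulator `m_t`
(i.i.d. Gaussian, or AR(1) within trials), and per-neuron couplings `c_n`
proportional to informativeness. The correction term keeps mean rates
fixed so modulation changes only variability.

**Estimation.** The modulated-SR model is a Poisson linear dynamical
system, `k_t ~ Poisson(exp(C m_t + B s_t))` with AR(1) latents, fitted by
EM with a Laplace E-step (block-tridiagonal Newton smoothing). Latent
dimensionality is chosen by 10-fold cross-validated leave-one-neuron-out
prediction. Informativeness is `d' = |mu0 - mu1| / sqrt(0.5 (s0^2 + s1^2))`
with a permutation null from splits of the stimulus-0 responses.

**Decoding.** Ideal-observer (`a_n = log lambda_n(1) - log lambda_n(0)`
with a modulator-dependent threshold, provably equal to exhaustive Bayes),
modulator-guided (`|a_n| = (1/T) sum_t m_t k_{n,t}`, signs from trial
feedback), sign-only, logistic and SVM baselines — plus training-size
sweeps and the accuracy-vs-modulator-strength analysis.

**Network.** A 4-layer model (fixed Gabor encoding with gain-exponent
couplings, locally connected processing, gain-gated decision layer) is
fine-tuned to a binary orientation task with distractors by training only
the couplings, with decision-layer gains set by the modulator-correlation
rule `g_n = (1/T) sum_t m_t h_n,t`.

## A worked example

Simulate one experimental block with a targeted AR(1) modulator, fit the
modulated-SR model, select dimensionality, and test whether coupling
magnitudes label informativeness:

```r
library(modlabel)

cfg <- experiment_config("block-pipeline", seed = 11,
                         params = list(n_trials = 30, folds = 3,
                                       max_D = 1, n_samples = 25,
                                       n_perm = 200))
rep <- run_experiment(cfg)

rep$selected_D
#> [1] 1
round(rep$modulator$tau_ms, 1)
#> [1] 71.1
round(unlist(rep$coupling_dprime_partial), 4)
#> estimate  p_value
#>   0.4087   0.0485
```

The cross-validated comparison picks a one-dimensional modulator
(`selected_D = 1`); its estimated fluctuation time constant (71.1 ms) sits
near the generating 72 ms; and after regressing out firing rate, coupling
magnitude still rank-correlates with informativeness (Spearman partial
r = 0.41, p = 0.049 for this single 24-unit block) — the modulator labels
the task-relevant units.

## Layout

- `R/recording.R` — recording container, I/O, inclusion criteria
- `R/simulate.R` — population, block, and downstream simulators
- `R/design.R`, `R/sr.R` — SR design and Poisson ridge regression
- `R/plds.R`, `R/model_selection.R` — modulated-SR EM and model comparison
- `R/decoders.R` — decoder suite and evaluation protocol
- `R/stats.R` — d', choice-d', partial correlations, cross-correlograms
- `R/network.R` — hierarchical modulated network
- `R/pipeline.R` — config-driven experiment orchestration
- `vignettes/modulator-labeling.Rmd` — models, conventions, limitations
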