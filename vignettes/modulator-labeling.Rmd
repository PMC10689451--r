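---
title: "Stochastic gain modulation as a task-relevance label: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic gain modulation as a task-relevance label: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modlabel)
```

# The scientific problem

In a visual change-detection task, only a small subset of a sensory
population carries information about the current decision, and that subset
changes whenever the task changes. A downstream circuit that must read out
the decision has no direct access to each upstream neuron's tuning, yet
animals re-acquire good performance within a handful of trials after a
task switch. `modlabel` implements a complete analysis and modeling suite
for one candidate mechanism: a shared, rapidly fluctuating multiplicative
gain signal (a "modulator") that preferentially targets task-informative
neurons, so that the co-fluctuation of a neuron with the modulator acts as
a label of its task relevance.

The package has three layers:

1. **Generative models and simulators** of modulated-Poisson populations
   (static and autoregressive modulators, downstream populations
   inheriting the modulator).
2. **Statistical estimation**: stimulus-response (SR) Poisson regression;
   the modulated-SR model, a Poisson linear dynamical system (PLDS) fitted
   by EM with a Laplace E-step; cross-validated latent-dimensionality
   selection; d-prime informativeness with a permutation null; and the
   derived summaries (modulator time constant, absolute/relative strength,
   coupling-informativeness partial correlations, choice d-prime,
   cross-area modulator cross-correlograms).
3. **Decoding theory and a network model**: the ideal-observer,
   modulator-guided (MG), sign-only (SO) and regression decoders; and a
   small hierarchical network fine-tuned through learned modulator
   couplings and a correlation-based gain rule.

# Encoding model

Spike counts in 50 ms bins are modeled as Poisson with a multiplicatively
modulated rate,

$$k_{n,t} \sim \mathrm{Poisson}\!\big(\lambda_n(s)\,
  e^{c_n m_t - \sigma_m^2 c_n^2/2}\big),$$

where $\lambda_n(s)$ is the stimulus-dependent rate, $m_t$ the shared
modulator, and $c_n \ge 0$ the per-neuron coupling. The correction term
$e^{-\sigma_m^2 c_n^2/2}$ cancels $E[e^{c_n m_t}]$ so the modulator
changes variability without changing mean rate; `simulate_iid_population()`
applies it by default and the test suite verifies the identity by Monte
Carlo. Couplings default to $c_n = |\log\lambda_n(1)-\log\lambda_n(0)|$,
making coupling magnitude proportional to informativeness ("targeted"
modulation); a proportionality constant and additive coupling noise are
exposed in the configuration.

The block simulator (`simulate_ar1_block()`) replaces the i.i.d. modulator
with a per-trial AR(1) process, $m_{t+1} = A m_t + \epsilon$, restarted
from its stationary distribution at every trial, and embeds it in the
experiment's trial structure: a geometric number (p = 0.25, truncated to
2–12) of repeated stimulus-0 presentations ends in one target
presentation; 200 ms stimulus-on windows alternate with off bins;
contrasts are randomly interleaved; behavioral outcomes are drawn from a
logistic function of the pooled informative-unit target response. The
geometric repeat law, the contrast scaling of 0.5, and the logistic hit
model are plumbing choices (the experimental design fixes none of them
quantitatively); their defaults produce roughly 75–80% hits and an average
trial length near the experimental one. In block simulations,
"uninformative" units can receive a small stimulus rate ratio
(`uninformative_ratio`), reproducing the graded continuum of
informativeness seen in recordings; in the decoding-theory simulations
they are exactly uninformative, matching the discrete three-group theory
setting.

# The modulated-SR model and its EM fit

`fit_sr()` fits per-unit Poisson regression on a design of
contrast-specific one-hot 50 ms time windows, an after-stimulus dimension
and an offset, with ridge strength $\alpha = 1$ on non-offset
coefficients. The design is deliberately over-parameterized (the offset is
collinear with the one-hot groups); the ridge makes the solution unique,
and only fitted log rates are compared against ground truth in tests.
Target presentations are excluded from all encoding fits — target
responses are reserved for informativeness and decoding.

`fit_plds_em()` adds a $D$-dimensional latent modulator with AR(1)
dynamics entering through the exponential link. The E-step maximizes each
trial's joint latent posterior by damped Newton iteration, exploiting the
block-tridiagonal Hessian (a block Thomas elimination; posterior marginal
and one-step cross covariances come from the standard backward
recursions), with a dedicated scalar fast path for $D = 1$. The M-step
updates the dynamics $(A, Q, Q_0)$ in closed form and the couplings and
stimulus weights $(C, B)$ by damped Newton on the expected complete-data
likelihood, with the same ridge on $B$ as the SR fit and $C$ unpenalized.

Numerical conventions:

* **Scale**: the latent's stationary variance is normalized to 1 per
  dimension and $C$ carries the magnitude (only the product is
  identifiable); **sign**: each latent dimension is flipped so its column
  of $C$ sums to $\ge 0$, which makes modulator traces comparable across
  areas.
* **Initialization**: $B$ from the SR-only fit; $C$ from the top factors
  of the Pearson-residual covariance; $A = 0.5 I$, $Q = 0.75 I$,
  $Q_0 = I$. The fit is deterministic given the data.
* **Convergence**: relative change of the Laplace-approximate
  log-likelihood below 1e-6, capped at 100 iterations. Because the
  objective is an approximation, it can decrease by a sub-tolerance amount
  near the optimum; the fitter stops at the first non-improvement and
  returns the best iterate, warning only if the decrease exceeds 1e-4 in
  relative terms.
* **Degenerate updates**: near-singular $Q$ or $Q_0$ receive a 1e-6
  jitter with a warning; $A$ is rescaled if its spectral radius
  approaches 1.

Model comparison (`select_dimensionality()`) holds out whole trials,
scores each $D$ by leave-one-neuron-out predictive likelihood (latent
inferred from the other units; the predictive likelihood averages over 100
posterior path samples drawn through the banded Cholesky factor), and
breaks ties toward smaller $D$. The modulator's time constant is
$\tau = -1/\log(A)$ bins; absolute modulator strength is the variance of
the estimated (posterior-mean) modulator path times the coupling norm
$\sqrt{\sum_n C_n^2}$ — using the estimated path's variance rather than
the normalized prior makes the strength vanish on modulator-free data —
and relative strength divides by the stimulus drive
$\sum_{n,i}\mathrm{Var}(s_i B_{n,i})$ over the fitted design rows.

# Decoders

All decoders share the linear-threshold form
$\sum_n a_n k_n > q$:

* **Ideal observer**: $a_n = \log\lambda_n(1) - \log\lambda_n(0)$ with the
  modulator-dependent threshold
  $q(m) = \sum_n e^{c_n m - \sigma_m^2 c_n^2 / 2}[\lambda_n(1)-\lambda_n(0)]$
  (the exact log-odds threshold of the mean-corrected model — the package
  verifies the decision rule against exhaustive Bayes enumeration on small
  populations). A constant-threshold variant optimizes $q$ on training
  data by scanning midpoints of the sorted training scores (ties resolve
  to the midpoint of the optimal interval).
* **MG**: weight magnitudes $(1/T)\sum_t m_t k_{n,t}$ over 50 ms bins,
  clipped at zero; signs from trial feedback (mean response difference on
  labeled data; zero differences get +1); constant threshold.
* **SO**: $a_n = \mathrm{sign}(\lambda_n(1)-\lambda_n(0)) \in \{-1,+1\}$.
* **Baselines**: L2 logistic regression (total penalty strength 1, via
  glmnet with $\lambda = 1/n$) and a linear-kernel SVM (e1071), both on
  window-summed counts.

Decisions aggregate the 200 ms window by summing counts before
thresholding; for the modulator-dependent threshold the per-bin log-odds
contributions $a^\top k_t - q(m_t)$ are summed over the window — bins are
conditionally independent given the modulator, so this is the exact
window-level Bayes decision (a majority vote over per-bin decisions, the
other natural convention, is measurably suboptimal and can be beaten by
the MG decoder). Ties decide stimulus 1 for determinism. Decoder evaluation
(`evaluate_training_curve()`) uses balanced training samples (one per
stimulus-contrast pair at the minimum size of 4) and a fixed held-out test
set.

In strength sweeps (`modulator_strength_sweep()`) the modulator is drawn
once per presentation — the same time scale as the stimulus — which
equates the data available to all decoders; the ideal observer's accuracy
then decreases monotonically with modulator strength while the MG decoder
follows an inverted U. The MG decoder's few-trial advantage over
regression appears when the modulator fluctuates at the bin time scale
(`modulator_timescale = "bin"`), because coupling estimates accumulate per
bin while regression learns per labeled presentation.

# Hierarchical network

`build_network()` constructs a 4-layer network: a fixed, unit-norm Gabor
filter bank over a grid of receptive-field centers (the encoding layer,
with gain exponent couplings $c_n$), locally connected rectified
processing layers, and a linear decision layer whose inputs carry gains
$g_n \ge 0$. The desk-scale configuration is a 28 x 28 input, 7 x 7
centers x 6 orientations (294 encoding units), a 3 x 3 x 24 locally
connected layer, a fully mixing 48-unit second processing layer, and a
10-way decision layer. The full-scale configuration (56 x 56 input,
16 x 16 x 10 = 2560 encoding units, final processing width 7840) is
constructable and pins the decision layer at exactly 78,410 parameters;
its local-connectivity geometry is a package choice, as the layer widths
alone do not determine it.

Training proceeds in three stages (`train_stage()`): glyph-classification
pretraining of all processing and decision weights (procedurally generated
segment-stroke glyphs at random positions stand in for handwritten digits
so no dataset download is needed; plain SGD, L1 penalty 0.001); a fresh
10-way orientation readout trained on positioned gratings; and coupling
learning on the binary orientation task with distractors. In the coupling
stage the modulator has a task-engaged slow baseline $m = 1$ carrying fast
fluctuations $\delta_t \sim N(0, 0.1)$, 100 steps per stimulus. Gains are
estimated from the fluctuation-activity correlations (the MG rule applied
to the zero-mean component) and smoothed across stimuli into a task-level
gain vector, which gates the decision layer both during the slow-scale
coupling gradient and at evaluation; couplings are the only trainable
parameters, updated by gradient descent with a 1/(1 + t/1000) step decay,
a gradient-norm clip, and a [-8, 8] clamp (the exponential link otherwise
allows runaway; negative values act as suppression of task-irrelevant
channels). Applying the smoothed rather than per-stimulus gain estimate in
the loss proved essential for stable learning; both are available.

The binary task places the target at the central grid position and draws
distractor orientations from the task pair itself at 1.2x contrast — the
hardest case, where only location separates target from distractor
evidence. With this design the fully mixed final layer is not linearly
separable for the task, so retraining the decision layer alone plateaus
below the 80% criterion, while coupling-based fine-tuning (294 parameters)
reaches it within a few hundred training samples and full weight
retraining needs substantially more (`run_comparison()` reproduces this
ordering over seeds).

# Problem sizes and what the tests show

The test suite and the acceptance script run everything at desk scale,
chosen so each property is measured in minutes: EM parameter recovery uses
50 units and 100 trials of roughly 60 bins over 5 seeds; dimensionality
selection uses 18-unit, 24-trial blocks with 3 folds and candidate
dimensions 0–2 over 10 (modulated) plus 5 (modulator-free) runs; the
decoder sweep uses 200 units (5% informative), 2000 training
presentations and 10 seeds; the permutation-test calibration uses 1000
null units at 1000 permutations; the network comparison uses the
desk-scale configuration with 3 seeds and up to 5000 task-training
samples. These sizes are the package's study conditions, not tuning
knobs.

The simulators emulate the structure of the recordings — blocked trials
with repeats and a final target, interleaved contrasts, a low-dimensional
fast multiplicative modulator preferentially coupled to informative units,
hit/miss outcomes coupled to neural responses, and a downstream area
inheriting the modulator with a feedforward lag. They do not emulate
adaptation within repeats, eye movements, oscillatory or on-off shared
dynamics, multi-dimensional modulators (the dimension is configurable but
defaults to 1), or the residual structured pairwise correlations present
in real recordings. Passing tests therefore demonstrate internal
consistency of the estimation and decoding machinery under the stated
generative assumptions, not that those assumptions exhaust real V1/MT
data.

# Known limitations

* The Laplace-EM objective is approximate; monotonicity holds only up to
  approximation error, and the fitter returns the best iterate.
* The modulator-strength estimate inherits smoothing shrinkage from the
  posterior mean path and underestimates the generative strength by
  roughly the posterior uncertainty fraction; comparisons across
  conditions are unaffected.
* In the network, the gain rule's contribution at evaluation is modest at
  desk scale: most of the stochastic variant's advantage flows through the
  learned couplings reshaping the encoding layer. The deterministic
  (constant-gain) control is correspondingly strong here, unlike at the
  full scale of the original experiments.
* d-prime permutation nulls split the stimulus-0 pool into disjoint
  subsets of sizes (n0 - n1, n1); when n1 is not small relative to n0 the
  null group sizes no longer match the observed comparison exactly.

# A worked example

```{r example, eval = FALSE}
library(modlabel)

cfg <- experiment_config("block-pipeline", seed = 11,
                         params = list(n_trials = 30, folds = 3,
                                       max_D = 1, n_samples = 25,
                                       n_perm = 200))
rep <- run_experiment(cfg)
rep$selected_D                 # 1: the targeted modulator is detected
rep$modulator$tau_ms           # estimated fluctuation time constant
rep$coupling_dprime_partial    # coupling-informativeness partial correlation
```
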