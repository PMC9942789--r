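---
title: "Confidence-weighted statistical learning of pain sequences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-weighted statistical learning of pain sequences: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painseq)
```

This vignette is the package's own account of the science it implements:
the generative model of the stimulus sequences, the six learners and their
outcome variables, the behavioral model-comparison machinery, the
single-trial EEG regression, and — because the package is driven entirely
by simulation — an explicit statement of what the synthetic-data generator
does and does not emulate.

## The task and its generative model

A participant receives sequences of two thermal intensities, cool `I1` and
painfully hot `I2`, delivered every 3 s. Each sequence of 100 stimuli is a
realization of a two-state Markov chain parameterized by the pair
$(p(I_1\mid I_2),\; p(I_2\mid I_1))$; the first stimulus is drawn from the
stationary distribution
$p(y_1 = I_1) = \frac{p(I_1|I_2)}{p(I_1|I_2) + p(I_2|I_1)}$, so no
transient start-up bias is introduced. The design crosses five pairs —
$(0.5,0.5)$, $(0.3,0.7)$, $(0.7,0.3)$, $(0.3,0.3)$, $(0.7,0.7)$ — each
delivered twice per participant in randomized order (10 blocks). Every
$15 \pm 3$ stimuli the sequence pauses and the participant reports the
probability of the next intensity and their confidence in that estimate.

## The learners

Two families of three models each track one sequence statistic: the item
frequency (IF, $p(I_1)$), the alternation frequency (AF, $p(\text{alt})$),
or the two transition probabilities (TP).

**Bayesian observers.** With a uniform $\mathrm{Beta}(1,1)$ prior and a
Bernoulli/Markov likelihood, the posterior over the tracked statistic is
conjugate: $\mathrm{Beta}(N_1 + 1, N_2 + 1)$ for IF over item counts,
$\mathrm{Beta}(N_a + 1, N_r + 1)$ for AF over alternations/repetitions
(the first stimulus contributes no alternation event), and a product of
two independent Beta posteriors over the transition rows for TP. Limited
memory is modelled by leaky counting: the $k$-th last counted observation
carries weight $e^{-k/\omega}$, with the integration time constant
$\omega \in [1, \infty]$ a free parameter and $\omega = \infty$ the
perfect integrator. Per trial the model reports:

- the **prediction** $p_{n} = E[\theta \mid y_{1:n}]$ (posterior mean),
  mapped to the probability that the next stimulus is $I_1$;
- the **confidence** $c_n = -\log \sigma(\theta \mid y_{1:n})$, the log
  precision of the posterior over the statistic that governs the next
  prediction;
- the **Bayesian prediction error** $e_n = 1 - p(y_n \mid y_{1:n-1})$ and
  the **Shannon surprise** $s_n = -\log p(y_n \mid y_{1:n-1})$, both
  computed *before* the state is updated with $y_n$, so
  $s_n = -\log(1 - e_n)$ holds exactly.

**Delta-rule (Rescorla–Wagner) models.** The tracked statistic is a state
value initialized at $V_0 = 0.5$ and updated with a constant learning rate
$\alpha \in (0,1)$: $V_n = V_{n-1} + \alpha (R_n - V_{n-1})$, where $R_n$
indicates the item (IF), an alternation (AF), or — for TP — updates only
the row matching the previous stimulus. Delta rules carry no posterior and
hence no inferential confidence.

At the first trial all models assign $p_{\mathrm{obs}} = 0.5$ (uniform
prior / $V_0$); the AF and TP models begin accumulating at the second
stimulus.

### Numerical and design choices in the learners

- **Leak-weight indexing.** "The $k$-th last observation is weighted
  $e^{-k/\omega}$" is ambiguous about whether the most recent observation
  has $k=0$ or $k=1$. We use $k=0$ (weight 1), which makes the finite- and
  infinite-$\omega$ learners agree on the newest observation; the
  alternative only rescales all counts by $e^{-1/\omega}$ and is exposed
  as `most_recent_weight_one = FALSE`.
- **TP decay clock.** All four transition counts decay at every transition
  event (one global event clock per model), so the two rows stay
  commensurate; alternations and transitions are decayed by their own
  event recency, not by trial index.
- **TP confidence.** The log precision is taken from the Beta marginal of
  the transition row conditioned on the previous stimulus — the quantity
  that governs the next prediction. A joint variant (sum of both rows' log
  precisions) is available via `tp_confidence = "joint"`; it changes the
  confidence scale but not the predictions, and we do not assert either as
  the historically "correct" reading.
- **Guards.** Probabilities are clamped to $[10^{-12}, 1 - 10^{-12}]$
  before logs; Beta parameters never fall below the prior floor of 1.
- The incremental recursion ($C \leftarrow e^{-1/\omega} C + \text{event}$)
  is verified at every trial against a brute-force re-summation of the full
  history (tolerance $10^{-12}$) and against numerical integration of the
  unnormalized posterior on a $10^4$-point grid (tolerance $10^{-6}$).

## Fitting and model comparison

Probability reports $x_n$ (confidence reports are never used to optimize
the fit) are pooled across a participant's blocks and regressed on each
model's predictions, $x_n = \beta_0 + \beta_1 p_n^{M_i,\omega_i} +
\epsilon$, by OLS. Model evidence is approximated by
$p(x \mid M_i) \approx e^{-\mathrm{BIC}/2}$ with
$\mathrm{BIC} = N \log \sigma_e^2 + q \log N$ and $q = 3$ (two regression
coefficients plus one model-free parameter), minimized over the parameter
grid: 99 learning rates linearly spaced on $[0.005, 0.95]$ and 103 time
constants — 102 log-spaced values on $[1, 400]$ plus $\infty$. Log spacing
reflects that $\omega$ acts multiplicatively on the forgetting rate and
places a grid point within 0.5% of $\omega = 8$. Pooling ratings per participant (rather than
per block) matches a fit performed "per participant and model"; per-block
fitting would only reduce $N$ per fit. An MSE floor of $10^{-10}$ keeps
noiseless simulations finite. Individual model probabilities normalize the
six best evidences within a participant.

Group-level comparison treats model identity as a random effect: a
variational Dirichlet scheme over population model frequencies (iterating
participant-wise model attributions against Dirichlet counts from a
uniform prior) yields expected frequencies, and the exceedance probability
$\phi$ — the probability that a model is the most frequent — is estimated
from $10^5$ seeded Dirichlet draws. The scheme is implemented from
scratch and run on log evidences, since $e^{-\mathrm{BIC}/2}$ itself
overflows at realistic $N$. The integration time constant is summarized by
Bayesian model averaging across the Bayesian models,
$p(\omega \mid x) \propto \sum_i e^{-\mathrm{BIC}(M_i,\omega)/2}$,
normalized per participant (log-sum-exp), averaged across participants,
and reported as the grid argmax $\omega^*$.

## Single-trial EEG regression

Epochs span $[-0.5, 1]$ s around stimulus onset at 500 Hz on the five
central electrodes C3, Cz, FCz, CPz, C4 (the closed interval is sampled:
751 timepoints). Trials whose absolute amplitude reaches 80 µV on any
channel are rejected. Because confidence is partly a function of the
prediction itself, the regressor of interest is the **residual
confidence**: the residual of
$c_n = \beta^r_{0,k} + \beta^r_1 p_n + \beta^r_2 p_n^2 + \beta^r_3 \log p_n
+ \beta^r_4 \log(1 - p_n) + c^r_n$ with block-grouped intercepts
$\beta^r_{0,k}$. Collinearity with the prediction error is checked with
$\mathrm{VIF} = 1/(1 - R^2)$ (values above 5 are conventionally
problematic; on the simulated design the average VIF rounds to 1).

Per participant, channel and timepoint, the signal is regressed on
$z_n = \beta_{0,k} + \beta_1 e_n + \beta_2 c^r_n + \epsilon$ across all
surviving trials, **separately per delivered intensity** (the cool and hot
vertex potentials have different component latencies; the split is
mandatory, not optional). Group inference is a two-tailed one-sample
t-test of the coefficients against zero, corrected with Benjamini–Hochberg
FDR jointly across the five electrodes and all timepoints, separately per
regressor and intensity — per-regressor families keep each effect's error
rate interpretable on its own. Points with identical nonzero coefficients across
participants (zero variance) are flagged as significant-by-convention
rather than propagating NaN; lowering $\alpha$ never adds significant
points.

## What the synthetic-data generator emulates

The generator is first-class, tested code that defines the study
conditions: 31 participants; ten 100-stimulus blocks, two per TP pair, in
randomized order; ISI 3 s; question trials every $15 \pm 3$ stimuli with
uniform integer jitter. Simulated raters report the generating learner's
prediction plus Gaussian noise (SD 0.05), clipped to $[0,1]$; confidence
reports min-max-normalize the learner's confidence over the participant's
own trace before adding noise — the physical endpoints of a rating scale
are arbitrary, so both reports live on the unit interval, which matches
the model quantities being fitted and changes nothing downstream (only
correlations and regressions consume them). Simulated epochs are a
biphasic template — a negative N2 and positive P2 Gaussian bump with
intensity-specific latencies (205/318 ms cool, 369/518 ms hot), fixed
channel gains peaking at Cz/FCz — scaled multiplicatively by
$1 + \beta_{\mathrm{conf}} c^r_n + \beta_{\mathrm{pe}} e_n$, plus a
per-block DC offset and white noise. One global seed expands
deterministically into per-participant, per-block streams, so identical
seeds give byte-identical pipelines.

What it does **not** emulate: volatility or change-points (the design is
stationary), metacognitive bias or variability in the reports, 1/f EEG
background, ocular/muscle artifacts, between-participant differences in
learning style or time constant, habituation, and peripheral physiology.
Passing tests therefore demonstrate that the analysis machinery recovers
known ground truth under the study's statistical structure — not that it
is robust to every pathology of real recordings.

## Problem sizes and verification

The test suite verifies, among others: Monte-Carlo agreement of generated
sequences with the stationary distribution and alternation rate at
$n = 10^5$; oracle equivalence of the incremental learners for
$\omega \in \{2, 8, \infty\}$; the Laplace rule for the perfect
integrator; model recovery for all six generators (8 simulated
participants per generator, noise SD 0.05, group winner by expected
frequency); $\omega$ recovery within one grid step for
$\omega \in \{4, 8, 16\}$; BH-FDR calibration at the nominal 5% level over
200 null simulations; and end-to-end recovery of a negative confidence
modulation (12 participants, noise 5 µV) with no false prediction-error
effect. Grid-resolution and cohort-size choices in individual tests are
analysis-scale choices; the generator itself always uses the study design
above. The acceptance script reruns the full 31-participant design and
reports the half-life $\mathrm{round}(\omega \ln 2) = 6$ stimuli and time
constant $\omega \times \mathrm{ISI} = 24$ s at $\omega = 8$, the rounded
mean VIF, the mean quadratic-fit $R^2$ of confidence on probability at
question trials, and the BMA $\omega^*$.

## Known limitations

- The variational random-effects scheme reports exceedance probabilities,
  not protected exceedance probabilities; with very few participants the
  Dirichlet posterior is diffuse and $\phi$ conservative.
- BIC-based evidence is an approximation; no free-energy evidence is
  computed.
- The EEG stage assumes preprocessed, epoched input; filtering, ICA and
  source analysis are upstream of this package.
- The TP-confidence convention ("row" vs "joint") changes the confidence
  scale; analyses mixing both conventions should fix one explicitly.
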