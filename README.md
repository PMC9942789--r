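# painseq

Confidence-weighted statistical learning of thermal pain sequences.

When people receive a stream of cool (I1) and painfully hot (I2) stimuli
generated by a two-state Markov process, they track the sequence statistics
and form predictions about the next stimulus — and the confidence of those
predictions modulates the cortical response to pain (the vertex potential).
`painseq` implements the full analysis of this paradigm for modellers of
perceptual inference and pain neuroscience:

- **Six sequence-learning models.** Bayesian ideal observers with leaky
  integration and Rescorla–Wagner delta rules, each tracking the item
  frequency (IF), the alternation frequency (AF) or the two transition
  probabilities (TP). The Bayesian observer holds a Beta posterior over the
  tracked statistic θ with a uniform prior, counts observations with leak
  weights `exp(-k/ω)` (k = 0 for the most recent; ω = ∞ is a perfect
  integrator), predicts with the posterior mean
  `p(y_{n+1} | y_{1:n}) = E[θ | y_{1:n}]`, and reports the inferential
  confidence `c_n = -log σ(θ | y_{1:n})` (log precision of the posterior),
  the Bayesian prediction error `e_n = 1 - p(y_n | y_{1:n-1})` and the
  Shannon surprise `-log p(y_n | y_{1:n-1})`. The delta rules update a
  state value `V_n = V_{n-1} + α (R_n - V_{n-1})` from 0.5.
- **Behavioral model comparison.** Probability reports are regressed on
  each model's predictions (`x_n = β0 + β1 p_n + ε`), scored with
  `BIC = N log σe² + q log N` (q = 3) over a grid of 99 learning rates and
  103 time constants, and compared at the group level with a random-effects
  variational Dirichlet scheme yielding expected model frequencies and
  exceedance probabilities φ, plus Bayesian model averaging of the
  integration time constant, `p(ω|x) ∝ Σ_i exp(-BIC(M_i, ω)/2)`.
- **Single-trial EEG regression.** Epoched vertex potentials are regressed
  at every channel and timepoint on the Bayesian prediction error and the
  residual confidence (confidence with the predicted probability, its
  square and logarithms projected out per block), with VIF collinearity
  checks, group one-sample t-maps and Benjamini–Hochberg FDR correction
  across the five central electrodes (C3, Cz, FCz, CPz, C4) and all
  timepoints.
- **A synthetic-data generator** reproducing the study design — 31
  participants, ten 100-stimulus sequences (two per transition-probability
  pair), question trials every 15 ± 3 stimuli, ISI 3 s, and biphasic
  N2/P2 epochs whose amplitude is linearly modulated by confidence and
  prediction error — so the entire pipeline runs and is tested without any
  recorded data.

## Worked example

```r
library(painseq)

# one testing block: mostly-hot sequence, p(I1|I2) = 0.3, p(I2|I1) = 0.7
s <- generate_sequence(c(0.3, 0.7), n_stimuli = 100, seed = 1)
s
#> <ps_sequence> block 1: 100 stimuli, TPs (p(I1|I2), p(I2|I1)) = (0.30, 0.70), ISI 3.0 s, seed 1
#>   first 20: 12221112212122222222 ...

# the winning behavioral model: Bayesian TP learner, omega = 8 stimuli
trace <- run_learner(s, model_spec("bayes", "TP", 8))
trace[14:16, ]
#> # A tibble: 3 x 7
#>   trial intensity p_next p_obs confidence    pe surprise
#> 1    14         2  0.468 0.430       1.65 0.570    0.844
#> 2    15         2  0.396 0.532       1.71 0.468    0.632
#> 3    16         2  0.341 0.604       1.78 0.396    0.504
```

At trial 15 the learner had assigned probability 0.532 to the hot stimulus
it then received (prediction error 0.468, surprise 0.632 nats), updated its
transition-row posterior, and now predicts I1 next with probability 0.396
at confidence 1.71 (log precision of the governing Beta marginal — higher
means a tighter posterior).

```r
sched <- schedule_questions(100, 15, 3, seed = 2)
sched
#> [1] 16 34 51 68 80 96
simulate_rater(s, sched, model_spec("bayes", "TP", 8), noise_sd = 0.05, seed = 3)
#> # A tibble: 6 x 3
#>   trial p_report conf_report
#> 1    16    0.293       0.524
#> 2    34    0.308       0.297
#> 3    51    0.244       0.687
#> ...
```

The simulated participant reports a 29% chance of a cool stimulus after
trial 16 — the learner's own prediction plus report noise, on the unit
rating scale.

The whole pipeline (simulate → learn → fit → EEG regression, with a
machine-readable `report.json` of winning model, φ, ω*, quadratic R² and
significant intervals) runs from one config:

```r
run_pipeline(study_config(n_participants = 2), out_dir = "demo", seed = 1)
```

or from the shell via `Rscript inst/cli/painseq.R all --out demo --seed 1`.

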