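# bindfuse

Bayesian binding-and-fusion observer models of audiovisual speech
identification, for researchers in multisensory perception and
computational psychophysics.

When a consonant is heard while watching the speaker's face, perception
reflects two stages: *binding* (how strongly the auditory and visual cues
are treated as sharing a cause) and *fusion* (reliability-weighted
combination of the bound cues). `bindfuse` fits three observer models of
this process to per-condition counts of B/D/G identification responses,
on a one-dimensional place-of-articulation axis:

* **Joint Prior (JP)** — the binding prior is a Gaussian ridge along the
  A = V diagonal with cross-diagonal variance σ²ₒ. The auditory marginal
  of the posterior is Gaussian with

      μ_AV = w_A μ_A + (1 − w_A) μ_V,   σ²_AV = w_A σ²_A,
      w_A  = (2σ²ₒ + σ²_V) / (2σ²ₒ + σ²_V + σ²_A)

  so σ²ₒ = 0 forces complete fusion and σ²ₒ → ∞ segregates the cues.
* **Bayesian Causal Inference (BCI)** — a mixture of the complete-fusion
  posterior (weight 1 − P(C=2)) and the auditory likelihood alone
  (weight P(C=2), the prior probability of separate causes).
* **MLE** — the forced-fusion baseline (σ²ₒ = 0 / P(C=2) = 0 everywhere),
  i.e. inverse-variance weighting.

Response probabilities are the masses of the posterior on the three pieces
of a finite interval cut at two fitted boundaries. *Full* variants fit one
binding parameter per synchrony condition (synchronous, 500 ms audio-lead
asynchronous); *Reduced* variants pin the synchronous parameter at
complete binding. Free parameters: 12 (MLE), 13 (Reduced), 14 (Full).

Models are fitted per subject by penalized maximum likelihood (multinomial
NLL + λ·Σ precisions, default λ = 7) with multi-start BFGS, compared by
42-fold leave-one-condition-out cross-validation RMSE, and summarized by
binding parameters and auditory weights. A synthetic-cohort generator
reproduces the design's structure (42 conditions × 25 repetitions = 1050
trials per subject; 16 subjects) so the whole pipeline runs without
behavioural data.

## Worked example

Simulate one subject from the default Reduced Joint Prior observer at 500
repetitions per condition and fit the same model:

```r
library(bindfuse)
design <- av_design(n_reps = 500)
subj   <- simulate_subject(default_observer("ReducedJP"), design, seed = 11)
fit    <- fit_observer(subj, "ReducedJP", design,
                       fit_config("test", n_restarts = 10, seed = 2))
fit
#> Fitted observer model: ReducedJP ( 13 free parameters )
#>   penalized NLL: 7224.349  (NLL 6376.614, lambda = 7)
#>   restarts: 10 finite of 10

w <- extract_auditory_weights(fit, design)
round(tapply(w$w_A, w$soa, mean), 3)
#> async  sync
#> 0.887 0.486
```

The fitted auditory weight is near 0.49 for synchronous audiovisual
stimuli (strong visual influence — the McGurk regime) and near 0.89 for
asynchronous ones: the 500 ms audio lead releases binding, which the model
expresses as a recovered asynchronous σ²ₒ (here 0.212) against the pinned
synchronous value of 0. The median absolute error of the per-condition
weights against the generating observer is 0.048 in this run.

Cohort-level comparison against the forced-fusion baseline:

```r
cohort <- simulate_cohort(cohort_spec(n_subjects = 8, seed = 202))
tab    <- cv_table(cohort, c("MLE", "ReducedJP"),
                   config = fit_config("test", seed = 303))
compare_models(tab)
#> Model comparison over 8 subjects
#> Mean CV RMSE by variant:
#>       MLE ReducedJP
#>    0.2394    0.2092
#> Mean improvement over MLE baseline:
#>       MLE ReducedJP
#>    0.0000    0.0302
#> Pairwise signed-rank tests:
#>          contrast alternative statistic  p_value mean_diff
#>  ReducedJP vs MLE        less         0 0.003906  -0.03024
```

The binding model predicts held-out conditions better than forced fusion
in all 8 subjects (signed-rank p = 0.004); on data generated *from* the
forced-fusion observer this advantage disappears, as it should.

`run_pipeline()` wraps simulate → fit → cross-validate → compare under a
single seed and writes `cv_rmse.csv`, `comparison_tests.csv` and
`weights.csv` to a run directory. `read_trials()` / `write_trials()`
define the long-format count CSV; `aggregate_trials()` converts
trial-level tables.

## Vignette

`vignettes/binding-and-fusion.Rmd` documents the models and their
assumptions, the unconstrained parameterization and optimizer settings,
the truncation and tie-handling conventions, what the synthetic cohort
does and does not emulate, and known limitations.
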