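# phichoice

Analysis tools for demand-selection experiments in which people choose
between a **cognitive task** (mental arithmetic at one of two difficulty
levels, performed for an imposed duration of 9, 18 or 27 s) and a
**physical task** (carrying an empty 0.0 kg or loaded 3.2 kg bucket over a
fixed distance). The package is for researchers studying effort-based
choice who want to (a) reproduce this analysis pipeline on their own trial
data and (b) test it end to end against a known generative model.

## The model

Each design cell (weight × difficulty × duration) yields a group-level
probability of choosing the bucket, p(Bucket). The common-currency model
maps every cell onto a single latent axis Φ, anchored in seconds of
cognitive-task duration, with the loaded-bucket/easier-task cell as
baseline:

    Φ = duration                 loaded bucket, easier task
    Φ = duration + k             loaded bucket, harder task
    Φ = duration + h             empty bucket,  easier task
    Φ = duration + k + h         empty bucket,  harder task

and fits a four-parameter logistic in Φ,

    p(Φ) = lower + (upper − lower) · σ(steepness · (Φ − inflection)),

choosing (k, h) by exhaustive search over integer grids to maximise
R² = 1 − SS_residuals/SS_total. A one-shift variant (`h` only) serves
designs where cognitive difficulty has no detectable effect, and a
*transfer fit* refits the logistic with `h` frozen at a value imported
from another experiment. Around the model sit the pipeline stages:
a synthetic trial generator with known truth, aggregation of binary
choices into p(Bucket), a fully within-subjects three-way ANOVA with
partial η², follow-up two-way ANOVAs, paired t tests with Cohen's
d_z, and within-participant confidence intervals.

## Worked example

Simulate a 48-participant experiment from a known generative model
(shifts k = 24, h = 8, steep choice curve), then run the analysis:

```r
library(phichoice)

design <- experiment_design(n_participants = 48)      # 2×2×3×2, 24 trials/person
truth  <- generative_params(true_k = 24, true_h = 8, seed = 2026)
trials <- generate_choices(design, truth)

choices <- aggregate_choices(trials)     # per-participant and group p(Bucket)
rm_anova(choices)
#> Repeated-measures ANOVA (fully within-subjects, n = 48)
#>  Effect                         F      df      p      eta_p^2
#>  Duration                       104.65 (2, 94) <0.001 0.69
#>  Difficulty                     849.89 (1, 47) <0.001 0.95
#>  Weight                         87.48  (1, 47) <0.001 0.65
#>  Duration × Difficulty          26.16  (2, 94) <0.001 0.36
#>  Duration × Weight              0.97   (2, 94) 0.3831 0.02
#>  Difficulty × Weight            11.88  (1, 47) 0.0012 0.20
#>  Duration × Difficulty × Weight 29.68  (2, 94) <0.001 0.39

fit <- grid_fit(choices, "two_shift", k_grid = 0:48, h_grid = -12:28)
fit
#> Common-currency Phi model (two_shift)
#>   k (harder cognitive task): 24
#>   h (empty bucket):          9
#>   logistic: lower=0.020 upper=0.956 inflection=30.72 steepness=0.233
#>   R^2 = 0.9974 on 12 cell means
```

All three main effects are large (duration F(2, 94) = 104.65, difficulty
F(1, 47) = 849.89, weight F(1, 47) = 87.48, all p < .001 with the η²
shown), as built into the generative curve. The grid search recovers the
difficulty shift exactly (k = 24 s-equivalent) and the weight shift to
within one grid step (h = 9 vs true 8 — one replicate's sampling noise),
with the single logistic explaining 99.7% of the variance in the twelve
cell means. `plot(fit)` draws the cells against Φ with the fitted curve;
`summary(fit)`, `coef(fit)`, `predict(fit)`, `residuals(fit)` and
`simulate(fit)` behave as for any fitted model. `run_pipeline(run_config(...))`
chains every stage (reading, aggregation, ANOVA + follow-ups, CIs, grid
and transfer fits) into one report serialisable with `report_json()`, and
`inst/scripts/phichoice-cli.R` exposes `simulate` / `fit` / `anova` /
`report` verbs from the shell.

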