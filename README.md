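# accelbudget

Behavior classification and diel activity budgets from tri-axial
accelerometry on small nocturnal mammals.

## The problem

Kangaroo rats and other small desert rodents are keystone species that are
nearly impossible to observe directly: they are small (< 50 g), nocturnal
and semi-fossorial. Miniature animal-borne accelerometers (tri-axial, 25 Hz,
±10 g) record their movement continuously for days, and a modest set of
video-validated bouts lets a supervised classifier translate acceleration
into behavior. `accelbudget` implements that workflow end to end:

* **Features** — non-overlapping windows (1–9 s) summarized by 44
  statistics per window: per-axis moments, extrema and percentiles, vector
  norm, covariances and Pearson correlations, mean |DBA| per axis and ODBA
  (overall dynamic body acceleration, the mean of
  |DBAx| + |DBAy| + |DBAz|), first-difference statistics, wave amplitude
  and DBA line crossings.
* **Classifier** — classes balanced by subsampling to the rarest class, a
  stratified 50/50 train/test split, and a grid of linear SVM, decision
  tree and random forest over feature sets and window sizes, ranked by the
  mean of macro accuracy, precision and recall
  (per-class precision = TP/(TP+FP), recall = TP/(TP+FN)).
* **Ephemeris** — geometric solar altitude, the eight-phase diel
  classification (evening, dusk, evening twilight, night, morning twilight,
  dawn, morning, day; twilight bands at 0–6° and 6–18° below the horizon,
  night below 18°), lunar illuminated fraction `(1 + cos i)/2`, moon
  intensity categories (< 0.33 low, 0.33–0.66 medium, > 0.66 high) and moon
  up/down state — all computed in-package and validated against an
  independent oracle and eclipse-anchored almanac instants.
* **Budgets** — proportion of time per behavior per (individual, night,
  light phase, moon state), conserving classified time exactly.
* **Mixed models** — GLMMs of budget proportions with random intercepts for
  individual and night; AIC selection across gaussian/poisson/binomial/gamma
  families; Wald chi-square tests per term; variance inflation factors
  `1/(1 − R²_j)`; Nakagawa-style conditional R².
* **Synthetic generator** — phase-switched continuous-time Markov chains
  over the four behaviors (motionless, travel, foraging, grooming),
  behavior-specific acceleration signal models with deliberately confusable
  foraging/grooming signatures, nightly weather and moonlight covariates,
  and injectable ground-truth effects, so every stage is testable against
  known truth.

## Worked example

```r
library(accelbudget)

site <- site_context(30.2, -103.5, "America/Chicago")

# a small synthetic study: 2 animals, 2 nights, 25 Hz
cfg <- pipeline_config(
  site = site, n_individuals = 2, nights = 2,
  window_sizes = c(3, 6),
  algorithms = c("random_forest", "decision_tree"),
  feature_sets = "all",
  output_dir = "run1"
)
res <- run_pipeline(cfg, seed = 23)

head(res$selection$leaderboard, 3)
#>       algorithm feature_set window_s overall_accuracy macro_accuracy
#> 1 random_forest         all        6          0.89375       0.946875
#> 2 random_forest         all        3          0.87875       0.939375
#> 3 decision_tree         all        6          0.86125       0.930625
#>   macro_precision macro_recall     score n_train n_test
#> 1       0.8940417      0.89375 0.9115556     800    800
#> 2       0.8790112      0.87875 0.8990454     800    800
#> 3       0.8620596      0.86125 0.8846449     800    800

res$selection$best$confusion
#>             predicted
#> true         motionless travel foraging grooming
#>   motionless        200      0        0        0
#>   travel              0    200        0        0
#>   foraging            0      0      153       47
#>   grooming            0      0       38      162
```

The random forest on all features at 6 s windows wins; held-out accuracy is ~89% and
essentially all remaining confusion sits in the foraging/grooming pair —
the two behaviors whose synthetic signal ranges deliberately overlap, as
they do in real kangaroo-rat data. The annotated deployments then yield
activity budgets:

```r
mr <- res$model_ready
day <- mr[mr$phase == "day" & mr$behavior == "travel", ]
weighted.mean(day$proportion, day$total_windows)
#> [1] 0.001372563
```

Travel occupies ~0.14% of the day phase — the animals are nocturnal, and the
recovered proportion matches the generator's day-phase stationary occupancy
(0.165%). Per-behavior GLMMs of the budget proportions against light phase
and sex land in `res$results`, e.g. for motionless the light-phase term gives
χ² = 4733.4 (df = 7, p < 0.001, conditional R² = 0.98) and for travel
χ² = 488.7 (df = 7, p < 0.001, R² = 0.87), while sex (which the generator
does not use) stays non-significant (p = 0.66 and 0.46). A moonlight model
(moon intensity × moon position, restricted to below-horizon phases) lands
in `res$moon_results`.

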