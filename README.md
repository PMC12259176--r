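# memdecode

Simulation and analysis of how **image memorability** and **repetition
suppression** jointly shape the vigor of visual neural population responses,
and of the linear decoders that can — or cannot — read familiarity out of
such populations.

## The problem

In single-exposure recognition memory, the leading account of the neural
familiarity signal is repetition suppression: a repeated image evokes a
weaker population response than a novel one, so a downstream reader can
classify `f(x) = w·x − b > 0` as "novel" with the all-ones weight vector
(a pure population-vigor threshold). But memorability — an image-intrinsic
score in [0, 1] for how likely an image is to be remembered — *also*
modulates vigor in high-level visual cortex: more memorable images evoke
stronger responses even when repeated. A vigor decoder then classifies the
most memorable repeated images as novel, while behaviorally those images are
the *most* likely to be correctly recognized as repeated. `memdecode`
implements this paradox and its resolution end to end on seeded synthetic
data:

- a generator of two-presentation (novel/repeated) image sequences with
  exact n-back target distributions, heterogeneous exponentially tuned
  Poisson units whose evoked rate scales with memorability ("ITC-like") or
  does not ("HC-like"), repetition suppression that grows with memorability,
  and logistic choice behavior;
- the unit/session screening filters and cross-session *pseudopopulation*
  assembly (units concatenated across sessions, image pairs aligned by
  novelty, n-back, and memorability bin);
- population-vigor statistics: grand mean firing rate (GMFR) versus
  memorability, Pearson correlations with exact-t p-values, regression
  slopes with a label-permutation test for slope differences between
  regions, percent suppression and its quartile profile, a log-log estimator
  of suppression scaling (slope 1 = proportional), and sliding-window
  correlation time courses with bootstrap CIs;
- linear memory decoders: per-unit d′, the diagonal-covariance Fisher linear
  discriminant `w_i = (μ_novel,i − μ_repeated,i)/σ̄²_i` (equivalently,
  d′-weighting), the all-ones repetition-suppression (RS) decoder,
  cross-validation with alignment shuffling, sliding-window decoding, and
  ranked unit-removal curves;
- Poisson maximum-likelihood fits of the tuning model `y(x; M) = A_M e^{−αx}`
  per unit, synthetic regeneration from fits, and the tuning-curve
  threshold sweep that probes whether sparsification alone can remove
  memorability while keeping memory (it cannot);
- the memorability-corrected decoder family
  `W(θ) = (cos θ − cot γ sin θ)·1̂ + (csc γ sin θ)·ŵ_MB`, rotating within the
  plane spanned by the RS axis and a memorability prototype axis (γ apart),
  scored against behavior with the prediction quality statistic
  `PQ = 1 − Δθ/90°` (slope-angle difference, reflected above 90°).

Everything is tibble-first and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and result types have `autoplot()` methods.

## Worked example

```r
library(memdecode)

cfg <- itc_config()                       # memorability-gained population
cfg$trial_window <- c(0, 520)             # post-stimulus epoch only

images  <- gen_images(150, seed = 1)
trials  <- gen_sequence(images, nback_spec(c(1, 2, 4, 8), core_count = 35), seed = 1)
units   <- gen_units(cfg, 120, images, seed = 1)
session <- simulate_session(units, trials, images, cfg, seed = 1)
pop     <- assemble_pseudopopulation(session, seed = 1)

tb <- gmfr(pop, window = c(300, 500))
memorability_correlation(tb, "repeated")
#> # A tibble: 1 × 4
#>   novelty      r    df        p
#>   <chr>    <dbl> <int>    <dbl>
#> 1 repeated 0.867   102 1.19e-32
suppression_stats(tb)$mean_percent
#> [1] 11.18458
```

Even repeated presentations correlate strongly with memorability (r = 0.87
across 104 pseudoimages), while repetition suppresses rates by ~11% on
average — the two ingredients of the paradox. The rotation sweep then shows
that a pure vigor decoder is misaligned with behavior while a rotated,
memorability-attenuating decoder predicts it:

```r
behavior <- behavior_by_quartile(simulate_behavior(trials, images, seed = 1), images)
sweep <- theta_sweep(pop, behavior, theta = seq(0, 355, by = 5),
                     window = c(100, 500), n_folds = 5, seed = 1, n_reps = 2)
c(gamma = attr(sweep, "gamma"), best_theta = attr(sweep, "best_theta"),
  best_pq = max(sweep$pq), rs_pq = sweep$pq[1])
#>      gamma best_theta    best_pq      rs_pq
#>   48.23766  310.00000    0.94960    0.31549
```

The RS and memorability axes sit γ ≈ 48° apart; at the RS axis (θ = 0) the
decoded accuracy-vs-memorability slopes are misaligned with behavior
(PQ ≈ 0.32, repeated-condition accuracy *falling* with memorability), while
the best rotation (θ = 310°, about 98° past the MB axis — just beyond
orthogonal, i.e. nearly memorability-blind) aligns with behavior
(PQ ≈ 0.95) and decodes memory *better* than the vigor decoder (0.68 vs
0.59). `autoplot(sweep)` and `autoplot(tb)` draw the corresponding figures.

An end-to-end paired run of both region phenotypes, with the permutation
test comparing their memorability slopes, is one call:

```r
demo <- run_demo(seed = 2, out_dir = "demo_out")
demo$comparison$repeated   # slopes and permutation p for the repeated condition
```

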