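---
title: "Decoding familiarity from memorability-modulated populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding familiarity from memorability-modulated populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(memdecode)
library(dplyr)
```

## The scientific problem

Single-exposure visual familiarity ("have I seen this image before?") is
widely thought to be signaled by *repetition suppression* (RS): when an image
is repeated, the overall vigor of the visual population response — in primate
inferotemporal cortex (ITC) in particular — is reduced, and a downstream
reader could report "repeated" whenever population firing falls below a
boundary. Image *memorability* complicates this account: memorability is an
image-intrinsic score in $[0,1]$ describing how likely observers are to
remember an image, and more memorable images evoke *more* vigorous ITC
responses, even when repeated. A pure vigor decoder therefore classifies the
most memorable repeated images as novel — yet behaviorally those are exactly
the images most likely to be correctly judged repeated. That is the
familiarity–memorability paradox.

`memdecode` implements, on fully synthetic but statistically faithful data,
the complete analysis chain used to expose this paradox and its proposed
resolution: hippocampus-like (HC-like) populations carry an isolated memory
signal (RS that grows with memorability, without memorability modulation of
vigor), and a linear decoder rotated within the plane spanned by the RS axis
and a memorability (MB) axis can extract familiarity from ITC-like
populations while attenuating the memorability nuisance.

## The generative model

Each unit $u$ has baseline rate $b_u$ (spikes/s), peak evoked amplitude
$A_u$, an exponential tuning curve over a private random ranking $r_u(i)$ of
the image set, a memorability gain $g_u$, and repetition-suppression
parameters. For an image $i$ with memorability $m_i$:

* novel evoked rate: $\nu_{u,i} = A_u\, e^{-\alpha_u r_u(i)}\,
  \big(1 + g_u (m_i - 0.5)\big)$, floored at zero (clips are counted and
  reported as a warning);
* repeated evoked rate: $\rho_{u,i} = s_u(m_i)\, A_u\,
  (\nu_{u,i}/A_u)^{\,e_u}$, where $e_u \ge 1$ is the suppression exponent and
  $s_u(m) = s_u - \kappa\,(m - 0.5)$ is the suppression base, optionally
  decreasing in memorability with slope $\kappa$
  (`suppression_mb_slope`).

With $e_u = 1$ and $\kappa = 0$ this is exactly constant proportional
suppression ($\rho = s\,\nu$); $e_u > 1$ makes the log-log relation between
repeated and novel rates steeper than 1, the convention used by
`suppression_scaling()`. The rate is $b_u$ before the response latency,
$b_u + \nu$ afterwards, and the evoked term switches to the suppressed value
at the memory-onset latency on repeated trials; bins straddling a latency use
the exact time integral of the piecewise-constant rate. Counts are Poisson in
20 ms bins. Memorability is centred at 0.5 in the gain term so that the mean
rate is invariant to the gain under a symmetric score distribution. All
randomness flows from one root seed through named sub-streams (images,
sequence, units, spikes, behavior, folds), so every stage is independently
reproducible.

### Region configurations

`itc_config()` and `hc_config()` encode the two population phenotypes:

| parameter | ITC-like | HC-like | meaning |
|---|---|---|---|
| baseline rate | lognormal, median 5 | median 2 | spikes/s |
| peak amplitude | lognormal, median 20, sdlog 0.25 | median 8 | spikes/s |
| selectivity $\alpha$ | lognormal, median 0.02 | same | tuning decay per rank |
| memorability gain | normal(0.8, 0.7) | normal(0, 0.05) | vigor scaling with $m$ |
| suppression base | normal(0.92, 0.03) | normal(0.95, 0.02) | repeated/novel ratio |
| suppression exponent | 1.2 | 1.0 | supra-proportionality |
| suppression–$m$ slope $\kappa$ | 0.2 | 0.03 | RS growth with $m$ |

Two structural choices matter and were made deliberately. First, in the
ITC-like configuration the *memorability gain is heterogeneous across units*
(some units are even negatively modulated) while *suppression is nearly
homogeneous*. This separates the population pattern of the memory signal
from the pattern of the memorability nuisance; if the two heterogeneities
are comparable the memory and memorability directions in population space
become collinear and no linear decoder can remove one while keeping the
other — the resolution the rotated decoder implements would be impossible in
principle, not just hard. Second, repetition suppression grows with
memorability through two channels: the supra-proportional exponent (more
vigorous responses are suppressed by more than a proportional rule predicts)
and the explicit $\kappa$ term; in the HC-like configuration only the
$\kappa$ channel is active, which yields RS that grows with memorability in
a population whose vigor is otherwise memorability-blind.

With these defaults an ITC-like session of 300 images and 500 units shows a
memorability–GMFR correlation near 0.9, mean suppression near 9% growing
from ~6% to ~13% across memorability quartiles, a d′ distribution shifted
positive (~90% suppressed units), and an RS–MB plane angle $\gamma$ near
50°. These are the regimes the downstream analyses assume; the magnitudes
are calibration choices, not predictions.

### Trial sequences and behavior

`gen_sequence()` places each image exactly twice — novel first, repeated
after a gap of `n_back` trials — and realizes an exact target distribution
of on-target gaps (uniform over the interior levels, half-frequency at the
extremes, e.g. 15/30/30/... for a core count of 30). Remaining images become
fillers whose repeats are flagged off-target and excluded from aligned
analyses. Placement is randomized with retries; infeasible targets raise an
error rather than silently degrade.

Behavior is a logistic choice model: the probability of reporting "repeated"
on repeated trials increases with memorability and decreases with
$\log(\text{n-back})$; on novel trials the false-alarm rate is non-increasing
in memorability. Defaults give ~86% hits and ~89% correct rejections with
hit rates rising from ~73% to ~94% across the memorability range, matching
the performance regime of well-trained macaques on this task.

## Screening and pseudopopulations

`responsiveness_filter()` keeps units whose 50–350 ms response differs from
the −300–0 ms baseline (paired two-sided t-test, $p < 0.10$; a unit with
identical pre/post counts is excluded, a perfectly constant responder is
included). `stability_filter()` rejects sessions whose baseline drifts more
than two-fold between the first and last fifth of trials — the paper-style
"across the session" criterion needs a concrete window rule, and
first-versus-last fifth is ours — or whose pre-stimulus rates differ between
novel and repeated trials ($p < 0.01$). Anatomical/hardware criteria are
metadata, not computed.

`assemble_pseudopopulation()` concatenates units across sessions and aligns
image pairs into *pseudoimages* within strata defined by an n-back level and
a memorability bin (default 10 equal-width bins on $[0,1]$; "similar
memorability" has no published bin width, so the bin count is exposed).
Each stratum keeps the minimum eligible pair count across sessions, dropping
excess pairs uniformly at random under the seed. Strata empty in some
session are dropped with a warning by default (`strict = TRUE` errors): with
dozens of strata a hard error would reject essentially every realistic
multi-session combination. `shuffle_alignment()` permutes, within each unit,
which image pair feeds which pseudoimage — destroying across-unit
memorability alignment while preserving each unit's marginal novel and
repeated distributions exactly; this is the control used when a memory
decoder must not be confounded by memorability.

## Vigor statistics

`gmfr()` computes the grand mean firing rate (mean over units, spikes/s) per
pseudoimage and condition in a spike-count window (default 300–500 ms;
100–500 ms is used for the decoding plane). On top of it:

* `memorability_correlation()` — Pearson r with the exact t-transform
  p-value (df = n − 2), matching the convention of reporting parenthetical
  degrees of freedom;
* `permutation_slope_test()` — region labels are reshuffled across points
  without replacement, slopes refit, and the two-sided p computed with the
  observed statistic included in the null set, so $p \ge 1/(n_{perm}+1)$;
* `suppression_stats()` — mean percent suppression and its quartile profile;
* `suppression_scaling()` — the least-squares slope of log repeated GMFR on
  log novel GMFR with a percentile bootstrap CI. A slope of 1 is
  proportional suppression; the generator's suppression exponent is
  recovered by this estimator *on evoked rates*. A baseline offset
  compresses the log-log slope (log(b + cv^e) is flatter than e·log v), so
  exponent-recovery studies use evoked-only configurations and a window
  fully inside the suppressed epoch;
* `correlation_timecourse()` — sliding 150 ms windows stepped by 20 ms with
  percentile bootstrap CIs over pseudoimages and significance flags.

## Decoders

All decoders are linear discriminants $f(x) = w \cdot x - b$ with the class
decided by the sign of $f$ (novel when positive; the integer-count tie
$f = 0$ goes to repeated). The bias is always the class-mean midpoint rule
$b = \tfrac12 w\cdot(\mu_1 + \mu_2)$ on training data.

* `rs_weights()` — all-ones weights: a pure population-vigor threshold.
* `fld_weights()` — Fisher linear discriminant with the off-diagonal
  covariance terms set to zero: $w_i = (\mu_{n,i} - \mu_{r,i}) /
  \bar\sigma^2_i$ with the per-unit variance averaged over conditions,
  floored at $10^{-6}$ of the mean variance. This weights each unit by its
  d′ ($d' = (\mu_n - \mu_r)/\text{pooled SD}$, positive = suppressed).
* `mb_weights()` — a prototype classifier for memorability: the difference
  between mean responses to the top and bottom halves of the training
  memorability distribution, pooling novel and repeated presentations by
  default (the pooling is not dictated by anything stronger than symmetry;
  novel-only and repeated-only variants are available).

Cross-validation partitions pseudoimages (a pair never splits across folds)
into folds dealt round-robin along the memorability order, so every fold
spans the score range; the default is 10 folds (no published fold count
exists, so it is a parameter). `decoding_timecourse()` slides the window;
`ranked_fld()` re-ranks units by their training-fold weights inside each CV
iteration, removes a fraction from either end of the signed ranking, and
refits before testing.

## The tuning model and the threshold sweep

`fit_tuning()` fits, per unit, $y(x; M) = A_M e^{-\alpha x}$ — separate
novel/repeated amplitudes, shared decay, $y$ an expected window *count* —
by Poisson maximum likelihood over the 100–500 ms counts of both conditions.
Because the model is log-linear, the MLE is a Poisson GLM with log link
(`count ~ condition + rank`), fit by IRLS; when the unconstrained decay is
negative the rank term is dropped ($\alpha = 0$, flagged). Image ranks come
from the unit's observed novel/repeated-averaged counts, best (rank 0) to
worst, ties broken by image order.

`apply_threshold()`/`predict_tuning()` implement the sparsification probe:
for a modified fraction $N$, every rank at or beyond the cutoff
$\lfloor (1-N)\,n \rfloor$ has *both* conditions' predictions replaced by
the repeated-curve value at the cutoff rank, collapsing the tail onto one
flat segment that carries no memory signal. The replacement value is
genuinely ambiguous — "the repeated firing" could also mean each rank's own
repeated value, which would preserve sub-threshold tuning and remove memory
only for novel presentations — so both rules are implemented
(`mode = "per_rank_repeated"` for the alternative); the collapsed-tail rule
is the default because the tail then carries no signal of any kind, which is
what a hard sparsification threshold means. `threshold_sweep()` synthesizes
a Poisson population from the (modified) fits at each fraction — sharing one
seed so fraction 0 reproduces the unmodified population exactly — and
reports the repeated-condition memorability correlation and cross-validated
FLD accuracy. The qualitative trade-off this probes: the modification
fraction that drives the memorability correlation to zero also destroys
nearly all memory information.

## The RS–MB plane and the rotated decoder family

With $\hat 1$ the normalized all-ones axis and $\hat w_{MB}$ the unit MB
axis at angle $\gamma$, the rotated family is

$$W(\theta) = (\cos\theta - \cot\gamma \sin\theta)\,\hat 1 +
(\csc\gamma \sin\theta)\,\hat w_{MB},$$

which is unit-norm for every $\theta$, equals $\hat 1$ at $\theta = 0$ and
$\hat w_{MB}$ at $\theta = \gamma$, and satisfies
$W(\theta)\cdot\hat w_{MB} = \cos(\gamma - \theta)$ — so
$\theta = \gamma \pm 90°$ are the memorability-blind directions. The default
sweep covers the full turn (0–359° in 1° steps) rather than half of it:
decoders are signed vectors, $W(\theta)$ and $W(\theta + 180°)$ make
opposite decisions, and with $\gamma < 90°$ the memorability-blind decoder
that *keeps* a positive memory signal lies at $\gamma - 90°$ (mod 360),
outside $[0°, 180°)$.

`theta_sweep()` cross-validates the whole family: per fold the MB axis and
all biases are trained on the training pseudoimages; held-out decisions are
pooled across folds into per-quartile accuracy curves and scored against a
behavioral benchmark with the prediction-quality statistic

$$PQ = 1 - \Delta\theta / 90°,$$

where $\Delta\theta$ is the absolute difference between the slope angles
(via $\arctan$) of the behavioral and predicted accuracy-vs-memorability
regressions, reflected to $[0°, 90°]$ (slopes 180° apart are the same line),
averaged over novel and repeated conditions. Accuracies enter as fractions
in $[0,1]$ so slopes are commensurate with the memorability axis — the
angular metric is not scale-invariant, and percentage units would saturate
every angle near 90°. Quartile bin centers are the midpoints between
consecutive quartile boundaries of the memorability distribution. Repeated
cross-validation (`n_reps`) averages the per-quartile accuracies over
independent fold assignments; the PQ statistic compares slopes of
four-point regressions, and averaging folds out the single-split noise that
otherwise dominates those slopes. The best-PQ rotation is the grid argmax,
with exact ties broken toward the rotation orthogonal to the MB axis.
`rescale_predictions()` maps decoded accuracies onto the behavioral range
with the single multiplicative factor minimizing squared error
(closed form $\sum pb / \sum p^2$), clamping rescaled values above 100%;
this one-parameter rescaling stands in for an explicit population-size
extrapolation, which is deliberately not simulated. `project_plane()`
visualizes held-out responses in an orthonormal basis of the plane (so an
isotropic cloud projects to a circle), rotated 45° for display, with
one-standard-deviation ellipses per condition and memorability quartile
from the eigen-decomposition of the projected covariance.

## Worked example

```{r demo, message = FALSE, warning = FALSE}
cfg <- itc_config()
cfg$trial_window <- c(0, 520)          # post-stimulus epoch only

images <- gen_images(150, seed = 1)
trials <- gen_sequence(images, nback_spec(c(1, 2, 4, 8), core_count = 35),
                       seed = 1)
units <- gen_units(cfg, 120, images, seed = 1)
session <- simulate_session(units, trials, images, cfg, seed = 1)
pop <- assemble_pseudopopulation(session, seed = 1)

tb <- gmfr(pop, window = c(300, 500))
memorability_correlation(tb, "repeated")
suppression_stats(tb)$mean_percent
```

```{r gmfr-plot}
autoplot(tb)
```

```{r sweep, message = FALSE, warning = FALSE}
behavior <- behavior_by_quartile(simulate_behavior(trials, images, seed = 1),
                                 images)
sweep <- theta_sweep(pop, behavior, theta = seq(0, 355, by = 5),
                     window = c(100, 500), n_folds = 5, seed = 1, n_reps = 2)
c(gamma = attr(sweep, "gamma"), best_theta = attr(sweep, "best_theta"),
  best_pq = max(sweep$pq), rs_pq = sweep$pq[1])
```

```{r sweep-plot}
autoplot(sweep)
```

## Numerical choices and degenerate inputs

* Spike-count windows not aligned to bin edges use fractional bin overlap.
* Zero-variance units get FLD weight 0; zero pooled SD gives d′ = 0; both
  are reported. The Poisson log-likelihood floors fitted means at $10^{-8}$.
* Degenerate memorability (all scores equal) makes the MB median split, and
  hence the plane, undefined — an error, not a silent fallback; collinear
  RS/MB axes likewise.
* Permutation p-values include the observed statistic in the null set;
  fewer than 100 permutations are rejected.
* `gen_sequence()` retries randomized placements (100 attempts) before
  declaring the n-back targets infeasible.

## Problem sizes

The packaged analyses and tests run on deliberately modest sizes — sessions
of 150–300 images and 120–800 units, 1,000–10,000 permutations or bootstrap
resamples, 5–10 cross-validation folds, 20-seed replication for the
qualitative claims — chosen so every property of interest is comfortably
detectable at those scales. The generator itself is vectorized and scales
linearly in units × trials × bins.

## What the generator does and does not emulate

It emulates: two-presentation sequences with exact on-target n-back targets;
heterogeneous exponential visual tuning; memorability-scaled vigor with
unit-level heterogeneity; repetition suppression whose magnitude grows with
memorability (proportional or supra-proportional); Poisson count noise;
behavioral accuracy patterns tied to memorability and lag. It does not
emulate: firing-rate adaptation within trials, correlated noise across units
(counts are conditionally independent given rates — real populations share
trial-to-trial variability, which typically *hurts* decoders), eye
movements, reward effects, session drift, or any biophysical spiking
dynamics. Passing tests therefore demonstrate that the analysis chain is
correct and that the paradox-and-resolution logic follows from the stated
population structure — not that real ITC or HC data have that structure.

## Known limitations

* The suppression law ties supra-proportionality to a per-unit power law
  normalized at the unit's peak amplitude; other normalizations would give
  the same proportional limit but different rank-dependence of the
  suppression fraction.
* The MB axis is estimated from finite data; its estimation error leaks a
  residual memorability confound into nominally blind rotations, which is
  why sweep fixtures use hundreds of units and pseudoimages.
* `suppression_scaling()` on baseline-inclusive GMFR underestimates the
  exponent; it is a tool for evoked-rate tables.
* Image ids restart per session; pseudoimage provenance is stored as a
  per-session vector, not a global id.
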