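---
title: "Methods: the synthetic RT-curation benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the synthetic RT-curation benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the generative model, the analysis assumptions, and
the numerical choices behind the package. The question the benchmark is built
to probe: if people recognize some category exemplars reliably faster than
others, do those fast exemplars make disproportionately good training items
for a small image classifier?

Because real reaction-time corpora for this task are not bundled, everything
here is synthetic, and the generator is constructed so that the ground truth
is known: each stimulus carries a latent typicality that *causes* both the
simulated human behavior and the objective learnability of the item. The
package's claims are therefore claims about the pipeline's behavior on this
generator, not about human data.

## 1. Stimulus generator

`glyph_prototypes()` defines four binary 28x28 prototypes (a thick bar, a
cross, an L-shape, a ring outline). The strokes are deliberately balanced to
roughly 70–76 foreground pixels each, so that a deformation of a given pixel
budget degrades every class at a comparable rate; unbalanced strokes would
make one class systematically easier and confound class with difficulty.

`generate_instances()` deforms a prototype by flipping `d` pixels drawn
without replacement from a candidate pool that is, with equal total weight:

* **deletions** — the prototype's own stroke pixels, and
* **spurious additions** — the union of the *other* classes' stroke pixels
  (minus pixels shared with the own stroke).

Additions drawn from other classes' strokes matter: purely random speckle is
trivially separable from stroke structure, while stroke-shaped clutter forces
a classifier to rely on the surviving configuration of the own stroke. The
deformation count is overdispersed,

```
rate ~ Gamma(shape = deform_shape, mean = deform_scale),  d ~ Poisson(rate),
```

a negative-binomial mixture. With a pure Poisson (`deform_shape = Inf`) the
instances cluster tightly around one difficulty level and no clearly clean or
clearly garbled exemplars exist; the Gamma mixing (default `deform_shape = 2`)
spreads the population so that curation has something to find. Typicality is
computed from the *realized* Hamming distance to the prototype:

```
tau = exp(-d / sigma_tau).
```

Defaults (`deform_scale = 60`, `sigma_tau = 38`) put mean typicality near
0.34 with substantial spread; they are study conditions, fixed before any
outcome-based evaluation, not tuned quantities.

## 2. Behavioral simulator

Each simulated participant classifies every instance (`repeats` times, default
2) via a two-boundary drift-diffusion process:

* Euler–Maruyama integration with `dt = 1 ms` and diffusion coefficient
  `s = 0.1`; start point midway between boundaries; the upper boundary is the
  correct response.
* The **drift rate is the only stimulus-dependent parameter**:
  `v_i = beta * tau_i`, with participant drift gain `beta ~ U(0.3, 2)`.
* Boundary separation `a ~ U(0.08, 0.12)`, non-decision time
  `Ter ~ U(0.25, 0.35)` s, and a lapse rate `lambda = 0.02` that replaces the
  response with a uniform class label while keeping the diffusion RT.
* RT is `Ter` plus the first-passage time; incorrect absorptions produce an
  error with the same RT law.

The closed-form hit probability `1 / (1 + exp(-a v / s^2))` is exposed as
`ddm_hit_probability()` and used by the tests to check the simulator against
an independent formula.

## 3. RT analysis

`filter_participants()` drops participants below 75% overall accuracy (the
generator's `beta` range deliberately straddles this filter so it is active).
`rank_within_class()` converts each retained participant's per-instance mean
RTs to *within-class midranks* — ranks are used instead of raw RTs so that
participants with different speed baselines are commensurable, and midranks
conserve rank sums under ties. `score_instances()` then runs, per instance, a
Welch t-test of its ranks against the pooled ranks of its class peers; the
sign labels the instance `easy` or `hard`.

The null calibration of this test is part of the test suite: under
exchangeable ranks its type-I rate is checked to be close to 5% — see
`tests/testthat/test-rt-analysis.R`.

## 4. Curation and augmentation

`curate_extreme()` takes the `k_per_class` most significant instances per
class in the requested direction. One asymmetric rule: an instance that *no*
retained participant ever classified correctly is excluded from the `good`
set (its fast ranks cannot reflect genuine recognizability), but not from the
`bad` set. `curate_random()` (seeded) and `curate_full()` provide the
controls. `augment_images()` expands every image 27-fold: rotations of
{−10°, 0°, +10°} (nearest-neighbor, re-binarized at 0.5) crossed with pixel
shifts of {−1, 0, +1} in each axis.

## 5. Networks

`train_network()` trains a small CNN — conv 6@5x5 / ReLU / 2x2 maxpool, conv
16@5x5 / maxpool, dense 128, dense 64, softmax — with inverted dropout 0.5,
He-normal initialization (Glorot-uniform output layer), and Adam
(`lr = 0.005`, 64 epochs, batch 64). The implementation is hand-written
RcppArmadillo in single precision; all random draws go through R's RNG so a
single `set.seed` (or the `seed` argument) makes training bit-reproducible.
`train_ensemble()` trains `n_nets` members from consecutive seeds
(`base_seed + i - 1`). Confidence for an image is the entropy of the softmax
output, in nats; low entropy = high confidence.

## 6. Correlation analyses

RTs entering correlations are per-participant normalized
(`normalized_rts()`): each participant's per-instance mean RTs are divided by
their sum, removing baseline speed differences. `correlation_report()`
computes, per network, the Spearman correlation between that network's
per-instance entropies and the across-participant mean normalized RT, plus a
headline `rho_of_means` using the ensemble-mean entropy. Spearman p-values
use the asymptotic approximation (`exact = FALSE`), appropriate at the n = 80
item counts used here. `compare_correlation_sets()` Fisher-z-transforms
per-network correlations (clamping |rho| at `1 - 1e-7`) before a Welch
t-test; `compare_accuracy_sets()` is a plain Welch t-test on per-network
accuracies. Significance tiers follow the usual `***`/`**`/`*`/`n.s.`
convention.

## 7. Drift-rate estimation

`pool_moments()` tallies per-instance accuracy and correct-RT moments over
the retained cohort; edge rules flag instances with zero or one correct
response and apply the standard `1 - 1/(2n)` correction to perfect accuracy.
`ez_fit()` is a closed-form EZ-style estimator (with `ez_moments()` its exact
forward inverse, used by the tests for a 1e-6 round trip).
`fit_drifts_shared()` assumes — matching the generator — that only drift
varies across instances: stage 1 fits each instance separately, stage 2 fixes
the boundary and non-decision time at their across-instance medians, stage 3
re-derives per-instance drift from accuracy alone under the shared boundary.
`drift_confidence_correlation()` then correlates fitted drifts with network
entropies (the generative prediction is negative: higher drift, lower
entropy).

## 8. Transfer stage

`run_exp3_analog()` simulates two fresh cohorts whose evidence quality
depends on what they "studied": for a participant trained on curated set S,
the drift on test item j is

```
v_j = gain * max(0, maxJaccard(j, S_class(j)) - sim_floor),   gain ~ U(0.5, 1),
```

i.e. proportional to the item's best pixel-overlap match to the same-class
members of S, with matches below `sim_floor = 0.25` contributing nothing.
Test items exclude members of either curated set. The accuracy comparison
uses all participants; the 2x2 crossed grid (good/bad-trained networks x
good/bad-trained cohorts) restricts correlation analyses to participants
above 50% transfer accuracy.

## 9. Numerical choices

* Single-precision network arithmetic: training is GEMM-dominated; float32
  halves memory traffic and matches the tolerance actually needed (test
  determinism is asserted at 1e-5 on probabilities, exact on stored weights).
* `dt = 1 ms` Euler–Maruyama: first-passage bias at this step size is well
  inside the tolerance of the closed-form accuracy checks (±0.03 at 5000
  trials) used in the tests.
* All stage seeds are derived deterministically from the single `config$seed`
  and kept below 2^31.

## 10. Limitations

* The generator realizes the *hypothesis* (typicality drives both RT and
  learnability); the benchmark can therefore validate the pipeline's power to
  detect such structure, but cannot test whether the hypothesis holds in
  humans.
* Drift proportional to typicality, shared boundary, and uniform lapse are
  modeling conveniences; the EZ-style estimator is consistent with this
  generator by construction and will be biased under generators that violate
  it.
* The CNN is small and the images are binary 28x28 glyphs; absolute accuracy
  levels have no external meaning — only the comparisons between curation
  conditions do.
* The transfer-stage drift rule is a stylized similarity model, not a model
  of human study-phase learning.

## Running everything

```{r}
library(exemplaRT)
res <- run_all(default_config())   # ~6 minutes on CPU, fully seeded
```
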