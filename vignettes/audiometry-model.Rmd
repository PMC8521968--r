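---
title: "A Gaussian-process mixture model for adaptive pure-tone audiometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Gaussian-process mixture model for adaptive pure-tone audiometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the numerical choices and
the synthetic-data generator behind `bayespta`. It is a methods document;
the worked example lives in the README and the quantitative checks live in
the test suite and in `scripts/acceptance.R`.

## 1. The model

### Frequency warping

All smoothness assumptions are placed on the Bark scale,
`bark(f) = 6·asinh(f / 600)`, a psycho-acoustical warping under which
perceptually similar frequency intervals have similar width. The standard
audiometric grid is `r "c(125, 250, 500, 750, 1000, 1500, 2000, 3000, 4000, 6000, 8000)"`
Hz, spanning roughly 1.7 to 20.3 Bark. Polynomial mean functions are
expressed in the centred coordinate `z = x − bark_centre()`, where
`bark_centre()` is the midpoint of the grid's Bark range; centring keeps
the cubic basis well conditioned over the ±9 Bark half-width.

### Response model

A tone of intensity `h` (dB HL) at a frequency with latent threshold `t`
is reported audible (`y = +1`) with probability

    P(y = +1 | h, t) = Φ((h − t) / σ_p),

i.e. threshold evaluation corrupted by Gaussian perceptual noise with
standard deviation `σ_p` (default 5 dB). `σ_p` is not identifiable from
tabulated audiograms alone, so it is a fixed model parameter, not a fitted
one.

### Prior: a mixture of Gaussian processes

An audiogram is modelled as a draw from one of `C` latent classes. Class
`c` is a GP with

- mean `m_c(x) = β_0 + β_1 z + β_2 z² + β_3 z³` (dB HL),
- squared-exponential kernel `k_c(x, x′) = v_c · exp(−(x − x′)² / (2 ℓ_c²))`
  with marginal variance `v_c` (dB²) and length-scale `ℓ_c` (Bark).

Class probabilities `α_c(I)` depend on side information `I` = (age,
gender) through a lookup table keyed by `"ageBucket|gender"` with 5-year
age buckets. Unknown keys resolve by nearest neighbour: bucket distance,
plus a fixed penalty of 500 when exactly one side has an unspecified age
and 1000 for a gender mismatch, so a near-miss in age is always preferred
to crossing gender. Fully unspecified queries return the stored marginal
entry.

### Posterior inference

Given trials `D = {(f_i, h_i, y_i)}`, each component's latent thresholds
at the *distinct* trial frequencies (duplicates share one latent value)
receive a Laplace approximation: Newton iteration with backtracking line
search on the strictly concave log-posterior, gradient tolerance `1e-8`,
at most 100 iterations. The Laplace evidence

    log Z_c = loglik(mode) + logprior(mode) + (n/2)·log 2π − ½·log det H

weights the components, `π_c ∝ α_c(I) · Z_c`, computed in log space with
log-sum-exp. Zero trials give the prior back with `log Z_c = 0` exactly.
Predictions at new frequencies follow standard GP conditioning through the
Laplace posterior covariance. The mixture threshold estimate uses the law
of total variance; the predictive response probability is the closed-form
probit–Gaussian convolution

    P(y = +1 | f, h, D) = Σ_c π_c Φ((h − μ_c(f)) / sqrt(σ_p² + σ_c(f)²)).

### Active stimulus selection

The next stimulus maximises the BALD mutual information between the
response and the latent threshold, which is closed-form here:

    I(f, h) = h₂(P(y = +1 | f, h, D))
            − Σ_c π_c · K/sqrt(σ_c² + K²) · exp(−(h − μ_c)² / (2(σ_c² + K²)))

with `K = σ_p · sqrt(π ln 2 / 2)` and `h₂` the binary entropy (bits). The
default grid is the 11 standard frequencies × intensities −20 to 120 dB HL
in 5 dB steps; ties resolve to the lowest frequency, then the lowest
intensity. A fast variant probes the frequency with the largest
moment-matched predictive variance at the intensity closest to the
predictive mean.

## 2. Learning a population model

`fit_model()` performs maximum-likelihood learning in three stages.

1. **EM.** A full-covariance `C`-component Gaussian mixture on complete
   records over the 11-dimensional threshold vectors; k-means++ seeding,
   best of `n_init` restarts, relative tolerance `1e-6`, at most 500
   iterations. Covariance eigenvalues are floored at `var_floor = 25/12`
   dB² — the within-cell variance of 5 dB quantisation — because with
   quantised data the unrestricted likelihood is unbounded (a component
   can collapse onto duplicated lattice rows).
2. **KL matching.** Each Gaussian `(μ_c, Σ_c)` is converted to a GP
   component by minimising the mass-covering divergence
   `KL(N(μ_c, Σ_c) ‖ N(m_c, K_c + σ_n² I))` over the four mean
   coefficients, `log v`, `log ℓ` and `log σ_n²` (BFGS followed by a
   Nelder–Mead polish). The fitted diagonal noise `σ_n²` absorbs the
   quantisation/measurement variance present in `Σ_c` that a smooth SE
   kernel cannot represent; it is reported as an attribute but is *not*
   part of the latent-threshold component. Without this term the match
   degenerates: the optimiser shortens the length-scale drastically to
   inflate the kernel's near-null eigenvalues toward the noise floor.
3. **Side-information table.** Every record's posterior responsibilities
   are computed under the marginal density `N(m_c, K_c + σ_n² I)` on the
   record's *defined* frequencies (so incomplete records contribute), then
   averaged within each `(age bucket, gender)` key. The unconditional
   entry stores the EM mixing weights. Using the noiseless prior here
   fails for the same reason as in stage 2: recorded audiograms sit off
   the smooth prior manifold and responsibilities collapse to one-hot
   vectors unrelated to curve shape.

Model comparison uses the zero-trial held-out score

    LL(t) = Σ_x log Σ_c π_c N(t_x | μ_c(x), σ_c(x)²),

the per-frequency marginal mixture density of a tabulated audiogram.

## 3. The synthetic-data generator

`default_population()` defines three audiogram prototypes:

- **flat** (mild, age-neutral): constant 20 dB HL mean, `v = 36`, `ℓ = 4`;
- **sloping** (presbycusis-like): cubic least-squares fit of a 20→70 dB
  ramp linear in Bark, `v = 100`, `ℓ = 5`;
- **cookie-bite** (mid-frequency loss): cubic fit of
  `15 + 35·exp(−(x − bark(1500))²/(2·2.5²))`, `v = 64`, `ℓ = 3`.

Class probabilities shift smoothly with age — the sloping share is
`plogis((age − 60)/12)`, the remainder splits 70/30 between flat and
cookie-bite, with the cookie-bite share multiplied by 1.5 for female
records — so that synthetic side information is genuinely informative.
Ages are drawn from a discretised normal centred at 58 (SD 18) on
[15, 100]; gender is balanced. Thresholds are drawn from the selected GP
at the standard grid and quantised to 5 dB (round half away from zero),
matching how audiograms are recorded. `missingness_mask()` blanks a
requested fraction of non-anchor cells while always keeping the clinical
anchor frequencies 500/1000/2000/4000 Hz.

The generator is a caricature, by design: it produces archetypes with
known mixing rules so that parameter recovery and side-information
benefits are checkable. It does not emulate conductive-versus-sensorineural
distinctions, asymmetric ears, test–retest drift, non-Gaussian response
lapses, or the age-by-frequency interaction structure of real clinical
populations.

## 4. Numerical choices

- **Jitter.** Kernel Gram matrices get `1e-8 · v` on the diagonal before
  Cholesky; `chol_jitter()` escalates the jitter if needed. The KL-match
  target is jittered identically so that a perfectly matching GP attains
  a divergence of numerically zero.
- **Stable probit terms.** `φ/Φ` ratios are computed via
  `exp(dnorm(log) − pnorm(log.p))`; curvature terms are clamped at zero
  against floating-point noise.
- **Centred total variance.** The mixture predictive variance is computed
  as `Σ_c π_c (σ_c² + (μ_c − μ)²)`, not `E[σ² + μ²] − μ²`; the latter
  loses ~13 digits to cancellation at audiometric scales and breaks exact
  ties in stimulus selection.
- **Newton stagnation.** The Laplace solver also accepts convergence when
  an accepted update moves the iterate by less than `1e-9` dB, the
  floating-point noise floor of the objective for extreme trial
  configurations.
- **Laplace accuracy.** The evidence estimate is exact at zero trials and
  accurate to a few `1e-3` nats once trials bracket the threshold, but for
  a *single* trial near the prior mean under a wide prior (SD 10 dB) the
  posterior skew biases it by up to ~4e-2 nats. Posterior mixing weights
  are much more accurate than the individual evidences because the bias
  largely cancels across components (see the inference tests).
- **Log-space mixing.** `π_c` and the held-out score are computed with
  log-sum-exp throughout.

## 5. Problem sizes

The defaults used in the tests and the acceptance script are the
package's own choices, sized for desk-scale runtimes: populations of
1000–5000 synthetic audiograms for fitting (a 5000-record, C = 3 fit
takes a few seconds), 4000/1000 train/held-out splits for model
comparison, 25-trial adaptive tests (~0.5 s each with C = 3), and 30–50
paired targets for simulation experiments.

## 6. Limitations

- `σ_p` is fixed, shared across frequencies, and assumed equal in the
  simulator and the model under test unless overridden.
- The cubic-mean/SE-kernel family cannot express notched audiograms
  sharper than its length-scale, and thresholds are modelled without
  floor/ceiling effects at the limits of audiometric equipment.
- The Laplace evidence bias above means single-response evidences should
  not be over-interpreted; mixing weights are reliable.
- The side-information table is a frequency-bucket lookup, not a smooth
  regression; sparsely populated buckets inherit nearest-neighbour
  entries rather than shrinking toward the marginal.
- Sequential inference refits from the full trial list at every step
  (exact, and fast at these sizes) rather than updating incrementally.
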