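---
title: "Normative modelling of brain morphometry with a conditioned adversarial autoencoder"
author: "aaenorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative modelling of brain morphometry with a conditioned adversarial autoencoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Normative modelling turns a group-comparison question into an anomaly-detection
one: instead of asking whether patients differ from controls on average, it
asks how far each individual sits from the healthy population's pattern.
`aaenorm` implements this with an adversarial autoencoder (AAE) over 101
regional brain volumes (68 Desikan–Killiany cortical subregions plus 33 Aseg
structures), trained exclusively on healthy controls.

The encoder maps the normalised feature vector $x \in \mathbb{R}^{101}$ through
two 100-unit leaky-ReLU hidden layers to a 20-dimensional linear latent code
$h$. The decoder receives $h$ concatenated with a 29-bit demographic condition
(a 27-position one-hot age vector over the 47–73-year range and a 2-position
sex vector) and maps it back to a 101-dimensional reconstruction $\hat{x}$.
Conditioning the decoder forces age and sex information out of the latent code,
so the model reconstructs "a healthy brain of this age and sex" rather than
memorising demographics. A discriminator (20 → 100 → 100 → 1) is trained to
tell standard-normal prior samples from encoded codes; the encoder is trained
to fool it, which pushes the empirical latent distribution toward the prior.

A subject's deviation from the norm is the mean squared reconstruction error

$$\mathrm{deviation}(x) = \frac{1}{101} \sum_{i=1}^{101} (x_i - \hat{x}_i)^2,$$

and the per-region squared errors $(x_i - \hat{x}_i)^2$ decompose it exactly,
which is what lets the same score be attributed to anatomy.

## Feature pipeline

Raw volumes are divided by total intracranial volume (head-size correction),
then robust-scaled per region: subtract the training-set median, divide by the
training-set interquartile range (type-7 linear-interpolation quantiles — the
convention is fixed so that small-sample tests are exact). The fitted medians
and IQRs are part of the model: clinical cohorts are always normalised with the
training cohort's statistics, never their own. Ages are integer years in
[47, 73]; fractional ages are rejected rather than rounded, because the one-hot
conditioning has no representation for them and silent rounding hides data
errors.

## Training

Each minibatch (size 256) performs three sequential updates:

1. **Reconstruction** — encoder and decoder minimise mean squared
   reconstruction error;
2. **Discriminator** — binary cross-entropy against fresh prior samples
   (label 1) and freshly encoded codes (label 0);
3. **Generator** — the encoder takes a non-saturating step to make its codes
   classified as prior.

All three phases use Adam (moments 0.9/0.999, eps 1e-8, separate state per
phase) for 200 epochs under a decaying triangular cyclical learning rate:
base 0.0001, first peak 0.005, amplitude multiplied by gamma = 0.98 each
cycle, half-period defaulting to 4 epochs' worth of minibatches.

Two numerical choices here are the package's own, and they matter:

* **Adversarial learning-rate scale (`advLrScale`, default 0.2).** Running the
  discriminator/generator phases at the full cyclical schedule (peak 0.005)
  makes the two-player game oscillate without ever settling: latent means
  drift beyond ±1 and a probe classifier separates codes from prior samples
  almost perfectly, at desk scale and at reference scale alike. Scaling the
  adversarial phases' learning rate by 0.2 (the reconstruction phase keeps the
  full schedule) lets the game equilibrate. Note that with Adam a *loss
  weight* is nearly a no-op — Adam normalises gradient magnitudes — so the
  learning-rate scale is the knob that actually balances the game;
  `advWeight` is retained for completeness.
* **Discriminator steps (`discSteps`, default 2).** One discriminator update
  per generator update leaves the critic too weak to pin down the latent
  scale (per-dimension SDs settle around 1.1–1.25). Two updates per minibatch,
  each with fresh prior samples, bring the latent moments to |mean| < 0.06 and
  SD within a few percent of 1, and a freshly trained discriminator-style
  probe reaches only chance-level AUC (~0.52). Both diagnostics are exposed
  via `latentPriorCheck()`.

Training runs in a compiled loop (RcppArmadillo) with all randomness drawn
from R's RNG, so a seed fully determines the result; the R-level network code
is used for inference and is checked against finite-difference gradients in
the test suite.

## Bootstrap evaluation

The headline analysis retrains the whole model on bootstrap resamples of the
reference cohort: per iteration, draw subjects with replacement (size
`n_ref - sizeOffset`; the reference-scale analysis this package emulates drew
11,032 of 11,034, our default offset is 0), re-fit the scaler, train a fresh
AAE, then score every clinical subject. Per iteration we record group mean
deviations, all pairwise mean differences, the deviation-score AUC of each
patient-vs-HC contrast, and per-region Cliff's delta effect sizes. Percentile
CIs (type-7 quantiles, 95%) aggregate over iterations; an effect is flagged
when its CI excludes zero. Per-iteration seeds derive deterministically from
one master seed, so any single iteration can be replayed alone.

Cliff's delta and the AUC share one pair-counting core (ties count one half),
which makes the identity $AUC = (\delta + 1)/2$ hold to machine precision and
lets each serve as a check on the other.

## The classifier baseline

The comparison arm is a linear-kernel relevance vector machine: sparse
Bayesian logistic classification over the kernel design matrix (bias + Gram
row per training point), fitted by alternating a Laplace approximation
(damped Newton with backtracking) with evidence updates
$\alpha_j \leftarrow \gamma_j / w_j^2$. Weights whose precision exceeds 1e9
are pruned — the absolute-threshold convention of standard sparse-Bayesian
implementations; a relative threshold never fires here because the
irrelevant-weight precisions diverge only after the relevant ones have
stabilised. The evidence iteration's tail is a slow oscillation that leaves
predictions unchanged, so the default cap is 100 outer iterations (AUCs agree
with a 500-iteration run to four decimals).

Within-cohort performance uses the 0.632+ bootstrap: resample the pooled
HC+patient subjects to the pool's size, hold out the never-drawn subjects as
the out-of-bag set, and blend resubstitution and out-of-bag AUC with
$\omega = 0.632 / (1 - 0.368 R)$, where $R$ is the relative overfitting rate
with 0.5 as the no-information AUC, clipped to [0, 1]. At $R = 1$ the formula
itself yields $\omega = 1$ (complete overfitting: trust only the out-of-bag
estimate); the cap at 1 is a safety net, not an active constraint. Iterations
whose out-of-bag set lacks a class are redrawn so the iteration count stays
fixed. Cross-cohort generalization applies each iteration's model (and its
training scaler — deployment logic) to external cohorts; classifier-vs-
normative comparisons pair the two bootstrap series by iteration index and
take the percentile CI of the differences.

## The synthetic cohort generator

Real multi-cohort morphometry (the reference analysis used UK Biobank plus
five clinical cohorts) is access-controlled, so the package ships a generator
that emulates its statistical structure. A subject's volume in region $r$ is

$$v_r = b_r \cdot \frac{tiv}{\overline{tiv}} \cdot
  \bigl(1 + s_r(\mathrm{age} - 60) + m_r\,[\mathrm{male}]\bigr) \cdot
  (1 + e_r) \cdot e^{\varepsilon},\qquad \varepsilon \sim N(0, \sigma^2).$$

Choices and defaults, fixed once:

* **Multiplicative log-normal noise** ($\sigma = 0.10$, ~10% between-subject
  CV) keeps volumes positive and produces the right-skewed deviation
  distributions seen in practice (the reason the analysis uses nonparametric
  effect sizes). TIV is Gaussian (mean 1.5e6 mm³, SD 1.3e5), resampled rather
  than clipped if a draw is non-positive.
* **Ageing effects**: cortical regions lose 0.3%/year, subcortical 0.2%/year,
  ventricular spaces expand 2%/year; a 2% male offset beyond TIV. These are
  the normal-ageing signals the conditioned decoder has to absorb.
* **Disease stages**: `adEffectMap(severity)` scales a fixed atrophy pattern
  linearly — at severity 1, hippocampus −25%, amygdala −22%, entorhinal −28%,
  parahippocampal −20%, lateral ventricles +40%, temporal horns +50%, 3rd
  ventricle +30% (13 affected regions). The EMCI/LMCI/AD analogues use
  severities 0.3/0.6/1.0. Magnitudes are a qualitative emulation of the
  published atrophy pattern, not fitted values.

What the generator does **not** emulate: scanner/site effects, longitudinal
trajectories, region–region correlation beyond the shared TIV and age/sex
factors, and non-log-normal tails. Passing tests on these cohorts therefore
demonstrates that the pipeline recovers known structure under its own
generative assumptions — not that it would perform identically on real
multi-site data.

## Problem sizes and determinism

The desk-scale configuration — reference n = 2,000, clinical groups of 150,
B = 20 normative bootstrap iterations, b = 50 classifier iterations, 200
epochs retained — is the package's default experiment and what the test suite
and acceptance script run; the reference-scale analysis (n = 11,034,
B = 1,000) is a documented configuration of the same functions. The null
calibration run uses a 1,000-subject reference, a zero-effect pseudo-patient
group and B = 12 at 100 epochs. Every stage derives its seeds from one master
seed; identical seeds give byte-identical cohort files, training logs and
result tables.

## Degenerate inputs and edge rules

* Regions with zero training IQR abort scaler fitting by name (a constant
  region cannot be normalised).
* Cohorts entering training must be all-HC; mixed cohorts are an error, not a
  filter.
* Bootstrap resamples re-uniquify subject identifiers so repeated subjects
  remain valid records.
* An out-of-bag set missing a class triggers a redraw (logged via the
  `redraws` counter) rather than dropping the iteration.
* Model artefacts carry an md5 sidecar; a checksum mismatch refuses to load.

## Known limitations

* The adversarial equilibrium settings were chosen on synthetic cohorts; real
  data with different feature scales may need `advLrScale`/`discSteps`
  adjusted (the `latentPriorCheck()` diagnostics say whether they do).
* The RVM evidence iteration is stopped pragmatically rather than at strict
  convergence; posterior covariances are therefore approximate (predictions
  are stable, hyperparameter traces are not).
* Deviation CIs reflect model-retraining variability only — the clinical
  cohorts are fixed across bootstrap iterations, as in the original scheme —
  so they understate total sampling variability for small clinical groups.
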