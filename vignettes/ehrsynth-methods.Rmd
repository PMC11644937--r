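---
title: "Generating and evaluating synthetic clinical tables with ehrsynth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and evaluating synthetic clinical tables with ehrsynth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrsynth)
```

## What the package models

`ehrsynth` synthesizes patient-level tables that mix continuous measurements
with categorical diagnoses, using a conditional generative adversarial network
built specifically for tabular structure. Three ideas carry the design:

1. **Mode-specific normalization.** Continuous clinical variables are rarely
   unimodal — an HbA1c column mixes diabetic and non-diabetic sub-populations.
   Min–max or z-scoring across such a column destroys that structure. Instead,
   each continuous column is modelled as a Gaussian mixture; every value is
   assigned to its most responsible component $k$ and encoded as
   $v = (c - \mu_k)/\sigma_k$ together with the one-hot indicator of $k$. The
   normalized value is clipped to $[-0.99, 0.99]$ for numerical stability.
2. **Separate conditional pathways.** The generator builds each column with its
   own sub-network: continuous pathways are conditioned on a sampled mixture
   mode (its one-hot and its $(\mu_k, \sigma_k)$ metadata), categorical
   pathways on an embedded class sampled from the empirical frequencies. The
   condition is copied through to the output layout, so inverting the
   representation is always well defined.
3. **A diversity-aware, norm-controlled critic.** The critic sees flat
   transformed rows, prepends minibatch-discrimination statistics (batch
   similarities that expose mode collapse), and wraps every dense layer in
   spectral normalization so its Lipschitz constant stays near one — the
   stability device that lets the Wasserstein objective be trained hard
   without vanishing gradients. Its scalar output has no final activation;
   higher means "more likely synthetic".

## Model assumptions

The generator treats rows as exchangeable and columns as conditionally
independent given the noise vector and the condition; inter-column dependence
is learned only through the shared noise and the adversarial signal, not
through an explicit dependence model. Continuous marginals are assumed to be
adequately described by finite Gaussian mixtures after clipping; categorical
columns are assumed to be closed vocabularies (generation can never invent an
unseen category — by construction, not by luck).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `max_modes` | 10 | Mixture-component cap per continuous column; BIC picks $1..G$, components with weight $< 10^{-3}$ are pruned and weights renormalized. |
| `sigma_floor` | $10^{-6}$ | Lower bound on component standard deviations; the reported deviation for constant columns. |
| `z_dim` | 128 | Total noise dimension, sliced contiguously across the per-column pathways. |
| continuous widths | 64, 64 | Dense widths of each continuous sub-network (LeakyReLU 0.2, batch norm, dropout 0.2, `0.99 tanh` head). |
| categorical width | 64 | Hidden width of each categorical sub-network (ReLU, batch norm, dropout, softmax head); embedding dimension `min(8, n_classes)`. |
| critic widths | 256, 128 | Spectrally normalized dense stack; LeakyReLU 0.2, dropout 0.3. |
| `mb_kernels`, `mb_dim` | 16, 8 | Minibatch-discrimination kernels $B$ and projection dimension $C$. |
| power iterations | 1 train / 5 eval | Per-forward spectral-norm refinement steps (cold starts iterate to convergence). |
| `epochs`, `batch_size` | 300, 32 | Training length and minibatch size (size $\ge 2$: minibatch discrimination needs neighbours). |
| `lr`, `betas` | $2\times10^{-4}$, (0.5, 0.9) | Adam settings, one critic step per generator step. |
| `tau` | 0.1 | Correlation-preservation tolerance in the evaluation suite. |

The architecture literature this package follows leaves sub-network depths,
widths, and the minibatch/spectral hyperparameters unstated; the values above
are this package's declared defaults, all configurable through
`generator_spec()`, `critic_spec()` and `train_config()`.

## Design choices made where the design was open

* **Conditioning by concatenation.** The condition enters each continuous
  pathway as `[z-slice, one-hot(k), standardized (mu_k, sigma_k)]`. The
  component parameters are standardized by the column's mixture-implied
  overall mean and deviation so their scale matches the noise. Modifying the
  noise multiplicatively would be an alternative; concatenation is simple,
  differentiable and inspectable.
* **Hard mode assignment in the flat layout.** The transform keeps both the
  soft responsibilities and the hard argmax mode; the flat row the networks
  exchange carries the hard one-hot (the soft posterior is available on the
  `transformed_table` for analysis). Feeding the critic the soft posterior
  instead is a plausible variant; the hard assignment keeps the real and
  generated representations structurally identical.
* **Mixture fitting by BIC-selected maximum likelihood.** Component-count
  adaptation uses `mclust` (unequal-variance models, $G = 1..10$, a variance
  prior for near-degenerate columns, BIC selection) rather than a variational
  mixture with a weight-concentration prior. Both adapt the effective number
  of components from the data; the likelihood route is deterministic,
  well-tested R practice, and its pruning step (weight $< 10^{-3}$) removes
  the residual components a Bayesian prior would have shrunk.
* **Categories are decoded by sampling.** Generated softmax blocks are decoded
  proportionally by default (argmax available), which preserves minority
  categories in small samples.
* **Batch normalization inside the spectrally normalized critic** follows the
  architecture as described, although the combination formally weakens the
  Lipschitz bound; `critic_spec(batchnorm = FALSE)` restores the strict
  surrogate.
* **Loss orientation.** The Wasserstein objective is written against the
  critic convention "higher = synthetic": critic loss
  `mean(real) - mean(fake)` (minimized), generator loss `mean(fake)`
  (minimized). An equivalent formulation flips both signs; the package
  implements the stated convention and all tests are written against it.
* **Missing values** raise an error by default; `missing = "drop_rows"` is the
  only built-in alternative. Imputation is out of scope.
* **Ties** in any argmax (mode assignment, categorical decoding) break to the
  lowest index, deterministically.

## The reference cohort generator

Real cardiovascular cohorts of this shape are access-restricted, so the
package ships `simulate_cohort()`: a fully synthetic, seeded stand-in with the
same schema — 13 continuous and 11 categorical columns, 218 records by
default. Its generating parameters are invented, chosen once to reproduce the
documented qualitative features of such data:

* bimodal baseline labs (e.g. HbA1c as a 55/45 mixture of N(5.6, 0.45²) and
  N(8.6, 1.2²), which guarantees the multimodal pathway is exercised);
* a zero-inflated log-normal coronary-calcium score (35% exact zeros,
  log-normal(4.6, 1.4) otherwise) for a genuinely heavy tail;
* follow-up measurements equal to baseline plus a small systematic shift plus
  noise scaled so the baseline/follow-up Pearson correlation is 0.6;
* height N(167, 9²) cm, weight linear in height plus noise, and BMI computed
  exactly as `WT / (HT/100)^2` — never drawn;
* an exact `round(0.766 n)` male count and ages drawn from a two-component
  mixture truncated strictly above 30 years;
* imbalanced binaries (hypertension 70% positive down to prior stroke 7%) and
  a three-level kidney-function category.

Ground truth (component parameters, analytic means and deviations where
tractable) is returned with the cohort, so recovery tests assert against what
was actually simulated. What the generator does **not** emulate: real
inter-diagnosis dependence (binaries are drawn independently), measurement
artefacts, missingness, or any claim of clinical equivalence to a hospital
cohort. Passing tests therefore demonstrate that the pipeline recovers the
structure this generator puts in — multimodality, heavy tails, imbalance,
baseline/follow-up coupling — not that it reproduces any particular real
dataset.

## Numerical choices

* Responsibilities are computed in log space, so far-tail points still yield
  posteriors that sum to one within $10^{-6}$.
* Clipping at $\pm 0.99$ binds often (any value beyond one component deviation
  from its mode clips); inversion is exact wherever it does not bind, and the
  round trip is tested at $10^{-9}$ on exactly those rows.
* Cold-start spectral normalization iterates the power method to convergence
  ($10^{-9}$ relative change, capped at 1000 rounds); training refreshes a
  persistent `u` vector with one step per forward pass and evaluation with
  five.
* All gradients are hand-derived and verified against central finite
  differences in the test suite (tolerances $10^{-3}$–$10^{-4}$), including
  the minibatch-discrimination layer and the spectral-norm correction term.
* Non-finite losses abort training with a diagnostic rather than continuing
  silently.

## Problem sizes used in the shipped checks

The package's own validation trains the default architecture for 300 epochs on
the 218-row reference cohort (batch 32, one critic step per generator step,
seeds 1–3, a few minutes per run on one CPU core), then compares the mean KS
statistic of 218 generated rows against the same statistic from an untrained
generator, and checks that every binary column whose minority class exceeds
10% achieves Jaccard 1. Mixture-recovery checks use 1000 points from a
two-component simulation separated by 10 standard deviations; metric oracles
run on hundreds of small random cases.

## Known limitations

* Column dependence is learned implicitly; strongly coupled columns (e.g.
  derived quantities like BMI) are not constrained to satisfy their defining
  identities in generated data.
* The clip range $[-0.99, 0.99]$ truncates each mode at roughly one component
  deviation, compressing within-mode spread; fidelity in the far tails is
  correspondingly limited.
* The correlation preservation rate depends on its tolerance $\tau$, which is
  always reported alongside the rate; rates computed under different
  tolerances are not comparable.
* Training runtime grows linearly with the number of columns (one sub-network
  each); very wide tables will be slow in this pure-R implementation.
* No privacy or identifiability guarantees are made or measured.
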