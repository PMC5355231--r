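---
title: "Conditional fingerprint generation with an adversarial autoencoder: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional fingerprint generation with an adversarial autoencoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(molaae)
```

## The model and its assumptions

`molaae` trains an adversarial autoencoder (AAE) on triples
(fingerprint, concentration, growth inhibition). The data model is the
dose-response screen of a single tumor cell line: each assay record is a
compound's 166-bit MACCS fingerprint **b**, the log10 molar concentration
`LCONC` at which it was tested, and the growth-inhibition percentage `GI`
observed at that concentration (negative GI = net reduction of tumor
cells). One training row corresponds to one (compound, concentration)
record; a compound tested at five concentrations contributes five rows
with the same fingerprint, because the autoencoder must learn to encode
and reconstruct the concentration as well as the structure.

The encoder (167 → 128 → 64 → 5) compresses (**b**, LCONC) into a
five-neuron latent code deliberately split in two: a single *GI neuron*,
trained by mean-squared-error regression to equal the measured GI, and a
4-d *representation* pushed toward a standard-normal prior by a
discriminator (4 → 64 → 64 → 1) that only ever sees those four neurons.
The decoder (5 → 64 → 128 → 167) maps a latent code back to 166
independent Bernoulli probabilities (logistic outputs, hence strictly
inside (0, 1)) plus a linear LCONC output. The modeling assumptions worth
stating explicitly:

- *Bit independence given the code.* The decoder factorizes the
  fingerprint distribution as a product of per-bit Bernoullis; all
  correlation between keys must be carried by the 5-d latent bottleneck.
- *A scalar efficacy axis.* One neuron suffices to encode "how active is
  this compound at this concentration"; the regression target is the raw
  assay GI, not a dose-response summary (no GI50 fitting anywhere).
- *Concentration-invariant structure.* The same molecule tested at
  different concentrations should map to the same representation. This is
  not implied by reconstruction (which needs concentration information in
  the latent) and is imposed explicitly by the manifold cost below; the
  tension is resolved by the GI neuron, which legitimately varies with
  concentration and becomes the channel through which the decoder
  recovers LCONC.

## The five-step iteration

Each minibatch triggers five sequential SGD updates, each on its own
parameter group with its own learning rate (there is no mixed objective):

a. **Discriminator** learns to label prior draws 1 and encoded
   representations 0 (binary cross-entropy over the combined batch, so a
   constant-0.5 discriminator scores ln 2; representations are detached
   from the encoder here).
b. **Encoder (confusion)** minimizes the cross-entropy of its
   representations against label 1, with the discriminator frozen.
c. **Encoder + decoder (reconstruction)** minimize the summed fingerprint
   logloss plus the squared LCONC error, batch-averaged.
d. **Encoder (GI regression)** fits the GI neuron by MSE.
e. **Encoder (manifold)** encodes each fingerprint of the batch at
   `manifold_batch` concentrations drawn from a normal with the
   *dataset's* concentration mean and variance, and minimizes one minus
   the mean pairwise cosine similarity of the resulting representations
   (0 when parallel, 1 orthogonal, 2 antiparallel; the mean is over all
   unordered pairs within a draw group, and a zero-norm representation
   contributes similarity 0 with a warning rather than NaN).

Strict step isolation is enforced and tested: step (a) touches only the
discriminator, (b)/(d)/(e) only the encoder, (c) encoder and decoder.

## Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| `encoder_widths`, `decoder_widths` | 128/64, 64/128 | hidden neurons (reference architecture) |
| `latent_width` | 5 | 1 GI neuron + 4-d representation |
| `leak` | 0.01 | negative slope of the leaky rectifier |
| `batch_size` | 64 | records per minibatch |
| `epochs` | 200 | passes over the training set |
| `lr` | disc/confuse/recon 0.05, gi 0.1, manifold 0.5 | per-step SGD rates |
| `manifold_batch` | 8 | concentration draws per fingerprint in step (e) |
| `grad_clip` | 5 | per-step global L2 gradient-norm ceiling |
| `eps` | 1e-7 | probability clamp for every log term |
| `holdout_frac` | 0.1 | records reserved for discriminator-accuracy tracking |
| `gi_mean`, `gi_sd` | 5, 1 | GI percent prior at generation |
| `lconc_threshold` | −5.0 | strict log10 molar cutoff on decoded profiles |
| `k`, `chunk_size` | 10, 1000 | hits per profile; library rows per streamed chunk |

## Numerical and design choices

Several aspects of the procedure are genuinely open and were fixed as
follows, once, as package policy:

- **Standardization (default on).** GI lives on the percent scale
  (spread of tens), LCONC near −6. Feeding them raw makes the GI
  regression gradients two orders of magnitude larger than the
  cross-entropy and adversarial gradients, and plain SGD then needs
  per-step rates so disparate that the shared encoder destabilizes — we
  observed divergence at any GI rate large enough to learn the
  regression. Training therefore z-scores LCONC and GI by the
  training-set moments (`norm_stats`, stored with the model). Everything
  user-facing stays on raw scales: decoded LCONC is un-standardized
  before the −5.0 filter (the threshold is meaningful in molar units),
  `predict_gi()` reports percent, and the generation prior N(5, 1) is
  interpreted in GI percent and converted to latent units inside
  `generate_profiles()`. Raw-scale training remains available
  (`standardize = FALSE`) for data already on tame scales.
- **Gradient clipping.** Each step's gradients are jointly rescaled to a
  global L2 norm of at most `grad_clip = 5`. Leaky-ReLU networks under
  plain SGD occasionally emit a minibatch gradient large enough to tip
  the shared encoder into divergence; clipping is the standard remedy and
  leaves small-gradient behavior untouched.
- **Hidden activation.** Leaky rectified linear units (slope 0.01);
  piecewise-linear activations keep gradients well behaved, and the leak
  avoids dead units in the narrow 5-d bottleneck.
- **Output activations.** Logistic for the 166 bit probabilities (the
  logloss needs (0,1)); identity for decoded LCONC, the GI neuron, and
  the representation (regression and prior matching need unbounded
  reals). Whether the GI neuron carries an output nonlinearity is
  unspecified in the reference design; linear is assumed and recorded.
- **Label convention.** Prior = 1, encoded = 0 — arbitrary but fixed.
- **Probability clamp.** All probabilities entering a log (reconstruction,
  adversarial, screening) are clamped to [1e-7, 1 − 1e-7], preventing
  −∞ from saturated logistic outputs.
- **Adversarial prior.** Standard normal with independent components over
  the 4-d representation; configurable.
- **Discriminator architecture.** Unspecified in the reference design;
  two hidden layers of 64 suffice to tell structured representations from
  the prior at this latent width, and the choice is recorded in the
  model's immutable config.
- **Filter boundary.** "LCONC < −5.0" is read as a strict inequality on
  the raw log10 molar scale; −5.0 itself is excluded.
- **Screening score.** "Maximum likelihood" is implemented as the
  independent-Bernoulli log-likelihood of library bits under a profile's
  per-bit probabilities — the natural likelihood for a probability
  vector. The sum is not normalized by bit count (constant 166, so
  ranking is unaffected). Ties break by library order, first seen wins,
  which makes streamed and exhaustive rankings identical by construction.
- **Seed fan-out.** A pipeline's single seed is hashed per stage
  (`stage_seed()`; exact in doubles, below 2^31) so stages can be rerun in
  isolation and two runs with one config are byte-identical.

## The synthetic-data generator

`generate_synthetic()` stands in for a real single-cell-line
dose-response screen joined to fingerprints. It emulates:

- *Structural clustering*: fingerprints are noisy copies of a few
  prototypes (default 4 prototypes at density 0.3, per-bit flip rate
  0.05, 500 compounds), mimicking chemical series around scaffolds.
- *Concentration design*: LCONC ~ N(−6, 1.5²) — screens typically span
  ~10 nM to 100 µM, centered near 1 µM.
- *Dose response*: GI = Σ w·b − 10·LCONC + ε, ε ~ N(0, 5²), with eight
  designated bits carrying weights ±10..±40. GI lands on the percent
  scale with spread ≈ 34 and a negative dose slope (higher concentration
  → more inhibition); the noise SD of 5 is small against that signal, so
  the GI head's held-out R² is limited by the model, not the noise. The
  generating weights are returned, and with zero noise they are exactly
  recoverable by least squares — the oracle the tests use.

What it does **not** emulate: correlated key structure within a real
MACCS dictionary (substructure keys are logically dependent; synthetic
bits flip independently), heteroscedastic and censored GI readouts,
replicate structure across plates, and any relation between a bit's
chemical meaning and its GI weight. Passing tests on synthetic data
therefore demonstrate that the machinery optimizes what it claims and
that ground truth is recovered where recovery is well-posed — not that
the learned chemistry transfers to a real screen.

Problem sizes throughout the test suite and the acceptance script — 500
training compounds, a 5000-compound library, 640 prior draws, 200 epochs
— keep a full run around a minute on one CPU while leaving every
estimate comfortably away from small-sample artifacts.

## Featurization

MACCS keys are computed through Open Babel (`ChemmineOB`), the toolkit
whose key definitions the workflow was designed around; key *i* of the
166-key public dictionary maps to vector position *i*. Key definitions
differ subtly across cheminformatics toolkits, so the test oracle is
pinned to one implementation: a frozen panel of 24 SMILES with on-bits
computed independently by the `obabel` command-line tool. Exact bit
parity with any particular historical pipeline (CACTVS-generated SMILES,
older Open Babel releases) is not attempted.

## Known limitations

- Decoded profiles are probability vectors, not molecules; the package
  deliberately stops at library matching and does not attempt structure
  generation from probabilities.
- The adversarial equilibrium is tracked (held-out discriminator
  accuracy per epoch) but not guaranteed; short runs leave the
  discriminator ahead of the encoder, as the README example shows.
- With standardized training, the GI prior is expressed in percent and
  mapped through the training-set moments; transferring a trained model
  to a dataset with different GI scaling requires retraining or explicit
  restandardization.
- Training is single-threaded, plain-SGD, CPU R; it is sized for
  method-level experiments (hundreds to thousands of compounds), not for
  production-scale screens.
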