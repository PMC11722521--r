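---
title: "Methods: equivariant featurization and slow-mode learning in GeomDyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equivariant featurization and slow-mode learning in GeomDyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model, the parameter choices, the design of the
synthetic benchmark systems, and the numerical decisions behind GeomDyn.  It
is a methods document: every empirical number referred to here is computed by
the package's test suite (`tests/testthat/test-acceptance.R`) or by the
acceptance script (`scripts/acceptance.R`); the vignette itself makes no
additional empirical claims.

## 1. Model overview

GeomDyn implements a two-stage approach to learning the slow dynamics of
molecular systems:

1. A **pretrained, frozen geometric featurizer**: an equivariant
   message-passing encoder maps each trajectory frame's atomic coordinates to
   per-atom scalar features `x` (rotation- and translation-invariant) and
   per-atom vector features `V` (rotation-equivariant, translation-invariant).
   The encoder is pretrained once by coordinate denoising and never updated
   afterwards.
2. **Lightweight learnable heads on tokens**: per-atom features are summed
   into per-residue *structural tokens*, and small trainable "token mixer"
   networks map token sets to a low-dimensional output.  Two dynamics
   objectives are supported: VAMPnets (slow collective variables, CVs) and
   the state predictive information bottleneck (SPIB, metastable-state
   labels), with Markov state model (MSM) construction from the labels.

Decoupling the expensive featurizer from the cheap dynamics heads means the
trajectory is featurized once and many dynamics models can be trained against
the cached features (`FeatureStore`).

### 1.1 Encoder contract

The encoder (`encode()`, configured by `encoderConfig()`) is a
TorchMD-ET-style equivariant attention network: distances enter through
radial basis functions under a smooth cosine cutoff, and scalar and vector
channels are updated along separate paths that only ever mix through
invariant contractions (norms, inner products) or equivariant products
(vectors scaled by invariants, relative-position directions).  The contract —
the property everything downstream relies on — is:

- scalars are unchanged under any rigid transform of the input frame;
- vectors rotate with the frame and ignore translations.

The acceptance suite checks this contract directly over random rigid
transforms rather than pinning down one specific layer architecture.  A gated
equivariant output head (`gatedEquivariantHead()`) maps `(x, V)` to per-atom
3-vectors and inherits the same equivariance; it is the denoising prediction
head.

### 1.2 Denoising pretraining

`trainDenoiser()` corrupts conformer coordinates with isotropic Gaussian
noise of unit variance (`corrupt()`) and trains encoder plus head to predict
the added noise, minimizing mean squared error per coordinate.  Predicting
zero scores exactly 1.0 on this objective, which makes 1.0 the natural noise
floor: any validation MSE below 1.0 demonstrates that the encoder has learned
geometry.  Validation conformers are held out, and the best-validation
checkpoint is kept.

### 1.3 Tokens and mixers

`coarseGrain()` sums per-atom features within each residue (an exact sum, so
token totals conserve atom totals), giving `M` tokens per frame.
`mixerConfig()` selects the trainable head:

- `pool`: mean over tokens, then a dense readout (the simplest baseline);
- `submixer`: an MLP-mixer alternating token-mixing and channel-mixing
  blocks with residual connections and layer norm;
- `subformer`: a transformer over the `M` tokens plus one prepended global
  token, so attention maps are `(M+1) x (M+1)` and row-stochastic.  The
  global token is either learnable or derived from pairwise distances of
  reference atoms (`makeGlobalToken()`);
- `*_gvp` variants first enrich token scalars with rotation-invariant
  contractions of the token vector channels (`gvpEnrich()`), letting the
  mixer see directional information without breaking invariance.

All mixers end in invariant quantities, so every downstream CV or state
label is automatically invariant to rigid motions of the input — this is
verified end to end in the test suite.

## 2. Dynamics heads

### 2.1 VAMPnets

`trainVampnet()` maximizes the VAMP-2 score of the mixer output
`chi`: with time-lagged correlation matrices
`C00 = E[chi_t chi_t']`, `C0t = E[chi_t chi_{t+tau}']`,
`Ctt = E[chi_{t+tau} chi_{t+tau}']`, the score is
`|| C00^{-1/2} C0t Ctt^{-1/2} ||_F^2`.  For a Markov chain observed through
uncentered one-hot features the score equals the sum of squared transfer
operator eigenvalues, which provides exact oracles: 1.49 for the two-state
chain with `P = [[0.9, 0.1], [0.2, 0.8]]`, and 2.30 for the three-state
chain with eigenvalues (1, 0.9, 0.7) used in the pipeline recovery test.

Numerical decisions:

- **Gradients** of the score through the matrix inverse square roots are
  computed analytically via the spectral decomposition (the standard
  eigenvalue-difference quotient rule), and are checked against central
  finite differences in the unit tests.
- **Regularization**: eigenvalues of `C00` and `Ctt` are floored at a
  relative `eps = 1e-6` before the inverse square root; small batches are
  the main source of ill-conditioning, so `vampTrainConfig()` warns below a
  batch size of 1000.
- **Centering convention**: centered scores (the default) measure only
  non-trivial modes; the uncentered convention counts the constant mode's
  eigenvalue 1 and is used where the analytic oracles are stated that way.
- **Early stopping** is dual-patience: training stops when the best training
  batch score has not improved for 500 batches, or when the validation score
  (evaluated every 10 steps) has not improved for 10 evaluations, whichever
  comes first.  The best-validation parameters are returned.
- **Scoring**: the best-validation checkpoint score is a maximum over noisy
  batch evaluations and is biased upward.  `vampScoreOnFrames()` therefore
  recomputes the score deterministically from *all* lagged pairs in a frame
  range; the acceptance tests use it on the validation half.
- **Canonical CV order**: `evaluateCVs()` orders outputs by the singular
  values of the whitened time-lagged operator, so CV 1 is the slowest
  learned coordinate.

### 2.2 Temporal splitting

`temporalSplit()` always reserves the second half of the trajectory for
validation; training indices come only from the first half, optionally as
randomly chosen contiguous segments.  Frame-level random splits are
deliberately not offered: successive frames are highly correlated, and a
random split lets a model validate on frames it has effectively seen.
Lagged pairs never span segment boundaries.

### 2.3 SPIB

`trainSpib()` learns a stochastic latent representation `z` of the current
frame that is predictive of the *state label at `t + tau`*, with labels
refined during training: each refinement replaces every frame's label by the
decoder argmax at the posterior mean.  States that lose all frames are never
revisited, so an initially generous state count (`initK`) anneals down to
the number of distinguishable metastable states.  The loss is the predictive
cross-entropy plus `beta` times a compression term against a VampPrior (a
mixture of the encoder evaluated at learnable pseudo-inputs).

The label-refresh cadence is the critical scheduling choice.  Refreshing
before the decoder has converged on the current labels is destructive: an
immature decoder places all its probability mass on a few states, the
refresh then empties every other state — including genuinely metastable
low-occupancy ones — and an emptied state cannot be repopulated.  The merged
solution is self-consistent, so the damage is permanent.  The package
default refreshes once per epoch, which is adequate when epochs are long;
the triple-well study below uses an explicit `refreshInterval` large enough
(~15 epochs of steps) for the decoder to converge between refreshes.

### 2.4 MSM construction

`buildMSM()` counts lagged transitions between labels (respecting segment
boundaries), row-normalizes, and reports occupancies and implied timescales
`-tau / log(lambda_i)`.  Rows with no observed transitions get a self-loop
and a warning rather than silent renormalization.

## 3. Synthetic systems and study conditions

The generator defaults below are the study conditions: they were fixed on
physical grounds before the corresponding acceptance outcomes were inspected,
and are not tuned against test thresholds.

**Toy conformer templates** (`conformerTemplates()`): `K = 3` template
structures of 4 residues x 4 heavy atoms, separated in shape, with Gaussian
jitter (sd 0.05 of the length scale) added per generated conformer.  Small
enough that a `d = 32`, 2-layer encoder featurizes thousands of frames in
minutes on one CPU, large enough that residue tokens are meaningful.

**Hidden Markov chain** (`reversibleChain()`): a reversible 3-state chain
with uniform stationary distribution and transfer-operator eigenvalues
(1, 0.9, 0.7), built by an orthogonalization construction that makes the
spectrum exact by design.  The chain path (`T = 4000`) is embedded as
conformers (`embedStatesAsConformers()`), so the full
encoder-token-mixer-VAMP pipeline must recover dynamics it can only see
through geometry.  The uncentered VAMP-2 oracle is `1 + 0.81 + 0.49 = 2.30`.

**Double well** (`langevinSpec("double_well")`): overdamped 2-D Langevin
dynamics (Euler-Maruyama) with two basins separated along `x`; the slow
coordinate is `x` by construction.  Defaults: 10000 steps, stride 2 on
embedding, VAMP lag 10, centered convention, output dimension 2.

**Triple well** (`langevinSpec("triple_well")`): two deep basins plus one
shallower basin.  `kT = 1.0` and 20000 steps were chosen on occupancy
grounds: at low temperature the shallow basin holds about 1% of frames and
transitions into it are too rare for any method to resolve at this
trajectory length, whereas at `kT = 1.0` it holds roughly 14% with a mean
dwell time well above the analysis lag of 10 steps, making three metastable
states a physically meaningful target.  SPIB study conditions: raw `(x, y)`
input, latent dimension 2, `beta = 0.01`, `initK = 20`, batch 1000, hidden
width 32, 10 pseudo-inputs, `refreshInterval = 150` steps with 150 epochs
(ten refresh cycles), three seeds.  The refresh interval follows the
convergence argument of section 2.3; the acceptance criterion asks for the
three-state solution in at least two of three seeds, with a populated-count
trace that trends monotonically downward.

**MSM consistency**: labels simulated directly from a known 3-state
transition matrix for `T = 1e5` steps; the estimator must recover every
entry to better than 0.02.

## 4. Analysis utilities

- `pmf2d()`: potential of mean force `-kT ln p` on a 2-D grid; empty bins
  are `NA`, not zero, and the minimum is shifted to zero.  The difference
  between two bins is exactly the log of their count ratio, which is the
  identity the tests check.
- `contactDefinition()` / `fractionNativeContacts()`: native contacts are
  residue pairs at sequence separation >= 3 with any heavy-atom distance
  below 4.5 A in the reference structure; `Q_t` is the fraction retained in
  frame `t`, with a centered moving average `Qbar`.
- `attentionReport()`: averages `(M+1) x (M+1)` attention maps globally and
  per state; per-state averages weighted by state counts recompose the
  global average exactly, and row/column sums summarize how much each token
  attends / is attended to.
- A small command-line interface (`runCli()`, `inst/cli/geomdyn.R`) chains
  simulate / pretrain / featurize / train / report steps on files.

## 5. Limitations

- The networks run on a pure-R reverse-mode autodiff tape; this is exact but
  slow compared to compiled frameworks, which bounds practical system sizes
  to the toy scale used here (tens of atoms, thousands of frames).
- The encoder implements the equivariance *contract*, not any one published
  layer architecture's exact arithmetic; results transfer at the level of
  properties, not weight-level reproduction.
- SPIB state-count recovery is scheduling-sensitive (section 2.3): with a
  refresh cadence faster than decoder convergence, low-occupancy metastable
  states can be irreversibly absorbed.  The acceptance run records the
  populated-count traces so this behavior is visible rather than hidden.
- MSM estimation is a plain maximum-likelihood row normalization without
  reversibility constraints or error bars.
- Only XYZ, PDB, and (with a topology) DCD inputs are supported; XTC is not.
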