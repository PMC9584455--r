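---
title: "Structured random receptive fields: models, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured random receptive fields: models, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structrf)
```

# The generative model

Sensory neurons are commonly summarized by a linear receptive field `w`
feeding a nonlinearity: the neuron's response to a stimulus `x` is
`sigma(w' x)`. Measured receptive-field populations (spike-triggered
averages) look like noisy, variable draws around a common structure, which
motivates modeling an entire population as samples from a zero-mean
Gaussian process: `w ~ N(0, C)` for a structured covariance matrix `C`
evaluated on the stimulus grid. Three covariance families are built in:

* **Stationary bandlimited** (`build_stationary_cov()`):
  `C(t, t') = sum_k lambda_k^2 cos(omega_k (t - t'))` over natural
  frequencies `omega_k = 2*pi*k/L` of the window `[0, L]`, with a flat unit
  spectrum on a passband `[f_lo, f_hi]` by default. Realizations are random
  sums of in-band sinusoids; the eigenbasis is the Fourier basis.
* **Sensilla** (`build_sensilla_cov()`): the stationary model multiplied by
  the separable decay `exp(-(t + t')/gamma)`. Realizations are smooth,
  oscillatory, frequency-selective temporal filters that decay away from
  stimulus onset, the characteristic shape of insect campaniform-sensilla
  receptive fields. `gamma` (ms) sets the effective integration window;
  `[f_lo, f_hi]` (Hz) the frequency selectivity.
* **V1** (`build_v1_cov()`):
  `C(t, t') = exp(-||t - t'||^2/(2 f^2)) * exp(-(||t - c||^2 + ||t' - c||^2)/(2 s^2))`
  on a pixel lattice. Realizations resemble simple-cell receptive fields:
  smooth on the scale `f` (pixels), localized around the center `c` on the
  scale `s` (pixels).

All covariances are trace-normalized, by default to `Tr(C) = d` so that
`E[||w||^2] = d` exactly as for spherical (unstructured) Gaussian weights;
this puts structured and classical random features on an equal footing.

## Units and grids

Public units are milliseconds and Hz; internally time is carried in
seconds. A harmonic `k` belongs to a passband when its natural frequency
`k/L` lies inside it, band edges inclusive; the constant `k = 0` term is
included only when `f_lo = 0`. Pixel coordinates are 0-based `(row, col)`
with row-major flattening, and the default field center is
`floor(c(height, width)/2)`.

# Basis change and effective kernels

If `C = Phi Lambda^2 Phi'`, then `w = Phi Lambda z` with standard normal
`z` (the Karhunen-Loeve construction used by `sample_weights()`), and

```
w' x = z' x_tilde,   x_tilde = Lambda Phi' x.
```

A structured projection is therefore an ordinary spherical random
projection of the *filtered* stimulus `x_tilde`: the stimulus is rotated
into the covariance eigenbasis and reweighted by the eigenvalue profile.
For bandlimited covariances the out-of-band coordinates of `x_tilde` are
exactly zero, so structured hidden layers delete out-of-band noise before
any learning happens. `basis_change()` exposes the transform;
`structured_kernel()` composes it with the closed-form arc-cosine kernel
of ReLU features (`relu_arccos_kernel()`), giving the infinite-width
kernel of a structured network.

Sampling goes through the eigenbasis rather than a Cholesky factor because
bandlimited covariances are rank-deficient by construction. The RNG
contract: every sampling operation takes a `seed`, consumes the
standard-normal stream row by row, and restores the caller's RNG state, so
enlarging a weight bank extends earlier draws instead of reshuffling them.

# The Hermite wavelet eigenbasis

The localized V1 covariance has a closed-form eigensystem. With
`a = 1/(2 s^2)` and `b = 1/(2 f^2)`, Mehler's expansion of the Gaussian
kernel conjugated by the Gaussian localizer gives 1-D eigenfunctions
`exp(-c1 t^2) H_k(c2 t)` (physicist's Hermite polynomials) and a geometric
eigenvalue decay with ratio `c3`, where

```
c1 = sqrt(a^2 + 2 a b),  c2 = sqrt(2 c1),  c3 = b / (a + b + c1).
```

Two-dimensional eigenfunctions are per-axis products indexed by a
multi-index `(k1, k2)` with eigenvalue proportional to `c3^(k1 + k2)`;
nonzero centers shift the functions. `hermite_eigenbasis()` evaluates the
continuous eigenfunctions on the pixel grid, which is exact only in the
continuum: restricted to a coarse lattice the analytic functions and the
numerical eigenvectors of `build_v1_cov()` differ by discretization error
that grows with the total order. On a 14 x 36 grid at `s = 1.87`,
`f = 0.70` px the leading-10 subspaces agree to within a maximum principal
angle of about 8 degrees and the leading eigenvalue curves agree to within
about 8% pointwise; the test suite asserts 10 degrees and a 0.2 bound on
the absolute log-ratio as the stated discretization tolerances, derived
from that numerical comparison on grids of at least 12 x 12.

# Synthetic benchmark tasks

`gen_frequency_detection()` and `gen_frequency_xor()` generate the two
timeseries benchmarks on a 100 ms window at 2 kHz (`d = 200`).

**SNR is a power ratio.** With unit amplitude, the sinusoid's power is
`A^2/2` and the per-sample noise variance is `A^2/(2 * snr)`; the default
`snr = 1.76` corresponds to `10*log10(1.76) = 2.46` dB. Detection
negatives are white noise whose variance equals the *total* expected power
of positives (`A^2/2 + A^2/(2 snr)`) — matched in overall amplitude, not
in spectral density. In the XOR task the mixture subclass carries both
components at amplitude `A` (doubling the signal power) with its noise set
from the combined power at the same SNR, and the noise subclass is
power-matched to the pure-tone subclasses; these are interpretation
choices, fixed once and documented here. Train/test sizes default to
4,000/1,000 balanced examples in the experiment drivers.

Two consequences of the power-matching convention are worth knowing when
reading error levels. First, because negatives match the positives' total
power, their noise *density* per frequency is higher; a network whose
passband excludes the signal frequency still sees that density difference,
so "incompatible" networks perform well above chance — at 300 neurons they
approach the accuracy of an ideal in-band power discriminator rather than
failing outright. For the same reason, in the XOR task an incompatible
network can still identify pure out-of-band tones by their low in-band
power, so its failures spread across subclasses rather than concentrating
on the out-of-band tone. Second, the XOR decision is invariant to the
random phases, i.e. a function of the per-tone amplitudes only; random
ReLU features approximate such phase-invariant functions slowly, and in
our experiments roughly a hundred structured neurons are needed before the
XOR error falls to the percent level, whereas detection is solved
essentially perfectly by 25 structured neurons. Both behaviors are
computed, not asserted, by the acceptance suite.

The generators emulate controlled psychophysics-style stimuli: exact
sinusoids, white Gaussian noise, exact class balance. They do not emulate
colored noise, amplitude drift, or measurement filtering found in real
recordings, so passing tests demonstrate correctness of the pipeline and
the inductive-bias ordering, not performance on physiological data.

# Random feature networks and the readout

`rfn()` wraps a frozen hidden weight bank; `hidden_features()` computes
`relu(X W')` (no hidden thresholds). The readout is a linear SVM with
squared hinge loss and l2 penalty, fit in the primal by a generalized
Newton method (the objective is smooth; the generalized Hessian over the
active set of margin violators gives superlinear convergence, with
backtracking line search). The regularization strength is tuned over 7
log-spaced values spanning `[1e-3, 1e3]` — decade resolution over the
stated range — by stratified 5-fold cross-validation with fold assignment
derived deterministically from the experiment seed; ties break toward the
smallest strength (strongest regularization). Features are not
standardized: the ReLU is positively homogeneous, so feature scale is
absorbed by the readout, and raw features keep the pipeline faithful to
its simplest description. Multiclass problems use one-vs-rest, the
standard reduction for this loss.

`error_curve_experiment()` reruns sampling + readout fitting `repeats`
times (default 5) per hidden-layer width and reports mean test error with
its standard error; each run's weight-bank seed and CV seed derive from
the master seed, so entire experiments are reproducible bit-for-bit.

# Fitting covariance models to populations

`empirical_covariance()` forms `C_data` proportional to `W' W` with no
mean subtraction — the generative model is zero-mean, and subtracting a
sample mean would bias the comparison for small populations. All
covariances entering a comparison are normalized to a common trace, and

```
frobenius_distance(C_data, C_model) = ||C_data - C_model||_F / ||C_data||_F
```

which is 0 for a perfect fit and exactly 1 for the zero model. This
normalization is one of several possible conventions; it is logged here so
users comparing against externally published distances know precisely what
is computed.

`fit_covariance_params()` minimizes this distance. For the temporal
families the band edges affect the model only through which natural
frequencies they include, so continuous edges are unidentifiable within a
harmonic gap; the fitter therefore searches *every* admissible harmonic
interval exhaustively (the discrete part of the space) and treats only
`gamma` continuously — a log-spaced coarse grid followed by golden-section
refinement and a final parabolic-vertex polish, which recovers exact
on-grid parameters to numerical zero. The V1 family uses a 15 x 15
log-spaced coarse grid over `(s, f)` followed by Nelder-Mead refinement in
log-parameter space; the center is held fixed at the grid center because
populations are first standardized with `center_receptive_fields()`
(energy center of mass moved to the grid center by integer-pixel shifts —
no interpolation, so fields are never smoothed). Null references
(`unstructured`, `fourier`, `v1_translation_invariant`) quantify how much
of the fit quality comes from localization versus frequency structure.

`finite_sample_covariance()` shows what the model predicts a finite
population of `m` neurons would look like; its distance to the ideal model
shrinks as `m^(-1/2)`, and small-`m` replicas reproduce the bumpy
structure seen in small recorded populations. `spectral_compare()` reports
unit-trace eigenvalue curves (each sums to 1, hence directly comparable),
leading eigenvectors, the cumulative variance explained, and principal
angles between leading subspaces — subspace angles rather than
vector-by-vector matches, because near-degenerate eigenvalues permute and
rotate freely.

Parameter-recovery experiments in this package run on a 2 kHz x 40 ms grid
(`d = 80`): the harmonic spacing (25 Hz) and the passband content are what
determine identifiability, not the sampling rate, and this size keeps the
exhaustive band search instantaneous. Recovery from 2,000 sampled fields
returns band edges exactly and `gamma` to within a few percent.

# Structured initialization for trained networks

`init_hidden_weights()` prepares hidden layers for full training at the
Kaiming scale: `"kaiming"` draws `N(0, (2/d) I)` and `"structured"`
samples from the covariance rescaled to `Tr(C) = 2`, so every condition
satisfies `E[||w||^2] = 2` and differences in training dynamics are
attributable to covariance *structure*, not weight magnitude.
`train_full()` runs full-batch gradient descent on softmax cross-entropy
through the ReLU hidden layer, recording per-epoch training loss and test
error. The readout starts at zero rather than at a random scale: hidden
features from different covariances have condition-dependent magnitudes,
so random initial logits would offset the loss curves at epoch 0 and
contaminate any area-under-the-curve comparison; with a zero readout
every condition starts at exactly the chance loss `log(K)` and training
is fully deterministic. The speed-of-learning metric is the area under
the training-loss curve (trapezoidal rule), and `lr_grid_search()`
selects the learning rate minimizing it over a log-spaced grid in
`(1e-4, 1e0)` separately per condition, excluding diverged runs.

On the desk-scale XOR task (80-neuron networks, 250 epochs, tuned rates)
the two initializations are not consistently ordered by loss-area —
unstructured weights can descend the *training* loss quickly while badly
overfitting — but the structured network ends at a much lower *test*
error, and that generalization gap is what the test suite asserts. The
full training-speed protocol on image benchmarks (uniformly random field
centers via `v1_weight_bank()`, 1,000 neurons, 3,000 epochs, grid-searched
`(s, f)`) is implemented and documented but exercised only on
user-supplied image datasets, which are not bundled.

# Numerical choices and degenerate inputs

* Eigendecompositions clip tiny negative eigenvalues (above
  `-1e-8 * lambda_max`) to zero; anything more negative is an error, never
  silently repaired. Eigenvector signs are fixed (largest-magnitude entry
  positive) for reproducible reports.
* An empty passband — no natural frequency inside `[f_lo, f_hi]` — is an
  error naming the band and the grid's frequency resolution.
* All-zero receptive fields cannot be centered and are left in place with
  a warning; all-zero populations are rejected.
* Divergent training (non-finite loss) aborts and returns the trace so
  far, flagged.
* CV tie-breaks, fold assignments, and per-repeat seeds are all
  deterministic functions of the experiment seed.

# Limitations

The package covers 1-D temporal and 2-D spatial stimulus domains;
spatiotemporal (3-D) covariances and recurrent covariance structure are
out of scope. The Gaussian-process model captures second-order structure
only; individual-neuron idiosyncrasies beyond the covariance are not
modeled. Real receptive-field datasets are accepted as plain CSV matrices
with grid metadata but are not distributed with the package, so
data-dependent quantities (fit distances and variance-explained fractions
for particular laboratories' populations) are reproducible only by users
holding those datasets.
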