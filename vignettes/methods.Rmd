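---
title: "Methods: eigenspectra, Gabor electrophysiology, predictivity and robustness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eigenspectra, Gabor electrophysiology, predictivity and robustness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model of the analysis

`v1robust` implements a pipeline relating a visual model's adversarial
robustness to three V1-like properties of its internal representations: the
power-law exponent of its response eigenspectrum, the distribution of
preferred spatial frequencies of its convolutional channels, and its
noise-corrected predictivity of V1-like neural responses. The theoretical
backdrop is the dimensionality argument for sensory codes: if the
eigenspectrum of responses to natural scenes decays as a power law
$\lambda_j \propto j^{-\alpha}$ with $\alpha < 1$, the code devotes so much
variance to fine stimulus detail that arbitrarily small stimulus
perturbations can produce disproportionate response changes — the same
failure mode that adversarial examples expose in image classifiers. V1
population codes sit near $\alpha \approx 1$.

Every stage runs on synthetic inputs generated by the package itself, so
the full pipeline is testable end to end without downloads. The synthetic
generators define the study conditions; their defaults are stated below
together with what they do and do not emulate.

# Eigenspectrum estimation

## cvPCA for trial-noisy data

Biological responses are observed through trial noise, and the eigenvalues
of the covariance of a noisy response matrix are biased upward by the noise
variance. Cross-validated PCA (`cvpca()`) removes this bias: trials are
split into two halves, the eigenvector basis $V$ is estimated from the SVD
of the first half-mean $X^{(1)}$, both half-means are projected onto $V$,
and the $j$-th eigenvalue is estimated as the cross-product
$\lambda_j = \sum_i \tilde X^{(1)}_{ij} \tilde X^{(2)}_{ij} / (S-1)$.
Because the two halves carry independent noise, the noise term cancels in
expectation and individual estimates may be negative. Spectra are averaged
over 20 random half-splits by default; with exactly two trials the split is
deterministic and a single pass is performed.

Numerical choices:

* both halves are column-centered with their own means (the covariance
  eigenstructure concerns centered responses; with the generator's
  near-zero stimulus means the alternative grand-mean centering is
  indistinguishable in practice);
* the cross-product is divided by $S-1$ so eigenvalues are in variance
  units; any fixed scale leaves the log-log slope unchanged;
* deterministic model activations need no cross-validation and use plain
  PCA (`pca_spectrum()`).

## Power-law fitting and the reliable component range

`fit_power_law()` is ordinary least squares on
$(\log j, \log \lambda_j)$ over an index window, with $\alpha$ the negative
slope. Natural logarithms are used (the slope is base-invariant), only
strictly positive eigenvalues enter the fit (non-positive cross-validated
estimates are excluded and counted), and the default window for model
layers is components 10–999, clipped to the spectrum length.

For cross-validated spectra the upper end of the window matters. The
estimator is unbiased only conditional on the eigenvector basis; once the
signal eigenvalue falls to the scale of the eigenvector-estimation error,
components mix with their neighbours and the tail of a steep spectrum
flattens. First-order perturbation theory puts that breakdown where the
signal eigenvalue meets the coupling scale
$\sigma^2_{\text{half}} \sqrt{N/S}$, with $\sigma^2_{\text{half}}$ the
trial-noise variance of a within-half mean, estimable directly from the
within-stimulus variance across trials. `reliable_component_range()`
returns the window ending at the last component above this floor, and the
recovery analyses fit over that window. The threshold is a derived scale,
not a tuned constant; the package's recovery analyses
(`analysis/01_eigenspectra.R`, the acceptance script) recompute it from
the data each run.

## What the spectrum generator emulates

`gen_powerlaw_responses()` plants $\lambda_j \propto j^{-\alpha}$ in the
*signal* covariance only — singular vectors drawn once per seed from the
Haar measure (avoiding axis-aligned artifacts), total signal variance 1 per
neuron on average — and adds i.i.d. Gaussian trial noise, because white
trial noise is exactly what cvPCA is built to strip. Real recordings
violate these assumptions in known ways: Poisson-like variance scaling,
correlated (shared) noise, slow drift. Passing recovery tests therefore
show the estimator is correct under its own noise model, not that it is
robust to structured noise.

# In-silico electrophysiology

## Stimuli

Gabor patches follow
$f(x,y) = \exp\!\big({-(x'^2 + \gamma^2 y'^2)}/{2\sigma^2}\big)
\cos(2\pi x'/\lambda + \psi)$ on orientation-rotated, canvas-centered pixel
coordinates. The standard $\gamma^2$ aspect-ratio form is used; at the
default $\gamma = 1$ it coincides with the $\gamma$-linear variant, so the
choice is cosmetic at the defaults but recorded here. Defaults: envelope
$\sigma = 35$ px at a 224-px canvas (scaled proportionally for other
canvases), 10 orientations evenly spaced on $[0^\circ, 172.5^\circ]$, 10
phases evenly spaced on $[0^\circ, 360^\circ)$ — the half-open convention
avoids a duplicated $0^\circ/360^\circ$ stimulus — and the 10 spatial
frequencies 2.5–56 cycles/image in half-octave steps, i.e. exactly 1000
stimuli. Patch values in $[-1, 1]$ are mapped to pixel range by
$v \mapsto (v+1)/2$: a mid-gray background at maximum contrast. The canvas
size and contrast are free choices (we default the canvas to the model's
input resolution); tuning conclusions should be checked for contrast
dependence when transferring to models with saturating nonlinearities.

With a field of view of 6.4 degrees (the package-wide default), frequencies
convert to cycles/degree by division: 56 cycles/image $= 8.75$ cpd, and the
ten grid frequencies fall one into each bin of the reference histogram.

## Tuning, preferred frequency, and the V1 SF score

Because every unit in a convolutional channel shares its filter, the unit
at the spatial center of the activation map (`representative neuron`,
zero-based $(\lfloor H/2\rfloor, \lfloor W/2\rfloor)$) stands in for the
channel. Its tuning-curve value at a frequency is the mean response over
the 100 orientation-phase combinations; the preferred frequency is the
curve's argmax. Ties break toward the *lowest* frequency — deterministic,
and conservative with respect to any claim that model units prefer high
frequencies. Channels with zero peak-to-peak tuning carry no preference
and are excluded.

An in-silico experiment samples 150 representative neurons with
replacement, bins their preferred frequencies (cpd) into the ten reference
bins (half-open $[e_i, e_{i+1})$, last bin closed; out-of-range values are
clipped into the terminal bins with a warning, which cannot occur with the
default grid), and scores the distribution against the macaque V1 foveal
reference (De Valois et al., bin edges 0.35–11.2 cpd, counts
0, 3, 3, 6, 17, 22, 18, 19, 9, 4, shipped as a packaged CSV). The score is
$1 - \max_i |x_i - y_i|$ on the binned empirical CDFs, computed on
proportions so that differing sample sizes are immaterial. 1000
experiments give a score mean ± SD.

## Optimal stimuli

`optimal_stimulus()` ascends the softmax across channels of spatially
averaged activations with Adam (learning rate 0.05), parameterizing the
image by its discrete Fourier transform by default (the image is the real
inverse transform; the objective gradient maps to the spectrum as
$\partial g / \partial Z = \mathrm{FFT}(\partial g/\partial x)/L$). A
direct pixel parameterization is provided and is what the tests use for
frequency-recovery checks, since it converges to a clean grating in fewer
steps at toy scale.

# Model adapters

All analyses address models through a small adapter contract: named
C×H×W layer activations, class logits, deterministic forward passes, and
gradients exposed as vector–Jacobian products (`adapter_logits_vjp()`,
`adapter_layer_vjp()`), from which any scalar objective's input gradient
follows. The bundled adapters implement analytic forward and backward
passes, verified against central finite differences in the test suite:

* `make_gabor_bank_model()` — one layer of quadrature-energy Gabor pairs
  (amplitude $\sqrt{e^2 + o^2}$), mean-subtracted and $\ell_2$-normalized
  filters, so each channel's preferred frequency is its construction
  frequency by design and the ground truth for tuning recovery is exact
  under phase averaging. A half-rectified linear variant is available.
* `make_tiny_cnn()` — two valid 3×3 convolutions with ReLU, global average
  pooling and a linear head, weights frozen from a seeded Gaussian.
* `make_linear_model()` — a linear softmax classifier, the vehicle for all
  closed-form attack oracles.

# Neural predictivity

The mapping pipeline mirrors the standard V1 benchmark procedure: stimuli
are center-cropped to 80 px, resized to 40 px, zero-padded to the model
canvas and channel-normalized (`preprocess_stimuli()`); layer features are
projected onto at most 1000 principal components fitted once on an
independent basis set so the projection is frozen across splits
(`reduce_features()`; when the feature dimension is smaller, all components
are used); and a partial least squares regression with 25 components (or
cross-validated ridge over coefficients $\{0.01, 0.1, 1, 10\}$, 5-fold)
maps features to trial-averaged responses on 20 random 75/25 train-test
splits. PLS centers features and responses but does not scale them; PLS is
delegated to `mixOmics::pls`, ridge is a closed-form solve.

Per neuron and split, predictivity is the test-set Pearson correlation
between prediction and observation divided by
$\sqrt{\text{reliability}}$, where reliability is the Spearman-Brown
corrected split-half correlation $2r/(1+r)$ of the neuron
(`neuron_reliability()`; with two trials the split is deterministic).
Per-neuron scores are averaged across splits before the median across
neurons is taken — the pooling alternative is a documented switch away,
but averaging is the default. The spread is the SD of per-split medians.
Neurons with non-positive split-half correlation are excluded rather than
floored (the square root of a non-positive reliability is undefined);
noise-corrected values may exceed 1 by sampling error and are reported
unclipped. Differences between layers or models are assessed by
resampling neurons with replacement 10 000 times
(`bootstrap_compare()`), one-sided in the direction of the headline claim
with the two-sided doubling reported alongside.

## The parameter-recovery fixture

`make_linear_truth()` samples ground-truth readout weights inside the span
of the top principal components (default rank 15) of the source layer, and
`gen_linear_v1_dataset()` adds Gaussian noise scaled to a requested SNR,
giving split-half correlation $\mathrm{snr}/(\mathrm{snr}+1)$ in closed
form. Restricting the truth to the dominant subspace is a fixture-design
choice, not a tuning step: a 25-component regression cannot represent a
readout with mass on hundreds of near-degenerate minor components, so an
unrestricted-truth test would measure PLS truncation bias rather than the
noise-correction identity the test is after. It mirrors the empirical
situation that neural signal loads on dominant feature dimensions.

For pipeline-level layer *identification*, the synthetic neurons default to
the first convolutional layer. A downstream layer is a deterministic
function of upstream activations, so signal planted in `conv2` is almost
equally linearly decodable from `conv1` and selection between them would be
a coin flip; planting upstream keeps the generating layer identifiable,
because the forward ReLUs genuinely destroy information.

# Adversarial robustness

`pgd_attack()` implements projected gradient ascent on the classification
loss: 20 steps of size $\varepsilon \times 2/20$, deterministic
$\delta = 0$ initialization without random restarts, per-norm ascent
directions (sign of the gradient for $\ell_\infty$; gradient normalized to
unit $\ell_2$ or $\ell_1$ norm otherwise — the dense $\ell_1$ rule is our
choice where the step rule is underdetermined, 20 dense steps approximating
the stronger attack), projection of $\delta$ onto the norm ball
(elementwise clip, radial rescale, or exact sort-based Euclidean projection
onto the $\ell_1$ ball), and clipping of $x + \delta$ to the valid pixel
range each step. Perturbations live in pixel space, where budgets such as
$1/1020$ are meaningful; the benchmark set is
$\|\delta\|_\infty \le 1/1020$, $\|\delta\|_2 \le 0.15$,
$\|\delta\|_1 \le 40$, and adversarial accuracy is top-1 accuracy averaged
over the attack set. On linear models the attack provably attains the
closed-form worst case, which the tests exploit as an oracle.

Two robust-training objectives are provided at toy scale. TRADES adds
$\beta \max_{v \in B(x,\varepsilon)} KL(f(v)\,\|\,f(x))$ to the
cross-entropy (default $\beta = 2$, 3 inner ascent steps of size
$\varepsilon \times 2/3$ under the $\ell_\infty$ projection). The KL and
its gradient vanish identically at $v = x$, so the inner point is
initialized with a small seeded Gaussian offset
($\sigma = \varepsilon/10$, fixed seed — the maximization stays
deterministic); this matches reference implementations of the objective.
Input gradient regularization adds the finite-difference penalty
$\frac{\lambda}{2h^2}(L(z) - L(x))^2$ with
$z = x + h\,\nabla_x L / \|\nabla_x L\|_2$ (defaults $\lambda = 0.3$,
$h = 0.01$; samples with gradient norm below $10^{-12}$ contribute no
penalty), whose small-$h$ limit is $\frac{\lambda}{2}\|\nabla_x L\|^2$.
`train_toy_classifier()` minimizes either objective (or plain
cross-entropy) by full-batch gradient descent on a linear softmax model,
treating the inner perturbation and finite-difference point as fixed in
the parameter gradient, as is standard. The accompanying fixture
(`gen_nuisance_classification()`) gives the objectives something to
disagree about: one robustly separated feature plus several
weakly-separated low-noise features whose class gap lies inside the attack
budget — plain cross-entropy leans on them, a robustness-regularized fit
learns not to. Note the finite-difference penalty has curvature of order
$\lambda/h^2$, so IGR training needs a smaller step size than the other
objectives.

# Pipeline and problem sizes

`run_pipeline()` executes the requested stages in dependency order from a
single validated, seeded configuration; when predictivity runs, the layer
with the highest median noise-corrected predictivity (the most "V1-like"
layer) is the one summarized by the tuning stage. Every stage seed derives
from the master seed, so full runs are bit-reproducible; stage failures
are recorded in the report without aborting later stages, and stage tables
are serialized as CSV/JSON when an output directory is set.

The analyses and acceptance script use deliberately modest problem sizes,
chosen once as the package's study conditions: spectra at
$S = 2000, N = 400$, two trials, trial-noise SD 0.5 (trial SNR 4), five
generator seeds per planted exponent; tuning at a 128-px canvas (the
smallest even canvas on which the full 10-frequency grid respects the
2-px Nyquist wavelength), 150 neurons × 1000 experiments; predictivity at
400–800 pink-noise stimuli, 50 neurons, SNR 1, two trials, feature cap
200, 20 splits; robustness at 1000 toy samples and 5 training seeds.

# Known limitations

* Trial noise is white Gaussian everywhere; no Poisson scaling, shared
  noise, or drift. cvPCA's unbiasedness claims are relative to this model.
* The cvPCA tail bias for steep spectra is excised, not corrected: the
  reliable-range rule discards components below the perturbation floor
  rather than de-biasing them.
* Adapters are toy models with analytic gradients; nothing here exercises
  batch-norm statistics, stride/padding variants, or pretrained weights,
  although the adapter contract is designed so an external model can be
  wrapped without touching the analyses.
* The in-silico protocol fixes contrast at maximum and orientation
  sampling at 10 points; orientation bandwidth and contrast saturation are
  out of scope.
* Robust training is demonstrated on linear models only; the objectives
  accept any adapter, but no multi-layer training loop is provided.
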