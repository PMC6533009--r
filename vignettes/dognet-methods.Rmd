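---
title: "Trainable Difference-of-Gaussians networks for puncta detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trainable Difference-of-Gaussians networks for puncta detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The detection problem

Synapses in multiplexed immunofluorescence images appear as *puncta* —
diffraction-limited bright spots — that colocalize across marker channels:
a genuine synapse carries signal in at least one presynaptic channel
(synapsin; vGlut for excitatory or vGat for inhibitory subtypes) *and* one
postsynaptic channel (PSD-95 or gephyrin), while nonspecific antibody
binding produces single-sided spots.  The detector must therefore combine
per-channel blob evidence across channels, under noise, and under a few
pixels of inter-channel displacement caused by the 3D orientation of each
synapse relative to the imaging plane.

Generic convolutional networks solve this task but carry thousands of
parameters and overfit when annotations are scarce (dense expert
annotation of synapses is expensive and ambiguous).  The architecture
implemented here — DoGNet — replaces every learned convolution kernel with
a *Difference of Gaussians* (DoG), the classical band-pass blob detector,
so that a whole network holds on the order of 10^2 trainable scalars and
can be fitted from a single small annotated region.

## The model

### DoG filter parameterizations

A DoG kernel is the difference of two concentric Gaussians.  Five
parameterizations are available (`dog_params()`), named by their trainable
degrees of freedom:

* `isotropic-4`: $k(x,y) = w_1 e^{-(x^2+y^2)/2\sigma_1^2} -
  w_2 e^{-(x^2+y^2)/2\sigma_2^2}$ with free amplitudes and bandwidths;
* `isotropic-2`: the same with amplitudes fixed at the 2D Gaussian pdf
  normalizer $w_i = 1/(2\pi\sigma_i^2)$, leaving two trainable scalars and
  a zero-DC band-pass kernel;
* `anisotropic-7` / `anisotropic-5`: each Gaussian has per-axis bandwidths
  $(\sigma_{i,x}, \sigma_{i,y})$ and the pair shares one orientation
  $\alpha \in [0, \pi)$, entering through the usual rotated quadratic form
  $\exp(-a x^2 - 2 b x y - c y^2)$; the 5-parameter variant fixes
  $w_i = 1/(2\pi\sigma_{i,x}\sigma_{i,y})$;
* `dog3d-6`: isotropic within axial slices with separate axial bandwidths
  $\sigma_{i,z}$, for volumetric data.

Note on the amplitude normalizer: the two-parameter variant is sometimes
written with $1/(2\pi\sigma)$; this package uses $1/(2\pi\sigma^2)$, the
constant that actually normalizes a 2D Gaussian, so that each Gaussian
term integrates to one and the rendered difference kernel sums to ~0
(verified to 1e-3 on a support of six standard deviations).

Kernels are rendered by evaluating the continuous formulas at the integer
pixel offsets of a centered grid (`kernel_support()`, default 15 × 15,
i.e. half-width 7) with no supersampling — standard discrete DoG practice.
`dog_kernel_grad()` returns the exact analytic derivative of every kernel
entry with respect to every parameter; the test suite checks all five
parameterizations against central finite differences at relative
tolerance 1e-4.

### Layers, mixing and the product head

One DoGNet layer (`dognet_layer_forward()`) convolves each of its $N$
input channels with its own $M$ DoG filters (depthwise; $M = 5$ by
default), mixes the $M \times N$ response maps into $K$ maps with a
trainable tensor $\gamma$ (a 1 × 1 convolution), adds a bias $\zeta_k$ per
map and applies the logistic sigmoid.  Convolution uses zero padding and
returns maps of the input's size, so the output aligns per-pixel with the
annotation mask.  A deep DoGNet (`depth` > 1, default 3 for deep
variants) simply feeds each layer's $K$ sigmoid maps to the next layer as
channels.

The final $K = 2$ maps are combined by a parameter-free element-wise
product (`elementwise_product()`).  Because each map lies in $[0,1]$, the
product acts as a soft logical AND: a pixel scores high only when *both*
maps support it, which lets one map specialize on presynaptic and the
other on postsynaptic evidence and suppresses single-sided spurious
puncta.

The shallow isotropic configuration (3 channels, $M = 5$, $K = 2$,
product head) holds exactly 62 trainable scalars; the shallow anisotropic
one 107 (`count_parameters()`).

### Initialization

Small networks are unforgiving of poor starting points, so filters start
as a grid of near-Laplacian-of-Gaussian priors: per channel, the $M$
first-bandwidths are the evenly spaced points spanning $[0.5, 2]$ pixels
(`init_sigma_grid()`; the midpoint 1.25 when $M = 1$) and the second
variance exceeds the first by 0.01, $\sigma_2 = \sqrt{\sigma_1^2 + 0.01}$
— read as a *variance* difference, not a bandwidth difference.
Anisotropic filters start isotropic at $\alpha = 0$; explicit amplitudes
start at their normalizing values.

The mixing weights start uniform at random in $\pm 1/\sqrt{M N}$ (the
standard 1 × 1-convolution initialization), seeded for reproducibility,
and biases at zero.  This was a genuinely open design point: a
deterministic uniform start $\gamma \equiv 1/(MN)$ looks attractive (it
begins every map at probability ~0.5) but is a trap — with the product
head, identical maps receive *identical* gradients at every step, the
symmetry never breaks, and the AND split between presynaptic and
postsynaptic evidence can never be learned.  Random signed initialization
removes the symmetry at no cost; on the synthetic benchmark it changes
held-out F1 by a few points and, more importantly, lets the two maps
specialize.

## Training

Point annotations (synapse centroids, in pixels or micrometers) are
rasterized into a binary mask: every pixel within 0.8 μm of a centroid is
positive, overlapping disks union (`rasterize_mask()`).  The network is
fitted by minimizing the soft-Dice loss

$$L = 1 - \frac{2\sum Y_g \Psi}{\sum \Psi^2 + \sum Y_g^2}$$

over randomly cropped 64 × 64 patches (10 per epoch by default), which is
far more robust to the ~5% positive-pixel imbalance of puncta masks than
cross-entropy.  An $\epsilon = 10^{-8}$ added to numerator and denominator
makes the degenerate all-zero/all-zero crop score 0 instead of 0/0.

Gradients flow through the sigmoid, the mixing tensor and the convolution
down to the DoG parameters via the analytic kernel derivatives
(`dog_kernel_grad()`), implemented with two compiled primitives: the
zero-padded correlation and the correlation-with-upstream-gradient that
yields $\partial L / \partial k(u,v)$ on the kernel support.  Full-model
gradients are finite-difference-checked (relative tolerance 1e-3 on a
9 × 9 input) for shallow and 3-layer networks.

Choices the underlying method leaves open, fixed here once:

* **Optimizer**: Adam with learning rate 0.01, $\beta_1 = 0.9$,
  $\beta_2 = 0.999$; the parameter count is tiny and convergence takes a
  few hundred epochs.  Patch losses within an epoch are averaged.
* **Bandwidth positivity**: a gradient step can push a raw $\sigma$
  through zero, which makes the whole network diverge.  Sigmas are
  optimized through a softplus reparameterization with a floor of
  0.05 px; all reported parameters live on the natural scale.
* **Normalization**: each channel is z-scored over the training region
  before training, and inference z-scores each input image the same way;
  this is also what makes cross-dataset transfer work after
  `harmonize_channels()` matches channel means, standard deviations and
  magnification.
* **Epoch budget**: the default is 5000 epochs
  (`dognet_control(epochs = )`); the studies in the test suite use
  400–1500, where training has converged on the scene sizes involved.
  No early stopping is used — the budget is fixed.

## Post-processing

The probability map is thresholded at $\tau = 0.5$, local maxima
(8-neighborhood; plateau represented by its first pixel in row-major
order) are visited in decreasing value order and accepted greedily unless
an accepted detection lies within $R = 1.6$ μm (non-maximum suppression,
`nonmax_suppression()`).

Accepted peaks are then moved to the centroid of the thresholded map
within the annotation-disk radius (0.8 μm).  This refinement exists
because soft-Dice training reproduces the *disk-shaped* targets: the map
develops broad flat-topped blobs whose raw argmax wanders several pixels
with noise — more than the 0.6 μm matching radius — while the blob
centroid tracks the synapse center stably.  Set `refine_radius = 0` in
`detect_synapses()` for raw peak positions.

Per detection and per channel, a 2D anisotropic Gaussian (amplitude,
offset, mean, full covariance) is least-squares fitted to the window of
radius $R$ (Levenberg–Marquardt, moment-based start, 100-iteration cap);
the descriptor reports the window mean intensity, the displacement of the
fitted mean from the window center (μm), the principal-axis orientation,
and the asymmetry as the major/minor axis ratio (≥ 1; an axis ratio, not
an eccentricity — the choice is documented here because either reading is
defensible).  Flat windows return a descriptor flagged `degenerate`.

## The synthetic scene generator

`generate_scene()` builds controlled multiplexed scenes with ground
truth.  What it emulates:

* true synapses as Gaussian puncta ($\sigma = 1$ px by default, a
  diffraction-limited spot at 0.1–0.2 μm/px) rendered in every channel of
  their side/subtype, each displaced independently and uniformly in a
  disk of radius `max_displacement` — the 2D shadow of the synapse's 3D
  orientation;
* spurious synapses with puncta on exactly one side (presynaptic-only or
  postsynaptic-only), the distractors that make the AND structure matter;
* lognormal punctum intensities ($e^{N(0, 0.1)}$);
* additive white Gaussian noise in every channel, with the global
  amplitude scale calibrated so that the mean *rendered* peak (maximum of
  the noise-free image within the 3 × 3 neighborhood of each punctum
  center) over the noise standard deviation equals the target SNR — the
  SNR definition is peak amplitude / noise sd, stated here because
  several inequivalent definitions circulate.

Defaults place 64 true plus 32 spurious synapses on a 128 × 128 scene
(~96 objects per 128 × 128, about 12 per 45 × 45 region — the crowding
regime of densely innervated cultures at this magnification) with a
minimum center separation equal to the suppression radius $R$ (8 px at
0.2 μm/px) so that ground truth remains resolvable under NMS; placement
is by dart throwing, and infeasible requests fail naming the achievable
count.  The border margin is fixed (3σ + 5 px) independently of the
displacement level so that sweeps over displacement reuse identical
synapse placements.

What it does **not** emulate: neurite morphology and background
structure, spatially correlated or Poisson noise, channel crosstalk,
intensity gradients, or 3D axial stacks.  Passing the synthetic studies
therefore demonstrates that the estimator recovers the model it assumes
— colocalized Gaussian blobs in white noise — not performance on real
tissue.

## Evaluation

Detections are scored against ground-truth centroids by one-to-one
matching within $\rho = 0.6$ μm: pairs are seeded greedily in increasing
distance order (ties by confidence, then index) and completed by
augmenting paths to maximum cardinality — a pure greedy pass can strand a
matchable pair when one detection lies between two truths, and the
augmented pairing is still deterministic with every pair distance below
$\rho$.  Precision, recall and F1 follow with zero-denominator
conventions of 0; `|DiC|` is the absolute counting error.  Pixel-wise AUC
uses the exact rank (Mann–Whitney) statistic, which needs no threshold
grid and is invariant under monotone transforms of the map.  Because
training is stochastic, benchmark numbers are means over independent
runs of per-run metrics (never pooled-count metrics); per-run values are
retained (`aggregate_runs()`).

## Problem sizes used by the bundled studies

The test suite and the sweep driver (`run_benchmark()`) use scenes scaled
to the package's study design: training on one 64 × 64 scene (16 true + 8
spurious synapses) for 1500 epochs and evaluation on a held-out 128 × 128
scene for the recovery study; 5 seeds per level and 400 epochs for the
SNR ({1.5, 3, 6}) and displacement ({0, 2, 4} px) sweeps.  These sizes
are where training has converged while keeping the full suite quick to
run; larger scenes and the full 5000-epoch budget are available through
`synthetic_config()` and `dognet_control()`.

## Known limitations

* The forward pass is 2D; `dog3d-6` kernels render with analytic
  gradients but no volumetric network is assembled — a 3D variant would
  need axial-support and slice-coupling choices that single-plane data
  cannot constrain.
* Blob-shaped objects only: elongated or large structures (nuclei,
  bacteria) violate the DoG prior.
* The product head assumes exactly the two-sided colocalization logic;
  markers with more complex joint structure would need a deeper stack.
* Descriptor quality (the per-channel Gaussian fits) is exposed but not
  validated against any reference — evaluating it is out of scope.
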