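---
title: "Physics-guided ptychographic reconstruction and multi-task virtual staining: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-guided ptychographic reconstruction and multi-task virtual staining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`ptychostain` implements a two-stage computational pipeline for label-free
digital histopathology:

1. **Stage I — physics-guided super-resolution.** From a stack of
   low-resolution intensity images acquired under angled LED illumination,
   it reconstructs a high-resolution complex specimen field
   `U(x, y) = A(x, y) exp(j phi(x, y))`, a Zernike-parameterized pupil
   `P(f) = circ(||f||/f_c) exp(j sum a_i Z_i)` and a global intensity gain
   `s`, by gradient-based optimization of a *bidirectional* physics
   objective.
2. **Stage II — multi-task virtual staining.** The normalized
   reconstructed amplitude ("interface image") is translated into four
   co-registered stain channels — LAP2 (nuclear envelope), DAPI (nuclear
   counterstain), panCK (epithelial cytoplasm) and H&E (morphology) — by a
   conditional GAN with a wavelet frequency branch, difference-aware
   frequency-spatial fusion, squeeze-and-excitation decoding, per-channel
   least-squares PatchGAN adversaries, cross-task structural constraints,
   and a frozen difference-perception quality critic.

Everything is exercisable end to end on simulated optics and procedural
tissue phantoms; no external data is required.

# Stage I: the imaging model and its inversion

## Forward model

A thin specimen with transmission `o(r)` illuminated by the n-th LED at
direction sines `(sin_x, sin_y)` contributes the shifted spectrum
`O(k - k_n)` with `k_n = 2 pi (sin_x, sin_y) / lambda`. The objective acts
as the band-limiting pupil, and the camera records

```
I_n = s | IFFT( P(f) U(f - k_n) ) |^2 ,
```

sampled on the low-resolution (LR) grid. The package implements this as a
DC-centered spectral crop: the LR patch of the high-resolution (HR)
spectrum centered at the LED's (bin-rounded) shift is multiplied by the
pupil and inverse-transformed. All FFTs are unitary, so Parseval's
identity holds exactly; the residual sub-bin illumination shift is kept in
metadata. The identical code path serves the simulator and the
reconstruction losses, so "ground truth in, zero physics loss out" holds
to machine precision.

## The bidirectional objective

The reconstruction minimizes

```
L = L_phys + lambda_d L_deconv + lambda_tv (TV(A) + TV(phi)) + lambda_p R(P)
```

* `L_phys` — mean squared error between measured and re-projected
  intensities, averaged per pixel and per LED (per-pixel means keep the
  published weights resolution-independent; the squared-norm notation in
  the literature is conventionally implemented as a mean).
* `L_deconv` — the inverse-physics anchor. The LED-averaged intensity is
  Wiener-deconvolved under the incoherent OTF (the pupil autocorrelation,
  computed on a zero-padded lattice so the doubled support never aliases):
  `U_deconv = IFFT( conj(H) FFT(I_avg) / (|H|^2 + alpha) )`. Because the
  deconvolved intensity estimates `|o|^2`, its square root is compared to
  the amplitude. Three numerical choices make this term an anchor rather
  than a bias, and they are deliberate:
  1. the comparison is restricted to the band where the OTF retains at
     least half its peak response (`deconv_band()`); attenuated bands are
     dominated by noise amplification and phase-object artifacts, and
     penalizing recovered super-resolved content against a target that
     cannot contain it would only blur the solution;
  2. the target is least-squares gain/offset-aligned to the current
     amplitude (intensity scale is unobservable in ptychography); the
     alignment constants carry no gradient;
  3. the deconvolution is treated as constant with respect to the pupil
     during backpropagation — pupil gradients flow only through the
     forward path, which identifies aberrations far more strongly.
  An earlier formulation that min-max normalized both operands created a
  feedback loop (the normalization range changed every step, so the
  applied update was not the gradient of any fixed objective) and is the
  reason the alignment constants are handled as above.
* `TV` — anisotropic L1 total variation of amplitude and phase
  (per-pixel mean), subgradient descent.
* `R(P) = eta1 sum a_i^2 + eta2 ||P(f) - conj(P(-f))||^2` — pupil
  regularization. The weights `eta1 = eta2 = 0.01` are package defaults
  (they are not published). They must be small: the Hermitian-symmetry
  penalty is *positive for every even aberration* (a defocused pupil is
  not Hermitian), so a large `eta2` actively prevents recovering the very
  aberrations the pupil model exists for. With the defaults, the penalty
  at a defocus of 0.5 rad is two orders of magnitude below the physics
  loss it competes with.

Defaults follow the published values where printed: `lambda_d = 0.1`,
`lambda_tv = 1e-4`, `lambda_p = 1e-3`, Wiener stabilizer `alpha = 1e-3`,
200 epochs at full scale, optical parameters frozen for the first 10
epochs ("early epochs" is unquantified; 10 of 200 is the package's
reading).

## Parameterization: the field itself is the network

The trainable parameters are the amplitude pre-activation (`softplus`
keeps `A >= 0`), the raw phase, 15 Noll-indexed Zernike coefficients
(piston included but frozen — it is unobservable in intensity), and the
log-gain (`s = exp(theta) > 0`). This is the physics-based-network
formulation in which the specimen's field is optimized directly under the
differentiable forward model; gradients are derived analytically with
Wirtinger calculus (verified against finite differences in the test
suite) and applied with Adam. A deep convolutional prior in front of the
field is a possible extension, not implemented: on CPU-scale problems the
direct parameterization converges in seconds and already satisfies every
property the pipeline needs from Stage I. Consequences of this choice:

* the published network learning rate (2e-4) does not transfer; the desk
  presets use Adam at 0.05 on field parameters and 0.05 on optical
  parameters, chosen for stable convergence of the direct
  parameterization;
* the "encoder features" exported to Stage II are a deterministic
  three-scale Haar pyramid of the reconstructed amplitude (approximation
  plus detail-energy channels at 1x, 1/2x, 1/4x), channel-aligned by
  learned 1x1 convolutions inside the staining encoder.

Zernike convention: Noll indices 1–15 with Noll normalization (orthonormal
on the disk), since the source names only "15 Zernike modes".

## Known degeneracies

Three gauge freedoms are inherent and handled rather than fought: global
phase (unobservable; amplitude comparisons only), intensity scale (`s`
versus `|A|^2`; reconstructions are least-squares rescaled before fidelity
metrics), and the tilt–translation pair (pupil tilt equals a lateral image
shift; the bin-rounded forward model breaks it weakly). Strong
amplitude-correlated phase objects additionally corrupt the LED-averaged
intensity as an amplitude proxy, which is why the deconvolution anchor is
band-limited; on pure amplitude objects the anchor is measurably
beneficial, on strong phase objects approximately neutral.

# Stage II: multi-task staining

## Architecture

The shared generator is an encoder–fusion–decoder network: a 3x3 stem plus
two stride-2 downsampling convolutions; a spatial branch that is either
the projected Stage-I features (default) or the encoder's own bottleneck
(`use_features = FALSE`, the feature-ablation variant); a frequency branch
applying WTConv — orthonormal Haar decomposition, independent depthwise
convolutions per subband (LL/LH/HL/HH), inverse transform (identity
initialization makes the block a perfect-reconstruction map); FS-FF fusion
`F_out = Conv3x3( DA(|F_s - F_f|) ) + F_s` whose closing convolution is
zero-initialized, so fusion starts as the identity; and a decoder with
nearest-neighbor upsampling, skip connections, squeeze-and-excitation
recalibration (reduction 8) and a sigmoid 4-channel head. H&E is one
grayscale channel (four channels total as specified); a fixed two-color
rendering exists for display only.

Each channel has its own conditional 70x70 PatchGAN discriminator (4x4
kernels, strides 2/2/2/1/1, leaky-ReLU 0.2) trained with the least-squares
objective, labels 1/0. The training objective is

```
L_stain = sum_c ( L_GAN^c + 10.0 L_L1^c + 0.2 L_DPIQA^c ) + 1.0 L_crosstask
```

with the cross-task constraint
`L = 1.0 consistency + 0.5 exclusive + 0.2 relative`:

* *consistency* — masked MSE between DAPI and H&E inside the nuclear mask
  `dapi > 0.5` (the mask carries no gradient; an empty mask yields 0 with
  a warning);
* *exclusive* — `mean(lap2 * panck)`;
* *relative* — L1 distance between soft-attention maps (absolute values
  normalized to unit sum; chosen over class-activation maps because it is
  deterministic and architecture-free), DAPI anchored against LAP2 and
  panCK.

## Training

Optimization is per-sample Adam with random flips, 90-degree rotations and
brightness jitter. The published schedule (1e-4, batch 8, 150 epochs)
targets GPU-scale runs; the desk preset uses 1e-3 with single-sample
updates, which reaches the documented behavior in minutes on one CPU.
Joint end-to-end training couples the stages through
`L_total = L_recon + lambda_s L_stain` with the published warm-up
(`lambda_s` linear from 0.1 to 0.5 over 10 epochs): each epoch the
per-specimen reconstruction takes a few physics steps with the staining
L1 gradient injected into its amplitude (through the interface
normalization, whose extrema are treated as constants), then the staining
model trains on the refreshed interfaces with its gradients scaled by the
same `lambda_s`. The decoupled mode (`joint = FALSE`) is the
joint-training ablation.

# The difference-perception critic

The critic has a main quality branch (two stride-2 convolutions, global
average pooling) and a wavelet difference branch (two-level Haar, subband
convolutions, multi-scale asymmetric feature fusion with per-scale sigmoid
gates). Pair dissimilarity `d` is regressed from the absolute difference
of the two images' fused features, making it symmetric by construction;
`q_main` and `q_aux` are squashed to (0, 1). Because detail subbands are
an order of magnitude smaller than the approximation band, they are
rebalanced (gain 4) before the convolutions, and a small vector of
hand-set image statistics (per-band detail energies, contrast, gradient
energy, flat-pixel fraction) feeds the absolute-quality heads, with pooled
convolutional features entering damped (gain 0.1). These conditioning
choices exist because the quality signal is carried almost entirely by
band statistics; without them the regression collapses to a constant
prediction under the L1 objective.

No opinion-score data is available, so the critic trains on synthetic
distortions: Gaussian blur (sigma up to 3 px), Gaussian noise (SD up to
0.1) and gray-level quantization at normalized strength `s`, labeled
`q = 1 - s`. The same strength maps to different perceptual severities
across distortion types, so the labels are deliberately noisy; rank
agreement, not absolute calibration, is the validated property. Training
averages gradients over batches of 8 pairs (single-pair L1 gradients are
sign-only and too noisy to escape the constant-prediction attractor) and
keeps the parameters with the best validation rank correlation, evaluated
on a held-back fifth of the training images. Inside the staining
objective the critic is frozen and applied as a perceptual distance
averaged over three dyadic scales.

As a reported quality column in sweeps, this locally trained critic is not
comparable to externally trained quality scores.

# Synthetic data

## Optics

The simulator's default configuration is the printed benchmark protocol:
505 nm illumination, NA 0.13, 4x magnification, 6.5 um camera pixels, a
13x13 LED array 98 mm below the specimen at 8 mm pitch, and Gaussian
noise with SD 0 to 1e-4 interpreted on intensities normalized to unit
maximum (the reference scale is not published; unit-maximum is the
package's choice). `baboon_protocol()` wires exactly this and emits one
stack per printed noise level. Reference images are treated as pure
amplitude objects there and in the noise sweep, matching a protocol that
measures reconstruction fidelity against the image itself; the general
phantom generator instead attaches an amplitude-correlated phase
`phi = pi A` by default, emulating the optical-path-length coupling of
unstained tissue.

## Tissue phantoms

`generate_bundle()` draws non-overlapping nuclear disks (DAPI =
anti-aliased interiors), rings them with envelopes (LAP2), carves both out
of a smooth epithelial region (panCK — exact exclusivity with LAP2 is
enforced, not approximated), and renders H&E to agree with DAPI inside
nuclei. The interface image is a grayscale render of the same geometry
with mild texture. Edges are anti-aliased by default so sigmoid-output
networks can fit them (`hard_edges` gives binary targets). Splits are
generated from disjoint seed ranges, mirroring slide-level separation.
What these phantoms do *not* emulate: real stain spectra and chromatic
variability, out-of-focus light, tissue-scale context, or imaging
artifacts correlated across channels — so passing tests demonstrate that
the machinery learns the constructed relations, not clinical performance.

# Problem sizes and scales

The package's documented experiment scales, used by the test suite and the
acceptance script, are chosen so a complete run takes minutes on one CPU:

* forward-model checks: 32 px, 3x3 LEDs;
* classical-versus-learned comparison: 128 px, 9x9 LEDs, 20 AP sweeps,
  150 reconstruction epochs;
* aberration recovery: 96 px, 7x7 LEDs, 300 epochs, injected defocus
  0.5 rad;
* noise sweep: 64 px, 5x5 LEDs, 2 patches per cell, noise SD
  {0, 0.5, 1} x 1e-4;
* staining battery: 48 training pairs at 64 px, 8 epochs, generator width
  4;
* critic corpus: 60 phantoms at 48 px, 600 batched steps.

Larger presets (full 13x13 arrays, 200-epoch schedules, width-8+
generators) use the same code paths.

# Limitations

* Stage I optimizes one specimen at a time; there is no amortized
  inference across stacks.
* The LED grid must map inside the HR frequency lattice; sub-bin
  illumination shifts are recorded but not compensated.
* GAN training at desk scale is intentionally short; adversarial texture
  quality is not a validated property at these sizes (pixel losses
  dominate by design via the published weight 10.0).
* Optimization-based training is seed-sensitive at desk scale; the
  documented seeds and scales are part of the experiment definitions.
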