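---
title: "Projection-domain CNN enhancement for low-dose tomography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projection-domain CNN enhancement for low-dose tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tomodenoise)
```

## The problem

Synchrotron X-ray tomography of radiation-sensitive samples (stained brain
tissue, polymers, hydrated specimens) faces a hard trade-off: long exposures
give clean projections but damage the sample; short exposures spare the
sample but drown the signal in noise. `tomodenoise` implements a
projection-domain strategy: acquire a *few* long-exposure projections of the
object, acquire the *full* angular scan at short exposure, train an
image-to-image convolutional network on the few matched low/high-dose pairs,
and apply it to every short-exposure projection before reconstruction.
Because training and application data come from the same object, a couple of
angles suffice — local image features repeat across projection angles — and
no explicit noise model is required.

## The enhancement network

The mapping $f : I_s(a) \to I_l(a)$ from a short-exposure projection to its
long-exposure counterpart at angle $a$ is a convolutional encoder-decoder
(`network_spec()`, `build_network()`):

* **Encoder** — 8 convolutional layers, $3\times3$ kernels, kernel counts
  $16,16,32,32,32,64,64,64$, with $2\times2$ strides at layers 2, 4 and 6,
  taking a $W\times H$ patch to $W/8 \times H/8 \times 64$.
* **Bottleneck** — one fully connected layer mapping the flattened encoding
  to an equal-sized vector, reshaped back to $W/8 \times H/8 \times 64$. A
  shape-preserving bottleneck is the minimal choice consistent with
  re-forming an image for the decoder; no width reduction is imposed.
* **Decoder** — 9 transposed-convolution layers, $3\times3$ kernels, kernel
  counts $64,64,64,32,32,32,16,16,1$, with stride-2 layers at positions 3, 5
  and 7 doubling the spatial size back to $W\times H$.
* **Merges** — after each stride-2 decoder stage the feature maps are
  concatenated with the encoder activations of the same spatial scale
  (decoder 3 with encoder 5, decoder 5 with encoder 3, decoder 7 with
  encoder 1). These skip paths carry full-resolution detail around the
  bottleneck; an ablation switch (`network_spec(merges = FALSE)`) exists and
  the test suite checks that disabling them measurably reduces
  high-frequency energy in the output.
* **Activation** — rectified linear everywhere, including the single-kernel
  output layer (outputs live in the normalized $[0,1]$ frame, so a
  nonnegative output range is harmless).

Which layers carry the strides, and the exact kernel schedule between the
$16$ and $64$ endpoints, are design choices of this package; the symmetric
placement guarantees every merge has a partner at its own scale.

The training objective is the inverse peak signal-to-noise ratio
(`psnr_loss()`):
$$\mathcal{L} = \frac{1}{\mathrm{PSNR}}, \qquad
\mathrm{PSNR} = 10\log_{10}\!\frac{I_{max}}{\mathrm{MSE}},$$
with $I_{max}$ entering *unsquared* and fixed to 1 after normalization —
at unit range this coincides with the conventional squared definition, and
minimising $1/\mathrm{PSNR}$ is a monotone transform of minimising the MSE.
Numerical guards: the MSE is floored at $10^{-12}$ (a perfect batch yields a
large finite PSNR), and the loss-to-MSE gradient factor clamps the PSNR at
1 dB from below so a catastrophic first batch cannot produce an unbounded
step. Evaluation PSNR (`psnr()`) uses the conventional
$10\log_{10}(\mathrm{range}^2/\mathrm{MSE})$, capped at 100 dB.

Optimisation is mini-batch Adam (learning rate $10^{-3}$, $\beta_1 = 0.9$,
$\beta_2 = 0.999$, batch 32 by default), with He-scaled Gaussian weight
initialisation. Every stochastic ingredient (initialisation, shuffling,
validation split) draws from a seed derived from one master seed, so runs
are bit-reproducible. 10% of patches are held out and their plain MSE is
logged per epoch as the validation error; `tidy()` on a fitted model returns
the log and `autoplot()` draws it.

All layer primitives (convolution, transposed convolution and their
gradients) are implemented in compiled code as im2col/col2im plus BLAS
matrix products; the exactness of the backward pass is verified against
finite differences in the test suite.

## Normalization and patches

Each projection image is normalized in two steps
(`normalize_two_step()`): standardise to zero mean and unit variance, then
rescale affinely onto $[0,1]$. The composition is invariant to positive
affine rescaling of the input, which places exposures of different lengths
on one scale. Normalization statistics are computed **per image**, and for a
training pair the *low-dose* image's parameters are applied to both sides of
the pair: enhancement later inverts exactly those parameters
(`denormalize_two_step()`), so input and target must share one intensity
frame — normalizing each side with its own statistics would introduce a
systematic affine error exactly as large as the difference between the noisy
and clean image ranges.

Overlapping patches (`extract_patches()`; default edge 64, multiple of 8 so
the three stride-2 stages divide evenly) turn a handful of projections into
up to $\sim 10^5$ training examples. Anchors advance by the stride and the
final anchor is clamped to the image edge, so every pixel is covered without
inventing padded values; reassembly (`reassemble_patches()`) averages all
patches covering a pixel, making extract-reassemble an exact identity.
Training uses stride 16 by default (denser stride 4–8 at small image sizes),
inference uses half the patch edge.

## The synthetic benchmark

`generate_phantom()` builds the three-phase test object: empty space (0), a
centred solid cube (0.3) and spherical particles (1.0) with diameters
uniform on [4, 20] voxels, centres uniform inside the cube with a
one-radius margin so particles are fully contained; overlaps are permitted.
The cube edge is 62.5% of the volume edge — the largest centred cube whose
rotation diagonal stays inside the detector width. The reference experiment
uses a $512^3$ volume with 1000 particles and 721 equispaced angles over
$[0°, 180°]$.

Projections are parallel-beam line integrals per horizontal slice
(`forward_project()`), with detector pitch equal to voxel pitch and angles
counter-clockwise from the $+x$ axis. Two interchangeable projectors exist:
a discrete voxel projector (linear splatting onto detector bins; the
reference path for arbitrary volumes) and a closed-form projector for the
parametric phantom (trapezoid chord for the square section, circle chord per
sphere), which makes the $512^3$ benchmark computable slice-by-slice in
minutes without ever materialising a volume
(`noise_reconstruction_benchmark()`). The closed form adds sphere chords
independently, so overlapping particles are double-counted along the overlap
chord — a sub-percent effect at the benchmark's ~1% particle density — and
a property test ties the two projectors together on small phantoms.

Low dose is emulated by additive zero-mean Gaussian noise with
$\sigma = \text{level} \times (\max - \min)$ of the clean projection stack
(`add_noise()`), applied identically to all projections. The "percent noise"
reference is a deliberate convention of this package: a percentage of the
global dynamic range is scale-free and reproducible. Where a noise
percentage is defined against another reference (per-image maximum, mean
signal, or a normalized intensity frame), reconstructions at nominally equal
percentages can differ substantially in reconstruction-domain SNR — a
several-dB effect on benchmark PSNR values; comparisons across conventions
should compare $\sigma$ directly. What the simulator does **not** model:
photon-counting (Poisson) statistics, detector blur/readout structure,
beam-hardening or phase contrast, cone/fan geometry. Passing synthetic tests
therefore demonstrates correct mechanics and strong denoising under
Gaussian noise, not performance on any particular beamline's data.

## Reconstruction

`reconstruct()` performs slice-wise filtered backprojection: sinogram rows
are zero-padded to the next power of two at least twice the detector width,
filtered with the exact discrete ramp (built from its spatial-domain kernel,
so the DC term is correct) multiplied by the Parzen (de la Vallée Poussin)
window at relative cutoff 1, backprojected with linear interpolation, and
scaled by $\pi / (2 n_{\text{angles}})$. The Parzen-windowed ramp is the
same smoothing choice popular Fourier-grid reconstructors default to; the
reconstructor is deliberately treated as an interchangeable backend, and the
rotation centre defaults to the detector midline (exact for synthetic data,
overridable for measured stacks). Round-trip fidelity (project then
reconstruct, $r > 0.95$; phase gray values recovered; impulse localisation)
is asserted in the tests.

## Quality metrics

`psnr()`, `ssim_map()`/`ssim()` and `volume_report()` implement the
evaluation: slice-wise PSNR and SSIM (Gaussian window $11\times11$,
$\sigma = 1.5$, $K_1 = 0.01$, $K_2 = 0.03$, symmetric boundary reflection —
the standard constants of the structural-similarity literature) with means
and standard deviations across slices, returned as tidy tibbles.

`histogram_modes()` formalises "how many distinguished peaks does a volume
histogram show": 256 bins (padded by two empty bins so a phase at the
intensity extreme forms an interior peak), 9-bin moving-average smoothing,
peaks counted on $\log_{10}(1+\text{count})$ with topographic prominence
$\geq 0.5$, a height floor of $10^{-4}$ of the tallest bin, and a minimum
peak separation of 1/8 of the intensity range (the taller peak absorbs
closer candidates). The log scale is essential: the particle phase holds
well under 1% of the voxels, so on a linear scale its peak can never reach a
fixed fraction of the background peak — visibility of a histogram phase is a
ratio phenomenon. The separation guard absorbs the narrow edge-response
bands that filtered backprojection paints next to each phase value. The rule
was calibrated on clean reconstructions and on planted Gaussian-mixture
volumes with known mode counts.

Small-volume caveat: reconstructions of few-hundred-voxel phantoms carry a
genuine partial-volume band between the cube and particle values (few
discrete sphere sizes, coarse angular sampling). The band shrinks as sphere
count and resolution grow, but at desk scale it can appear as a fourth mode
in *clean* volumes, and conversely the particle peak of *network-enhanced*
volumes at mid noise levels can stay just below the prominence threshold
when the network was trained on only a few hundred patches. The acceptance
tests document exactly which of these sub-checks hold at the surrogate
scale.

## Baselines

The classical comparators are a sliding-window median filter
(`median_denoise()`, symmetric edge reflection) and total-variation
denoising (`tv_denoise()`, Rudin–Osher–Fatemi model solved with Chambolle's
dual projection scheme at a fixed iteration budget; the TV weight is
specified as a fraction of each image's dynamic range so one default covers
unit-scaled and line-integral-scaled stacks). For the comparison with the
learned enhancement, each baseline runs at the settings that maximise *its
own* projection-domain SSIM on the synthetic 10%-noise case, found by a
small grid search — median window over $\{3,5,7,9,11\}$ (best: 11, SSIM
0.42/0.59/0.67/0.71/0.72) and TV weight over
$\{0.02, 0.05, 0.1, 0.2, 0.4\}$ of range at 100 iterations (best: 0.1,
SSIM 0.31/0.68/0.83/0.79) — so the learned method is compared against the
baselines at their best, not at a strawman setting.

## Problem sizes used by the tests

The test suite exercises the full mechanics at sizes chosen for a
single-CPU workstation; these are the package's documented study
conditions:

* the no-network noise benchmark runs at the full $512^3$ / 721-angle /
  1000-sphere scale, streamed slice-by-slice (the test asserts on a
  systematic 64-slice subset; `scripts/acceptance.R` runs all 512 slices);
* the learned-enhancement experiments run on a $128^3$ surrogate with 16
  spheres (the reference phantom's particle density and diameter law), 181
  angles, training pairs at 0° and 45°, patch edge 32, stride 8, batch 32;
  20 epochs per noise level, with the 30% level trained to 40 epochs (and a
  weight snapshot at epoch 20) for the convergence check;
* unit tests use $48^3$ phantoms and patch edge 16.

A desk-scale caveat the acceptance tests make explicit: at the surrogate
training budget (~10³ patches from two 128×128 projections) the learned
enhancement does **not** overtake the grid-tuned TV baseline on the
synthetic case — piecewise-smooth noiseless-structure projections under
pure Gaussian noise are exactly the signal class TV regularisation is
optimal for, while the network is data-starved. The learned method's edge
is expected from dense patch extraction on large projections
(~10⁵ patches) and on textured real data that violates TV's
piecewise-constant prior.

## Known limitations

* No photon-noise model; the Gaussian-percentage convention above is one of
  several in use, and reconstruction-domain PSNR at a nominal noise
  percentage is sensitive to it.
* One model per noise level / exposure condition; no transfer across
  samples, no pre-trained weights.
* Parallel-beam geometry only; no ring-artifact removal, phase retrieval,
  or iterative reconstruction.
* The CPU implementation favours exactness and reproducibility over speed;
  full-scale *training* ($512^3$, $10^5$ patches, 40 epochs) is
  hours of CPU time and is not run in the test suite.
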