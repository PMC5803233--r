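# tomodenoise

Projection-domain CNN enhancement for low-dose X-ray tomography, in R.

## The problem

Imaging radiation-sensitive samples (stained brain tissue, polymers,
hydrated specimens) with synchrotron X-ray tomography forces a trade-off:
long exposures give clean projections but cook the sample; short exposures
spare it but bury the signal in noise. `tomodenoise` implements a
projection-domain answer for beamline scientists and image-analysis
developers: record the full angular scan at *short* exposure plus a **few**
matched *long*-exposure projections of the same object, learn the mapping
between the two conditions, and apply it to every short-exposure projection
before reconstruction. Because training and test data come from the same
object, two or three angles of paired projections suffice.

## The method

The learned mapping f : I_s(a) → I_l(a) (short- to long-exposure projection
at angle a) is a convolutional encoder–decoder operating on overlapping
image patches:

- **encoder**: 8 convolutional layers (3×3 kernels, 16→64 kernels per layer,
  three stride-2 layers taking W×H down to W/8×H/8), then a fully connected
  bottleneck;
- **decoder**: 9 transposed-convolution layers (3×3 kernels, 64→1 kernels,
  three stride-2 layers back up to W×H), with the feature maps after each
  upsampling stage *merged* (concatenated) with the encoder features of the
  same scale so full-resolution detail bypasses the bottleneck;
- **objective**: minimise 1/PSNR, with PSNR = 10·log10(I_max / MSE) on
  two-step-normalized patches (standardise, then rescale to [0, 1]);
  mini-batch Adam, deterministic given one master seed.

Around the network the package provides the full experimental bench: a
three-phase synthetic phantom (empty space 0 / solid cube 0.3 / spherical
particles 1.0) with a closed-form Radon projector that scales to 512³
volumes slice-by-slice, percentage-of-range Gaussian noise to emulate dose
levels, Parzen-filtered backprojection, PSNR/SSIM/histogram-mode evaluation
with tidy per-slice reports, and median-filter / total-variation baselines.
All of it is plain R + Rcpp; no deep-learning framework is required.

## Worked example

A complete small-scale experiment — simulate, corrupt, train on two angles,
enhance the full scan, reconstruct, evaluate:

```r
library(tomodenoise)

phantom <- generate_phantom(size = 64, n_spheres = 8, d_min = 8, d_max = 16,
                            seed = 5)
angles  <- seq(0, 180, length.out = 91)
p_o <- forward_project(phantom, angles)      # clean projections
p_n <- add_noise(p_o, level = 0.30, seed = 2)  # 30% low-dose surrogate

model <- build_network(network_spec(patch_edge = 32), seed = 3)
model <- train_cnn(model, training_pairs(p_n, p_o, angles = c(0, 44)),
                   epochs = 30, batch_size = 8, patch_stride = 4, seed = 4)
p_e <- enhance(model, p_n)

r_o <- reconstruct(p_o)    # reference volume
r_n <- reconstruct(p_n)    # low-dose volume
r_e <- reconstruct(p_e)    # enhanced volume

volume_report(r_n, r_o)
#> <quality_report> 64 slices: PSNR 15.55 +/- 0.24 dB, SSIM 0.09 +/- 0.069
volume_report(r_e, r_o)
#> <quality_report> 64 slices: PSNR 26.04 +/- 1.43 dB, SSIM 0.43 +/- 0.197
```

Reconstructing from the raw 30%-noise projections leaves a volume that
shares almost no structure with the reference (PSNR ≈ 15.5 dB, SSIM ≈ 0.09);
after enhancement with a network trained on just the 0° and 44° pairs, the
same projections reconstruct ~10 dB closer to the reference with almost
five times the structural similarity. `glance()` on a report gives the summary as a
one-row tibble, `tidy()` the per-slice values, and `autoplot()` the
slice-wise curves; `histogram_modes(r_e)` counts the gray-value phases that
make thresholding-based segmentation possible again.

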