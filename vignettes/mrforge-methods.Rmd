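---
title: "mrforge: models, simulators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mrforge: models, simulators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mrforge` implements a complete desk-scale toolchain for MR image-quality
research: simulators for the four dominant 2-D artefacts, a gradient-aware
convolutional loss, a label-masked multi-task objective, a dual-domain
residual correction network, and the standard quality metrics. This
vignette explains the science in the package's own terms, the tunable
parameters and their defaults, and the design decisions taken where the
problem left genuine freedom.

## Fourier conventions

Everything sits on one set of conventions (module `kspace`): centered 2-D
discrete Fourier transforms with orthonormal scaling, so Parseval's
identity `sum(x^2) == sum(|K|^2)` holds exactly and "the center of
k-space" is literal. The DC component is pinned to index `ceiling(n/2)`
(1-based) on each axis, and the normalized phase-encode coordinates
returned by `pe_coordinates(n)` are evenly spaced with step `2*pi/n` on
the half-open interval `(-pi, pi]`, with the DC line at exactly 0 at that
same index. For even `n` the two requirements — a monotone coordinate
vector inside `(-pi, pi]` and DC at the centered index — cannot both be met
by the textbook `fftshift` placement (which puts `-pi` at the first line);
we therefore center on `ceiling(n/2)` rather than `floor(n/2) + 1`. The
Nyquist line is labelled `+pi`, consistent with the half-open interval.
A "k-space line" is one full index along the phase-encoding axis (`pe_axis`
is 1 for rows or 2 for columns, the R margin convention).

`fourier_crop()` implements the standard reduction of large scanner
matrices (512×512 → 320×320): transform, keep the centered block, inverse
transform, and rescale by `sqrt(N_out/N_in)` so constants are preserved.
The same machinery zero-pads when a NIfTI volume is smaller than the model
size (`read_nifti_volume()`).

## Phantoms

The generator (module `phantoms`) draws `n_regions` nested ellipses with
random pose and shrinking semi-axes, fills each with a constant intensity
drawn uniformly from `intensity_range`, and smooths boundaries with a
Gaussian of `edge_softness` pixels. The design goal is not anatomical
realism but the *right kinds of structure*: piecewise-constant plateaus
(so multiplicative bias and noise are numerically distinguishable) and
soft edges (so the Prewitt/Sobel/Laplace stencils of the convolutional
loss have genuine gradients to respond to). Intensities default to
`[0, 1]`; the model Z-normalizes its reconstruction, so a fixed input
scale convention keeps losses comparable across slices. Everything is
bit-reproducible from `(spec, seed)`; `generate_dataset()` derives one
child seed per slice.

What phantoms do *not* emulate: tissue-contrast physics (T1/T2),
anatomical texture inside regions, 3-D continuity, and coil-array
sensitivity profiles. Tests passing on phantoms demonstrate that the
simulators and the training loop behave as specified — not that a model
trained on phantoms transfers to clinical data.

## The four artefact simulators

**Bias field.** A stationary Gaussian spatial random field with
correlation `cov(r) = exp(-(pi/4) * (r/l)^2)` is synthesized on a 32×32
grid (`l` uniform in `(10, 50)` grid units, variance 50 — the variance is
erased by the min–max normalization but kept for fidelity to the model),
then upsampled smoothly and normalized to a multiplicative range. The
synthesis is spectral: the covariance kernel is evaluated on a torus
sized so the Gaussian decays below 1e-9, its FFT gives the circulant
eigenvalues (tiny negative truncation values clipped at zero), and white
noise is filtered by the square root of the spectrum. This is exact up to
the clipping and costs `O(M^2 log M)` per draw. The 32→target upsampling
uses separable cubic-spline interpolation, which is smooth and
shape-preserving at these scales.

Three range conventions are available because the conventional anchor
ranges are mutually inconsistent: a strength of 10 % is usually quoted as
`[0.95, 1.05]` while 100 % is quoted as `[0.5, 2]`. No affine rule maps
strength to both; the reciprocal rule `[1 - s/2, 1/(1 - s/2)]` reproduces
both anchors and is the default. `"half-span"` (`[1 - s/2, 1 + s/2]`) and
`"symmetric"` (`[1 - s, 1 + s]`, the convention under which 5/10/20 %
fields mean `[0.95, 1.05]`, `[0.9, 1.1]`, `[0.8, 1.2]`) are selectable.
The normalized field attains its bounds exactly and is strictly positive;
a combination that would touch zero (symmetric at full strength) is
rejected.

**Subsampling.** Masks select whole PE lines. The center band —
`round(band% * n)` contiguous lines around DC, with band% = 16/12/8/4 for
acceleration 2/3/4/8 — is always fully sampled; the remaining budget of
`round(n/accel) - band` lines is taken equidistantly (fixed stride
`floor((n - band)/m)` with a seeded offset uniform in `[0, stride)`) or
uniformly at random; the `"centered"` kind keeps only the band. Counts
use round-half-away-from-zero (R's `round()` rounds half to even, which
would break the printed 26-line example at acceleration 4). Zero-filled
reconstruction: unselected lines are zeroed, selected lines stay
bit-identical.

**Rigid motion.** `round(f * n)` lines (`f` uniform in `[0.30, 0.80]`)
are split into 4–24 contiguous segments placed uniformly at random without
overlap (segment lengths are a uniform random composition; the free lines
are spread over the gaps). Each segment gets one rigid transform —
rotation about the image center (σ = 12°) and per-axis translations
(σ = 30 voxels) — applied in image space with a hand-rolled vectorized
bilinear warp (zero padding outside); the transformed image's k-space
replaces that segment's lines. Non-corrupted lines are copied verbatim
from the clean k-space, and the assembled k-space is returned alongside
the image because the verbatim-copy contract is only checkable there (the
real-valued image output re-symmetrizes its spectrum). The warp is written
in-package rather than through an image library so that the coordinate
convention (center, axis order, padding) is pinned by our own tests.
Translations are drawn per axis; a per-axis σ of 30 voxels was chosen over
a single magnitude draw as the more common reading. An optional protected
center band (`protect_center_frac`) supports evaluation settings where
25/12.5/5 % of central lines stay clean.

**Periodic (respiratory) motion.** A pure phase error applied per PE
line: `S(kx, ky) = S0(kx, ky) * exp(-1i * phi(ky))` with
`phi(ky) = ky * Delta * sin(alpha*ky + beta)` for `|ky| > ky0` and 0
otherwise (`Delta` in `[20, 120]` pixels, `alpha` in `[0.1, 5]`, `beta`
in `[0, pi/4]`, `ky0` in `(pi/10, pi/8]`). The multiplier has unit
modulus, so the corruption is an exact per-entry isometry of k-space, and
protected center lines are not touched at all (bit-identical). `alpha` is
applied literally as radians per unit `ky`; no further unit conversion is
implied by its nominal Hz label.

**Noise.** With `S` the mean absolute k-space value, the per-component
noise standard deviation is `N = S / 10^(snr_db/20)`, i.e.
`SNR = 20*log10(S/N)` exactly; independent Gaussian noise of that σ is
added to the real and imaginary part of every entry and the slice is
inverse-transformed. With a 320×320 slice the realized SNR (recomputed
from the drawn sample) sits within 0.05 dB of target, comfortably inside
the 0.2 dB acceptance band. Noise is added to the k-space of the
magnitude image, since inputs are real-valued magnitude slices.

`draw_sample()` applies exactly one artefact per slice, drawn uniformly
over the four types with parameters uniform over the ranges above. The
`"brain"` profile uses rigid motion only; `"pelvic"` picks rigid or
periodic motion with equal probability.

## Losses

The convolutional loss family replaces the plain MSE with
`L(I, x, xhat) = MSE(I * x, I * xhat)` for a stencil `I`, and combines
nine stencils (identity; Prewitt top/right; Sobel 3×3 and 5×5 top/right;
Laplace 3×3 and 5×5) with per-kernel weights δ in `[0, 1]`:
`L_C = Σ δ_k L(I_k, ...)`. Shipped δ values are the
Bayesian-search optima for the brain multi-task model
(δ_E = 0.30, δ_PT = 0.83, δ_PR = 0.25, δ_S3T = 0.74, δ_S3R = 0.30,
δ_S5T = 0.21, δ_S5R = 0.72, δ_L3 = 0.09, δ_L5 = 0.82; α = 0.87;
learning rate 10^−3.91 with RMSprop) and for the pelvic model; they are
constants here, not re-optimized.

Numerical choices: stencils are applied unflipped (cross-correlation);
each stencil is symmetric up to sign under 180° rotation, so this only
fixes a sign that the squared loss ignores, but it makes hand oracles
unambiguous. Evaluation is valid-region only (no padding), avoiding
boundary gradients; all-zero border rows/columns of a stencil are trimmed
first, so the 3×3 identity stencil has a 1×1 support, acts on every pixel,
and the identity reduction `L(I_E, x, xhat) == MSE(x, xhat)` holds exactly
(to 1e-12 in the acceptance suite) rather than only on an interior crop.

The multi-task objective for a sample with artefact label `y` is
`L(v, u + p_y)` — the indicator masking zeroes the other heads, making the
loss value and its data-term gradients *exactly* invariant to them (tested
bitwise). Each head additionally carries `alpha * ||p_i||^2` with a single
shared α; the regularizer is the only gradient source for non-selected
heads. In training the base loss is computed on Z-normalized images,
matching the model's normalized output.

## The dual-domain model

Two structurally identical encoder–decoder branches: the image branch
consumes the corrupted slice, the k-space branch consumes its centered
transform as two real channels and maps each head's two-channel output
back through an inverse-Fourier layer (real part kept). Each branch is
twelve convolutional blocks — input feature block, five stride-2 blocks
with `64·2^d` channels (d = 0..4), five upsampling blocks
(nearest-neighbor resize + convolutions) whose inputs concatenate the
matching down-block output (U-Net skips), and an output block — with
three 3×3 convolutions per block, each followed by per-channel
normalization and LeakyReLU (slope 0.2). Four 1×1 heads per branch emit
the residuals; corresponding heads are summed and
`vhat = znorm(u + Σ p_i)`.

The block composition beyond "5 down + 5 up" is under-determined, and the
up-path channel schedule is free; we fixed input/output blocks at the base
width and up-path outputs `[4b, 2b, b, b, b]` (halving after each concat),
which is the faithful 12-block reading and lands the reference model at
75.55 M trainable parameters — within 0.2 % of the 75.4 M design target;
no faithful composition we enumerated hits that figure exactly, and the
acceptance test checks 1 % relative agreement. `count_model_params()` is a
pure function of the configuration and always equals the built model's
parameter total.

Implementation notes: the network, conv2d forward/backward (im2col + GEMM
in RcppArmadillo), instance-style normalization (per-sample spatial
statistics, so inference needs no running moments), nearest-neighbor
upsampling, the Fourier layers, and RMSprop are implemented in-package —
no deep-learning framework exists in the target R environment, and the
dual-domain residual architecture is part of the method rather than a
commodity step. All gradients, including through the inverse-Fourier head
layers and the Z-normalization, are verified against central finite
differences (worst relative error below 1e-4 in the suite; LeakyReLU kink
crossings are handled by retrying the step size). Z-normalization uses the
sample standard deviation so the output's `sd()` is exactly 1; statistics
are per-image. Normalization layers default on (they are counted in the
75.5 M), but the scaled-down training runs disable them: with per-sample
statistics at batch size 8 they destabilize more than they help at 64×64.

Training minimizes the masked data term plus the per-head regularizer,
with early stopping on validation MSE (patience 10). The shipped learning
rate 10^−3.91 is the full-scale optimum; it is the default of
`train_model()`.

## Scaled-down training demonstration

`training_smoke()` is the package's end-to-end check: 200 phantom slices
at 64×64, corrupted only by noise at 0 dB, a small configuration (base 4
channels, 2 convolutions per block, no normalization — about 0.16 M
parameters), 12 epochs of RMSprop at learning rate 5e-4, regularization
α = 0.87 scaled by 1/(64·64). Two scale adaptations matter and are
deliberate: the learning rate is raised from the full-scale default
(which under-trains a model this small within the epoch budget), and α is
divided by the pixel count so the sum-form regularizer stays commensurate
with the mean-form data term (at full scale the two conventions differ by
a constant the original α was tuned against). Under these conditions
validation MSE falls monotonically by a factor of ~10–80 and held-out
SSIM of reconstructions exceeds the corrupted baseline by 0.03–0.11
across seeds. The problem sizes here (and the 200/12-epoch budget) were
chosen so the whole demonstration runs in a few minutes on one CPU core;
they are the package's canonical smoke conditions, used verbatim by the
test suite and the acceptance script.

## Metrics

MSE is the plain per-pixel mean. SSIM uses the standard 11-pixel Gaussian
window (σ = 1.5), K1 = 0.01, K2 = 0.03, population window statistics,
valid-region evaluation, and data range `max − min` of the reference (the
reference-based range is a documented choice; it matches the common
default when the true dynamic range is unknown). The implementation
agrees with scikit-image's `structural_similarity` (gaussian weights,
population covariance) to 10 decimal places on a frozen fixture.

VIF is the pixel-domain variant over 4 dyadic scales with visual-noise
constant `sigma_nsq = 2.0` and reference-first argument order; pyramid
and window filtering use reflected-border same-size Gaussian convolution
so the decomposition is defined down to 32-pixel images. Pixel-domain VIF
can legitimately exceed 1 when the test image carries more
reference-consistent information (contrast amplification, and even mild
noise on smooth references); the suite therefore asserts monotone
degradation under increasing noise and `VIF < 1` only at strong noise.
The wavelet-domain variant was not chosen; the pixel-domain parameters
are pinned for reproducibility, not asserted to match any external
implementation.

## Degenerate inputs and tie-breaks

Zero-variance images are rejected by `znorm` (and hence by the model
forward pass); all-zero images are rejected by `add_noise` (SNR
undefined); a flat random field draw (measure zero) normalizes to the
midpoint of its bounds; `n_segments` is clamped to the number of
corrupted lines when the requested fraction yields fewer lines than
segments; masks whose center band exceeds the sampling budget are
rejected with a diagnostic naming both counts.

## Known limitations

Phantom realism as above; single-coil, magnitude-input, 2-D only;
rigid motion is in-plane; the k-space branch sees unnormalized spectra
(the DC channel dominates, which the normalization layers absorb at full
scale but which slows the small no-normalization configuration);
training at the 320×320 reference scale is out of desk-scale reach, so
all learning claims are made at the smoke scale; and HDF5 interchange
writes real/imaginary planes rather than compound complex types (the
reader accepts both dialects).
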