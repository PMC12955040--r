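---
title: "Dual-modality light-field microscopy simulation and fusion reconstruction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-modality light-field microscopy simulation and fusion reconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`lffuse` simulates the image formation of two complementary single-shot 3D
microscopy modalities — conventional light-field microscopy (LFM), with the
microlens array (MLA) at the native image plane, and Fourier light-field
microscopy (FLFM), with the MLA conjugate to the objective's back focal
plane — and reconstructs 3D volumes from the pair with a four-branch
convolutional fusion network supervised at multiple levels. A matched-adjoint
Richardson–Lucy (RL) deconvolution baseline and PSNR/SSIM evaluation close
the loop: every number the package reports can be recomputed from a seeded
synthetic phantom, with no external data.

This vignette records the models, the discretisation choices, and the design
decisions that were genuinely open, in the order the pipeline runs.

# Wave-optics core

## Debye focal field

The scalar field of a point source at axial position $z$ is the Debye
integral
$$U_b(r;z) = \int_0^{\theta_{\max}}
  U_o(\theta)\, e^{i 2\pi n z \cos\theta/\lambda}\,
  J_0\!\left(\tfrac{2\pi}{\lambda} r \sin\theta\right) \sin\theta\, d\theta,
  \qquad \theta_{\max} = \arcsin(\mathrm{NA}/n),$$
evaluated by Gauss–Legendre quadrature with 256 nodes
(`debye_radial()`). Doubling the node count changes the result by less than
$10^{-6}$ relative (enforced by a test), so quadrature error is negligible
against every tolerance used downstream. The apodization $U_o(\theta)$ is
configurable and defaults to a uniform pupil; nothing in the pipeline
depends on a particular choice. The 2D field is assembled from the radial
profile evaluated once per distinct grid radius, so its radial symmetry is
exact by construction.

## Propagation, aperture, band limit

Free-space propagation uses the band-limited angular-spectrum kernel
$H(f_x,f_y)=\exp(i 2\pi d \sqrt{\lambda^{-2}-f_x^2-f_y^2})$ with evanescent
components ($\lambda^{-2} < f_x^2+f_y^2$) set to zero. Without padding the
discrete operator is exactly unitary on the propagating band, which is what
the round-trip and energy-conservation tests check; for imaging chains the
field is zero-padded to twice its extent and cropped back to suppress
wraparound (`propagate_angular_spectrum(pad = TRUE)`).

The Fourier-plane aperture is the super-Gaussian
$P(\rho)=\exp(-(\rho/\lambda_c)^{2\alpha})$: $\lambda_c$ acts as a clipping
radius and $\alpha \ge 1$ sharpens the edge toward a hard disk. The
anti-aliasing band limit multiplies the spectrum by the transform of the
radial kernel $\mathrm{sinc}(2\rho/\lambda_c)$, which is supported inside
radial frequency $1/\lambda_c$; we realise it as the ideal radial low-pass
with unit passband gain. The exact transform carries a
$1/\sqrt{1-(f\lambda_c)^2}$ amplitude ripple that diverges at the cutoff;
dropping it keeps the filter's only stated role — suppressing content beyond
the cutoff — and makes the filter idempotent, so repeated application is
harmless.

## Aperture tailoring by gradient descent

`optimize_aperture()` fits the aperture transmission so the simulated
intensity PSF $\mathrm{PSF}_{sim}(P)=|L(U_0 \odot P)|^2$ (with $L$ a unitary
propagation) matches a target, minimising
$$J(P)=\|\mathrm{PSF}_{t}-\mathrm{PSF}_{sim}(P)\|_2^2
 + \lambda_1 \|\nabla P\|_1 .$$
The data-term gradient is computed with the adjoint of $L$
(`aperture_gradient()`, validated against central finite differences at
$10^{-4}$ relative), the total-variation term uses forward differences with
subgradient 0 at ties, and the update is projected descent
$P_{n+1} = \Pi_{[0,1]}(P_n - \eta \nabla J)$ with automatic halving of
$\eta$ (up to 20 times) whenever a step would increase $J$; the objective
history is therefore non-increasing, and a step-size exhaustion raises an
error carrying the history.

# The LFM point-spread function and forward model

The LFM response is stored as the 5D tensor
`psf[z, w, h, u, v]`: the sensor-plane intensity patch of a point source on
the optical axis, over a $16\times16$ lenslet patch with $11\times11$
sensor pixels per lenslet at the reference preset (40×/0.8 NA, 580 nm,
150 µm pitch, $f_{ml}=3.5$ mm, 61 depths from −30 to 30 µm). $(w,h)$ index
the lenslet — the spatial sample of the light field — and $(u,v)$ the pixel
within the lenslet — the angular sample. Two parameterisations of such a
(61, 16, 16, 11, 11) response are possible a priori: a lenslet grid ×
pixels-per-lenslet sensor patch, or a sub-lenslet source-offset sweep whose
sensor response is folded over the lenslet patch. We adopted the first
after establishing numerically that the fold of the second collapses every
per-view kernel to an exactly centred function of the source offset at all
depths, i.e. it provably erases the disparity that the epipolar-plane
images must carry. Under the adopted convention the light field is
`L(u, v, w, h)` with angular axes of size 11 and spatial axes at lenslet
resolution (16), which also matches the shapes of the EPI stacks below.

Numerically, each depth is simulated on an odd, mirror-closed grid of
$17\times17$ lenslets at 3× sub-pixel sampling (the lenslet focal spots are
about one sensor pixel wide; without oversampling the binned defocus
patterns alias visibly). The chain is: radial Debye profile → relay
magnification onto the MLA plane → thin-lens MLA phase
$\exp(-i\pi(x'^2+y'^2)/\lambda f_{ml})$ per tile → angular-spectrum
propagation over $f_{ml}$ → intensity → pixel binning → crop to 16 complete
lenslet blocks. On the odd grid the optical point symmetry
$\mathrm{PSF}(x,y,z)=\mathrm{PSF}(-x,-y,z)$ holds exactly and is verified to
$10^{-8}$. Each depth slice is normalised to unit sum, so forward projection
conserves flux plane by plane (exactly, for sources whose patch lies inside
the sensor window), which in turn makes the RL flux bookkeeping exact.

Projection (`project_lfm()`) treats the system as laterally shift-invariant
at the voxel scale — the standard approximation of the view-channel-depth
(VCD) simulation lineage: the sensor image is
$I = \sum_z I_z * \mathrm{PSF}_z$ by zero-padded FFT convolution, then
rearranged into views. The object-space voxel pitch equals the sensor pixel
pitch divided by the magnification (150/11/40 ≈ 0.34 µm at the reference
preset, matching the stated dataset sampling; 176 px × 0.34 µm = 59.84 µm of
lateral field).

# The FLFM point-spread function and forward model

FLFM is simulated on the reconstruction voxel grid. Per depth the processed
field is `debye_wavefront()` → aperture window → sinc band limit, with the
aperture half-angle capped at the grid's representable band
(0.95× Nyquist) so the sampled field is alias-free; the simulated system
therefore operates at the sampling-limited effective NA of the chosen voxel
pitch, and the seven sub-aperture views are laid out by scaling the 2-3-2
footprint (radius 1.5 lenslet pitches after the $f_{R2}/f_{R1}$ relay) onto
that band. Each view is the intensity of the field restricted to its
circular sub-aperture in the frequency domain; defocus tilts across a
sub-aperture become lateral shifts, so view-dependent disparity emerges
from the wave model rather than being painted in. View intensities are
placed on a $3V\times3V$ sensor mosaic (2-3-2 rows, disjoint windows),
normalised to unit sum, and stored as the frequency-domain transfer stack
$\mathrm{PSF}_{FLFM}(f_x,f_y,z)$ — Hermitian by construction, so each
depth response has a real inverse transform.

The depth weights $w(z)$, shaped $(n_z,1,1)$, are the normalised complex
inner products between the depth-$z$ processed field and the in-focus
field: $w(0)=1$, $|w|\le1$, and $w$ acquires an imaginary part off focus as
the defocus phase decorrelates the fields. Projection is the frequency-domain
sum $I = \mathrm{Re}\,F^{-1}\{\sum_z w(z) F\{I_z\} \mathrm{PSF}_{FLFM}\}$.
Because each $H_z$ is Hermitian while $w(z)$ is complex, the imaginary
residue of the inverse transform is $\sum_z \mathrm{Im}(w_z)(I_z * h_z)$:
it vanishes for single-plane content and for real weights, and is logged as
an attribute (with a warning above the tolerance) rather than silently
discarded in the general case. Negative intensities after the real part are
clipped, with the clipped mass logged.

# Epipolar-plane images

EPI extraction is pure, bit-exactly invertible axis rearrangement:
`lfm_epi()` produces the u-h plane stack $(v\cdot w, u, h)$ and v-w plane
stack $(u\cdot h, v, w)$ (channels v-major/u-major respectively; at the
reference geometry both are $176\times11\times16$), and `flfm_epi()`
produces the c-w $(h, c, w)$ and c-h $(w, c, h)$ stacks with $c=3$ views. A
2-3-2 row layout contains exactly one complete horizontal collinear triple
(the central row, used for c-w) and no strictly vertical triple; the c-h
stack therefore uses the collinear top-left/centre/bottom-right triple,
which is the only other full collinear view set in the layout.

`epi_dominant_slope()` estimates disparity as the dominant line orientation
of an EPI slice by the structure tensor, after Gaussian pre-smoothing
(σ = 1 px), and refines the estimate by shearing the slice with the current
slope and measuring the residual orientation. The refinement removes the
finite-difference bias that otherwise grows with slope (drawn test lines of
slopes 0.5–2 px/view are recovered within the tested 5% tolerance); ties in
the tensor
break toward slope 0, and constant slices return a flagged `NA`. On
simulated point sources the slope is ≈0 at the focal plane and its
magnitude grows monotonically with |z| (Spearman ρ ≥ 0.9 over 11 central
depths at the reference geometry), which is the quantitative sense in which
the extracted EPIs encode depth.

# Phantoms

`make_tubulin_volume()` rasterises smooth random spline curves (cubic
spline through a control-point random walk) with a Gaussian cross-section —
emulating a sparsely labelled filament sample at 176×176×61 voxels,
0.34/0.34/1 µm — and `make_vessel_volume()` grows recursive bifurcating
trees with radius tapering, emulating branching vasculature. Morphology
parameters (curve stiffness, branch angles, taper) are package choices
exposed in `phantom_config()`; they are tuned for visual plausibility, not
derived from data. Generation is seed-deterministic, and
`make_dataset()` projects each volume through both simulated systems,
extracts the four EPI stacks, and splits samples 8:2 by a seeded shuffle.

What the phantoms deliberately do not model: sensor noise (projection is
noiseless by default), aberrations, scattering, or the intensity statistics
of real confocal stacks. Passing tests on these phantoms demonstrates the
correctness and internal consistency of the simulation, extraction and
reconstruction machinery — not performance on real microscope data.

# The four-branch fusion network

Each modality stack enters an adapter — bilinear interpolation of the
spatial axes to the ground-truth lateral size, then a 3×3 convolution to a
unified channel width; the two EPI stacks of a modality are adapted
separately (no weight sharing) and merged by a further convolution. Inputs
are normalised per sample to unit maximum inside the adapter. Each branch
then runs a small 2D U-Net (two encoder/decoder levels at desk scale,
configurable) whose head emits the volume with depth as output channels —
the VCD-style depth-as-channels decoder, matched to the 2D stacked inputs.
Spatial sizes that are not divisible by $2^{depth}$ are zero-padded and
cropped back, never an error.

Fusion is hierarchical and result-level: A = fuse(LFM, LFM_EPI),
B = fuse(FLFM, FLFM_EPI), final = fuse(A, B); a model built with a subset
of branches passes the available volume through its cascade stage unfused.
Each fusion block concatenates its two volumes, applies
conv–ReLU–conv, and adds the result to the average of its inputs; the last
convolution is zero-initialised. We first implemented the block without the
residual mean path (plain zero-initialised output): in a cascade this is a
degenerate design — the pair outputs are identically zero, the cross
block's activations are therefore zero, and every fusion parameter receives
exactly zero gradient, so training can never engage fusion. The zero-init
residual form keeps the warm start (an untrained block is the mean of its
inputs) while guaranteeing gradient flow; this is the standard zero-init
residual trick.

The loss is multilevel supervision: the mean squared error of each branch
volume and of the final fused volume against the ground truth, summed —
$\mathrm{Loss} = \mathrm{loss}_{LFM} + \mathrm{loss}_{FLFM} +
\mathrm{loss}_{LFM\_EPI} + \mathrm{loss}_{FLFM\_EPI} +
\mathrm{loss}_{Fuse}$ — so every branch is pushed toward a full volume
reconstruction (the EPI branches are supervised against the same 3D ground
truth). Training (`train_recon()`) is a seeded Adam loop (default learning
rate $10^{-4}$; the desk benchmark uses $2\times10^{-3}$, which converges
in the small-step budget); a non-finite loss aborts with the last finite
weights attached to the error condition. The network and its reverse-mode
tape are implemented in the package itself (im2col convolutions through
BLAS), with gradients validated against finite differences.

# Richardson–Lucy baseline and metrics

`rl_deconvolve()` runs the multiplicative RL update
$x \leftarrow x \cdot A^{T}(m/Ax)/A^{T}1$ with $A$ the package's own
forward projector for the chosen modality and $A^{T}$ its exact adjoint
(verified by inner-product tests); iterates are non-negative and the
I-divergence between measurement and reprojection is non-increasing on
noiseless data. PSNR uses $10\log_{10}(L^2/\mathrm{MSE})$ with
$L = \max(\mathrm{GT})$ per sample (the convention is recorded in the
report); SSIM uses the standard constants $K_1=0.01$, $K_2=0.03$ with a
7×7 Gaussian window (σ 1.5), computed per z-slice and averaged, with the
joint range of both inputs as $L$ so the measure is symmetric.

# The desk benchmark

The ablation study runs at a reduced scale chosen for a single-CPU budget:
5 sensor pixels per lenslet, a 6×6 lenslet patch (30×30×16 voxel volumes at
0.75 µm lateral pitch), depths −7.5 to 7.5 µm in 1 µm steps (the FLFM
preset's ~7 µm depth of field makes wider ranges uninformative for the FLFM
arm), 20 tubulin samples split 16:4, and the network at unified width 12,
U-Net depth 2/width 12, trained 28 epochs at learning rate
$2\times10^{-3}$ — the step count at which the four-branch model's test
metrics stop improving at this scale. Four branch sets are compared — LFM,
FLFM, LFM+FLFM, and all four — each as the median test PSNR over three
seeds, against the RL baseline at 50 iterations; RL is run on the FLFM
measurement (the classical reconstruction algorithm of that modality, and
the algorithm the full-scale study compares against), with the LFM-side RL
also reported by the acceptance script for context. The expectation
mirrored from the full-scale study is ordinal, not numeric: all-four ≥
dual ≥ best single, and the trained fusion above RL. Two caveats are worth
stating plainly: variant differences at this scale are a few tenths of a
dB against a seed scatter of similar size, so the ordinal comparison is a
coarse check rather than a sharp one; and on noiseless simulated light
fields with an exactly known forward model, RL applied to the
better-conditioned LFM measurement is a stronger reconstructor than any
network this package can afford to train on CPU — absolute desk-scale
numbers say nothing about the full-scale regime (public datasets,
GPU-scale training), which is out of scope here.

# Known limitations

- The LFM projector is shift-invariant at voxel scale; true LFM PSFs vary
  periodically within a lenslet. The approximation is shared with the VCD
  simulation lineage the design follows.
- The FLFM simulation runs at the sampling-limited effective NA of the
  reconstruction grid; absolute FLFM resolution is therefore tied to the
  chosen voxel pitch, and only the geometry (2-3-2 layout, relative
  disparities) is preserved at reduced scale.
- Complex depth weights make the FLFM sensor image's imaginary residue
  nonzero for general multi-plane volumes; it is logged, not hidden.
- The network is a small CPU-budget instantiation of the architecture; no
  claim is made that its absolute numbers transfer to GPU scale.
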