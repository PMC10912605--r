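---
title: "Methods: the lfcyto light-field flow cytometry digital twin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the lfcyto light-field flow cytometry digital twin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lfcyto` models a Fourier light-field imaging flow cytometer end to end:
the optical train, the flowing fluorescent sample, the camera, the
reconstruction pipeline and the population-level cytometry. This vignette
is the package's account of the science: the models and their assumptions,
the parameters that matter, what the synthetic data do and do not emulate,
and the numerical and design choices made where the problem left them
open.

## 1. Optical model

### Train and geometry

The instrument is an epi-fluorescence microscope (objective M_obj = 100×,
NA 1.45, oil immersion n = 1.515; tube lens) whose native image plane is
Fourier-transformed by a Fourier lens (f_FL = 275 mm). A hexagonal
microlens array (f_ML = 117 mm) sits in that Fourier plane, where the
relayed objective pupil is a disc of radius NA·f_FL/M_obj = 3.99 mm; the
camera (6.5 µm pixels) lies one microlens focal length behind. Each
lenslet whose center falls inside the pupil forms one *elemental*
perspective image; the effective magnification is M_obj·f_ML/f_FL = 42.5×,
giving a sample-referred pixel of 153 nm.

The tube lens focal length is taken as 200 mm (the manufacturer convention
for this objective line); it only enters through the pupil-relay ratio and
cancels out of every sample-referred quantity.

**MLA pitch.** The pitch is not independently fixed by the printed optics,
but the three-elemental-image geometry constrains it tightly: with the
lattice deep-hole centered on the axis, exactly three lenslet centers fall
inside the pupil only for pitch in (√3/2, √3)·R_pupil = (3.45, 6.91) mm.
The package default is 3.5 mm, the smallest comfortable value, which sets
the maximum elemental field of view at pitch/42.5 = 82 µm. Note a genuine
tension: a 70–80 µm field of view cannot be reconciled with the
exactly-three-lenslet condition at these focal lengths; `lfcyto` treats
70–80 µm as the width of the hydrodynamically focused sample core (which
the 82 µm elemental field comfortably contains) rather than as the
elemental-image spacing. The pitch is a configuration field, so a known
manufacturer value can override the default.

### Pupil, defocus, aberrations

Scalar diffraction is used throughout. The field in the MLA plane for a
point emitter at defocus z is the uniform pupil disc carrying the
angular-spectrum phase `exp(i 2π z √((n/λ)² − ρ²))`, with ρ the
sample-side spatial frequency (|ρ| ≤ NA/λ). A scalar model at NA 1.45 is a
deliberate, documented model error — vectorial effects and the
polarization-dependent apodization of a real 1.45-NA lens are not
represented — accepted because the instrument's own operating resolution
(400–600 nm after reconstruction) sits well above the vectorial limit.

The *hybrid* PSF interface separates the ideal model from calibration: an
`aberration_map` (Noll-indexed Zernike coefficients in waves RMS, or a
measured pupil phase map) multiplies the pupil. An all-zero map reproduces
the ideal PSF bit-for-bit, and the calibration recipe of any particular
instrument can be dropped in without touching the forward model.

### PSF construction and sampling

Per axial plane: pupil → ×MLA transmittance → Fresnel propagation f_ML to
the sensor → squared modulus → integration over camera pixel footprints
(computed by `oversample`-fold supersampling of the sensor grid followed
by binning; the default oversample of 2 implements area integration
rather than point sampling). The stack is normalized so the in-focus
plane sums to one; per-plane energy is then conserved across defocus
(Parseval), which the tests assert.

Two numerical points deserve note:

* **Merged quadratics.** The Fresnel kernel and the lenslet quadratic
  phase are individually badly sampled on desk-scale grids, but within
  each hexagonal Voronoi cell with center c their product is the exactly
  linear phase `exp(iπ(2r·c − c²)/(λ f_ML))` — the factor that steers that
  cell's light to its elemental image. `build_psf_stack` uses this
  analytic form; `mla_transmittance` still exposes the plain lenslet
  transmittance, and a test ties the two together.
* **Sampling guards.** The builder refuses grids where the pupil radius
  falls below 12 samples or the defocus phase at the pupil edge advances
  more than half a cycle per sample at the requested z-range. In practice
  this sets the minimum lateral crop per axial range: 160 px up to ±3.5
  µm, 200 px at ±4.5 µm, 256 px for the full ±5 µm, 101-plane stack.
  These are the problem sizes the tests and the acceptance script use.

Lenslets whose elemental image would miss the computed sensor crop are
masked (finite sensor). On small crops this removes the faint partial
images formed by second-ring lenslets clipped by the pupil corners —
exactly what a small sensor would do physically.

### Axial asymmetry is a feature

A widefield microscope's aberration-free PSF is mirror-symmetric in ±z. A
three-lens light-field PSF must not be: opposite defocus produces opposite
parallax of the elemental spots, and that sign is precisely what lets a
single snapshot distinguish above-focus from below-focus. The deep-hole
lenslet triangle is not inversion symmetric, so the ±z planes decorrelate
— the package tests assert this asymmetry, and verify the complementary
fact that an inversion-symmetric aperture (a single axis-centered lenslet,
i.e. plain Fourier imaging) recovers exact ±z point symmetry.

### Scaled twin for desk-scale work

`scaled_optical_config(scale)` multiplies f_FL, f_ML and the pitch by a
common factor while keeping NA, M_obj, camera pixel and axial sampling
fixed. This preserves the effective magnification, the sample-referred
pixel, the NA partition of the pupil among the three lenslets, and hence
every resolution-relevant quantity, while shrinking the elemental-image
spread so the three views fit on a 128–256 px crop. All shipped tests run
the scale-0.125 twin; the full-scale 1024×1024×101 configuration is the
same code path.

## 2. Phantom generator and camera model

### What it emulates

Sparse fluorescent objects in a 70–80 µm hydrodynamically focused core
(default; desk-scale runs confine the core to the scaled field), imaged at
200 fps with 100 µs strobes while flowing at ≈4.5 mm/s:

* **Bead mixtures** (0.2/1/2/4 µm) with fluorescence proportional to
  volume, placed uniformly in the core laterally and over the channel
  depth truncated to the PSF capture range axially — the positional
  distribution is the package's choice, since none is physically fixed.
* **Cell phantoms**: peroxisome puncta; a membrane shell around a solid
  nucleus (ground-truth N:C ratio `(d_nuc/d_cell)³`); two-color
  mitochondria/peroxisome cells; apoptotic cells whose k nuclear
  fragments are rescaled so the mean fragment-to-centroid distance equals
  the requested dispersion *exactly* (making parameter-recovery tests
  sharp), with total nuclear volume condensed by 0.7 when fragmented; and
  reporter cells whose positive population carries a 10-fold reporter
  density.

Rendering per strobe is quasi-static: objects are frozen at the strobe
timestamp and motion within the strobe is a line-kernel blur of length
v·τ (0.45 µm at defaults, about three sample pixels) applied along the
flow axis before the optical blur. Intra-strobe brightness integration
beyond that kernel is neglected, justified because v·τ is at the scale of
the lateral resolution. In two-color mode frames strictly alternate
channels and the second strobe of each pair fires t2 after the first, so
both colors see near-identical object positions.

Voxelization is partial-volume exact: boundary voxels are supersampled
(4³ sub-centers by default) so integrated density matches the analytic
component volume to better than 1%.

### Camera noise and photon budget

Expected photons per pixel s become counts
`Pois(s·p)/p + offset + N(0, σ)` with p the photon scale (p → ∞, σ = 0 is
the deterministic noise-free limit), offset 100 and σ = 2 counts by
default; 16-bit saturation is flagged, never wrapped. The default bead
brightness (2×10⁶ photons/µm³) is an order-of-magnitude choice calibrated
once so the *dimmest* study objects — 200 nm beads — land at peak SNR
≈ 10, inside the 5–15 band where blank-frame screening and denoising are
non-trivially exercised; larger beads are then bright, as in the real
instrument. Real per-cell photon budgets and sCMOS calibration maps are
not represented.

### What it does not emulate

No computational fluid dynamics (lateral position is a stochastic model,
not a flow solution), no cell deformation in flow, no photobleaching, no
spectral crosstalk, no sensor-specific fixed-pattern noise. Passing tests
therefore demonstrate the correctness of the optics, reconstruction and
statistics chain under controlled conditions — not robustness to every
artifact of real acquisitions.

## 3. Reconstruction pipeline

Stages run in the order screen → (pair) → rolling-ball background →
denoise → pad → Richardson–Lucy, each stage logged.

* **Screening** keeps frames whose background-subtracted peak exceeds a
  robust-z (default 8) or counts threshold; a maximum bright-region
  extent rejects debris. An optional *central-frame* gate keeps only
  frames whose bright-region centroid lies within a margin of the sensor
  center along the flow axis: objects near the field edge have partially
  vignetted elemental images (the spots clip at the sensor boundary while
  the object is still inside the field — intrinsic to the light-field
  geometry at any sensor size), and selecting the centered frame of each
  transit mirrors the screening/selection step of the real processing
  chain.
* **Rolling-ball background**: grayscale opening with a disc (erosion
  then dilation by shifted min/max; radius 15 px default, to be kept above
  the feature radius), subtracted and clipped at zero.
* **Denoising** is a stand-in behind a plug-in interface, since the
  instrument's own denoiser is prior published work: a generalized
  Anscombe transform brings Poisson-plus-read noise to unit variance, a
  local adaptive (Wiener-type) shrinkage pulls pixels toward their 7×7
  neighborhood mean in proportion to the local excess variance, and the
  transform is inverted. The pipeline contract — a PSNR gain of several
  dB at SNR ≈ 5–15, centroid displacement below half a pixel, near-identity
  on clean frames — is what downstream stages rely on, and is what the
  tests pin; any denoiser satisfying it can be plugged in.
* **Richardson–Lucy** uses the plain multiplicative update with the
  division guarded by `1e-12·max(frame)`, a uniform positive
  initialization, no regularization and no background term (background is
  handled upstream). The forward operator is the phantom module's
  renderer: per-plane 2D convolution with the matching hPSF plane summed
  over depth, evaluated at the linear-convolution size (5-smooth FFT
  lengths) and cropped back, with per-PSF OTF caching. Because each
  z0-normalized PSF plane sums to ≈1, total reconstructed flux tracks
  input flux; the tests assert agreement with an explicit dense-matrix
  implementation of the same update to 1e-6 relative, likelihood
  monotonicity, and 10% flux stability. Ties in argmax reporting resolve
  to the lowest index; the algorithm is deterministic.
* **Elemental images** are deconvolved jointly: the PSF kernel contains
  all three spots, so "elemental image selection" reduces to cropping the
  sensor region containing them. Iteration counts follow instrument
  practice: 30 for beads, 50–80 for biological samples.

## 4. Cytometry

Segmentation thresholds are Otsu (default) or fraction-of-max; the
parameter-light fraction mode suits beads, and for uniform solid objects
the 0.5 fraction is the unbiased half-maximum isosurface. Components are
3D 26-connected (voxel adjacency graph), filtered at 5 voxels minimum,
with optional border-object exclusion along the flow axis (partial
transits have truncated volume and intensity). Coordinates are physical:
voxel centers in µm with the optical axis at voxel `floor(n/2)+1`,
distances Euclidean.

Feature definitions: equivalent diameter (6V/π)^(1/3); ellipsoid radii
√(5·eigenvalues) of the intensity-weighted position covariance (the
scaling under which a uniform ball returns its true radius), sorted
Ra ≥ Rb ≥ Rc with planar objects flagged; FWHM by linear interpolation of
half-maximum crossings along axis profiles; micronuclei dispersion as the
mean distance of component centroids to their unweighted common centroid
(single component ⇔ distance 0 ⇔ intact nucleus).

Open questions were resolved as configuration-exposed choices:

* **Apoptosis call**: micronuclei count > 1 (overridable) — the
  morphology criterion is not otherwise pinned down.
* **"Enclosed within micronuclei"**: inside the 3D convex hull of the
  micronuclei voxel set. With no computational-geometry package
  available, hull membership is evaluated as an intersection of
  support-function half-spaces over 368 fixed directions (Fibonacci
  sphere plus axes) with half-voxel tolerance — a deterministic outer
  approximation whose error the tests bound against an analytic-hull
  configuration.
* **Reporter gating**: Otsu split of log10 total intensity by default,
  explicit threshold overridable.

Population structure uses a Gaussian mixture on (log10 volume, log10
intensity) with BIC selection over 1–6 components, additionally capped so
every candidate component keeps at least five records — small cohorts
otherwise admit degenerate single-point components. Diameter histograms
use Freedman–Diaconis bins with a least-squares Gaussian fit on bin
centers, falling back (flagged) to sample moments when the fit fails.

## 5. Study-scale versus desk-scale

The shipped tests exercise the scale-0.125 twin at 96–256 px crops with
9–101 axial planes, chosen so the whole suite (including the end-to-end
four-class bead run: 40 beads, 240 frames, 30 RL iterations each) and the
acceptance script each complete in minutes on one CPU. One further timing
choice follows from the scaling: the full instrument advances a transit
by roughly a quarter of its elemental field per frame (82 µm field,
22.5 µm per frame at 4.5 mm/s and 200 fps); the desk-scale bead runs keep
that ratio (19.6 µm field, 5 µm per frame), so every object is sampled
once near the field center, as in the full-scale geometry. The full-scale
configuration is the identical code path and remains available behind the
`--full-scale` CLI flag.

## 6. Known limitations

Scalar (not vectorial) diffraction at NA 1.45; a shift-invariant PSF
across the field (no per-lenslet registration offsets or field-dependent
aberrations); the denoiser is a contract-preserving stand-in, not the
published algorithm; hull membership is an outer approximation; no GPU
acceleration (the reference implementation's per-iteration timing is
hardware-specific and out of scope); and the phantom simplifications of
section 2. Within those bounds, every quantitative behavior claimed here
is computed by the test suite or the acceptance script, not asserted.
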