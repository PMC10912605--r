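# lfcyto — digital twin of a light-field imaging flow cytometer

Imaging flow cytometry records a fluorescence image of every cell that
passes through a microfluidic channel. Conventional instruments capture a
single 2D view, so volumes, organelle positions and nuclear morphology must
be inferred from projections. A Fourier light-field flow cytometer removes
that limitation: a microlens array (MLA) placed in a pupil (Fourier) plane
of an epi-fluorescence microscope splits the light into three *elemental*
perspective images on one camera frame, and a 3D volume is recovered
computationally from that single snapshot — stroboscopic laser excitation
freezing the motion of cells flowing at several mm/s.

`lfcyto` is a simulation and analysis package for this instrument class,
aimed at people building, calibrating or evaluating such systems: it
implements the wave-optics forward model, a synthetic phantom flow
simulator, the reconstruction pipeline and the downstream 3D single-cell
statistics, so the entire acquisition-to-cytometry chain can be exercised
and validated without hardware.

## The model

**Optics.** The objective (100×, NA 1.45 oil) and tube lens form an image
at the native image plane; a Fourier lens (f_FL = 275 mm) transforms it
onto a hexagonal MLA (f_ML = 117 mm), with the camera one microlens focal
length behind. The relayed objective pupil (radius NA·f_FL/M_obj) is tiled
by exactly three lenslets, so each frame carries three perspective views
and the effective magnification becomes

    M_eff = M_obj · f_ML / f_FL = 100 · 117/275 = 42.5×,

trading raw sampling for throughput while computational synthesis of the
three views restores near-diffraction-limited 3D resolution. For an
emitter at defocus z the field in the MLA plane is the pupil disc carrying
the angular-spectrum phase `exp(i·2π·z·sqrt((n/λ)² − ρ²))`; multiplying by
the lenslet transmittance and propagating to the sensor yields one plane
of the hybrid point-spread function (hPSF); repeating over a ±5 µm range
at 100 nm steps gives the 101-plane deconvolution kernel. A Zernike or
measured-phase aberration map can be folded into the pupil to calibrate
the ideal model against a real system.

**Forward model and reconstruction.** A fluorophore-density volume `x`
maps to a camera frame through per-plane 2D convolution with the matching
hPSF plane, summed over depth (`y = A x`), preceded by a motion-blur line
kernel of length v·τ (flow speed × strobe duration). Reconstruction is
plain Richardson–Lucy deconvolution,

    x ← x · Aᵀ( y / (A x) ),

30 iterations for microspheres, 50–80 for biological samples, after frame
screening, rolling-ball background subtraction, variance-stabilized
denoising and padding.

**Cytometry.** Reconstructed volumes are thresholded (Otsu or
fraction-of-max), labeled by 3D 26-connectivity, and summarized per object:
volume, equivalent diameter (6V/π)^(1/3), total intensity, ellipsoid radii
Ra ≥ Rb ≥ Rc from second moments, per-axis FWHM, nuclear-to-cytoplasmic
(N:C) volume ratio, micronuclei count/volume/dispersion, mitochondrial
enclosure, reporter gating, and Gaussian-mixture population counts.

## Worked example

A desk-scale run uses `scaled_optical_config()`, a geometrically scaled
twin of the instrument (same NA, magnification and pupil partition, so
resolution-relevant quantities are unchanged) on a small sensor crop:

```r
library(lfcyto)

config <- scaled_optical_config(scale = 0.125, sensor_shape = c(128, 128),
                                z_range = 2, z_step = 0.25)
effective_magnification(config)
#> [1] 42.54545

psf <- build_psf_stack(config, channel = 3)   # 680 nm emission
psf
#> <psf_stack> 128 x 128 x 17, voxel 152.8 x 152.8 x 250 nm, 680 nm emission

flow  <- flow_config(flow_speed = 1.0, core_width = 8)
beads <- make_bead_mixture(diameters = c(1, 2, 4), counts = c(3, 3, 3),
                           flow = flow, z_limit = 0.6, lateral_limit = 2,
                           seed = 7)
seq <- simulate_sequence(beads, psf, flow, noise_model(seed = 7),
                         n_frames = 40, seed = 7)
seq
#> <frame_sequence> 40 frames (24 occupied), single color, 128 x 128 px

res <- run_pipeline(seq, psf,
                    pipeline_config(rl_iterations = 30,
                                    central_margin_px = 16))
records <- do.call(rbind, lapply(res$volumes, function(v)
  segment_objects(v, method = "fraction", exclude_border = TRUE)$records))
records <- records[abs(records$centroid_x_um) <= 2.6, ]
round(records[, c("volume_um3", "eq_diameter_um", "total_intensity")], 2)
#>   volume_um3 eq_diameter_um total_intensity
#> 1       4.03           1.97         7091938
#> 3      25.03           3.63        49491999
#> 4       4.31           2.02         7244102
#> 5      24.99           3.63        50358281
#> 7       0.55           1.02          803091
#> 8       4.29           2.02         7186248
#> 9      26.36           3.69        51082569
```

The seven centered, unvignetted beads measure 1.0 / 2.0 / 3.6 µm — the
1 µm and 2 µm classes essentially exact, the 4 µm class slightly truncated
by the ±2 µm axial capture range of this small grid. Intensity scales with
volume, so on larger cohorts `population_count()` separates the classes as
distinct populations (the test suite runs a 40-bead, four-class version).

Cell-level measures work the same way; the two-channel
membrane-plus-nucleus phantom reproduces its generator ground truth:

```r
cell <- make_cell_phantom("membrane_nucleus",
                          params = list(d_cell = 7.99, d_nuc = 6.57))
cell$truth$nc_ratio
#> [1] 0.5559756
vols <- voxelize(cell, 0.15, c(61, 61, 61))
nuc <- segment_objects(vols[["2"]], method = "fraction", fraction = 0.5,
                       voxel = rep(0.15, 3))
nuc$records[, c("volume_um3", "eq_diameter_um")]
#>   volume_um3 eq_diameter_um
#> 1   147.8891       6.561139
```

— an N:C ratio of 0.556 (reported as 0.55 at two decimals) and a measured
nuclear diameter of 6.56 µm for the 6.57 µm phantom.

A command-line surface wraps the same functions
(`exec/lfc build-psf | simulate | reconstruct | analyze | report`); every
run writes its resolved configuration and a JSON provenance log next to
its outputs.

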