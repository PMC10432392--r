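---
title: "Simulating SPEN fMRI of the olfactory bulb: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating SPEN fMRI of the olfactory bulb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
acquisition physics, the activation model, the analysis chain, the
parameters that matter, and the choices made where the design was genuinely
open. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem being modeled

The mouse olfactory bulb (OB) is a paired, few-millimetre structure sitting
next to the nasal cavity and the eyes. Air/tissue susceptibility differences
make the static field inhomogeneous over the bulb; at ultrahigh field the
off-resonance reaches hundreds of Hz. Single-shot EPI encodes its
phase-encode axis with a per-pixel bandwidth of only `1/T_acq` (about 38 Hz
for the 26 ms acquisitions used here), so such fields displace and distort
the image by many pixels. Spatiotemporal encoding (SPEN) encodes the same
axis with a chirped inversion pulse instead, and its robustness to
off-resonance grows with the encoding strength. The package simulates both
families end to end — phantom, acquisition, reconstruction, block-design
BOLD experiment, and statistical analysis — at desk scale.

## Phantom

`make_ob_phantom()` builds two elliptical hemispheres with three concentric
layers: an outer glomerular rim, an external plexiform (EPL) ring, and a
granule-cell core. Each layer carries a relative proton density (0.9, 1.0,
0.8) and transverse relaxation values (T2 30/40/35 ms; T2' 40/50/50 ms),
with `1/T2* = 1/T2 + 1/T2'` by construction. These tissue values are
package defaults chosen to give plausible contrast and visible T2* effects
near field perturbers; relaxometry of the mouse OB at 15.2 T is not
established, so they are parameters, not measurements. The default grid is
96 x 70 pixels at 108 x 107 um — the 10.4 x 7.5 mm field of view of the
acquisition protocol. A small log-normal proton-density texture
(`texture_sd = 0.02`) prevents degenerate exactly-uniform regions.

Air interfaces are modeled by `air_interface_field()` as analytic 2D
dipoles: a disk of radius `a` contributes `peak * (a/r)^2 * cos(2*theta)`
outside itself, the in-plane field of a magnetized cylinder. An analytic
form (rather than a susceptibility FFT solver) gives every test a closed
oracle. `default_field()` places a large nasal cavity below the bulbs and
two smaller ocular perturbers beside them with a 1 kHz surface peak — a
modest value for air/tissue susceptibility at 15.2 T — producing
off-resonance of order 100-300 Hz over the bulbs, i.e. several EPI
pixel-bandwidths. This default is deliberately in the regime where EPI
visibly fails and SPEN does not, which is the regime the methodology
addresses.

## Acquisition model

The readout (x) axis is treated as an ideal Fourier axis; all inhomogeneity
acts on the low-bandwidth (y) axis. For every low-bandwidth sample `m` the
signal is a sum over object positions of encoding phase, off-resonance
evolution `exp(i 2 pi Df tau(y, t_m))`, T2 decay over the elapsed time, and
T2' decay over `|tau|`, with `tau` the sequence's net T2* evolution time:

- GE-EPI: `tau = t` from excitation; SE-EPI: `tau = t - TE`;
- SPEN: `tau = Delta + (t - t*(y))`, where `t*(y)` is the position's
  stationary (acquisition) moment, `Delta = 0` under full refocusing and
  4 ms under the partial-refocusing default.

SPEN's quadratic phase is parameterized by a `chirp_factor` (default 3):
the encoding time-bandwidth product is `chirp_factor * Ny`, so the residual
off-resonance displacement is the EPI shift divided by the chirp factor.
Two consequences follow and are treated as physics, not artifacts of the
implementation. First, the acquisition must sample `chirp_factor * Ny`
points along y (time-bandwidth-matched sampling); with exactly `Ny` samples
the encoding operator is rank-deficient. Second, full refocusing removes
inhomogeneous *broadening and attenuation* but not the (chirp-reduced) bulk
displacement: a constant off-resonance leaves the OB-mean magnitude
unchanged at the sub-percent level while displacing the profile by
`Df * T_acq / chirp_factor` pixels. The tests encode exactly this reading:
ROI-mean invariance below 2%, displacement bounded by the EPI shift over
the chirp factor.

Finite voxels are modeled to first order: the intra-voxel phase gradient
contributes a `sin(u)/u` envelope which is what localizes the stationary
point (a zero-width point source would emit a flat-magnitude signal). EPI
keeps the pure-DFT pixel model so that its reconstruction is an exact
inverse. Multi-shot segmentation, partial Fourier, odd/even-echo ghosting,
eddy currents and RF waveform effects are not modeled; coherent averaging
of `n_averages = 2` acquisitions is.

## Reconstruction

EPI images are inverse DFTs on the sequence grid (an undersized field of
view therefore wraps, as in a real acquisition). SPEN offers the
stationary-point magnitude readout (low resolution, no inversion) and
super-resolution (SR) Tikhonov inversion of the explicit encoding matrix,
`min_rho ||A rho - s||^2 + lambda ||D rho||^2` with `D = I` by default
(first differences available). The SR literature spans several algorithms;
regularized linear inversion was chosen because it is transparent, has an
exact least-squares oracle (`lambda = 0` matches the SVD pseudo-inverse to
machine precision in the tests), and exposes a single meaningful parameter.
`lambda` is expressed relative to the mean diagonal of `A^H A`; the working
default `1e-3` is small enough that noiseless recovery error is far below
the noise floor, large enough to keep the (condition number ~2) inversion
stable at SNR 30. `lambda = 0` on an ill-conditioned operator is refused
with the measured reciprocal condition number.

## BOLD experiment generator

The paradigm defaults are the study protocol: 10 events of 120 s air
followed by 26 s odor, 700 volumes every 2 s (TR 1 s x 2 averages), with a
10 s linear ramp to odor steady state. Note the arithmetic: the paradigm
spans 1460 s but the run lasts 1400 s, so the run truncates during the
final air block and the 10th odor onset (t = 1434 s) is never acquired;
epoch averaging therefore uses the 9 complete epochs. The generator keeps
this truncation rather than resolving the protocol's internal
inconsistency.

Activation lowers R2* in the active regions by up to `delta_r2star_hz`
(default 5 1/s), scaled by the HRF-convolved stimulus and a saturating Hill
concentration response (`c50 = 60 ppm`, exponent 1.5), placed so that
physiological concentrations (of order 100 ppm) sit in the saturating
regime. Aversive odors modulate the EPL ring, appetitive odors the lateral
glomerular sectors, neutral odors both; single-nostril occlusion zeroes the
ipsilateral hemisphere. A fraction `t2_fraction = 0.4` of the R2* change
acts on 1/T2 (microvascular, T2-like — the part a fully refocused
acquisition retains); the remainder acts on 1/T2' and is seen through each
sequence's `tau`. The exact microvascular fraction is not an established
number; 0.4 makes the FR response a substantial but smaller fraction of the
PR response, and the ordering GE-EPI >= PR >= FR is a tested invariant
regardless of its precise value. With these defaults the PR-SPEN
epoch-averaged peak exceeds 5% — the package's headline regime — and the
canonical double-gamma HRF (delay 6 s, undershoot 16 s, ratio 1/6) is used
unmodified, with a faster rodent preset available
(`hrf_params_rodent()`).

Nuisance defaults: multiplicative drift of 1% per run (linear plus one
low-frequency cosine) and motion spikes at a per-volume probability of
0.002 with 1-pixel amplitude. Motion is applied as an integer translation
of the reconstructed volume: translation commutes with the encoding up to
phase factors that magnitude reconstruction discards, so this is exact for
integer shifts and keeps 700-volume runs tractable. Respiratory/cardiac
noise, anesthesia effects, and mechanistic sex differences are not modeled
(amplitude scalings can emulate the latter). Noise is calibrated by
bisection on the measured image SNR (OB mean over background SD) with
common random numbers across evaluations; the reconstruction's own
sidelobe leakage sets an SNR ceiling that the calibration reports when a
target above it is requested.

## Analysis chain

The raw readout is the mask-mean time course; `percent_change()` baselines
each epoch on the final 30 s of the preceding air block and averages all
complete epochs, which cancels slow drift to first order. The first-level
GLM uses an HRF-convolved, max-normalized task regressor, second-order
time modulation (task times mean-centered linear and quadratic time, the
package's reading of "second-order time modulation" for non-stationary
response amplitude), a cosine drift basis with a 256 s cutoff (equivalent
to high-pass filtering under OLS but testable in closed form), and an
intercept. Pixels with numerically zero residual variance are flagged and
reported as infinite t rather than dividing rounding noise. Thresholding
defaults to uncorrected p < 0.001 (the convention of threshold-level
activation maps); Benjamini-Hochberg FDR and max-statistic permutation FWE
are provided because the protocol's correction method is ambiguous. An
optional analysis mask restricts suprathreshold pixels to the OB, the
standard brain-masked analysis; the lateralization checks use it, since SR
sidelobes just outside the bulb otherwise count against a hemisphere
fraction they have nothing to do with.

Second-level inference is pixelwise: pooled-variance two-sample t
(`df = nA + nB - 2`, signed), one-way ANOVA F (`k - 1, N - k`), and
SnPM-style permutation with the maximum-|t| null (labels permuted for two
groups, signs flipped for one sample; exhaustive enumeration whenever the
number of distinct relabelings does not exceed `n_perm`, e.g. all 20 splits
of 3 vs 3). The observed labeling always counts as one permutation, so the
smallest achievable FWE p is `1/n_perm` (or `2/2^n` under sign flipping,
where the global flip duplicates every maximum).

QC mirrors plain-inspection discard criteria: per-volume center-of-mass
displacement from the run median and detrended global-intensity deviations
(robust z > 4, with absolute floors of half a pixel and 1% intensity so
task-related micro-fluctuations of very clean runs are not "motion"),
fitted linear drift (|drift| > 3% per run discards), and split-half epoch
consistency (correlation < 0.3 discards when a response is required).
Thresholds are package defaults; the protocol reports discard outcomes,
not rules.

## What the generator does and does not show

Passing tests demonstrate that the pipeline recovers what it injects under
the stated noise, drift, motion and field models — e.g. that a 5% injected
response is read back within +/-20% at SNR 30, that plugged-nostril runs
lateralize, that the GLM's type-I error is calibrated on null data. They do
not show that real OB data behave this way: physiological noise structure,
anesthesia depth, ghosting, B1 inhomogeneity of a cryogenic surface coil
and real susceptibility geometry are all outside the model. The measured
ROI percent change also runs systematically below the injected voxel-level
change (reconstruction point-spread mixes active and inactive tissue at
region borders, more so under the default field), which is why recovery is
asserted at +/-20% rather than exactly.

## Problem sizes

The test suite exercises the full 96 x 70, 700-volume protocol once (the
headline amplitude check) and otherwise uses 48 x 36 grids with 5-event,
190-volume paradigms, where every claim under test is scale-free; the
statistical calibration tests run on pure-noise arrays of at least 10^4
pixel series. `scripts/acceptance.R` runs the full-size protocol for the
amplitude and SNR quantities.
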