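---
title: "Methods: myocardial ULM from beamforming to morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: myocardial ULM from beamforming to morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(srulm)
```

This vignette documents the models and numerical choices behind `srulm`:
what each stage assumes, which parameters matter, where the design was
genuinely open and how we decided, and what the synthetic tests do and do
not establish about clinical data.

## Acquisition model

A cardiac phased array (80 effective elements, 270 µm pitch, 21.6 mm
aperture) transmits diverging waves from a virtual source 21.6 mm behind
the array centre, giving a sector of
$2\,\mathrm{atan}(10.8/21.6) \approx 53^\circ$. Six steering angles in an
ascending-then-descending triangle ordering
$(-15^\circ,-3^\circ,9^\circ,15^\circ,3^\circ,-9^\circ)$ are each fired as a
three-pulse amplitude-modulation (AM) group (half, full, half amplitude),
so a 5,490 Hz PRF compounds to $5{,}490/(6\times3)=305$ frames/s. The PRF
is treated as a given instrument constant, not derived from the imaging
depth: real systems add dead time per transmit that we do not model.

Unit conventions: lengths in µm internally, times in s, frequencies in Hz;
constructors accept mm/MHz. Coordinates: array centre at the origin, depth
$z$ downward, lateral $x$ signed, polar angle from broadside. Sound speed
defaults to 1540 m/s (standard soft tissue); with it the half-wavelengths
at the two transmit frequencies are 320.8 µm (2.4 MHz) and 452.9 µm
(1.7 MHz).

## Contrast beamforming

**AM combination.** The contrast channel is `full − (half_a + half_b)` on
RF. In the simulator the half-amplitude transmits drive interleaved
element subgroups, so linear scatterers cancel exactly and any nonlinear
response (modelled as amplitude$^\gamma$, default $\gamma=1.5$) survives.
A centred 3-frame moving-average subtraction per steering angle removes
residual quasi-static tissue; edge frames use truncated windows so the
frame count is preserved (the alternative — dropping edge frames — would
complicate every downstream frame index for no accuracy gain).

**DAS and CV.** Pixels are reconstructed on a polar grid (67.8 µm × 0.5°)
by summing analytic channel signals at the two-way time of flight
(transmit path from the virtual source minus the source offset, plus the
receive path), linearly interpolated in time. B-mode uses plain DAS —
linear in echo amplitude, which the SVD tissue filter downstream needs.
The contrast image uses the coherence-to-variance weight
$w=\min(|\bar s|^2/\mathrm{var}(s),\,w_{\max})$ with the mean and the
complex sample variance pooled over all channels and angles and
$w_{\max}=1$. Two open points were settled as follows: the variance is
*pooled* (not per-angle-then-averaged), and the coherent sum is normalized
by the sample count before squaring. The normalization matters: with the
raw squared sum in the numerator the weight is $O(1)$ for incoherent noise
and, once clipped at $w_{\max}$, suppresses nothing; with the squared
*mean* the weight is an SNR-like quantity that is $\sim 1/N$ for noise and
$w_{\max}$ at full coherence, which is the behaviour the beamformer exists
to produce.

**Inter-angle bubble motion.** Compounding assumes bubbles hold still
across the six angles; at myocardial flow speeds they do not. The axial
velocity is estimated per pixel from the lag-1 complex autocorrelation
between repeats of the same steering angle in consecutive compounded
frames ($\Delta z = \arg(R)\,\lambda/4\pi$ per frame), and each angle
image is shifted along depth to the compounding-centre time. No separate
phase rotation is applied: shifting the *analytic* signal moves envelope
and carrier together. Numerically this demands a band-preserving
interpolator — the analytic carrier advances ≈1.33 rad per 67.8 µm cell,
where linear interpolation loses up to ~20% amplitude at half-cell shifts
(enough to erase the correction's benefit); we therefore shift with
Lanczos-3 windowed-sinc interpolation, whose response at the carrier
frequency is within a fraction of a percent of unity. The estimator
aliases above $\lambda f_{frame}/4$ (≈49 mm/s at 305 Hz and 2.4 MHz); the
ordinary ensemble/wall-filter details of production Doppler estimators are
out of scope, so the lag-1 estimator is a documented stand-in.

**Scan conversion** uses Catmull–Rom bicubic ("spline") sampling onto the
Cartesian grid (67.8 µm axial × 135.0 µm lateral), with the polar image
edge-replicated by two cells so sector-edge pixels do not blend with
zeros; pixels outside the sector are zero and flagged in a validity mask.

## Gating and motion correction

Gating uses the correlation of adjacent frames: systole starts are the
local minima of the trace, selected greedily below a threshold a quarter
of the way from the mean to the minimum, with a refractory window of 0.4
periods (period estimated from the trace's autocorrelation peak). The
diastole of each cycle is the *longest contiguous plateau* of frames whose
correlation exceeds the cycle's 75th percentile, clipped to at most 0.4 s
(keeping the tail nearest the next systole) and discarded below 0.2 s.
The plateau rule is our operationalization — only the 0.2–0.4 s bound and
the minimum-correlation definition of systole are fixed by the method; the
bound is treated as a constant clip range, not adapted per subject. A
stack with no detectable periodicity raises a typed condition carrying the
correlation trace for diagnosis.

Within a cycle, bubbles are removed from the B-mode by keeping the top 5%
of singular values of the space × time matrix. Note the rank implication:
on short synthetic stacks (tens of frames) 5% keeps only 1–2 components
and flattens genuine tissue motion; the fraction is a parameter, and the
full-cycle recovery test uses 0.5 for that reason, while the gated
pipeline applies it to low-motion diastole runs where 5% behaves as
intended. Frames are log-compressed over 50 dB (shared reference level)
and the reference frame is the one most similar to the cycle mean under a
Gaussian-windowed structural-similarity score with the conventional
constants ($C_1=(0.01L)^2$, $C_2=(0.03L)^2$, $\sigma=1.5$); ties break to
the lowest index.

Registration is two-stage. The affine stage minimizes the sum of squared
differences by Levenberg–Marquardt (`minpack.lm::nls.lm`), capped at 500
iterations with a parameter tolerance of $10^{-4}$. The B-spline stage
optimizes cubic-spline control displacements by steepest descent on
SSD/pixel plus a thin-plate (bending-energy) penalty, weight
$\lambda=0.01$ after normalizing the penalty per control and per squared
spacing so the two terms share a scale. The descent is preconditioned by
the Gauss–Newton diagonal (including the penalty's ~24/control diagonal —
without it, border controls with no data support blow up the step) with
per-control step clamping at half a control spacing, a backtracking line
search, a 500-iteration cap, and early stop when the cost improves by
less than 0.001% for 20 consecutive iterations. A coarse-to-fine Gaussian
smoothing pyramid (σ = 6, 3, 0 px) gives the SSD a basin wider than the
texture correlation length; warm-started neighbour frames skip to a short
(σ = 3, 0) schedule. Control spacing defaults to 32 px (16 px for the
denser ex vivo setting). Transforms map reference coordinates into each
frame (the resampling direction); localization coordinates go the other
way via fixed-point inversion of the transform.

Across cycles, cycle-averaged contrast images (log-compressed) are aligned
to the first cycle by a rigid transform (rotation about the image centre +
translation), again by Levenberg–Marquardt. The `no_gating` pathway —
for ex vivo preparations with no breathing or cardiac twisting — skips
gating and the inter-cycle stage and registers all frames directly.
Out-of-plane motion is not correctable from 2-D data and is out of scope.

## Localization

Pixels below an adaptive threshold or a noise floor are zeroed. The
adaptive component is the local mean over a square window of 1/8 the
smaller image dimension. The noise floor is estimated per 16-row depth
block as median + $k\cdot$MAD of the sub-75th-percentile intensities
(excluding bubbles from the estimate); $k=7$ places the floor near
2.6 standard deviations for envelope-like (half-normal) noise, i.e. about
a 1% per-pixel false-positive rate. Surviving pixels form 8-connected
patches.

The image is split into 5 (depth) × 5 (lateral) regions; each region's PSF
is the peak-aligned average of the 10 roundest, most isolated
single-bubble patches found there, normalized to unit peak. Selection
uses roundness $4\pi A/P^2 \ge 0.6$ — with the taxicab edge count
corrected by $\pi/4$ toward the Euclidean boundary length, without which a
digitized ellipse of modest 2:1 aspect already fails the criterion — and
isolation of at least 3 patch diagonals. Regions with too few candidates
borrow the nearest populated region's PSF; if no region qualifies the
analytic depth-dependent Gaussian model is used with a warning.

Each patch is matched against its region PSF by windowed, zero-padded
normalized cross-correlation; every 8-connected NCC region above 0.5
yields one localization (so one patch can produce several bubbles): the
intensity-weighted centroid of the patch pixels under that NCC region
*and* the threshold mask — sub-threshold skirt pixels carry mostly noise
and would inflate the centroid variance — snapped to the 13.5 µm grid.
The bubble intensity is the sum of the cropped pixel values. NCC is
scale-invariant, so doubling the image intensity moves no coordinate.
Closely overlapping bubbles beyond NCC multi-peak handling are not
separated; that is an accepted limitation of the smoothing the NCC
performs.

## Tracking

Active tracks carry a constant-velocity Kalman state
$(x, z, v_x, v_z)$ with discrete white-acceleration process noise $Q(q)$
and measurement noise fixed at the localization grid's quantization
variance ($13.5^2/12$ µm² per axis). The pairing cost of a track and a
candidate localization is the intensity difference normalized by the
stronger intensity, divided by the bivariate Gaussian innovation density
(floored at $10^{-12}$ — the ratio is undefined at zero probability).
Candidates outside a 150 mm/s search window (applied to the raw
displacement) are forbidden. The assignment, including dummy partners for
appearing/disappearing bubbles, is solved to the exact global optimum by a
shortest-augmenting-path Hungarian algorithm; the dummy cost limit
defaults to the cost of a median intensity mismatch at the window edge and
is configurable, since "over a limit" is otherwise unquantified. New
tracks start with a fuzzy-initialized velocity: a membership-weighted
average of the velocities implied by previous-frame localizations in the
window, memberships decaying with distance (scale = half window) and
relative intensity mismatch (scale 0.5); with no neighbour the initial
velocity is zero. $q$ is estimated from the data as
$\mathrm{var}(\Delta v)/\Delta t$ over a nearest-neighbour warm-up pass,
falling back to a documented default when fewer than eight velocity
increments exist. Tracks are linked over consecutive frames only (no gap
closing), and tracks observed in fewer than 4 frames are discarded as low
confidence. The exact fuzzy-membership and noise-estimation formulas of
the original framework are not public; the implementations here honour
their stated intent and are validated behaviourally (velocity inside the
candidate hull; $q$ recovered within 20% on generative data; crossing
trajectories resolved strictly better than nearest-neighbour linking).

## Maps and quantification

Trajectories are rasterized as straight segments on the 13.5 µm grid with
supercover traversal (every cell a segment passes through — avoiding
speed-dependent gaps), then widened by a 2-D Gaussian of FWHM $\lambda/4$
(160.4 µm at 2.4 MHz); the unwidened accumulation is also kept. Speed and
direction maps accumulate per-step speeds/velocities on trajectory cells,
smooth numerator and denominator with a disk of diameter equal to the
Gaussian FWHM, and take the ratio where density is positive — smoothing
the ratio's parts rather than the ratio keeps the kernel size from biasing
the velocity estimate. Direction convention: 0° = +x, 90° = towards the
probe; cells whose averaged vector cancels are masked as undefined. HSV
composition maps speed or direction to hue and normalized density to
value. The animation advects a marker along each track at its estimated
speed, warm colours moving towards the probe.

FRC splits whole tracks (never within a track) into random halves,
renders both identically (raw accumulation by default — widening would
impose the kernel's own correlation length on both halves; a widened
variant is available), and finds the first crossing of the ring
correlation below the ½-bit threshold
$T(n) = (0.2071 + 1.9102/\sqrt n)/(1.2071 + 0.9102/\sqrt n)$ with
one-frequency-sample rings and per-ring counts $n$; the crossing is
linearly interpolated and its inverse frequency is the resolution. No
crossing is flagged and reported at the grid Nyquist wavelength.

Morphometry binarizes the density map at any positive value, skeletonizes
by Zhang–Suen thinning, and reads the local diameter as
$(2d_{px}-1)\times 13.5$ µm from the Euclidean distance transform at each
skeleton pixel (the $-1$ removes the half-pixel-on-each-side bias of
pixel-centre distances); the distribution is length-weighted with 50 µm
bins capped at 1,500 µm. Speed statistics histogram the non-zero speed
map pixels in 5 mm/s bins and fit a lognormal by the closed-form MLE.
Cross-sections sample a line with perpendicular averaging over a 0.5 mm
band, normalize to the maximum, and report peaks (local maxima above 0.3
of the maximum, separated by at least 2 cells), interpolated FWHMs and
separations.

## The simulator: what it does and does not emulate

The generator produces vessel trees (parallel pairs, Murray-scaled binary
trees, rings), Poisson bubble arrivals advected along centrelines at
lognormal speeds (default mean 30 mm/s), per-bubble lognormal intensities,
and frames rendered by splatting each bubble with the local depth-dependent
Gaussian PSF. The lateral FWHM anchors (1,700 µm at 30 mm to 5,850 µm at
120 mm) follow the contrast-mode beam of a 2 MHz-class phased array; the
axial FWHM (500–800 µm) corresponds to a ~2-cycle pulse envelope, a value
we chose since axial beam tables are rarely printed. SNR is defined as
peak signal amplitude over noise standard deviation, in dB, with additive
white Gaussian noise; stack defaults are 30 dB and a bubble density sparse
enough for the slow-bolus/infusion regime the localization method assumes.
Tissue motion is a periodic field — affine (translation, rotation, scale)
plus a smooth non-rigid component on a coarse control grid — under a
$\sin^2$ systolic envelope over 35% of the cycle, normalized so the peak
in-plane displacement equals the configured amplitude (default 1.5 mm,
inside the 1.4–1.7 mm range observed in vivo); diastole is exactly
motion-free in the model, which real hearts are not. RF simulation is
single-scattering, narrowband Gaussian-pulse superposition at analytic
delays with no attenuation, aberration, element directivity or multiple
scattering; it is desk-scale (≲100 scatterers) and exists to exercise
delay arithmetic, AM cancellation and compounding, not to imitate tissue
speckle. Consequently, passing tests demonstrate the correctness of the
algorithms under their own assumptions — they do not establish robustness
to chamber side lobes, nonlinear propagation breakthrough, out-of-plane
motion, or bubble-size-dependent echoes, none of which the generator
models.

## Problem sizes and determinism

Test and acceptance runs use desk-scale versions of the study conditions,
as our own choice of test design: point-precision measurement uses 100
isolated targets per depth at 30/70/110 mm and 40 dB SNR; motion-recovery
uses a 15 × 15 mm field at 135 µm cells over one 0.8 s cycle sampled at
30 Hz; tracking suites use ≲60 concurrent bubbles; the end-to-end pipeline
smoke test compounds at 40 Hz for 0.5 s. Every stochastic operation takes
an explicit seed, all seeded outputs are bit-reproducible, and the run
manifest (config hash, package version, seeds, stage outputs) suffices to
reproduce a pipeline run exactly.

## Known limitations

* 2-D only: no elevation focusing, no out-of-plane motion correction, no
  3-D matrix-array pathway.
* The Doppler inter-angle estimator aliases above
  $\lambda f_{frame}/4$; faster axial flows are neither estimated nor
  corrected.
* The CV beamformer's weight normalization and the pooled variance are
  this package's reading of a briefly specified method.
* No gap closing in tracking; a single missed detection splits a track,
  and the 4-frame filter then discards short fragments.
* FRC on sparsely saturated or quasi-one-dimensional vasculature reflects
  saturation as much as localization precision; its seed-to-seed spread is
  part of the reported result, not noise to be averaged away.
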