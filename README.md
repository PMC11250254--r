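# srulm — super-resolution ultrasound localization microscopy for the moving heart

Imaging myocardial microvasculature in vivo is hard: the vessels are
hundreds of micrometres across — below the diffraction limit of a 2 MHz
cardiac probe — and the heart never stops moving. Ultrasound localization
microscopy (ULM) breaks the diffraction limit by detecting individual
microbubble contrast agents frame by frame, localizing each one to
micrometre precision, and accumulating their tracks over thousands of
frames into super-resolved maps of vascular structure and flow.

`srulm` implements a complete transthoracic myocardial ULM processing
pipeline for diverging-wave phased-array acquisitions, aimed at researchers
in super-resolution ultrasound and quantitative echocardiography:

* **Contrast beamforming** — three-pulse amplitude-modulation (half, full,
  half) echo combination `full − (half_a + half_b)` that cancels linear
  tissue echoes; temporal moving-average subtraction of residual tissue;
  delay-and-sum (DAS) beamforming of analytic channel signals on a polar
  grid; a coherence-to-variance (CV) beamformer whose per-pixel weight
  `w = |mean(s)|² / var(s)` (clipped at 1) suppresses incoherent noise and
  side lobes; Doppler-based correction of bubble motion *between* steering
  angles; spline scan conversion.
* **Cardiac gating and two-level motion correction** — systole detection
  from the adjacent-frame correlation trace; diastole selection (0.2–0.4 s
  plateaus); SVD tissue extraction (top 5% singular values); two-stage
  affine (Levenberg–Marquardt) + cubic B-spline non-rigid (steepest
  descent, SSD + thin-plate penalty) registration within each cycle, and
  rigid registration of cycle-averaged contrast images across cycles.
* **Localization** — adaptive thresholding with a depth-dependent noise
  floor, 8-connected patch extraction, a 5 × 5 spatially varying PSF bank
  averaged from isolated bubbles, normalized cross-correlation (threshold
  0.5) and intensity-weighted centroiding onto a 13.5 µm grid.
* **Feature-motion-model tracking** — constant-velocity Kalman prediction;
  pairing cost = (relative intensity difference) / (motion-model
  likelihood); globally optimal graph assignment with dummy nodes
  (Hungarian algorithm); a 150 mm/s search window; fuzzy velocity
  initialization of new tracks; data-driven process-noise estimation;
  removal of tracks shorter than 4 frames.
* **Maps and quantification** — density / speed / direction maps on the
  13.5 µm grid (Gaussian track width = λ/4; disk-smoothed ratio estimators
  for speed and direction); Fourier ring correlation (FRC) resolution with
  the ½-bit information threshold over random track-split halves; vessel
  morphometry by skeleton + distance transform (50 µm bins, 1,500 µm cap);
  lognormal flow-speed statistics; cross-section profile analysis.
* **A ground-truthed simulator** — vessel-tree phantoms, Poisson bubble
  transits with lognormal speeds, periodic cardiac tissue deformation
  (calibrated peak, default 1.5 mm), depth-dependent PSFs
  (lateral FWHM 1.7 mm at 30 mm depth to 5.85 mm at 120 mm), configurable
  SNR, and desk-scale RF channel simulation for the beamforming chain —
  so every stage is testable without clinical data.

## Worked example

```r
library(srulm)

# Two microvessels 300 um apart at 70 mm depth, imaged for 6 s at 305 Hz
tree <- vessel_phantom("parallel_pair", centre_mm = c(0, 70),
                       separation_um = 300, length_mm = 5,
                       diameter_um = 60, speed_mm_s = 30)
gt <- simulate_transit(tree, duration_s = 6, frame_rate = 305,
                       bubble_rate = 30,
                       speed_law = list(dist = "constant"), seed = 6)

# Idealized localizations (ground truth snapped to the 13.5 um grid)
locs <- data.frame(frame = gt$frame,
                   x_um = round(gt$x_um / 13.5) * 13.5,
                   z_um = round(gt$z_um / 13.5) * 13.5,
                   intensity = gt$intensity)
tracks <- track_localizations(locs, frame_rate = 305)

grid <- sr_grid_for_tracks(tracks)
maps <- render_maps(tracks, grid, geom = acq_geometry(f_tx_mhz = 2.4))
cs <- cross_section(maps$density, grid, c(0, 69000), c(0, 71000),
                    avg_width_um = 500)
frc <- frc_resolution(tracks, grid, seed = 1)
```

Output:

```
tracked 180 bubbles over 1830 frames
vessel separation from the density profile: 297.0 um
mean flow speed on the map: 30.1 mm/s (truth: 30)
FRC resolution (half-bit threshold): 628 um
```

The cross-section of the density map across the vessel pair shows two
ridges 297 µm apart (truth: 300 µm; the super-resolved grid quantizes to
13.5 µm) with a deep dip between them — the pair is resolved at roughly a
quarter of the 1.3 mm diffraction-limited beamwidth at this depth. The
speed map reproduces the simulated 30 mm/s flow. The FRC number is
conservative on a phantom of two short straight lines: FRC measures global
spectral consistency between half-datasets, which for sparse, almost
one-dimensional scenes is dominated by the low saturation rather than the
localization precision (the same caveat applies to sparsely saturated
clinical maps).

The full pipeline (simulate → gate → motion-correct → localize → track →
maps → quantify) runs from a single config:

```r
cfg <- read_pipeline_config(system.file("extdata", "default_config.yaml",
                                        package = "srulm"))
run_pipeline(cfg, out_dir = "my_run")        # ex vivo path: no_gating = TRUE
```

and from the shell via the thin CLI at `inst/cli/srulm`
(subcommands `run`, `simulate`, `ulm`, `maps`, `quantify`).

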