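# leadtrack

Tracking an implantable cardioverter-defibrillator (ICD) lead tip through
the kilovoltage projections of a cone-beam CT (CBCT) scan, for motion
management in stereotactic arrhythmia radioablation (STAR).

During STAR, the distal ICD electrode anchored in the right ventricle is a
natural radio-opaque surrogate for the cardiorespiratory motion of the
target. Each CBCT projection, however, only resolves two of the three
spatial coordinates: the component along the X-ray beam is lost. This
package implements the full measurement chain that turns a rotational
projection sequence into a 3D motion trajectory:

1. **2D segmentation** — the planning 3D tip coordinate is forward-projected
   onto the imager at each gantry angle; a 70 × 70 pixel search region is
   extracted around it; a bank of cylinder-projection templates (in-plane
   rotations at 5° steps — 8 for breath-hold scans, 20 for free-breathing,
   abdominal-compression and high-frequency-ventilation scans — at three
   scales) is matched by normalized cross-correlation (NCC), and the
   intensity-weighted centroid of the best match is the segmented position.
2. **Online outlier filtering** — segmentations whose superior–inferior
   coordinate deviates more than 25 pixels (20 mm at the default 0.8 mm
   pixel spacing) from an iteratively updated running mean are rejected.
3. **2D → 3D estimation** — a single 3D Gaussian over target position,
   `p ~ N(mu, Sigma)`, is fitted by maximum likelihood to all accepted 2D
   observations. Writing `a(theta)`, `b`, `c(theta)` for the resolved
   lateral, resolved vertical and unresolved depth directions at gantry
   angle `theta`, each observation `(u, v)` has marginal
   `N((a'mu, b'mu), H Sigma H' + sigma_m^2 I)` with `H = [a'; b']`. The
   per-frame depth is then the conditional mean
   `w = c'mu + k' C^{-1} ((u, v) - m_uv)`, with `k = H Sigma c`, giving the
   3D estimate `u a + v b + w c`.
4. **Evaluation** — 2D success fractions (< 2 mm in both imager axes),
   motion displacement (absolute deviation from the scan-mean position,
   5th–95th percentile summaries), all-axes 3D error fractions (< 2 mm),
   and an exact Wilcoxon signed-rank comparison of filtered vs raw errors.

Because clinical CBCT projections of this kind are not publicly available,
the package ships a first-class **digital phantom**: a cylinder-shaped lead
tip moving with combined respiratory (cos^4 waveform with end-exhale dwell,
or mode-specific variants) and cardiac (sinusoidal) motion, rendered by
analytic chord-length projection with configurable contrast, noise and
wire-like clutter, together with exact 2D/3D ground truth.

Intended users are medical-physics researchers prototyping intrafraction
motion monitoring, and anyone needing a reproducible test bed for
fiducial-tracking and 2D-to-3D estimation algorithms.

## Worked example

Simulate a free-breathing scan of 120 projections (respiratory amplitude
(2, 8, 3) mm LR/SI/AP, cardiac (1, 1.5, 1) mm at 70 bpm, moderate noise)
and run the whole pipeline:

```r
library(leadtrack)

dir  <- file.path(tempdir(), "demo")
lead <- lead_tip_model(planning_position = c(3, -2, 5))
generate_dataset(dir, projection_meta(120), motion_model("FB"),
                 lead, beam_geometry(), noise_sd = 0.2, seed = 42)

report <- run_pipeline(dir, mode = "FB", verbose = FALSE)
report
#> <tracking_report> mode FB, 120 projections
#>   2D success 100.0% (filtered 100.0%), rejection 0.0%
#>   3D errors < 2 mm: 100.0% filtered, 100.0% raw
```

Every segmented centroid lands within 2 mm of the ground-truth projection
(both axes), nothing is rejected on this clean scan, and every 3D estimate
is within 2 mm of the reference trajectory on all three axes. The fitted
position distribution:

```r
report$fits$filtered
#> <gauss_pdf_fit> 3D target-position Gaussian (maximum likelihood)
#>   mu    (3.74, 1.00, 6.12) mm (lr, si, ap)
#>   sigma (0.01, 3.05, 1.39) mm (marginal sd)
#>   NLL 474.129 over 120 observations (arc 357 deg)
```

The mean matches the simulated scan-mean position (the planning position
(3, −2, 5) mm plus the mean respiratory and cardiac offset, (3.75, 1.00,
6.13) mm). The SI and AP marginal spreads reflect the motion amplitudes;
the LR spread collapses because the phantom's axes move coherently and the
fitted covariance captures that motion through its correlations.
Displacement of the reference trajectory, summarized as the paper-style
5th/50th/95th percentiles of |position − mean| per axis:

```r
report$metrics$displacement
#> # A tibble: 3 × 4
#>   axis    p5_mm median_mm p95_mm
#> 1 lr    0.00612     0.196   1.24
#> 2 si    0.300       2.30    5.01
#> 3 ap    0.188       0.831   2.83
```

`plot_trajectory(report$trajectories)`, `plot_segmentation_scores()` and
`autoplot()` on a fit give the corresponding ggplot views, and `tidy()` /
`glance()` return the fit as tibbles.

A thin command-line front end with `simulate`, `segment`, `track`,
`evaluate` and `run` subcommands is installed under `inst/cli/leadtrack`.

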