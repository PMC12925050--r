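---
title: "Methods: lead-tip tracking in rotational kV projections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lead-tip tracking in rotational kV projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(leadtrack)
```

## The problem

Stereotactic arrhythmia radioablation irradiates a ventricular tachycardia
substrate in one or a few fractions, so intrafraction cardiorespiratory
motion of the heart matters directly. Patients carry an implantable
cardioverter-defibrillator whose distal lead electrode, anchored in the
right ventricle, is radio-opaque and moves with the target. During the
pre-treatment cone-beam CT, the gantry-mounted kV source–imager pair
rotates around the patient and acquires a few hundred projections; each
projection shows the lead tip in two dimensions only, because the position
component along the X-ray beam is unresolved. `leadtrack` reconstructs the
tip's 3D trajectory from this rotational 2D sequence, and quantifies how
well it does so.

## Geometry and conventions

Room coordinates are right-handed (LR, SI, AP) in mm with the origin at
isocenter. The gantry rotates about the SI axis; at gantry angle 0 the
source is anterior. The beam frame at angle $\theta$ is

$$a = (\cos\theta,\, 0,\, \sin\theta), \quad b = (0, 1, 0), \quad
  c = (-\sin\theta,\, 0,\, \cos\theta),$$

with $a$ the resolved lateral (imager $u$) direction, $b$ the resolved
vertical (imager $v$, always SI — true for a panel that rotates with the
source), and $c$ the unresolved depth toward the source. A point $p$
projects to $(a \cdot p,\, b \cdot p) \cdot \mathrm{sdd}/(\mathrm{sad} -
c \cdot p)$ on the imager. Back-projection at an assumed depth (default 0,
the nominal magnification) rescales imager mm to isocenter-scale resolved
coordinates.

Defaults are a standard C-arm linac geometry — SAD 1000 mm, SDD 1500 mm —
and a 512 × 384 panel at 0.8 mm/pixel. No vendor publishes these choices
with the tracking method itself; they are package defaults, chosen so that
25 pixels correspond to exactly 20 mm, the equivalence in which the
SI-filter threshold is quoted. Whether that equivalence was originally
meant at the imager plane or the isocenter plane is ambiguous; we apply
the filter in pixels on the imager, which makes the two readings coincide
by construction. Couch/collimator rotations, panel offsets and flex are
out of scope.

## The digital phantom

Clinical projection data of this kind are not redistributable, so the
generator is a first-class, tested module. The trajectory is closed-form:

$$p(t) = p_0 + \beta + \delta t + A_r \odot r(t) + A_c \odot
  \sin(2\pi f_c t + \varphi_c),$$

with planning position $p_0$, baseline offset $\beta$, drift $\delta$, and
per-axis respiratory and cardiac amplitudes. The respiratory waveform
$r(t)$ is $\cos^4$ for free breathing and abdominal compression — the
standard radiotherapy motion model, dwelling at end-exhale — and a slow
(DIBH residual) or fast (high-frequency ventilation) sinusoid otherwise.
Cardiac motion is a single sinusoid; real cardiac motion is not
sinusoidal, which is acceptable for a surrogate phantom. One phase is
shared across axes: a lead tip moves coherently, which makes the three
axes strongly correlated, as in real data.

Mode defaults were fixed once, at values typical of the radiotherapy
motion literature: FB (2, 8, 3) mm at 4 s; AC (1, 4, 1.5) mm at 4 s; DIBH
residual (0.5, 1, 0.5) mm at 10 s; HFV (0.3, 1, 0.5) mm at 240 cycles/min;
cardiac (1, 1.5, 1) mm at 70 bpm everywhere. A scan is 368 projections
(the reported median per scan) uniformly over 360° in 60 s.

The lead tip is a solid cylinder (default radius 1 mm, length 8 mm,
configurable — electrode dimensions vary by model) rendered by analytic
chord length: each pixel receives `contrast ×` the length of its ray's
intersection with the cylinder, rays taken parallel to the beam axis
within the footprint and drawn at the nominal magnification. Divergence
across a ~10 mm object at SAD 1000 mm changes the local magnification by
under 1%, so the parallel-beam approximation is harmless. White Gaussian
noise (default sd 0.2 against a maximum lead signal of ~2–8) and optional
clutter — rectangular wire/lead-like segments, rendered before the noise —
complete the frame. Stacks are written as 16-bit multi-frame TIFF with the
affine quantization recorded in a JSON sidecar.

What the phantom does *not* emulate: anatomical background (ribs,
diaphragm), scatter and beam hardening, ECG-shaped cardiac waveforms,
panel lag. Passing tests therefore demonstrate correctness of the
algorithmic chain under controlled conditions, not clinical performance on
patient images.

## 2D segmentation

For each projection the planning tip is forward-projected and a fixed
70 × 70 pixel search region extracted around it, shifted (never padded) to
stay inside the panel so NCC statistics are never computed over synthetic
values; the crop origin maps region coordinates back to the imager
exactly.

The template bank projects the cylinder as seen at the current gantry
angle with the same renderer as the phantom, noiseless. In-plane rotations
at consecutive 5° offsets are placed symmetrically about the planning
orientation — 8 for DIBH, 20 for FB/AC/HFV — each at isotropic scales 0.9,
1.0 and 1.1. The symmetric centering and the scale set are package
choices: the rotation counts and 5° step are given, their range is not,
and "size" optimization is not enumerated anywhere. Each rotation is
rendered analytically (the projected axis is rotated in the imager plane
before projection) on one shared canvas sized to the largest footprint
plus a 2-pixel margin. Rendering each rotation avoids the interpolation
blur of rotating a sampled image, and the shared canvas lets one im2col
patch matrix per frame serve the entire bank, which is what makes
exhaustive NCC affordable (a full 368-projection scan segments in ~25 s).

NCC is the exact Pearson correlation between the template and the covered
patch over the template footprint, at every valid integer placement;
constant patches score 0. There is no subpixel refinement — reported
errors are at pixel scale and beyond. The global argmax over placements,
rotations and scales wins; exact ties break to the smallest absolute
rotation offset (negative first), then the scale closest to 1, then the
smallest row-major placement index, so matching is fully deterministic.
The reported position is the intensity-weighted centroid of the winning
template's above-threshold footprint placed at the winning position — not
the placement center, which differs for asymmetric footprints. Frames
where a human would have excluded an invisible tip are instead always
emitted with their score; an optional minimum-NCC visibility threshold
(off by default) flags them.

## SI outlier filtering

Gross mismatches (typically clutter hits) jump in the superior–inferior
coordinate. The online filter keeps a running mean of accepted SI pixel
values; after a warm-up of 10 unconditionally accepted segmentations
(the initialization is not specified anywhere, so it is exposed as a
parameter), a segmentation is rejected when it deviates from the mean by
more than 25 px (20 mm). Only accepted values update the mean — "rejected"
would otherwise poison the statistic — and rejected rows are flagged,
never altered. Only SI is filtered: the lateral coordinate mixes LR and AP
as the gantry rotates, so a fixed lateral threshold would reject genuine
rotation-induced excursions. The threshold is a global default with a
per-scan override.

## Maximum-likelihood 3D Gaussian and conditioning

All accepted observations of a scan are pooled into one static Gaussian
$p \sim N(\mu, \Sigma)$ over target position (one model per scan; no
time-varying density). With $H_\theta = [a'; b']$, an observation is
modeled as $y = H_\theta\, p + \varepsilon$,
$\varepsilon \sim N(0, \sigma_m^2 I)$, giving the marginal likelihood

$$y_i \sim N\!\left(H_{\theta_i} \mu,\;
  H_{\theta_i} \Sigma H_{\theta_i}' + \sigma_m^2 I\right).$$

The 9 parameters (3 mean, 6 covariance) are fitted by BFGS on the exact
negative log-likelihood. $\Sigma = LL' + 10^{-4}\,\mathrm{mm^2}\, I$ with
$L$ lower-triangular and log-parameterized diagonal: positive
semidefiniteness holds by construction, and the $10^{-4}$ mm² floor keeps
degenerate (static-target) fits well-posed. Initialization is data-driven
($\mu_{SI}$ from the mean vertical coordinate, $\mu_{LR}, \mu_{AP}$ by
least squares of $u = \cos\theta\,\mu_{LR} + \sin\theta\,\mu_{AP}$,
$\Sigma = 25\,\mathrm{mm^2} I$). The measurement variance
$\sigma_m^2 = 0.25$ mm² (about half a pixel at isocenter scale) is a fixed
hyperparameter, not fitted: it regularizes the projected covariance and
sets the noise floor the fit attributes to segmentation error. Fits from
a single angle are refused (depth unidentifiable); arcs under 30° warn.
Cross-covariances can be frozen at zero (`fix_offdiag`) for the restricted
6-parameter variant.

One point deserves emphasis: with coherent (rank-deficient) motion the
likelihood is maximized by a correspondingly degenerate $\Sigma$ — e.g. an
LR marginal near the floor with the LR–SI covariance carrying the motion.
This is correct behavior, not a failure: the conditional depth estimate
uses exactly those correlations, which is why a strongly correlated SI
observation pins down an otherwise unresolved LR/AP excursion.

Each frame's depth is the Gaussian conditional mean
$w = c'\mu + k' C^{-1}(y - H\mu)$ with $k = H \Sigma c$ and $C$ the
projected covariance including $\sigma_m^2$; the 3D estimate is
$u\,a + v\,b + w\,c$, leaving the resolved coordinates untouched. One
optional refinement pass (default on) rescales the raw imager measurement
with the magnification at the estimated depth $(\mathrm{sad} -
w)/\mathrm{sdd}$ and re-conditions; fixed nominal magnification plus one
correction is accurate to well under the pixel scale for depths within
±50 mm. Rejected frames yield no estimate rather than an interpolated one.
The reference trajectory ("from 2D ground truth") runs the identical code
path on the phantom's exact projections; the raw variant runs it with
filtering disabled.

## Evaluation metrics

- **2D success**: per-axis errors in mm (pixel difference × pixel
  spacing); a frame succeeds when strictly below 2 mm (the planning-CT
  slice thickness) in *both* axes — per-axis absolute differences, not
  Euclidean distance, matching how the criterion names the two directions
  separately.
- **Displacement**: absolute deviation from the scan-mean position per
  axis, summarized by 5th/50th/95th percentiles with linear interpolation
  between order statistics (R type 7; no method is prescribed anywhere).
  Reported per scan; pooling across scans is left to the caller.
- **3D errors**: signed per-axis differences on common frames; the
  headline fraction counts frames strictly below 2 mm on *all* axes.
- **Wilcoxon signed-rank**: midranks for tied absolute differences, zero
  differences dropped; exact two-sided p by full enumeration of the $2^n$
  sign assignments for $n \le 12$ (doubling the smaller tail, capped at
  1), tie-corrected normal approximation without continuity correction
  otherwise. Implemented in the package because the classical
  implementation cannot give exact p-values under ties; it agrees with
  `stats::wilcox.test` on tie-free cases.

## Numerical choices and degenerate inputs

- NCC uses one exact arithmetic path (global mean-centering of the region,
  im2col patch matrix, BLAS products); patches with zero variance after
  centering score 0; templates with zero variance are an error.
- Matching is integer-pixel; the rotation bank resolves orientation to
  about ±2° of the midpoints between 5°-spaced offsets on a ~19-px
  template — poses near a midpoint can legitimately match either
  neighbour.
- BFGS convergence: relative NLL tolerance $10^{-14}$, max 500 iterations;
  non-convergence is an error carrying the optimizer diagnostics.
- Points at or behind the source, tips projecting off the panel, stacks
  whose frame count disagrees with the geometry descriptor, and CSVs with
  wrong headers all fail fast with named errors.

## Problem sizes used by the tests

The unit tests run on reduced geometries (160 × 160 px panels, 8–60
frames) chosen to keep the default suite around two minutes; the
end-to-end property checks use the full default conditions — 368
projections, 512 × 384 panel — for the static-tip and free-breathing
scans, 600 observations for parameter recovery, $10^4$ points for the
geometry round trip and $10^4$ phases for the displacement percentile
check. `scripts/acceptance.R` reruns the full pipeline at default size
twice (clean and cluttered) in about two minutes.

## Known limitations

- The phantom's clean background overstates NCC scores relative to
  patient images with ribs, wires and scatter; the clutter option probes
  the failure mode but not its clinical frequency.
- A single static Gaussian cannot represent baseline drift within a scan;
  drift inflates the fitted covariance instead.
- Multi-lead patients are handled only through the deterministic
  tie-break, not explicit disambiguation.
- No DICOM/vendor projection formats; inputs are TIFF + JSON + CSV.
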