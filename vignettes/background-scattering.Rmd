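---
title: "Characterising carrier-medium background scattering in serial crystallography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising carrier-medium background scattering in serial crystallography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfxbg)
```

## The problem

In serial femtosecond crystallography (SFX), protein microcrystals are
embedded in a viscous carrier — mineral-oil grease, synthetic grease, or a
water-based matrix such as hyaluronic acid — and extruded slowly through the
X-ray focus. The carrier itself scatters, and its diffuse background sets
the noise floor for weak Bragg intensities and anomalous signals. Choosing a
carrier therefore requires a quantitative, resolution-resolved comparison of
background scattering across media, computed from tens of thousands of noisy
single-pulse detector frames that also contain crystal diffraction.

`sfxbg` implements that comparison end to end, together with a synthetic
frame simulator so every stage can be validated against known ground truth
without beamline data.

## The background estimator

The core computation works per detector pixel, over all frames of a stack:

1. **Per-pixel statistics.** For each pixel, the mean $m$ and sample
   standard deviation $s$ (denominator $n-1$) of its counts over frames are
   accumulated in one numerically stable streaming pass (Welford updates).
   A streaming pass matters because a realistic stack (2000 frames of
   512×512 pixels) does not need to be traversed more than twice.
2. **Bragg rejection.** Observations strictly brighter than $m + 3s$ are
   discarded. The rejection is applied per (pixel, frame) *observation*,
   not per pixel: a pixel that a crystal spot hit in a handful of frames
   keeps its remaining clean observations, so the resulting "clean"
   background image has full spatial coverage. Because $m \ge \min$ and
   $s \ge 0$, the minimum observation always survives and no pixel is left
   empty. A single reject-then-reaverage pass is used; the procedure is not
   iterated.
3. **Radial averaging.** Using the detector metrology (pixel pitch, camera
   length, beam centre, photon energy), every pixel is assigned a
   resolution $d = \lambda / (2 \sin\theta)$ with
   $2\theta = \arctan(r/L)$, and the clean image is averaged over
   resolution shells. Shells are equal-width in $q = 1/d$, which keeps
   pixel counts per shell nearly uniform; the count is configurable
   (default 100). Empty shells are reported missing, never zero.
4. **Cross-dataset scaling.** To compare media measured at different
   incident intensities, each profile is multiplied so that its value in
   the highest-resolution (smallest $d$) shell matches the first profile's.
   The first dataset is an arbitrary but documented reference; after
   scaling, all profiles agree exactly at the anchor shell, and re-scaling
   scaled profiles is a no-op.

Two robustness choices deserve a note. The $3s$ clip can only ever remove
an observation when the stack is long enough — with $n$ observations the
largest possible standardised deviation is $(n-1)/\sqrt{n}$, so no
observation can exceed $m+3s$ for $n \le 10$. The estimator is intended
for stacks of hundreds to thousands of frames, where a Bragg spike appears
in a small fraction of a pixel's history and is clipped cleanly. Second,
the sample (unbiased, $n-1$) standard deviation was chosen over the
population form; for the stack sizes involved the difference is
negligible, but the convention is fixed and documented.

## Ring detection and per-frame ring prevalence

Carrier media differ not only in their smooth diffuse profile but in sharp
powder-like rings: a mineral-oil grease shows a ring at 14 Å in every
frame, while a synthetic grease shows a 4.8 Å ring in only a fraction
(~30%) of frames. Two tools quantify this:

* `detect_rings()` subtracts a moving-median baseline (default window 11
  shells) from a radial profile and reports local maxima whose residual
  exceeds a prominence floor (default 1 photon/pixel). A sharp ring spans
  2–3 shells and survives the median; a broad diffuse band spans tens of
  shells and does not. This is why the strong 4–5 Å band never registers
  as a ring.
* `ring_prevalence()` classifies individual frames. It first requires the
  stack-level mean profile to show a detected ring at the queried position
  — without that gate, profile curvature near a band edge could mimic a
  faint ring and noise would be classified. Per frame, the statistic is
  the median count over the ring shells minus the average of the two
  flanking shell medians (a local linear baseline); medians keep Bragg
  spots from biasing the statistic. Frames above half the maximum
  statistic are flagged. Rings whose stack-averaged amplitude
  (peak × occurrence) is below the detection floor are reported absent —
  a documented detection limit rather than a guess.

## The simulator

`simulate_stack()` emulates the study conditions so that the analysis can
be tested against ground truth:

* **Media.** Each medium is a piecewise-linear smooth profile in $q$
  plus Gaussian-in-$q$ rings with occurrence probabilities. The three
  presets encode the qualitative signatures of the media they are named
  after: `az_grease` (strongest 4–5 Å band, 14 Å ring in every frame),
  `super_lube` (strong band, 4.8 Å ring in 30% of frames), and
  `hyaluronic_acid` (no ring, lower profile that exceeds the greases only
  in the 3.5–2.5 Å range). Published figures fix only these ordinal
  relations, not absolute photon counts; the preset amplitudes (roughly
  2–16 expected photons/pixel) were chosen once as plausible
  photon-counting levels and share a common knot grid so the ordinal
  relations hold at every $q$, not just at the knots.
* **Crystal hits.** A configurable fraction of frames carries Bragg spots
  from a randomly oriented tetragonal crystal: the reciprocal lattice is
  rotated by a uniform SO(3) quaternion, points within an excitation
  half-width of the Ewald sphere diffract, screw-axis systematic absences
  (00l with l ≠ 4n, h00 with odd h) are honoured, and surviving spots are
  rendered as isotropic 2-D Gaussians truncated at 4σ with
  exponentially distributed integrated intensities. There is no
  partiality or mosaicity model — the spots exist to drive spot counting
  and the $m+3s$ clip, not to model diffraction physics.
* **Noise and reproducibility.** The observed image is an independent
  Poisson draw of the expectation image. Every random draw for frame $i$
  comes from an RNG substream seeded from (seed, $i$), so identical
  configurations give bit-identical stacks and a per-frame manifest
  records every draw (ring flags, hit flag, orientation, rendered spot
  count).

What the simulator deliberately omits: water-ring physics, detector gain
and pedestal structure, panel seams, beam-intensity jitter, realistic
structure-factor statistics. Passing tests therefore demonstrate that the
*estimators* recover known inputs under Poisson noise and Bragg
contamination — not that any particular real medium scatters at the
simulated amplitudes.

## Geometry choices

The detector model is a single flat panel normal to the beam: 0-based
pixel coordinates, pixel centres, fractional beam centre allowed, no
polarisation or solid-angle corrections (profiles are averages of raw
counts, matching how such backgrounds are reported). The standard test
geometry is a 512×512 panel, 0.2 mm pitch, with the camera length solved
so the frame corner sits at 2.3 Å for 7 keV photons
(λ = hc/E with hc = 12.3984 keV·Å, i.e. 1.77 Å) — the camera length and
pixel pitch of the real instrument are not published, so the fixture is
calibrated only to the documented edge resolution and wavelength. A pixel
exactly at the beam centre has no finite resolution and is excluded from
all shells.

One consequence of a short camera length worth knowing: with a large unit
cell (~80 Å) the projected spacing between neighbouring reciprocal-lattice
rows shrinks to a few pixels and spot footprints merge into chains.
Spot-count validation in the test-suite therefore uses small cells that
keep spots separated; crowded patterns are still fine for background
estimation, where only the $m+3s$ clip matters.

## Hit finding and merging statistics

`find_spots()` is a deliberately minimal spot finder: background-subtracted
signal above `snr_min` (default 5) Poisson standard deviations of the
clean background (`sqrt(max(bg, 1))`), 8-connected components of at least
`min_pix` (default 2) pixels, signal-weighted centroids. A frame with
strictly more than 20 spots counts as a hit — the standard SFX criterion.
Printed hit/indexing rates are rounded half-up to one decimal, which is
the convention that reproduces published indexing rates from their own
image counts. Indexing itself is delegated to external programs; only the
bookkeeping lives here.

For merged-data quality, reflections are reduced to canonical
representatives under Laue class 4/mmm (all 16 operations, Friedel pairs
merged), unique reflections are enumerated in an inclusive resolution
window with $d = 1/\sqrt{(h^2+k^2)/a^2 + l^2/c^2}$, and half-set
statistics are computed from a seeded alternating split:
$R_\mathrm{split} = 100 \cdot 2^{-1/2} \sum |I_A - I_B| / \tfrac12 \sum
(I_A + I_B)$ and CC$_{1/2}$ as the Pearson correlation of the merged
halves. Systematically absent reflections are *excluded* from unique
counts by default: for the published tetragonal data sets this convention
reproduces the printed unique-reflection counts to within one reflection,
whereas counting absences overshoots by ~0.5%. The flag
`include_absences` exposes both conventions.

## Problem sizes and defaults

The standard study configuration — three media, 2000 frames each on the
512×512 fixture geometry, 100 shells, 25% crystal-hit frames with a
lysozyme-like cell — mirrors the ~2,000-image averages used for published
background comparisons and runs in about five minutes on one CPU core.
Unit tests use 24–256 pixel geometries and tens to hundreds of frames;
statistical assertions use 3–5 standard-error bands so that fixed seeds
are a convenience, not a crutch.

```{r quick-look, eval = FALSE}
# a scaled-down version of the full study (seconds, not minutes)
cmp <- run_media_study(seed = 1, n_frames = 300, n_pixels = 128)
print(cmp)
plot_profiles(cmp)
```

## Known limitations

* Only single-panel, untilted detector geometries; no CrystFEL `.geom`
  or Cheetah dialects.
* Only tetragonal cells and Laue class 4/mmm in the merging module.
* The spot finder is not a Cheetah replacement: no resolution-dependent
  thresholds, no peak-profile fitting.
* Ring prevalence has a detection floor (stack-level prominence ≥ 1
  photon/pixel by default); fainter intermittent rings are reported
  absent.
* Absolute background amplitudes of the media presets are ordinal
  constructions, not radiometric calibrations.
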