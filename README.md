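# sfxbg

Background-scattering analysis for serial femtosecond crystallography
(SFX), with a synthetic diffraction-frame simulator for validation.

In SFX, microcrystals are delivered into the X-ray focus embedded in a
viscous carrier medium (mineral-oil grease, synthetic grease, hyaluronic
acid, ...). The medium's own diffuse scattering sets the noise floor for
weak Bragg and anomalous signals, so carriers must be compared
quantitatively, resolution shell by resolution shell, from stacks of noisy
single-pulse frames that also contain crystal diffraction. `sfxbg`
implements the standard robust recipe for this:

* **per-pixel statistics with Bragg rejection** — for every detector pixel,
  the mean *m* and standard deviation *s* over frames; observations
  brighter than *m* + 3*s* (crystal spots) are rejected and the survivors
  re-averaged into a *clean background image*;
* **resolution-resolved radial averaging** — pixels are mapped to
  d-spacing via the detector metrology (d = λ / 2 sin θ,
  2θ = arctan(r/L)) and averaged over shells equal-width in q = 1/d;
* **cross-medium scaling and comparison** — profiles are scaled to agree
  at the highest-resolution shell, sharp rings are detected against a
  moving-median baseline, intermittent rings are classified per frame,
  and diagnostic bands (5–4 Å, 3.5–2.5 Å) are summarised;
* **hit finding and rate bookkeeping** — a minimal SNR-threshold spot
  finder, the strict ">20 spots" hit criterion, and half-up-rounded
  hit/indexing rates;
* **merging statistics for tetragonal crystals** — canonical Miller
  indices under Laue class 4/mmm, unique-reflection enumeration with
  systematic-absence conventions, Monte Carlo merging, and the half-set
  statistics R_split = 100·2^(−1/2)·Σ|I_A − I_B| / (½Σ(I_A + I_B)) and
  CC1/2 (Pearson correlation of merged half-sets);
* **a frame simulator** — medium presets (`az_grease`, `super_lube`,
  `hyaluronic_acid`) with smooth diffuse profiles and occurrence-weighted
  Gaussian rings, Bragg spots from randomly oriented P4₃2₁2-like crystals
  on the Ewald sphere, Poisson noise, and a per-frame ground-truth
  manifest, all bit-reproducible from a seed.

## Worked example

Simulate and compare the three carrier media at the standard study
conditions (2000 frames per medium, 512×512 detector whose corner reaches
2.3 Å at 7 keV, 100 shells, 25% crystal-hit frames):

```r
library(sfxbg)
cmp <- run_media_study(seed = 1)
print(cmp)
```

```
<media_comparison>
  scale factors:
         dataset scale_factor
       az_grease    1.0000000
      super_lube    1.0302749
 hyaluronic_acid    0.8830413
  detected rings:
    dataset         d          q shell prominence
  az_grease 13.760614 0.07267118    17   9.393380
 super_lube  4.828404 0.20710776    48   2.119141
  band summary (scaled intensity):
         dataset         band d_max d_min mean_scaled_intensity
       az_grease     band_5_4   5.0   4.0             15.717578
      super_lube     band_5_4   5.0   4.0             12.573609
 hyaluronic_acid     band_5_4   5.0   4.0              6.127418
       az_grease band_3.5_2.5   3.5   2.5              3.999987
      super_lube band_3.5_2.5   3.5   2.5              3.535313
 hyaluronic_acid band_3.5_2.5   3.5   2.5              4.179193
  ring prevalence:
    dataset d_center prevalence n_frames manifest_prevalence agreement
 super_lube      4.8      0.303     2000               0.303       1
```

Reading the output: the full pipeline recovered the injected AZ-grease
ring at 13.8 Å (one ring, within a shell of its true 14 Å position) and
the Super Lube ring at 4.83 Å, found no ring for hyaluronic acid, and
estimated the Super Lube ring's per-frame prevalence at 30.3% against a
configured 30% (perfect per-frame agreement with the simulator manifest).
After anchoring all profiles at the 2.3 Å shell, hyaluronic acid scatters
roughly half as strongly as the greases through the diffuse 5–4 Å band but
slightly *more* than either grease in the 3.5–2.5 Å band — the
characteristic trade-off of the water-based medium. A scaled-down call
(`run_media_study(seed = 1, n_frames = 300, n_pixels = 128)`) shows the
same structure in seconds.

Individual stages are exported (`pixel_stats()`, `clean_background()`,
`radial_average()`, `scale_profiles()`, `detect_rings()`,
`ring_prevalence()`, `find_spots()`, `rate_summary()`, `count_unique()`,
`mc_merge()`, `split_half()`, `r_split()`, `cc_half()`,
`completeness()`), stacks round-trip through HDF5
(`write_stack()`/`read_stack()`), and `run_comparison()` drives a full
configured run writing CSV/JSON reports. A thin command-line front end
lives at `inst/cli/sfxbg` (subcommands `simulate`, `analyze-background`,
`hit-stats`, `merge-stats`, `run`).

## The methods vignette

`vignettes/background-scattering.Rmd` documents the estimator and its
assumptions, the simulator's scope and what it deliberately omits, the
numerical conventions (rejection threshold, shell binning, scaling
anchor, rounding, absence conventions), and known limitations.
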