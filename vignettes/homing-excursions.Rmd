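---
title: "Homing excursions, compass runs, and axial circular statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homing excursions, compass runs, and axial circular statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compassrun)
```

## The problem

Free-roaming hunting dogs taken on forest walks regularly leave their owner
to pursue game scent and then navigate back. GPS collars on the dog and a
handheld receiver with the owner record both tracks at 2.5 or 5 s intervals
with about ±4.2 m positional accuracy. Each *excursion* begins the moment
the dog is 100 m from the owner (at which point the owner stops and stays
put) and ends when the dog comes back within 10 m of that marked spot.

Two qualitatively different return strategies occur. In *tracking*, the dog
retraces its own outbound route, staying within a ±30 m corridor of it. In
*scouting*, the dog takes a novel route separated from the outbound track by
more than 30 m. Scouting returns begin with a short, fast, strikingly
straight segment — the *compass run* — whose direction clusters along the
magnetic north–south axis regardless of where the owner actually is. The
axial (modulo-180°) alignment of that run is the scientific phenomenon this
package measures; `compassrun` re-implements the whole measurement chain as
tested, reusable code, together with a synthetic trial generator so that
every stage can be validated without any field data.

## The measurement chain

1. **Excursion detection** (`detect_excursions`). The owner's position is
   linearly interpolated to the dog's timestamps. An excursion opens at the
   first dog fix ≥ 100 m from the concurrent owner position; the owner's
   location is frozen at that instant; the excursion closes at the first
   later fix within 10 m of it. Excursions shorter than 200 m of path, and
   excursions with no return before the track ends, are excluded.

2. **Turning trajectory and turning point** (`locate_turning`). The
   excursion path is cut into ten segments of equal path length. The decile
   with the slowest mean speed is the *turning trajectory*; within it, the
   consecutive fix pair with the slowest speed marks the *turning point*
   (ties to the earliest pair). If the slowest decile is improbable — first
   or last decile, or containing a single > 120 s gap — the second slowest
   is used; if that too is improbable, the remaining deciles are scanned
   from slowest upward for the first that reaches farther from the
   excursion start than the median fix does.

3. **Azimuths** (`azimuth_a`, `azimuth_b`, `extract_compass_run`). All
   azimuths are magnetic: the true bearing minus the per-trial declination.
   Azimuth A is the outbound direction over the first 5 s; azimuth B points
   from the turning point to the owner; azimuth C is the chord bearing of
   the compass run, which extends from the turning point to the first point
   where the step heading deviates more than 20° from the chord *and stays
   deviated at the next point* (so a one-fix jiggle around an obstacle does
   not end the run).

4. **Strategy classification** (`corridor_profile`, `classify_return`).
   Every inbound fix is scored by its minimum distance to the outbound
   polyline. Fixes within the first and last 60 m of inbound path are
   masked (the endpoints coincide with the outbound track by construction).
   Runs of in-corridor (≤ 30 m) or out-of-corridor fixes shorter than 150 m
   of path are merged into their neighbour; all-in gives TRACKING, all-out
   SCOUTING, anything else COMBINED with per-sub-track compass runs.

5. **Metrics and statistics** (`homing_efficiency`, `rayleigh_test`,
   `watson_u2`, `dog_level_means`). The homing-efficiency index is
   100 × inbound path length / beeline. Azimuths A and B are angular;
   azimuth C is axial and analysed on doubled angles. The Rayleigh p-value
   uses the series-corrected large-sample form
   $p = e^{-Z}\bigl[1 + \tfrac{2Z - Z^2}{4n} - \tfrac{24Z - 132Z^2 + 76Z^3 - 9Z^4}{288 n^2}\bigr]$
   with $Z = n r^2$. Watson's two-sample $U^2$ is computed from the pooled
   ranked empirical distribution functions (origin-invariant), with table
   bounds generated from the asymptotic distribution and an optional
   label-permutation p-value as an internal oracle.

## A worked example

```{r example}
sim <- sim_config(n_trials = 40, seed = 1)
res <- run_pipeline(sim = sim)
res$summary$strategy
subset(res$summary$circular, azimuth == "C" & strategy == "SCOUTING")
```

With the default generator settings the scouting compass runs are drawn
from an axial von Mises distribution centred on magnetic north–south, so
the recovered axial Rayleigh test on azimuth C rejects uniformity and the
recovered mean axis sits near 0°/180°.

## What the generator emulates — and what it does not

`simulate_trial` reproduces the protocol's observable structure: an owner
walking then freezing at 100 m separation; a dog outbound modelled as a
smoothly curving correlated random walk (total heading change 90–150°, 5°
per-step heading noise, 3 m/s) of 400–600 m; a 50 s decelerating pause at
the turning point; a compass run whose axial direction is drawn from a von
Mises distribution on doubled angles (default concentration 1.5 about the
magnetic north–south axis) with length Normal(18.1 m, 6 m) truncated at
5 m; and a return by tracking (retracing with AR(1) lateral noise of 8 m
SD, clipped at 15 m), scouting (a novel route kept ≥ 60 m from the
outbound track over its central half, steered around the outbound arc), or
a single tracking→scouting switch. I.i.d. Gaussian noise of
4.2/√2 m per coordinate (≈ 4.2 m 2-D RMS) is added to every fix of both
tracks.

The generator does **not** model terrain, forest path networks, scent
fields, game behaviour, multi-switch combined returns, or autocorrelated
GPS error. The last point matters for interpretation: real Garmin error is
strongly autocorrelated in time, so real tracks accumulate far less
spurious path length over a stationary dog than i.i.d. noise does. Passing
tests therefore certify the pipeline's behaviour under a *harsher* noise
model than the field data, but they cannot certify anything about
behaviour the generator does not contain (e.g. real outbound tortuosity).

### Numerical choices driven by the noise model

Several defaults follow directly from arithmetic about i.i.d. fix noise;
they are choices of this package, all configurable:

- A stationary fix pair at σ = 4.2/√2 m per coordinate measures
  E|step| ≈ 5.3 m of apparent path, i.e. ≈ 2.1 m/s of phantom speed at
  2.5 s sampling. A detectable stop must therefore span a meaningful slice
  of a path decile: the generator's 50 s pause yields ≈ 105 m of apparent
  path against ≈ 110–160 m deciles.
- Because every pause pair is pure noise, the detected turning point falls
  essentially uniformly within the pause. The classifier's inbound can
  then open with up to the full pause's apparent path plus the
  corridor-resident start of the return (≈ 150–190 m in the worst tail).
  The terminal buffer (60 m) plus minimum run length (150 m) are sized so
  that this spurious "tracking" stretch cannot flip a scouting label.
- Bearings over displacements comparable to the noise envelope are
  meaningless, so the compass-run scan skips candidates whose chord from
  the turning point is under 10 m (`min_chord_m`, ≈ 2.4 per-coordinate
  sigmas) and steps under 1 m.
- The compass-run **length** defaults to the chord from the turning point
  to the run end rather than the along-track path: path length across the
  near-stationary turning cluster integrates noise (≈ 5 m per fix), so the
  along-track "length" of a short run would be dominated by jitter, not
  movement. The two agree exactly on noise-free straight runs;
  `run_length_measure = "path"` restores the along-track measure.
- Excursions whose inbound is too short to carry a corridor profile are
  excluded and logged rather than aborting a batch analysis, mirroring the
  field protocol's exclusion of unanalysable excursions.

### Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `separation_m` | 100 | m | excursion opening (receiver alarm distance) |
| `closure_m` | 10 | m | return threshold at the marked start |
| `min_excursion_m` | 200 | m | exclusion of short excursions |
| `corridor_m` | 30 | m | tracking/scouting corridor half-width |
| `deflection_deg` | 20 | ° | compass-run termination rule |
| `persistence_pts` | 1 | fixes | "no immediate return" horizon |
| `terminal_buffer_m` | 60 | m | masked inbound ends (see above) |
| `min_run_m` | 150 | m | corridor-run merge threshold (see above) |
| `wind_halfwidth_deg` | 22.5 | ° | olfactory-suitability sector |
| `kappa_axial` | 1.5 | – | doubled-angle concentration of simulated runs |
| `run_length_mean` | 18.1 | m | mean simulated compass-run length |
| `gps_noise_sigma` | 4.2/√2 | m | per-coordinate fix noise (2-D RMS ≈ 4.2) |

## Covariate reference frames

The sun table (`sun_table`) holds the solar azimuth for the 15th day of
each month at every daylight hour, computed with the standard low-accuracy
solar-position equations (declination series plus hour angle) at the
configurable reference location 49.8° N, 15.5° E. Compass-run azimuths are
converted to true bearings (adding the declination) before subtracting the
sun azimuth at the nearest tabulated hour; night-time trials are excluded.

Wind uses the meteorological *from* convention, stated explicitly because
it is easy to invert: `wind_from` is the direction the wind blows from. Air
travelling from the owner to the dog arrives at the dog from the owner's
bearing, i.e. from azimuth B, so a scouting return is "suitable for
olfactory piloting" when |wind_from − azimuth B| ≤ 22.5° on the circle.
Absent wind is `NA` ("not assessable"), never 0°.

## Validation strategy and problem sizes

The test suite checks each module against independent oracles (brute-force
path sums, 0.1 m densified polyline distances, closed-form circular
statistics, permutation tests) and the whole pipeline against the
generator's ground truth: strategy recovery on 200 mixed trials, turning
point recovery within two fixes on 500 noise-free trials, axial-alignment
recovery on 250 noisy scouting trials (concentration 1.5), and a
type-I-error calibration of the full pipeline on 1000 independent 30-trial
datasets with a uniform axial null. The null calibration uses 30-trial
datasets because the test's rejection rate does not depend on the number of
trials per dataset; this keeps the suite's runtime proportionate. Bootstrap
confidence-arc coverage is checked at 250 simulated samples of 40 bearings
(concentration 3).

## Known limitations

- The decile-based turning detector resolves the turning point only to
  within the stationary pause under realistic noise; downstream azimuths
  inherit a few degrees of scatter from that.
- Compass runs shorter than the ~10 m measurement floor cannot be measured
  and surface as late terminations with longer, noisier chords.
- The "second slowest, then farthest" fallback for improbable turning
  segments encodes the published verbal rule with explicit thresholds
  (first/last decile; a single > 120 s gap); the original workflow used
  video review, which has no software counterpart here.
- Mixed-effects modelling of speed/efficiency covariates is deliberately
  out of scope; the summary reports group means only.
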