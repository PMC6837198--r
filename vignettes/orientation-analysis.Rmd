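---
title: "Methods: circular orientation analysis for drifting chamber experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circular orientation analysis for drifting chamber experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discorient)
```

## The experimental system and its data

A drifting *in situ* chamber (DISC) is a transparent circular arena
(here 40 cm diameter) holding one animal, drifting freely at sea. A camera
underneath records the head position once per second; because the frame
rotates while drifting, a digital compass mounted on the camera axis records
the magnetic heading of the image's up-axis at the same cadence. A deployment
lasts 15 min: the first 5 min (`acclimation_s = 300`) are discarded and the
remaining 10 min (`analysis_s = 600`, one bearing per second) are analysed.

The system boundary of this package is the *post-tracking* interface: text
files of per-second positions (`t_s,x_px,y_px`) and headings
(`t_s,heading_deg`), plus a flat key-value metadata file per deployment
(start time, site coordinates, tide phase, arena calibration). Video
processing is upstream and out of scope.

## From positions to bearings

The bearing of the animal at second $t$ is the angle of its head position
about the arena centre, in the camera frame
($\theta^{cam}_t = \operatorname{atan2}(dx, dy)$, $0$ = image-up, clockwise),
rotated into the magnetic frame by the compass heading $h_t$ of the up-axis:

$$\theta_t = (\theta^{cam}_t + h_t) \bmod 360.$$

This cancels chamber rotation exactly, whatever the rotation path. Compass
samples are matched by nearest timestamp within 1 s (the two loggers are not
synchronised in the field); a deployment with more than 10% unmatched seconds
errors out, and one with less than 80% of the analysis window retained is
flagged `low_coverage` and excluded from group analyses. Gaps are never
interpolated. Head *position*, not frame-to-frame displacement, defines the
bearing: the animal's station-holding direction in the arena is the
behavioural signal of interest, and it is what makes the 1-Hz samples
meaningfully exchangeable.

Position files record their vertical-axis convention in a header comment
(`# y_axis: up|down`); a y-down file is reflected about the calibrated centre
at extraction time, so the bearing math always sees mathematical y-up.

Swimming speed is the per-second Euclidean step length converted to cm by the
calibration (`radius_cm / radius_px`); steps spanning gaps are excluded, and a
deployment is summarised by the arithmetic mean (and median) of its
per-second speeds.

## Two-level circular statistics

**First order (within animal).** For bearings $\theta_1,\dots,\theta_n$ the
mean resultant length $\bar R$ and mean direction $\bar\theta$ come from the
mean unit vector. Uniformity is tested with the Rayleigh statistic
$Z = n\bar R^2$ and the finite-sample-corrected p-value

$$p = e^{-Z}\left[1 + \frac{2Z - Z^2}{4n}\right],$$

clamped into $[0,1]$ (the series can leave the unit interval at extreme $Z$;
a clamped 0 simply means "far beyond machine-resolvable significance").
*Choice of correction order.* Both the $1/n$ correction above and the longer
$1/n^2$ series are standard. At every group size this package targets
($n$ from 9 to 600) the two agree to two significant figures of $p$, and the
first-order form reproduces published summary tables at their printed
precision across the whole range of $(n, r)$ pairs we validate against; the
longer series buys accuracy only below that precision, so we use the shorter,
more transparent form. An animal is "orienting" when $p < 0.05$; no
multiple-testing correction is applied at the individual level, matching the
convention of the field (each deployment is a separate experiment).

**Second order (across animals).** Whether animals share a direction is
tested by applying the same Rayleigh machinery to *one mean bearing per
animal* (equal weights), restricted to individually significant animals.
Group summaries report both the magnetic frame and the moon-relative frame
(below) over the same set of animals.

**Confidence arcs.** The 95% arc around a mean direction uses the
large-sample circular-dispersion method: with
$\hat\rho_2 = \tfrac1n\sum\cos 2(\theta_i - \bar\theta)$,
$\hat\delta = (1-\hat\rho_2)/(2\bar R^2)$ and
half-width $\arcsin(z_{0.975}\sqrt{\hat\delta/n})$. For small or diffuse
samples ($n < 25$ or $\bar R < 0.2$) the normal approximation is unreliable
and a 2000-replicate bootstrap percentile arc is used instead. Arcs are only
reported when the Rayleigh test rejects at 0.05 and $n \ge 5$. The test suite
verifies ~95% coverage of the dispersion arc at $n = 600, \kappa = 1$ and at
the group-level regime $n = 45$, $E[\bar R] \approx 0.42$, and that the two
methods agree within 5° of half-width where both apply.

**Ties.** Duplicate bearings are legitimate 1-Hz samples and are never
jittered.

**Speed contrast.** Per-animal mean speeds are compared between strata with a
two-sided Wilcoxon rank-sum test: exact by complete enumeration of the
rank-sum distribution (a shift-algorithm over doubled mid-ranks, so tied data
are handled exactly, conditionally on the tie pattern) when both groups have
at most 10 members, otherwise a normal approximation with tie-corrected
variance and 0.5 continuity correction. The exact branch is verified against
an independent full-enumeration oracle for every size split of
$n_1 + n_2 \le 10$.

## Moon-relative orientation

The moon azimuth is the clockwise angle from north to the moon's vertical
projection onto the horizon. For each significant animal,

$$\alpha_{moon} = (\bar\theta - A_{moon}) \bmod 360,$$

so 0° means "toward the moon" and 180° "away". One $\alpha_{moon}$ per animal
(not per second) enters the second-order test, mirroring the per-individual
presentation of stratified result tables. The reference instant is the
deployment midpoint (start + 7.5 min with defaults); the azimuth moves by
under 2° within a deployment, so this choice is immaterial. Because compass
bearings are magnetic while astronomical azimuths are true-north, the site
carries a `magnetic_declination` (east positive) and cue azimuths are
expressed in the magnetic frame as `azimuth − declination`. The default is
0°: at the western-Norway sites this package was built around, declination in
2015–2017 was ≈ 0–1°, below the resolution of the analysis. A sun-relative
analysis (`sun_frame = TRUE`) repeats the group tests against the sun azimuth
as a daytime control.

Stratification keys are the lunar phase label, the tide phase (always
supplied as metadata — tide is *never* computed), and whether the moon is
above the horizon (strict `altitude > 0`; an altitude of exactly 0 counts as
below). Pooled rows (e.g. all new-moon deployments regardless of tide) are
available via `pool_phases`.

## The built-in ephemeris

Rather than depending on an online calculator, the package computes
low-precision astronomy from truncated trigonometric series with documented
term tables in the source: a ~50-term lunar longitude/distance series with a
30-term latitude series, and a classical low-precision solar longitude.
Coordinates go ecliptic → equatorial (mean obliquity) → topocentric
(spherical-Earth parallax correction, which matters up to ~1° for the moon)
→ horizontal via Greenwich mean sidereal time. Design constants: TT − UTC
fixed at 69 s (exact to a few seconds over the supported 1950–2050 window,
i.e. < 0.01° of lunar motion); no nutation (< 0.005°); no atmospheric
refraction, so `above_horizon` is geometric. Verified accuracy against a
rigorous independent ephemeris at ten instants spanning 2015–2017:
≈ 0.005° in azimuth and altitude for both bodies — far inside the 1° (moon)
and 0.1° (sun) design targets, which themselves are far inside the
tens-of-degrees scale of the orientation effects.

The illuminated fraction is $k = (1 - \cos\psi)/2$ with $\psi$ the geocentric
sun–moon elongation, evaluated at local *solar* noon when a daily value is
needed (the reporting hour of almanac services varies; $k$ moves by < 0.01
across any plausible "noon"). Phase labels use the moon–sun ecliptic
longitude difference $d$: `new` within ±22.5° of 0, `first_quarter` /
`full` / `third_quarter` within ±22.5° of 90/180/270, otherwise `waxing`
($d < 180$) or `waning`. Note these are *instantaneous* labels: a field
campaign's "full moon period" of several days will straddle `full` and
`waning` labels near its end. Two real-sky caveats found while validating:
the sun–moon azimuth gap at a "new" instant can exceed 15° near the window
edges once projected to the horizon, and the synodic month realised as the
spacing of illumination minima varies by ±0.25 d around 29.53 d; the tests
encode both facts.

`gravitational_pull()` is a worked-example utility (Newtonian attraction of
the moon/sun at mean distance, or surface weight for the Earth) used to put
the "is it lunar gravity?" question to rest numerically: the moon pulls on an
80 kg mass with ≈ 0.0027 N, five orders of magnitude below its ≈ 785 N
weight.

## The synthetic world

`simulate_deployment()` generates a complete, ground-truthed deployment:

- with probability `p_orient` (default 0.96) the animal is an *orienter*
  whose preferred direction is $\mu_i \sim \mathrm{vM}(\mu_{pop},
  \kappa_{pop})$; otherwise it is a non-orienter whose bearings are uniform;
- per-second magnetic bearings $\theta_t \sim \mathrm{vM}(\mu_i,
  \kappa_{within})$, i.i.d.;
- chamber heading $\phi_t$: wrapped-normal random walk with increment s.d.
  `sigma_rot` (default 2° s⁻¹ — drifting gear rotates slowly but
  persistently); the compass series records $\phi_t$, so
  camera angles are $(\theta_t - \phi_t) \bmod 360$ and extraction recovers
  $\theta_t$ *exactly* (the adjointness test asserts 10⁻⁶ deg);
- per-second speeds are lognormal with median `speed_median` (default
  3.0 cm s⁻¹) and log-s.d. `speed_logsd` (default 0.22, giving a
  mean ± s.d. spread close to 3.0 ± 0.7 cm s⁻¹, positive and mildly
  right-tailed); head positions are placed on the simulated camera angles at
  radii (5–95% of arena radius) chosen so consecutive step lengths match the
  drawn speeds whenever geometrically feasible.

Defaults are chosen once to match the stated world of the motivating study:
$\kappa_{within} = $ `kappa_from_r(0.30)` so individual $\bar R$ at $n = 600$
lands near 0.30; $\kappa_{pop} = $ `kappa_from_r(0.42)` for group-level
resultant lengths near 0.42; `p_orient = 0.96` at the high end of observed
orienting proportions; `mu_pop = 195°` (southerly); 203 deployments across
four phase windows in `default_campaign_calendar()`. With
`moon_following = TRUE` the population direction tracks each deployment's
magnetic moon azimuth plus `mu_offset`.

Reproducibility: one global `seed`; each deployment uses a substream derived
from it by a counter, so campaigns are deterministic file-for-file
(byte-identical trees for equal seeds) and individual deployments can be
regenerated in isolation.

**What the generator does *not* emulate.** (i) Bearing autocorrelation: real
animals turn smoothly; i.i.d. draws are deliberately chosen because the
Rayleigh calibration (5% type-I error under the null) assumes exchangeable
samples, and that is the property under test. (ii) Because i.i.d. bearings at
finite radius sometimes demand cross-arena jumps, realised speeds exceed the
lognormal target by roughly 20% (geometric floor); location *contrasts*
between strata are preserved, which is what the speed analysis consumes.
(iii) No tidal drift, depth behaviour, or behavioural state switching. A
green end-to-end test therefore establishes the correctness of the analysis
chain, not the realism of eel behaviour.

## Numerical choices and edge cases

- All angles are wrapped into [0, 360) by one shared utility; internal trig
  is in radians; degrees at every interface.
- A mean direction is "undefined" when $\bar R < 10^{-12}$ (e.g. exactly
  antipodal pairs); it is reported `NA` without error.
- `kappa_from_r()` solves $A_1(\kappa) = \bar r$ by root bracketing with
  exponentially scaled Bessel functions, $|A_1(\kappa) - \bar r| < 10^{-6}$;
  $\bar r \ge 1$ errors ("degenerate concentration").
- von Mises sampling uses the Best–Fisher wrapped-Cauchy envelope rejection
  method, vectorised; $\kappa = 0$ falls back to uniform, $\kappa = \infty$
  to the point mass.
- Exact rank-sum p-values double the smaller tail and cap at 1; identical
  values across both groups give p = 1 with a warning.
- Group cells with fewer than 2 significant animals are reported as
  `insufficient` rather than silently dropped; empty strata raise warnings.
- Reports are deterministic: fixed column order, fixed stratum ordering
  (phase in lunar-cycle order, then tide, then horizon), no timestamps.

## Known limitations

- The ephemeris is valid 1950–2050 and deliberately omits refraction and
  nutation; it should not be reused where sub-0.1° lunar accuracy matters.
- The per-instant phase label will disagree with multi-day campaign labels
  near window boundaries; classify deployments, not campaigns.
- The dispersion confidence arc is slightly anticonservative for very diffuse
  samples; the automatic bootstrap fallback covers the regime where this
  bites ($n < 25$ or $\bar R < 0.2$).
- Axial (bimodal) orientation, modern alternatives to the Rayleigh test, and
  covariate models of orientation are out of scope.
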