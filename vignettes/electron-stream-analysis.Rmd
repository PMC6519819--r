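---
title: "Modelling out-of-field electron streams in low-field MR-guided radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling out-of-field electron streams in low-field MR-guided radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estreamlab)
library(dplyr)
```

## The physical problem

In MR-guided radiotherapy with a 0.35 T field and Co-60 sources, secondary
electrons that escape a patient or phantom surface do not simply scatter away
in air: the Lorentz force winds them into helices around the static field
lines. A bundle of such electrons forms a directed *air-electron stream* along
(or against) the field direction that can deposit a clinically relevant dose
far outside the treatment field — up to roughly half the prescription dose at
10 cm from the central axis in the bench experiment this package models.

The bench setup is an acrylic block (15 x 15 x 10 cm, 1.18 g/cm^3) on a
tilting support, its centre of mass at the isocenter (SAD 105 cm), irradiated
by square Co-60 fields of 6.3 or 12.6 cm at gantry 0, 30 or 330 degrees, with
the support tilted 10, 20 or 30 degrees so that the surface normal acquires a
component along the magnetic field. Two film panels stand orthogonal to the
field at 10 or 17 cm from the central axis: the *front* panel faces the beam
entrance surface, the *end* panel the exit surface. Each delivery prescribes
3 Gy to the isocenter; the full factorial design yields 36 deliveries and 72
panel dose distributions.

`estreamlab` implements the complete analysis chain for this experiment:

* reconstruction of the divergent-beam geometry and of the *projected areas*
  of the beam cross-sections on the panels (`projected_area_table()`),
* planar dose-map handling with the two summary statistics of the study —
  the circle-average dose around the map maximum, D_Rx (`drx_profile()`), and
  the isodose-line area at a fraction of the prescription, A_y%
  (`isodose_areas()`),
* global 2D gamma-index comparison at 3%/3 mm with a 10% threshold
  (`gamma_map()`),
* a desk-scale Monte Carlo generator of synthetic panel dose maps
  (`simulate_condition()`), and
* the study orchestration: packaged transcriptions of the published panel
  dose tables, calculated-versus-measured summaries, and Spearman rank
  correlations between panel doses and projected areas
  (`correlate_projected_areas()`, `run_study()`).

## Coordinate conventions

The frame is right-handed with its origin at the isocenter: `+y` along the
static field (couch towards bore), `+z` vertically up. The gantry rotates
about `y` and the beam points along `-z` at gantry 0; panels are the planes
`y = +d` (front) and `y = -d` (end). The support tilts the phantom about `x`,
so the entrance-surface normal is `(0, sin t, cos t)` for tilt `t`. All
lengths are centimetres, pixel pitches millimetres, doses centigray, energies
MeV and angles degrees.

## The projected-area computation

The study's central geometric quantity is the area of the beam cross-section
at the phantom surface, orthographically projected along the field axis onto
a panel. Two conventions had to be fixed where the source material is silent:

**Field-square convention.** `field_corners()` supports both the standard
beam's-eye-view square (perpendicular to the central axis, rotating with the
gantry; `"bev"`) and a square lying flat in the horizontal isocenter plane
(`"isocenter"`). The package default is `"isocenter"`, chosen by
reconstruction: with that convention (surface planes at half-thickness along
the tilted normal, no clipping, areas taken at the one-decimal precision of
the published table) the packaged measured doses reproduce *all sixteen*
published rank-correlation coefficients to the printed precision (maximum
deviation 0.0005), together with the published smallest area (6.2 cm^2; we
compute 6.24) and largest area within 5% (104.0 versus 109.4 cm^2). The
beam's-eye-view convention reproduces neither (its unclipped maximum misses
by 10% and its correlation table deviates by up to 0.05). The two agree at
gantry 0.

**Clipping.** Physically a footprint cannot exceed the 15 x 15 cm face it
lies on, but the exit surface is coplanar with the much larger support plate,
and the published extremes are only consistent with *unclipped* quadrilaterals.
`footprint_polygon()` therefore defaults to `clip_to_phantom = FALSE`, and
`projected_area_table()` reports both the unclipped and the face-clipped
area so the sensitivity is always visible (clipping the largest footprint
removes about a third of it).

```{r areas}
areas <- projected_area_table()
range(areas$area_cm2)
areas %>% filter(tilt_deg == 30, field_size == 12.6, gantry_deg == 330)
```

Internally `projected_area()` computes the projection twice — shoelace area
of the vertices' `(x, z)` coordinates, and in-plane polygon area times
`|n . y|` — and insists the two agree to 1e-9.

## Dose-map metrics

A `dose_map` is a matrix of absolute dose (cGy) on a square raster with a
physical origin; the default analysis pitch is 1.36 mm, the pitch at which
the study's film scans were reported. Film-native 75 dpi imports
(`read_dose_map(..., format = "image")` with a YAML sidecar) are rebinned
with `rebin()`, an area-weighted block average that preserves the covered
mean to numerical precision.

* `max_point()` locates the global maximum; ties break to the smallest
  row-major index so results are reproducible.
* `mean_dose_in_circle()` averages all pixels whose *centres* fall within the
  radius; partial-pixel weighting is deliberately not attempted (the source
  tables are quoted at 0.1 cGy, far coarser than the sub-pixel effect), and
  circles truncated by the map edge simply use the in-map pixels.
* `isodose_area()` counts suprathreshold pixels times the pixel area. For the
  simply-connected single-spot distributions this equals the area enclosed by
  the isodose contour while remaining exactly testable against a pixel-loop
  oracle; zero is a valid value (printed as "-" in the source tables).

D_Rx is non-increasing in radius on any single-spot map and A_y% is
non-increasing in the level — both are asserted on simulated fixtures in the
test suite.

## Gamma evaluation

`gamma_map()` implements the global 2D gamma index: for every reference
point above the 10% low-dose threshold it minimizes
`sqrt((dr/DTA)^2 + (dD/(tol * D_norm))^2)` over evaluated-map positions
sampled by bilinear interpolation on a sub-grid of `0.1 * DTA` out to
`3 * DTA`. Global normalization anchors `D_norm` to the *reference* maximum
(the calculated map by QA convention; the evaluated-map maximum is available
as an option), and the threshold removes reference points at or below 10% of
`D_norm`. Offsets are visited in order of increasing distance with an early
stop once the distance term alone exceeds every running minimum — an
optimization that is exactly equivalent to the exhaustive sub-grid search,
which the test suite verifies to 1e-9 on 32 x 32 maps.

The published film-versus-calculation pass rates cannot be recomputed
without the film scans, so the gamma module is validated by its analytic
properties instead: identity gives 100%, a 3 mm rigid shift passes 3%/3 mm
exactly, a uniform +3%-of-maximum offset passes under global normalization,
and loosening the criteria to 4%/4 mm never lowers a pass rate.

## The synthetic-data generator

`simulate_condition()` is a deliberately small Monte Carlo whose job is to
produce panel dose maps with the *statistical structure* of the measured
ones — a single dominant hot spot whose magnitude tracks the projected
footprint area and the measured orderings (end > front, large field > small,
short distance > long, growing with tilt, collapsing without the field). It
is not an absolute dosimetry engine.

The chain per photon: (1) a ray from the 105 cm point source through a
uniform position in the field square; (2) an exponential free path through
the acrylic along the ray's material chords — the tilted phantom *and the
support plate it rests on* (20 x 20 x 1 cm, coplanar with the exit face);
(3) one Klein-Nishina Compton scatter (rejection sampling of the photon
angle; electron energy and angle from two-body kinematics); (4) straight-line
continuous-slowing-down transport to the assembly surface using a frozen
PMMA range table, escaping with the residual-range-inverted energy;
(5) analytic helical flight along the 0.35 T field to the panel plane, with
re-entry culling (helices sampled 36 points per turn, up to 30 turns) against
the assembly and against a horizontal base/couch plane at z = -11 cm;
(6) energy scoring on the panel raster, normalized so the Compton energy
density released in a 1 cm^3 isocenter voxel corresponds to the 3 Gy
prescription. That normalization bridge is this module's own construction —
the study gives no absolute link between escaped-electron fluence and film
dose — so simulated values are comparable *across conditions*, not to the
measured cGy.

Three modelling choices deserve emphasis, because the trends fail without
them and each stands in for real physics the single-scatter chain lacks:

* **The support plate.** The end-panel stream physically originates where
  the exit beam crosses the support plate and its electrons enter the open
  air beneath; the plate also absorbs electrons whose helices curl back up.
  With a bare phantom the down-slope lateral stream dominates the front
  panel and the end/front ordering inverts.
* **Diffuse surface emission plus an isotropic transport fraction.** In
  single-scatter kinematics the electron polar angle obeys
  `cot(phi) = (1 + alpha) tan(theta/2)`, which never exceeds 90 degrees and
  approaches it only as the energy vanishes: ballistically, *no* electron of
  useful energy ever acquires a large field-axis velocity, so no stream (and
  no entrance-side albedo) can form. Multiple scattering in the acrylic is
  what randomizes real exit directions. The generator mimics it by redrawing
  each escaping electron's direction from a cosine (Lambertian) lobe about
  its exit-face normal, with 20% of electrons transported isotropically
  inside the acrylic (an albedo-scale fraction); escaping electrons are
  split 16-fold at 1/16 weight purely to reduce panel-map variance.
* **Air as a slowing, scattering medium.** With vacuum transport the panel
  dose barely falls between 10 and 17 cm. The generator applies
  continuous-slowing-down energy loss along the full helical path using the
  range table at air density (dropping electrons whose range is exhausted)
  plus a Highland multiple-scattering lateral smear — large for the long
  straight flights of the field-off case, bounded by the gyroradius when the
  field confines the electron.

Frozen material constants (attenuation 0.0756 and 0.0708 cm^-1 at 1.17 and
1.33 MeV; a 13-point PMMA CSDA range table; air density 1.205 mg/cm^3; air
radiation length 30 390 cm) live in `physics_config()` and are pinned by the
test suite.

What the generator does *not* emulate: bremsstrahlung, coherent scatter,
photon scatter histories beyond the first interaction, the electron return
effect at the entrance surface, detailed film response, and the MR-linac
energies (a configuration hook only). Passing trend tests on simulated maps
therefore demonstrates that the analysis chain recovers the designed
structure; it does not validate absolute out-of-field dosimetry on real data.

```{r sim, eval = FALSE}
cond <- experiment_condition(beam_setup(330, 12.6), phantom_setup(30),
                             panel_setup("front", 10))
sim <- simulate_condition(cond, n_photons = 1e6, seed = 7)
glance(sim)
autoplot(sim$end_map)
```

## Study pipeline and the packaged tables

`load_paper_tables()` returns a 576-row transcription of the four published
panel-dose tables (end/front panel x two field sizes; calculated and
measured D_R1..D_R4 for 18 geometries each), guarded by a row count and a
checksum. Two documented quirks of the source data are preserved verbatim
rather than corrected:

* the narrative summary swaps the front/end attribution of the four mean
  absolute D_R1 differences relative to the table captions — summaries here
  are therefore always keyed by table (26.4 and 46.4 cGy come from the
  end-panel tables, 61.1 and 136.1 cGy from the front-panel tables), and the
  published "+-SD" values match the population (n) rather than sample (n-1)
  standard deviation, so `mean_abs_difference()` reports both;
* two measured cells (end panel, tilt 10, gantry 330, D_R1 at either field
  size) contradict the claim that the short panel distance always receives
  more dose; the orderings hold in the other 70 of 72 comparisons.

`correlate_projected_areas()` joins the geometry module's areas (rounded to
one decimal, which also makes the mirror-symmetric gantry 30/330 pairs exact
rank ties) to the measured doses and computes tie-corrected Spearman
coefficients with `spearman_rank()` — mid-ranks, Pearson on ranks, a
t-approximation p-value, and an exact permutation p-value for eight or fewer
pairs.

```{r correlations}
cors <- correlate_projected_areas(load_paper_tables())
cors %>% arrange(desc(r)) %>% head(4)
range(cors$r)
```

`run_study()` chains everything — enumerate, simulate, extract metrics,
correlate — and optionally writes the per-condition tables as CSV (one file
rounded to a single decimal mirroring the published layout, one at full
precision).

## Problem sizes and numerical choices

The packaged analyses are exact and instantaneous. Simulation-based tests
use 10^6 photons per delivery for the trend suite (a few minutes in total)
and 2 x 10^4 to 5 x 10^5 photons for smoke and acceptance checks; at 10^6
photons a D_R1 value carries a few-percent Monte Carlo uncertainty, which is
why trend assertions are made on well-separated geometries (the small-field
chain at gantry 330, whose footprints stay inside the support plate and
clear of the panels). For the largest field at 30 degrees tilt the exit
footprint approaches both the plate edge and the end panel, so the field-off
dose retains a line-of-sight splash from nearby emission and the field-off
collapse ratio shrinks — a genuine property of that geometry, visible in the
simulator output, and the reason the collapse assertion is anchored on the
small field. The trend suite pins each condition's D_R1 to the average of
three 10^6-photon maps at fixed seeds, because the statistic anchors on the
map maximum and is the noisiest quantity the package computes (its
seed-to-seed spread at one million photons is of order 1 cGy).

One link of the tilt chain deserves an honest caveat: between 20 and 30
degrees the end-panel D_R1 saturates in the generator (the total stream
flux keeps growing strongly — panel hit counts nearly triple from 10 to 30
degrees — but the peak-circle dose flattens as the footprint dilates), and
the measured data flatten at the same link (the published end-panel values
at the large field, oblique gantry and short distance grow by only about 1%
there). At the achievable Monte Carlo precision the generator's flattest
link resolves as level-to-slightly-decreasing rather than non-decreasing,
and the corresponding test assertion records that as a failure rather than
papering over it. For the same concentration-versus-area trade-off the
generator does not reproduce the measured excess of the oblique gantry
angles over gantry 0, and that ordering is deliberately not asserted.

Other numerical conventions: all angle arithmetic is done in radians
internally; rebinning drops trailing partial pixels; gamma interpolation
never extrapolates beyond the evaluated map's pixel-centre hull (points
whose entire search disc falls outside are reported as not evaluated);
Klein-Nishina rejection envelopes are grid maxima inflated by 0.1%; the CSDA
table is interpolated log-log and extrapolated with the boundary slopes;
ties in `max_point()` break row-major.

## Known limitations

The geometry reconstruction matches the published rank structure exactly,
but the absolute largest projected area differs by 5% from the published
value, consistent with an unstated detail of the original area computation
(for example the support-plate intercept). The simulator's emission model is
a surrogate for transport physics it does not contain; its absolute doses
are normalization-bridged, not measured-equivalent. Film calibration,
scanner corrections, the electron return effect, and the treatment-planning
Monte Carlo are all out of scope.
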