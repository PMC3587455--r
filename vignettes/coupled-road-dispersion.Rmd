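---
title: "Coupling a regional background with road-source dispersion kernels: methods and assumptions"
author: "aqcouple"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling a regional background with road-source dispersion kernels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqcouple)
```

## The problem

Epidemiological and exposure studies need hourly NO2 and O3 at the scale
of a street, but regional chemistry-transport models resolve kilometres.
`aqcouple` implements a one-way coupling: the regional model supplies the
urban background as an input field; a local dispersion model supplies the
road increment; the two are added on a fine 20 m grid and a minimal
NO–NO2–O3 chemistry accounts for the fast titration/photolysis adjustment
that happens between tailpipe and receptor. The coupling is "one-way"
because nothing is fed back into the background model — which is also why
a quantifiable double-counting error appears (see below).

## Road sources

Road centrelines are divided into consecutive 10 m arc-length sections;
the final remainder section is kept as its own (shorter) source rather
than merged, so the sections tile the polyline exactly. Each source takes
the midpoint and local bearing of its interval, folded into [0°, 180°)
because a road axis is undirected.

Emissions are NOx as NO2-equivalent mass (the UK inventory convention).
The primary NO2 fraction `f_no2` is interpreted as the mass fraction of
that NO2-equivalent total emitted directly as NO2; the remainder is NO,
whose mass rate carries the molar-mass ratio 30/46. On a mole (and hence
ppb) basis `f_no2` is then exactly the NO2 share of NOx, which is the
form the constrained-chemistry evaluation uses. Hour-of-week (168) and
month (12) scaling factors must each average to one so that temporal
scaling preserves the annual emission total.

## Dispersion kernels

The kernel of a road category is the concentration per unit emission
rate (1 g km⁻¹ s⁻¹) around a standard 10 m source, computed hourly on a
5 m lattice extending 225 m from the source (91 × 91 nodes) and truncated
to zero beyond 225 m radial distance. Six categories are used: open
roads, typical built-up streets, and four street-canyon orientations
(axes at 0°, 45°, 90°, 135°). One kernel per (category, hour) is shared
by every source of that category — the central performance idea: the
plume physics is evaluated once per category, then translated to ~10³–10⁵
source positions by table lookup.

The plume itself is a ground-level Gaussian with full ground reflection,

\[ \chi = \frac{Q}{\pi\,u\,\sigma_y\,\sigma_z}
   \exp\!\left(-\frac{y_c^2}{2\sigma_y^2}\right), \]

evaluated at ground level, zero upwind, with the 10 m line source
represented by an 11-point midpoint-rule quadrature of point sources
along the category axis. Lateral and vertical spread follow the Briggs
open-country curves for a Pasquill stability class diagnosed from
surface sensible heat flux and 10 m wind speed (strong daytime heating
and light wind → A–C; near-neutral or windy → D; nocturnal negative flux
→ E–F). σ_z is capped at the boundary-layer height. Design choices worth
stating explicitly:

* **Wind floor.** Calm hours use u = 0.5 m s⁻¹; the Gaussian form
  diverges as u → 0 and sub-0.5 m s⁻¹ anemometer readings are not
  meaningful hourly averages.
* **Receptors and releases at z = 0.** This matches the kerbside
  monitoring context; road traffic has no plume rise worth modelling.
* **Category-level bearing.** Because one kernel serves a whole
  category, the 10 m line is oriented along the category's nominal axis
  (the canyon axis for canyon categories, north for open/typical roads).
  A source whose true bearing differs from its category axis is
  approximated by the category plume translated to its midpoint. At 5 m
  kernel resolution and 20 m output resolution the orientation of a
  10 m line is a second-order effect; the approximation is shared by the
  direct evaluation path, so it does not contaminate the
  superposition-vs-plume verification.
* **Street canyons.** The canyon model is deliberately minimal: when the
  wind crosses the canyon axis by more than 30°, concentrations within
  half a street width (W/2) of the axis are multiplied by a
  recirculation factor `1 + c·H/W` (default c = 2; H = 25 m, W = 30 m
  for canyons, versus the 10 m / 20 m typical-road geometry, so the
  canyon enhancement strictly exceeds what typical geometry would give).
  Along-axis winds leave the kernel unchanged. The factor is monotone in
  the aspect ratio, isolated behind one function, and swappable for a
  full canyon flow model without touching the rest of the pipeline.

Mass conservation is the kernel's integrity check: the crosswind- and
vertically-integrated flux through any downwind transect (before the
225 m truncation) recovers the emitted 0.01 g s⁻¹ to well within 1 %,
by numerical quadrature against the analytic vertical profile.

## Superposition, snapping and the output grid

The output grid uses a lower-left origin, 0-based indices and half-open
cell extents; values refer to cell centres. Each source contributes to
all cells within 225 m, by bilinear interpolation of its category kernel
at the map-frame receptor offset, scaled by `rate × length / 10 m`.

Source midpoints are snapped to the kernel's 5 m lattice (anchored at
the grid origin) before application. Since 20 m cell centres also sit on
that lattice, every sampled offset lands exactly on a kernel node and
the interpolation is exact: the kernel-lookup field agrees with a direct
per-source plume evaluation at every cell to machine precision, which
the test suite verifies on 50-source instances. The ≤ 2.5 m positional
snap is within the kernel's own resolution. General (off-node) bilinear
sampling is implemented and tested as well; snapping is simply the
default positioning rule of the pipeline.

The per-cell **time of flight** is accumulated during superposition as
the concentration-weighted mean of straight-line travel times
(distance / u10) from each contributing source; cells with no road
contribution carry time zero by convention.

The coarse background (3 km cell centres) is downscaled by bilinear
interpolation of the four surrounding centres; outside the outermost
centres coordinates are clamped to the edge (nearest-edge
interpolation) — the scheme is exact on planar fields and can never
leave the coarse field's min/max range. Road increments are converted
from µg m⁻³ to ppb by the ideal gas law at the hour's temperature and
standard pressure, then added to the background NO and NO2; background
O3 passes through; NOx and Ox totals are recorded for the chemistry.

## Chemistry

Two reactions — NO + O3 → NO2 (rate k₁) and NO2 + hν → NO + O3 (rate
j) — both conserve NOx = NO + NO2 and Ox = O3 + NO2. The state therefore
reduces to one ODE,

\[ \frac{d[O_3]}{dt} = j\,(Ox - [O_3]) - k_1\,(NOx - Ox + [O_3])\,[O_3], \]

whose fixed point is the photostationary state, the physical root of a
quadratic in [O3] confined to [max(0, Ox − NOx), Ox]. Each grid cell is
advanced over its own time of flight by classical RK4 with substeps
capped at 1/20 of the fastest linearised relaxation time
(`j + k1·max(NOx, Ox)`); that keeps the truncation error below 10⁻⁶ ppb
(verified against a Richardson-extrapolated fine-step Euler oracle and
against a general-purpose ODE solver), while NOx and Ox are conserved to
machine precision *by construction*, since NO and NO2 are recovered from
the conserved totals after integration. Cells with zero time of flight
(no road influence) pass through untouched — the background is
deliberately not re-equilibrated, matching the add-then-react order of
the coupling.

Rate parameters are explicit stand-ins for a photolysis pre-processor:
k₁ follows the Arrhenius form 3.0·10⁻¹² exp(−1500/T) cm³ molec⁻¹ s⁻¹
converted to ppb⁻¹ s⁻¹ at ambient temperature and pressure (≈ 4.8·10⁻⁴
at 298 K), and j = j_max cos(θ)^e by default (j_max = 8·10⁻³ s⁻¹,
e = 0.8, zero for solar zenith ≥ 90°), with an hourly j series acceptable
in place of the parameterisation. This two-reaction relaxation ignores
VOC chemistry and O3 entrainment; it is adequate in the minutes-scale
near-road regime and in modest-photochemistry climates, and should not
be pushed beyond that.

## Double counting

The background model already contains the road emissions the kernels add
again. The error estimator releases each site's road NOx emission
(per-km rate × road length, length capped at 3 km to match the
background cell) into a well-mixed box of one background cell
(3 km × 3 km × 14 m). Two bracketing modes are provided because a box
average depends on what removes mass: **ventilated** (steady state of a
wind-flushed box, C = Q/(u·W·H), the default with the met series'
mean wind) and **static dilution** (C = Q·τ/V with τ = 3600 s). The box
average, converted to ppb, over the observed roadside NOx is the
percentage error. For a 3 km → 9 km cell change the static-dilution
ratio is the area ratio 9 — the upper bound on the improvement — while
the ventilated ratio is the width ratio 3; "up to a factor of 9" is thus
reproduced as an inequality, not a point estimate.

## Evaluation protocol

`eval_stats()` implements FAC2 (fraction of pairs with M/O in [0.5, 2]),
MB, NMB (ΣM−O / ΣO), RMSE and Pearson r, after pair-wise deletion of
missing values (no data-capture threshold; one is easy to apply
upstream). Two conventions the protocol leaves open are fixed here:
pairs with O = 0 count inside FAC2 only if M = 0; and r is reported as
missing for degenerate (constant) series rather than erroring. RMSE is
reported in concentration units (ppb). Confidence bands on temporal
profiles use the normal approximation 1.96·sd/√n per bin (hour of day,
day of week, month, or hour of week with Monday 00:00 first).

The constrained-NOx evaluation isolates the chemistry scheme: per hour
the modelled NOx total is pinned to the observation, split into NO and
primary NO2 by the inventory f-NO2, added to the background O3 (and
optionally background NO/NO2), advanced over the time of flight, and the
modelled NO2 regressed on observed NO2. Both readings of "constrained"
are implemented: `"total"` (default — the observed NOx is the
post-combination total; the road share is observation minus background)
and `"increment"` (the observation is treated entirely as road
increment). R² is from OLS with intercept (equivalently the squared
Pearson correlation), a choice the protocol does not specify and which
is therefore stated here.

## Synthetic fixtures: what they do and do not show

The generators emulate the *structure* of the real inputs — mixed road
orientations across all four canyon classes, log-uniform emission rates
(0.05–2 g km⁻¹ s⁻¹ for network links), f-NO2 uniform in [0.16, 0.26],
diurnal wind/heat-flux/boundary-layer cycles, a smooth anticorrelated
NO2/O3 background dome, lognormal observation noise with seeded gaps.
The double-counting site records use typical major-road emission
magnitudes (0.02–1 g km⁻¹ s⁻¹) against roadside NOx observations of
80–400 ppb, the regime in which the estimator is meant to operate. All
randomness derives from one integer seed, with an independent stream
offset per generator so each input class is reproducible on its own.

The default desk-scale scenario is a 2 km × 2 km domain, 100 × 100 fine
cells at 20 m, ~50 links (~10³ sources) and 168 hours; the full run
takes about a minute on one core, and the end-to-end closure test —
pipeline output evaluated against its own noise-free pseudo-observations
must return FAC2 = 1, MB = 0, r = 1 — exercises every module boundary.

What passing these tests does **not** show: that the Gaussian/canyon
kernel reproduces a real dispersion model; that the synthetic scenario
matches any city's spatial statistics; or that the headline evaluation
numbers of a real application (which require a real emissions inventory
and monitoring network) are reproduced. The tests verify the coupling
machinery — conservation, linearity, exactness of the lookup path,
convergence of the chemistry, correctness of the statistics — which is
precisely the part that transfers.

## Numerical choices, edge cases, limitations

* Wind floor 0.5 m s⁻¹ everywhere a wind speed divides something
  (plume, time of flight, ventilated box).
* Kernel truncation at exactly 225 m radial distance; beyond it the
  background alone speaks.
* Canyon-axis ties at 22.5° between orientation classes break toward
  the lower axis angle (deterministic).
* Degenerate inputs are rejected loudly: zero-length polylines, negative
  rates, empty coarse fields, observation sites off the grid,
  non-positive roadside observations in the double-count ratio.
* Hours with missing meteorology are skipped and logged in the run
  report; the run continues.
* Bilinear edge behaviour is clamping (nearest-edge), a stated choice
  where the scheme itself is silent.
* Not modelled: plume rise, deposition, elevated/buoyant sources, VOC
  chemistry, conservative regridding, two-way feedback to the background
  model, geographic CRS handling (inputs must arrive in projected
  metres).
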