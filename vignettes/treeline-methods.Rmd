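---
title: "Simulating Siberian treeline migration: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating Siberian treeline migration: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

tundraline studies how fast the latitudinal treeline of the Siberian
tundra–taiga ecotone tracks climate warming, and what that means for the
tundra area squeezed between the advancing forest and the Arctic Ocean. It
is an individual-based, spatially explicit model of a single
*Larix gmelinii*-like species on a long, narrow latitudinal transect,
driven by monthly climate forcing constructed for 501–3000 CE, together
with the downstream accounting that turns simulated stand structure into
treeline positions, migration rates, climate-analogue comparisons and
tundra-area time series.

This vignette is the package's methods reference: the model and its
assumptions, the parameters that matter, what the synthetic data generators
emulate, and the numerical and design decisions taken where the problem was
genuinely open.

## The transect world

Space is a strip `transect_length_km` long (y, metres, increasing poleward
from a treeline field site towards the shoreline) and `transect_width_m`
wide (20 m by default). The east–west margins wrap: a seed blown across the
western edge re-enters from the east, so the strip represents a slice of a
laterally continuous treeline. The poleward margins do not wrap — seeds
flying past the shoreline or back into the hinterland are lost.

Climate is defined at nodes spaced 10 km apart along the transect. Each
tree senses the climate of its own y-position by linear interpolation
between the two flanking nodes; positions outside the node span clamp to
the nearest node.

## The yearly life cycle

Each simulated year invokes, in a fixed order: environment update, growth,
seed dispersal, seed production, establishment, mortality, ageing.

**Environment.** Every tree deposits a triangular influence kernel of
radius `r0_crown + r_per_h * height`, weighted by its basal diameter; the
*density index* of a tree is the summed influence of all neighbours at its
position. This is the exact (zero-cell-size) limit of a gridded deposition
map; `update_environment()` also exposes the gridded map (0.2 m cells by
default) for inspection, while the simulator evaluates the kernels exactly
to avoid building a 25-million-cell raster on an 800-km transect. The
active-layer depth follows a Stefan-type simplification,
`edaphic_factor * sqrt(NDD0)` (cm), where NDD0 is the annual sum of
daily-interpolated temperatures above 0 °C.

**Growth.** The potential basal-diameter increment is
`g_max * ramp(TJul10) * ramp(NDD0_10) * ramp(ALD)`, a product of saturating
ramps in the trailing 10-year means of July temperature (zero at 9.0 °C,
maximal at 11.5 °C) and net degree days (zero at 550, maximal at
900 °C·day), times a reduction when the active layer is shallower than
25 cm. Realised growth discounts the potential by
`exp(-c_growth * density_index)`; diameters never shrink. Height follows
the saturating allometry `h = h_max (1 - exp(-k_allom * d))` (28 m
asymptote; 1.3 m at a basal diameter of about 2.5 cm), and breast-height
diameter grows once height exceeds 1.3 m. Trees taller than 1.3 m are
*stems*, the unit of all density bookkeeping.

**Dispersal.** Seeds ripen on the parent for one year and are then released
individually: each samples one wind observation (Weibull speeds, von Mises
directions around the prevailing direction) and flies ballistically,
`distance = release_height * speed / fall_velocity`, multiplied by a
median-one lognormal turbulence factor (`turb_sdlog = 1.6`). The lognormal
factor gives the monotonically decreasing heavy tail that long-distance
dispersal by gusts and updrafts produces; the median distance stays at the
textbook ballistic value, which is what the dispersal tests check
analytically. Rare kilometre-scale jumps from this tail, followed by
maturation of the outpost trees, are what carries the migration front.

**Production.** A tree reproduces after reaching its individually drawn
maturation height (normal, mean 2.2 m, sd 0.6 m, floored at 1 m). The
yearly cone count has a Poisson marginal with mean
`fec_max * d/(d + fec_d_half) * ramp(TJul) * exp(-c_fec * density_index)`
— increasing in size, scaled by current-year July warmth, and discounted
by competition. The surface function draws counts as `qpois(u, lambda)` so
that for a fixed random state the count is monotone in the mean, making
the competition-monotonicity property testable pathwise.

**Establishment.** Every ground seed germinates independently with
probability `germ_max * ramp(TJul)` (current-year weather, as germination
is an annual weather gamble rather than a climate response). Germinated
seeds become 0.05-cm seedlings in place.

**Mortality.** A tree's death probability is one minus the product of
survival factors — juvenile vulnerability (decaying with size), cold
climate (ramp in the 10-year July mean below 9 °C), drought (ramp in the
drought index below 0.05), density-dependent thinning of small trees, and
senescence past 60 % of the 400-year age limit — floored at the background
rate of 0.004. Seeds die at one constant rate (0.5) whether on the tree or
on the ground, and are removed at the species seed age limit (2 years).

The functional forms and constants above are this package's own
parameterisation: the study this design follows reports which processes
exist and what drives them, but not their equations, so `larch_params()`
defines explicit forms with every constant in one list, calibrated once so
that the qualitative behaviours hold — a stand equilibrates under constant
climate, the treeline sits inside the transect under the modern synthetic
climate, fronts advance under warming with a realistic century-scale lag,
and established stands persist through cooling. The calibration targets
behaviours, not any published number.

The drought index deserves a note: it is defined as annual precipitation
over growing-season degree days (`p_year / max(NDD0, 1)`), a stand-in for
an unstated formula. Its stress threshold is set low (0.05) so that only
genuinely arid conditions kill trees: with precipitation held at the
modern climatology, strong warming inflates degree days and would
otherwise starve hot scenarios of forest entirely, which contradicts the
warm-scenario forest expansion this model family exhibits.

## Boundary conditions and spin-up

Growth is initiated by 100,000 seeds per year (desk scale: divided by 100)
during the first 50 spin-up years, placed from the southern boundary with a
negative-exponential kernel (mean 5 km, so the spin-up population spans the
whole climatically viable zone rather than a narrow southern band).
Extinction is prevented by a permanent background rain of 1000 seeds per
year per 200 km of transect (uniform along the transect; the count is
deterministic and exactly proportional to length), and the first 500 m
receive a hinterland seed rain scaled by the climate-dependent growth
factor at the southern boundary, standing in for the unsimulated forest to
the south.

Runs start with a 200-year stabilization phase. Its climate loops a fixed
30-year window: the 30 years immediately *preceding* the first simulated
year when the forcing provides them. Using the pre-simulation window (1970–
1999 for runs starting in 2000) rather than the first 30 simulated years
keeps spin-up climate identical across scenarios, so every scenario of an
experiment starts from the same year-2000 baseline stand (identical down to
the RNG stream, since scenarios share the pre-2006 forcing); spin-up length
was chosen so stand density and the treeline position plateau well before
the transient begins.

## Climate forcing construction

`build_forcing()` chains six steps, each usable on real data through the
same tabular interfaces:

1. An instrumental-era monthly series per 10-km node (synthetic stand-in
   for a gridded product; see below).
2. An annual proxy series (ice-core stand-in, nominally 934–1998) whose
   pre-industrial (< 1800 CE) variability is resampled in 25-year
   contiguous blocks, with replacement, to cover 501–1900. Block joins are
   not smoothed — the reference's interannual variability is the signal
   being transplanted, and smoothing would dampen exactly that.
3. Node-wise OLS calibration of annual mean temperature and annual
   precipitation on the proxy value over the 1901–1998 overlap; the fits
   applied to the extended proxy give annual targets for 501–1900. A
   zero-variance proxy is a refusal, not a silent fallback.
4. Monthly assembly: 15-year instrumental blocks are resampled and each
   source year's months shifted so its annual statistics meet the target —
   additively for temperature, multiplicatively for precipitation
   (precipitation handling is unstated in the source design; a
   multiplicative scaling preserves non-negativity and the within-year
   shape, an additive shift would not).
5. Scenario anomalies 2006–2300: logistic ramps rebased to zero at 2005
   and passing exactly through each scenario's July warming median at 2100
   (+1.8 °C RCP2.6, +2.1 °C RCP4.5, +5 °C RCP8.5, relative to 1971–2000),
   reaching about +0.5, +3.1 and +14 °C by 2300. RCP2.6 declines linearly
   after its 2100 peak. RCP2.6* is *constructed* as half the RCP2.6
   anomaly path — its realised 2100 median is therefore +0.9 °C, and the
   +1.2 °C sometimes quoted for it is kept only as metadata (the two
   published characterisations of this scenario are mutually inconsistent;
   the half-rate construction is the one the package guarantees).
   Anomalies apply uniformly to all months, so the July median equals the
   all-month anomaly. The printed "+144 °C" for RCP8.5 at 2300 in the
   source material is treated as a typo for ≈ +14.4 °C.
6. Extension: 2301–2500 continues the linear trend fitted to the
   2100–2300 anomaly; 2501–3000 either replays the 1901–1978 monthly data
   in a loop ("20th-century cooling") or copies the 2301–2500 block
   ("continued"). The cooling replay tiles a 78-year block into a 500-year
   window; the remainder (500 mod 78 = 32 years) makes replayed July means
   agree with the 1901–1978 means only up to the sampling error of a
   32-year sub-block, about 0.005 °C under the generator's damped gridded
   variability — within the 0.01 °C agreement the package promises.

Two pseudo-scenarios complete the set for controlled experiments:
`control` (zero anomaly) and `step` (a constant anomaly, default +1.5 °C,
switched on in 2050), with `step` + cooling replaying 20th-century climate
after 2500 like any other scenario.

Tuned regional lapse offsets (`region_offsets()`) for Taimyr, Buor Khaya,
Kolyma and Chukotka shift January and July temperatures (other months by
cosine interpolation over the annual cycle — the sources state offsets
only for the extreme months) and rescale annual precipitation
multiplicatively.

## The synthetic generators, and what they do not emulate

`synth_instrumental()` produces a seasonal cycle (July maximum, January
minimum) plus a regionally shared AR(1) interannual anomaly (sd 0.3 °C,
lag-one correlation 0.5) and shared monthly weather noise (sd 0.25 °C);
July temperature falls linearly poleward. The interannual variability is
deliberately modest and perfectly correlated across nodes, as in a
station-sparse gridded product that relaxes towards climatology; real
station series at the Siberian treeline are noisier (July sd above 1 °C)
and partially decorrelated over hundreds of kilometres. Precipitation is a
summer-peaked climatology with multiplicative gamma noise, uncorrelated
with temperature — so the proxy-precipitation calibration (step 3) has,
by construction, almost no signal to find, and pre-industrial
precipitation is essentially climatological. The proxy generator couples
the proxy value linearly to transect-mean annual temperature (slope 0.5
per °C, residual sd 0.3) so the temperature calibration does recover a
real relation.

Passing tests on these generators therefore demonstrate the machinery —
block resampling, calibration, assembly, scenario appending, the
simulator's response to a warming gradient — not fidelity to any real
region: there is no topography, no maritime/continental contrast, no
precipitation trend, no co-variability between warmth and wetness, and the
desk transect's poleward gradient (9 °C per 100 km) is steepened roughly
ninefold against the real ~1 °C per 100 km so that a 50-km transect spans
the whole forest-to-tundra transition. Real forcing can be substituted at
every step through the documented tabular interfaces.

## Treeline metrics

Stand snapshots every 10 years are reduced to stems-per-hectare profiles
in 1-km bins (half-open, south-inclusive; bin length is a visible argument
and sits between the 10-km node spacing and the individual scale). From a
profile:

* **single-tree stand**: northern edge of the northernmost bin anywhere
  with ≥ 1 stem ha⁻¹;
* **treeline stand**: northern edge of the contiguous run of bins
  ≥ 1 stem ha⁻¹ connected to the southern boundary ("continuous forest
  cover" made operational as boundary-connected contiguity; a gap of one
  full bin breaks the run);
* **forestline stand**: northern edge of the northernmost bin
  > 100 stems ha⁻¹.

If no bin reaches 1 stem ha⁻¹ all three are NA (absent, not zero). The
ordering forestline ≤ treeline ≤ single-tree holds whenever all are
defined.

The **climate analogue** is the along-transect position whose July
temperature equals the July temperature at the year-2000 treeline — where
the treeline would sit if it tracked its isotherm instantaneously. The
July series is smoothed with a trailing 10-year mean before the isotherm
is located (the tracking is nominally instantaneous, but unsmoothed
interannual noise makes the analogue jitter by tens of kilometres on a
shallow gradient, swamping the signal); the position is found by linear
interpolation between nodes, scanning from the north, and clamped to
[0, shoreline].

The **lag/overshoot trajectory** rescales both the simulated treeline and
the analogue to fractions of the corridor between the year-2000 position
and the shoreline, averaged in 25-year segments. Below the diagonal the
treeline lags its climate; above, it overshoots (it occupies positions the
current climate alone would not grant it, by persistence of established
trees). The equilibrium-crossing year is the first segment at or above the
diagonal after the initial lag phase; a trajectory that starts on the
diagonal and never lags reports its first segment.

Migration rates are first differences of decadal positions, anchored at
the year-2000 baseline. Fig.-2-style trajectory plots
(`autoplot()` on a `lag_trajectory`) and area time series
(`autoplot()` on a `tundra_series`) are built in.

## Tundra-area accounting

The `area` module works on an equal-area planar corridor: land between a
treeline polyline (southern boundary) and a coastline, both
piecewise-linear in the west–east coordinate, with four transect anchors
along the treeline and region boundaries midway between anchors (end
regions extend to the corridor ends). Per-region treeline advances are
interpolated to stations every 10 km of treeline arc length
(inverse-distance weights of the two flanking anchors; end stations take
the nearest anchor), buffered poleward, clipped at the coast, and
integrated exactly — the forested extent is the integral of the
piecewise-linear advance profile, evaluated on the union of all
breakpoints and intersection points, so rectangle closed forms are
reproduced to 10⁻⁶ relative and the returned polygon's shoelace area
equals the integral. The extent is recomputed each decade from the current
advances rather than accumulated as a running union, so tundra recovers
when the treeline recedes — a ratchet union would forbid the partial
recovery that cooling scenarios produce.

This corridor representation was chosen over a general polygon engine
deliberately: no polygon-buffering geometry library is part of the
package's dependency set, and for the corridor-class geometries the module
defines, the piecewise-linear construction is exact where a general
buffer-and-union pipeline is approximate. Real coastline/treeline data
enter through the same vertex-table (or WKT) interface after equal-area
projection upstream; strongly re-entrant coastlines that a poleward
(+y) buffer cannot represent are outside this module's scope.

## The experiments

`full_plan()` records the study-scale setup: four regions (Taimyr,
Buor Khaya, Kolyma, Chukotka; corridors of 573, 137, 146, 626 km;
simulated on 800-km transects for the two long corridors and 300-km for
the two short — the mapping of the two stated transect lengths to regions
follows corridor length), eight scenarios (four RCPs × continued/cooling),
three repeats, 10-year cadence, 2000–3000 CE. Executing it at that scale
is configuration, not a package default.

`desk_plan()` is the default experiment actually run by the tests and the
acceptance script: one synthetic region, 50 km × 20 m transect, six
climate nodes (0–50 km, so the interpolation span covers the transect
end), 600 years (2000–2600), three repeats, boundary seed counts divided
by 100, and nine scenarios — control, step (+1.5 °C at 2050) in continued
and cooling variants, the four RCPs continued, and cooling twins for
RCP4.5 and RCP8.5. These sizes were chosen so the full experiment (27
individual-based runs of 800 model years each) completes in minutes on a
single core while keeping at least three climate nodes between the
year-2000 treeline and the shoreline. The desk experiment exhibits the
three headline phenomena — an early-century migration lag behind the
climate analogue, eventual overtake under sustained warming, and
persistence of the advanced treeline (overshoot) through cooling — which
is precisely what the acceptance tests assert.

All randomness derives from one master seed: every (region, scenario,
repeat) combination hashes to its own stream seed via a fixed integer
hash (`derive_seed()`), and each repeat runs as a single R RNG stream with
the process order fixed by the code, so the same master seed reproduces
every table bit for bit, and dropping a scenario from a plan does not
shift any other scenario's results.

## Numerical choices

* Daily temperatures come from linear interpolation between mid-month
  anchors on a 365-day year, periodic across the year boundary (December
  and January of the *same* year anchor the wrap; the daily scheme is a
  package choice, stated rather than inherited).
* Trailing 10-year climate means are computed over the simulated year
  sequence (spin-up loop included), with shorter windows at the start.
* Position comparisons inherit the 1-km bin resolution; scenario-ordering
  checks therefore allow one bin's worth of area
  (corridor width × 1 km) as tolerance.
* Ties in position extraction: thresholds are ≥ 1 (treeline/single-tree)
  and strictly > 100 (forestline) stems ha⁻¹; positions are the bin's
  northern edge (half-open bins, south-inclusive).
* The competition kernel is evaluated pairwise in C++ with a y-sorted
  sliding window (cost proportional to population × local neighbourhood);
  the seed life cycle (release, flight, germination draw, mortality,
  ageing) runs as two single-pass C++ kernels over the seed arrays using
  R's RNG, so runs remain reproducible and platform-stable.
* Degenerate inputs refuse loudly: forcing gaps abort before a simulation
  starts, a zero-variance proxy aborts calibration, a shoreline equal to
  the baseline treeline aborts trajectory rescaling, and precipitation
  rescaling that would cross zero clamps at zero with a warning.

## Known limitations

Fire, permafrost-thaw feedbacks (thermokarst, waterlogging), mycorrhiza,
herbivory, interspecific competition with shrubs, and albedo feedback are
not represented — consistent with the modelling tradition this package
follows, which treats them as implicit or out of scope. A single species
is simulated. The synthetic climate omits topography and
temperature–precipitation co-variability, and the desk-scale gradient
steepening means desk-scale migration rates are not comparable in absolute
terms to published full-scale rates; the published headline numbers
(remaining tundra of 5.7 %, 32.7 %, 54.9 %; year-2000 advances of +66,
+88, +98, +16 km; rates up to 30 km per decade) were produced with real
forcing, real geometry and 800-km transects, and are recorded here as
context for the full-scale configuration, not as desk-scale expectations.
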