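---
title: "Methods: equity-weighted heat-stress metrics for urban overheating mitigation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equity-weighted heat-stress metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatequity)
```

## The problem

Cities deciding between cool roofs, green roofs and street trees usually ask
which strategy cools the most.  That question has a well-known blind spot:
the strategy that cools a city's *average* pedestrian the most is not
necessarily the one that cools its most *vulnerable* residents, because the
physical levers of each strategy (roof area for rooftop interventions,
street planting space for trees) are themselves correlated with neighborhood
vulnerability.  This package implements a metric chain that makes the equity
dimension explicit, together with everything needed to exercise it
end-to-end on synthetic inputs: heatwave detection from station climatology,
a Beer's-law street-tree radiation scheme, the UTCI thermal-comfort
polynomial, and the vulnerability-weighted heat-stress statistics.

## The metric chain: HS, DCH, ADCH, VDCH

Pedestrian thermal comfort is measured by the Universal Thermal Climate
Index (UTCI).  With a heat-stress onset threshold of 26 °C (32 °C is
supported for sensitivity analysis), the hourly heat-stress exceedance is

$$\mathrm{HS}_t = \max(\mathrm{UTCI}_t - 26,\; 0),$$

the daily cumulative heat stress is the sum over one local day,
$\mathrm{DCH} = \sum_{t=0}^{23} \mathrm{HS}_t$ (24 hourly samples; a 25th
sample would double-count midnight), and ADCH averages DCH over all
simulated days of all heatwave events of one experiment.  The
equity-weighted comparison of experiment $i$ against the control is

$$\mathrm{VDCH}_i = w \cdot \mathrm{SVI} \times
  \frac{\mathrm{ADCH}_i - \mathrm{ADCH}_{CTL}}{\mathrm{ADCH}_{CTL}}
  \times 100\%,$$

with $w = 1$ by default so vulnerability and heat-stress change count
equally.  Negative VDCH is improvement; the SVI weighting deliberately
discounts cooling delivered to resilient neighborhoods — a 1 % ADCH
reduction where SVI = 1 is "worth" a 10 % reduction where SVI = 0.1.
Cells with zero control ADCH have nothing to mitigate; their VDCH is set to
0 with a warning rather than propagating a division by zero.

Two small inverters make DCH percentages tangible: `duration_equivalent()`
converts a percent DCH reduction into minutes of exposure removed at a held
UTCI level, and `cooling_equivalent_pct()` converts a sustained cooling into
the percent of DCH it removes.  For a day pinned at UTCI 40 °C
(DCH = 336 K·h), a 2 % reduction is 28.8 minutes, or equivalently cooling
all 24 h by 0.3 K.

## Street-tree radiation scheme

Trees enter through shortwave interception.  With clumping coefficient
$\Omega$, leaf-orientation factor $G$, leaf area index $L$ and solar zenith
$\varphi$, the flux under the canopy is
$SW_{tree} = SW_{sun}\exp(-\Omega G L / \cos\varphi)$, the cell's street
receives $SW_{ground} = (1-tc)\,SW_{sun} + tc\,SW_{tree}$ for tree cover
$tc$, and the intercepted energy $enloss = SW_{sun} - SW_{ground}$ is split
by a fixed Bowen ratio $\beta$ into sensible
($\beta\,enloss/(\beta+1)$) and latent ($enloss/(\beta+1)$) heat, so the
two always sum to the interception exactly.  Defaults are
$\Omega = G = 0.5$, $L = 3$ (a reasonable LAI for evergreen urban street
trees), $\beta = 2$ (a Houston-like climate), all exposed in
`canopy_params()`.  Net longwave exchange of the foliage is taken as zero,
and energy storage in leaves and wood is neglected.

Two conventions are worth stating.  First, at $\varphi \ge 90°$ the
$1/\cos\varphi$ path length diverges; transmission and interception are set
to 0 there (no direct beam).  Second, the transmission is applied to the
total ground-level shortwave, not only its direct component — the scheme is
written for instantaneous hourly fluxes and does not carry a
direct/diffuse split.

The geometry that maps ground-level shortwave to the mean radiant
temperature a pedestrian feels inside a canyon is out of scope; the tree
scenario instead uses a linear response, `mrt_adjustment()`:
$\Delta \mathrm{MRT} = -s \cdot \Delta SW_{ground}$.  The sensitivity $s$
is a free parameter.  Its default (0.066 K per W/m²) is calibrated so that
the high-intensity tree scenario produces an urban-average daytime UTCI
reduction in the 0.2–0.3 K range under the default synthetic forcing,
between the cool-roof and green-roof responses; for orientation, a 200 W/m²
shading reduction at $s = 0.025$ gives −5 K, the order observed for midday
road surfaces under a canopy densification.

## UTCI evaluation

UTCI is evaluated with the published sixth-order polynomial operational
approximation — 210 monomials in air temperature, wind speed, the
radiant excess $T_{mrt} - T_a$, and vapour pressure — with coefficients
vendored verbatim.  Relative humidity is converted to vapour pressure with
the ITS-90 saturation formulation.  Inputs are clamped to the polynomial's
published validity domain ($T_a \in [-50, 50]$ °C, $v_a \in [0.5, 17]$ m/s,
$T_{mrt}-T_a \in [-30, 70]$ K, vapour pressure ≤ 50 hPa) with a warning;
the polynomial oscillates outside it.  The implementation evaluates the
terms from precomputed power tables; the test suite checks it against an
independent scalar term-by-term evaluation of the same published table on
10⁴ random in-domain points at 10⁻⁴ K.

Within a grid cell, pedestrians experience a distribution of wind speeds.
The construction of that subgrid distribution is not specified by the
upstream canyon model this package abstracts; we default to a lognormal
centred (in median) on the cell wind with log-scale spread 0.3, exposed as
`wind_dist`.  UTCI evaluated at the 10/50/90 % wind quantiles gives the
cool-spot, midrange and hot-spot values; the three are sorted, since in hot
conditions more wind means less heat stress and the hot spot is the
low-wind tail.  All downstream metrics use the midrange (p50) value, which
represents average conditions.

## Heatwave detection

Detection follows a station-climatology cascade.  The threshold is the
plain seasonal (June–August) mean of the across-station-averaged daily
maximum temperature — applied to a 30-year Houston-like record this sits
near 32.1 °C.  Days strictly above threshold are hot days; maximal
consecutive runs are episodes; episodes of at least 6 days ("extending
beyond 5 days") are heatwave events.  Severe events additionally require a
peak daily maximum strictly above 35.1 °C and duration strictly above 14
days.  All inequalities are strict, reading "surpassing"/"beyond"
literally.  A WMO-style check (`wmo_check()`) verifies a run of at least 6
days more than 5 K above the long-term average daily maximum.  Simulation
windows span ±48 h around the event peak pinned at 21Z (15:00 Central
Standard Time).  Missing days fail fast by default (`max_missing_frac = 0`);
station records are averaged before thresholding, not detected per-station.

## What the synthetic generator emulates — and what it does not

`gen_urban_grid()` draws an abstract city: SVI uniform on [0, 1] (it is a
rank index by construction); street fraction rising linearly with SVI from
just under 30 % (SVI < 0.1) to about 40 % (SVI > 0.9), with roof fraction
its complement; control tree cover decreasing with SVI around a 17 % mean;
and a tree-equity-targeted cover addition increasing with SVI (mean 14 %,
so the full addition lifts mean street tree cover to about 31 %).  Gaussian
scatter is added to each relation and clipped to physical ranges.

`gen_met_forcing()` produces sinusoid-plus-Gaussian-noise diurnal cycles:
2-m temperature peaking at 15:00 local, humidity in antiphase, an idealised
solar elevation (`sin(π(h−6)/12)`, exactly zero outside 06–18 h), and MRT
exceeding air temperature in proportion to solar elevation.  The
"heatwave" preset (default) gives daily maxima near 37.5 °C, safely above
the severe-event 35.1 °C criterion, and afternoon midrange UTCI well above
the 26 °C onset, so DCH is informative.

The rooftop strategies have no closed-form link from albedo or coverage to
the 2-m fields — in the full system that response is emergent from the
urban canopy physics — so they are represented by *linear surrogates*:
daytime 2-m cooling proportional to roof fraction × strategy magnitude ×
instantaneous solar forcing, with a humidity rise of 2.5 %/K of cooling,
and for green roofs an additive nighttime warming term (heat stored by the
soil layer by day, released after dark) active only when shortwave is zero.
The tree strategy perturbs only MRT, through the canopy scheme scaled by
street fraction.  Surrogate sensitivities are calibrated once so the
high-scenario urban-average daytime UTCI reductions fall in the 0.2–0.3 K
range with cool roofs strongest, then trees, then green roofs.

Passing tests on this synthetic city therefore demonstrate that the metric
chain, the canopy scheme and the detection cascade are implemented
correctly and that the equity ordering is recovered *given* the assumed
structure (tree benefits rising with SVI, roof benefits falling with SVI).
They do not validate mesoscale physics: no sea breeze, no advection, no
urban-rural circulation, no LCZ-resolved morphology, no tree drag on wind,
no foliage heat storage, and no geolocated rasters — cells are abstract.
One known asymmetry: because the green-roof surrogate's only nighttime
mechanism is warming, its nighttime VDCH is slightly positive here, whereas
full simulations can show nighttime improvement; daytime and whole-day
rankings are the meaningful outputs of the surrogate pipeline.

## Numerical and design choices

- Day/night split for period-resolved metrics: an hour is daytime iff
  `sw_down > 0`; configurable upstream of the metrics, which only see hour
  masks.  Sub-numerical solar elevations at sunrise/sunset are treated as
  dark so the split is exact.
- SVI curves use decile bins over the full [0, 1] range; the extreme bins
  coincide with the SVI < 0.1 / > 0.9 classes.  Empty bins are reported as
  missing, never zero.  Bin summaries are medians with interquartile ranges.
- DCH requires exactly 24 hourly values; ADCH requires a complete
  day-by-event table.  Both fail loudly rather than imputing.
- Every generator takes an explicit integer seed and is bit-reproducible;
  the suite runner derives per-event seeds as `seed + event`.
- Default problem sizes: the shipped examples and tests run suites of
  150–500 cells over 1–2 events of 1–3 days, which resolves the urban-mean
  VDCH differences between strategies while keeping a full seven-experiment
  suite in seconds.

## Limitations

The surrogates are calibrated, not derived: absolute VDCH magnitudes from
synthetic runs characterise the package's default scenario strengths, not
any particular city.  Applying the chain to real data means supplying real
forcing per scenario (e.g. from an urban-canopy model run) as a
`met_field`, real urban descriptors as an `urban_grid`, and using the same
metric functions unchanged.
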