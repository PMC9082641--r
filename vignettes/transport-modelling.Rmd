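---
title: "Modelling prehospital stroke transport with fast-dispatch helicopters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling prehospital stroke transport with fast-dispatch helicopters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helistroke)
options(helistroke.verbose = FALSE)
```

## The problem

A patient with suspected large-vessel occlusion (LVO) stroke can be driven
to the nearest primary stroke centre (PSC) for intravenous thrombolysis
(IVT) and transferred onward for endovascular therapy (EVT) if needed — the
*drip-and-ship* strategy — or taken directly to a comprehensive stroke
centre (CSC) that offers both treatments — the *bypass* (mothership)
strategy. Bypass shortens time to EVT but risks delaying IVT for the
majority of patients who turn out not to have an LVO. In *intermediate
density* regions — where less than half the population lives at rural
densities (< 300 persons/km²) and less than half at urban densities
(> 1,500 persons/km²) — distances are too short for classical air-retrieval
logistics yet long enough that ground bypass meaningfully delays IVT.
Helicopters with fast dispatch, launched simultaneously with the ground
ambulance, change that trade-off.

`helistroke` models this decision problem end to end on synthetic
geography: it generates a country-scale region with the statistical
structure of the Danish setting (98 municipalities, 5.8 M inhabitants,
43,000 km², 7 PSCs, 3 full-time CSCs, one PSC that operates as a CSC in
working hours, 4 helicopter bases), composes the prehospital time chain
under four transport configurations, simulates helicopter fleet capacity
with a discrete-event model, and summarizes the results.

## The time-chain model

All times are minutes. The fixed components (`delay_table()`) are
registry-derived medians:

| component | min | | component | min |
|---|---|---|---|---|
| onset to call | 30 | | door-to-needle | 27 |
| ambulance dispatch | 1 | | door-to-groin, bypass | 68 |
| ambulance response | 8 | | door-to-groin, after transfer | 41 |
| on scene | 20 | | door-in-door-out at PSC | 60 |
| helicopter dispatch | 5 | | helicopter loading | 11 |

The four configurations compose as:

* **Drip-and-ship (ground)** — IVT at the PSC:
  $T_{IVT} = 30 + 1 + 8 + 20 + g(\text{scene},\text{PSC}) + 27$;
  EVT adds door-in-door-out, the transfer leg and the post-transfer
  door-to-groin: $T_{EVT} = T_{IVT} - 27 + 60 + t_{transfer} + 41$.
* **Drip-and-ship (helicopter transfer)** — identical IVT; the transfer
  leg is helicopter dispatch + flight from the base nearest the PSC +
  flight PSC→CSC.
* **Bypass (ground)** — the same prefix driven to the CSC, with
  door-to-groin 68 in place of door-to-needle for EVT.
* **Bypass (helicopter)** — ambulance and helicopter are dispatched
  simultaneously. The helicopter reaches the scene $5 + a(\text{base},
  \text{scene})$ minutes after the call, but air transport cannot start
  before the 28-minute readiness floor (ambulance response 8 + on-scene
  preparation 20); loading takes 11 more:
  $t_{dep} = \max(5 + a, 28) + 11$, then flight to the CSC and the door
  delays.

Two deliberate reproductions of the source arithmetic are worth naming.
First, the ground prefix uses dispatch + response ($1+8$) while the
28-minute floor uses response + on-scene ($8+20$) — the published figures
are internally inconsistent on whether the 1-minute dispatch is inside the
8-minute response, and we reproduce them as printed rather than
harmonizing. Second, the 11-minute loading is taken as *non-overlapping*
with the 28-minute floor (the patient is prepared, then loaded); the
alternative overlapped reading would shave up to 11 minutes off every
helicopter chain, and the non-overlapping one is the conservative choice
consistent with preparation *followed by* departure.

Helicopter dispatch is considered worthwhile only when ground transport to
the nearest EVT-capable site takes at least the 28-minute floor
(`helicopter_viable()`; the boundary case is allowed). The AHA-style
routing rule (`aha_bypass_rule()`) is strict: a CSC-minus-PSC difference of
exactly 15 minutes keeps the PSC routing.

The hybrid centre is treated as a CSC during working-hours periods
(morning peak, midday) and as a PSC otherwise, so off-hours CSC lookups
fall back to the three full-time centres — the afternoon/night lengthening
of CSC trips is emergent, not hard-coded. The four EVT-capable sites
(3 CSCs + hybrid) constitute the SHS (specialized hospital services)
destinations of the helicopter fleet around the clock.

## Travel models

Helicopter time is straight-line distance at 240 km/h — an effective speed
that absorbs take-off and landing. Ground time is straight-line distance
× a detour factor of 1.3 (road over crow-fly distance) at 80 km/h, with
multiplicative period effects {1.0, 1.0, 1.1, 1.0} for morning peak,
midday, afternoon peak and night. These stand in for routed map-API travel
times, which are out of scope; the defaults were chosen so the synthetic
national medians land near the observed ~26 min scene-to-PSC and ~50 min
scene-to-CSC. Planar coordinates in km with Euclidean distances replace
geodesic computation — at a 250 km country scale the projection distortion
is far below the minute-level resolution that matters here. Times are kept
real-valued throughout; rounding happens only in reports.

## The synthetic region generator

Municipality territories are a Voronoi partition of 98 generator points
clipped to a 1.4:1 rectangle of 43,000 km²; roughly 30% of generators
cluster around a handful of city centres, which yields small cells there.
Population is assigned by density class so the intermediate-density
definition holds *by construction* for every seed: the smallest cell
becomes an urban core (density above 1,500/km², capped at 8% of the
population), the next-smallest cells become towns absorbing 60% of the
population at 450–1,100/km², and the rest is rural (well under 300/km²).
Within-class draws are rescaled to class totals and clamped back into the
class density band; rounding preserves the national total exactly. The
resulting shares — ~40% rural, ~58% intermediate, ~2% urban — keep both the
rural and the urban share strictly below one half, which the test suite
asserts across 100 seeds.

CSCs, the hybrid and PSCs are placed in the highest-population
municipalities subject to a minimum mutual separation (population follows
cities, and stroke centres follow population); helicopter bases are spread
by greedy max–min dispersion starting from the municipality farthest from
any CSC, mirroring their coverage role. Address sampling draws a fixed
number of uniform points per municipality (10 by default, giving 980),
via fan triangulation of the convex cells.

Demand increases with remoteness: annual stroke codes per municipality are
`population × base_rate × (1 + gradient × d/d_max)` with `d` the distance
to the nearest EVT-capable site. The base rate (0.004 codes/person/year,
~23,000 codes nationally) and gradient (0.5, i.e. the most remote
municipality has 1.5× the per-capita rate of one beside a CSC) are free
parameters of the synthetic setting: the source registry's per-municipality
magnitudes were never published. They were fixed once from the documented
operating point of the real fleet — about 2.8 missions per helicopter per
day across four bases — together with an LVO-suspect share of 0.12 of
stroke codes and 7 other-acute (trauma, PCI) missions per day fleet-wide:
0.5 (share of codes outside the 28-min zone) × 23,000 × 0.12 / 365 + 7
≈ 11 requests/day ≈ 2.8 per helicopter.

What the generator does *not* emulate: real road networks (ferries,
bridges, motorway asymmetries), islands without bridge connections
(excluded from the source analysis too), within-municipality population
texture, and seasonal or diurnal demand cycles. Passing tests therefore
demonstrate internal consistency of the models and reproduction of the
arithmetic and orderings — not calibration to any real registry.

## Fleet capacity: discrete-event simulation

Mission requests form a superposition of per-municipality Poisson streams
(stroke codes outside the zone cutoff) plus a region-wide other-acute
stream; each request flies to the nearest SHS by air. Catchment zones are
defined by the ground-time cutoff to the nearest SHS: LARGE (≥ 28 min),
MIDDLE (≥ 38), SMALL (≥ 48) — a larger helicopter zone means a smaller
ground-only area and more demand.

The simulator is an event-driven engine written for this package. A
request seizes the nearest base with an idle, in-service helicopter (ties
to the lowest base id); otherwise it waits in a FIFO queue. Waits beyond
15 min mark the request *queued*; waits beyond 60 min *reject* it to
ground transport (rejected requests were necessarily queued first — the
classifications overlap, and outputs preserve that reading). The 90%
operational availability is realized as an independent per-mission,
per-unit Bernoulli refusal — a refused unit never serves that request,
which keeps waiting for any other unit. Availability could alternatively
be modelled as scheduled weather windows; the per-mission reading was
chosen because only the marginal figure is documented, and the draw
stream is isolated so a block-outage model can replace it. Service time
is either the documented 165-minute average trip (`FIXED_AVERAGE`, the
default) or composed from the flight legs plus a 15-minute handover
(`COMPUTED`).

All randomness is pre-drawn from named streams derived from one master
seed, so runs are bit-identical. In the zone × fleet-size sweep, each
replicate generates one mission stream at the LARGE cutoff and thins it
for smaller zones, and availability draws are keyed to mission identity on
a fixed two-slot-per-base grid — comparisons between zones and between 1
and 2 helicopters per base replay the same patients under the same
weather. This pairing is what makes the monotonicity properties (more
helicopters never increase rejections; larger zones never decrease
demand) assertable per replicate rather than only in expectation. With
thresholds disabled and availability 1 the engine is an M/M/c queue, and
the suite checks its mean wait against the Erlang-C closed form at 10⁵
arrivals within Monte-Carlo error.

## Summary statistics

Quartiles use linear interpolation between order statistics (type 7) —
the source never states its rule, and this is the common default. The
onset-to-treatment table restricts to addresses whose nearest stroke
facility is a PSC under each period's working-hours rule: those are the
patients for whom drip-and-ship versus bypass is a real choice (this also
explains why fewer address–period combinations enter the table than were
sampled). The paired Wilcoxon signed-rank test uses the exact distribution
for n ≤ 25 without ties and the tie-corrected normal approximation
otherwise; Spearman's rho is the Pearson correlation of mid-ranks. The
number needed to fly is `floor(1 / |Δp|)` of the excellent-outcome
probabilities (0.29 drip-and-ship ground, 0.31 bypass ground, 0.32 bypass
helicopter), with the floor guarded against binary representation error so
that a nominal Δp of 0.02 yields 50, and 0.03 yields 33.

## A worked example

```{r example}
region <- assign_demand(generate_region(region_spec(seed = 1)))
addresses <- sample_addresses(region, 10, seed = 1)
tab <- table1_summary(region, addresses)
knitr::kable(tab, digits = 0)
```

The qualitative structure matches the modelled Danish system: bypass by
helicopter reaches EVT fastest, drip-and-ship reaches IVT early but pays
heavily at EVT (door-in-door-out plus transfer), and ground bypass is the
slowest route to IVT.

```{r des}
sweep <- scenario_sweep(region, n_reps = 20, horizon_days = 28, seed = 1)
aggregate(cbind(frac_queued, frac_rejected) ~ zone + helicopters_per_base,
          sweep, mean)
```

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the full default region
(98 municipalities, 980 addresses, 4 periods), a year of dispatch-pattern
missions, 200 DES replicates of 28 days for the capacity sweep, and 10⁵
arrivals for the queueing cross-check — sizes chosen to exercise every
code path at full structural fidelity while completing in well under a
minute each. The published thousand-replicate sweep is one configuration
flag away (`des.n_reps`).

Degenerate inputs are handled explicitly: empty facility sets raise lookup
errors; an empty eligible-municipality set yields an empty mission stream
with a warning; all-zero paired differences and zero rank variance raise
degenerate-input errors rather than NaNs; equal travel times break ties by
lowest facility id; and a request refused by every unit is rejected at the
threshold rather than waiting forever.

## Known limitations

Travel times are a two-parameter surrogate, not routed roads; ambulances'
traffic-law exemptions are ignored. Clinical outcome modelling beyond the
fixed excellent-outcome probabilities, stroke-scale triage
sensitivity/specificity, rendezvous logistics, refueling, crew duty
cycles and cost-effectiveness are out of scope. The dispatch-pattern
correlation reproduces the *sign* of the observed remoteness effect; its
magnitude depends on geographic detail the synthetic generator does not
carry.
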