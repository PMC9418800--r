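---
title: "From ASGM mercury emissions to global health damages: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ASGM mercury emissions to global health damages: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asgmrisk)
```

Artisanal and small-scale gold mining (ASGM) burns mercury amalgam in the
open and is the largest anthropogenic source of atmospheric mercury. The
emitted Hg⁰ has an atmospheric lifetime of roughly half a year to a year,
long enough to mix globally before depositing; anaerobic methylation then
moves it into seafood, freshwater fish and rice as methylmercury (MeHg),
so the exposure burden falls largely on general populations far from the
mines. This package implements the full chain needed to quantify that
externality: emissions → environmental mercury cycle → dietary exposure →
health endpoints → money → comparison with gold revenue.

This vignette documents the model, its assumptions, the calibrated
defaults, and the design decisions that were genuinely open.

## The reduced-complexity mercury cycle

The environmental stage is a six-compartment, annual-step, linear box
model: atmosphere; fast, slow and armored soil; surface and subsurface
ocean. Each year the emission is added to the atmosphere and first-order
transfer fractions are applied: deposition (default 0.80 yr⁻¹, an
atmospheric lifetime near 0.6 yr) split 40% to land and 60% to ocean;
soil pools age from fast to slow to armored while re-emitting to the
atmosphere at rates ordered fast > slow > armored; the surface ocean
evades to the atmosphere and exchanges with a subsurface reservoir, whose
burial flux is the only permanent sink. Three diagnostics are read off
the state: global-mean atmospheric deposition `D` (µg m⁻² yr⁻¹), plankton
MeHg `P` (fmol L⁻¹, proportional to surface-ocean mercury through a fixed
methylation-plus-uptake yield) and soil mercury `S` (proportional to the
summed soil pools). All processes are linear, so scenario responses
superpose exactly — the property the attribution logic relies on.

Two scenarios are run. The ASGM-only scenario starts from zero mass in
1970 (the inventory window opens there and no ASGM legacy precedes it)
and is driven by the annual ASGM series. The all-sources baseline is held
at the steady state of a constant total emission. The ASGM contribution
to each pathway in year *y* is the field ratio

  rD = D_ASGM/D_baseline, rP = P_ASGM/P_baseline, rS = S_ASGM/S_baseline,

clipped to [0, 1] with a warning if a ratio ever exceeds one.

The default coefficients (`inst/extdata/box_model_params.yaml`) were
calibrated once, against three anchors: an atmospheric lifetime inside
0.5–1 yr; a soil reservoir large and old enough that the ASGM share of
soil mercury stays far below its deposition share; and 2012 attribution
ratios near 12.2% (deposition), 10.4% (plankton MeHg) and 0.63% (soil).
With the packaged emission series the calibrated model gives 12.20%,
10.40% and 0.63%. The baseline reservoirs it implies are physically
sensible: ~10⁶ t in soils, ~1.8×10⁵ t in the deep ocean, ~6×10³ t in the
atmosphere, with a constant all-sources emission of 3,595 t yr⁻¹. The
absolute ASGM deposition flux in 2012 comes out at 1.87 µg m⁻² yr⁻¹,
somewhat above the ~1.6 µg m⁻² yr⁻¹ a 3D transport model produces; the
calibration prioritizes the ratios, which are what the exposure equations
consume.

### Growth damping and the role of legacy mercury

A subtlety worth recording. For *any* causal linear system started from
zero, the first-year response is produced solely by the first-year input,
while later responses also integrate history; hence the response growth
factor over the run is necessarily **at least** the input growth factor.
Started from zero in 1970, the modeled deposition grows *faster* than the
6.8× emission growth (about 10× here), because re-emitted legacy mercury
adds to fresh deposition. Damped growth — deposition growing more slowly
than emissions, as observed in the real world where pre-1970 legacy
mercury already loads the surfaces — emerges as soon as the run starts
from a spun-up state: with the baseline steady state as the initial
condition, the model's deposition growth factor falls below the emission
growth factor. Both facets are asserted in the test suite: the zero-state
response always lies below the equilibrium deposition for the
current-year emission rate (the memoryful system lags its steady state),
and the legacy-initialized run shows damped growth.

## Dietary exposure

Per-capita baseline MeHg intake is the intake-weighted sum over food
categories, normalized by body weight:

  E_baseline = (Σ I_seafood·C_seafood + Σ I_fwfish·C_fwfish + Σ I_rice·C_rice) / BW,

in µg per kg body weight per day. Categories may carry strata (fish
trophic levels, rice production regions) whose I×C products are summed
within the category; the default is one stratum per category. The ASGM
share scales each category by the ratio of the environmental compartment
that feeds it — plankton MeHg for seafood, atmospheric deposition for
freshwater fish, soil mercury for rice:

  E_ASGM = rP·I_sea·C_sea/BW + rD·I_fw·C_fw/BW + rS·I_rice·C_rice/BW.

Assuming food MeHg responds linearly to the environmental level makes
E_ASGM a conservative upper bound (ecosystem dosing experiments show a
concave response). No time lags are carried between environmental level,
food concentration and intake; most affected foods are harvested and
consumed within a few years, though long-lived wild freshwater fish would
in reality smooth the trend. Storing exposure per kg body weight means
the dose-response products below recover µg day⁻¹ by multiplying with BW.

## Health endpoints

Two endpoints are assessed, with five coefficients
(`dose_response_params()`):

* IQ decrement of the newborn cohort, linear and without threshold:
  ΔIQ = γλβ·ΔE·BW per newborn, assigned to the birth cohort of the
  exposure year (their lifelong loss is booked in that year).
* Fatal heart attacks (FHA) of adults, log-linear and saturating:
  ΔCF = Σ_g POP_g·Cf_g·ω·(1 − e^(−φλβ·ΔE·BW)).

Defaults: β = 0.8 µg L⁻¹ blood per µg day⁻¹ intake (one-compartment
toxicokinetics), λ = 0.25 µg g⁻¹ hair per µg L⁻¹ blood (the conventional
250:1 hair:blood ratio), γ = 0.18 IQ points per µg g⁻¹ hair, φ = 0.066
per µg g⁻¹ hair, ω = 0.5. ω is a subjective down-weighting of the
cardiovascular evidence base; published burden studies do not pin it
down, and 0.5 is the neutral midpoint of its [0, 1] range. All five are
plain config values; the unit tests deliberately use unit coefficients,
not these defaults, as ground truth. Whether BW should be gender-specific
in the FHA equation is not settled; a single mean adult body weight per
country is used.

Source attribution differs across the two endpoints only through
curvature. Attributable impact is computed by exposure differencing,
H(E_baseline) − H(E_baseline − E_ASGM): for the linear IQ endpoint this
equals the direct response to E_ASGM regardless of baseline; for the
concave FHA endpoint it is smaller than the response to E_ASGM evaluated
from zero, and decreases as the baseline rises — both properties are
asserted numerically.

## Valuation

Monetization is H = EL·ΔIQ + VSL·ΔCF, with reference values of $18,832
per IQ point (2008 USD) for lifelong earning loss and $6.3 million (2005
USD) for the value of statistical life. Both are restated in the
reporting currency year with US CPI-U factors (packaged for the years the
analysis needs) and transferred to each country by PPP-adjusted GDP per
capita through a power law with income elasticity 1 — plain
proportionality, the most transparent reading of an income adjustment;
the elasticity is exposed in `econ_params()` for sensitivity work. Annual
series are discounted at 3% yr⁻¹. Two discount/reporting base years are
supported because the source material is genuinely ambiguous between
realizing values to 2012 and to 2020; the package defaults to 2020 (the
year the headline dollar figures are quoted in) and accepts 2012
everywhere.

## Gold economics

Revenue is gross metal value, production × 32,150.7 oz t⁻¹ × annual
price. The loss-to-earning comparison is reported per year and as a
sum-over-sum cumulative ratio; because discounting is linear, the
cumulative ratio is invariant to the shared discount base. Emissions
beyond the 2012 inventory are extrapolated by four gold-market proxies
(price, mine production, demand, supply), each scaling the 2012 emission
by its index relative to 2012 — simple ratio-to-base-year scaling, with
an optional multi-year-mean rebase since a single-year base is a choice,
not a law — and averaged without weights. With the packaged stylized
market series the multi-proxy mean reaches 846 t in 2021 and individual
proxies span roughly 556–981 t over 2013–2021.

## The synthetic world

No external inventories ship with the package. `generate_world()` draws a
self-consistent bundle: a regional emission inventory with a geometric
1970–2012 trajectory (optionally jittered year-to-year while preserving
totals and the endpoint growth factor exactly); country intakes and food
MeHg concentrations drawn log-normally across countries (consumption data
are right-skewed); demography, baseline FHA incidence by gender and PPP
income drawn for 2012 and rolled back with fixed growth rates (population
1.5% yr⁻¹, newborns 0.3% yr⁻¹, income 3.3% yr⁻¹); a stylized gold market;
and the proxy series. Every draw is fixed by one seed, and 20 countries
is the default problem size — large enough for aggregation texture, small
enough that the full pipeline runs in about two seconds.

`reference_world()` additionally calibrates three scales at generation
time so the 2012 *global* aggregates match the published headline burden:
food concentrations (IQ points are linear in them, so the scale is exact),
the income level (the monetized IQ loss is linear in it), and the FHA
incidence field — a level and an income gradient solved jointly by
root-finding so that both the death count and its monetized value hold.
The negative income gradient this produces is also the realistic shape of
the field: cardiovascular mortality is higher in lower-income countries. The emission inventory totals
(15,400 t; 4,970/4,470/2,610/3,350 t by region) and the gold anchors
(86 t at ~$35 oz⁻¹ in 1970; 590 t at ~$1,776 oz⁻¹ in 2012) are built in
directly.

What passing tests therefore do and do not show: they demonstrate that
the equations, their invariants and the printed arithmetic identities are
implemented correctly, and that the global calibration anchors are
reproduced; they do **not** show that country-level or regional loss
distributions match the real world — the synthetic countries have no real
geography, intake inventory or income map, and the package makes no claim
about per-country results.

## Numerical choices and degenerate inputs

The cycle uses an explicit annual step (the system is stiff only on
timescales far longer than the step); mass balance closes to 1e-9
relative by construction and is asserted at every step. Attribution
ratios at a zero baseline raise an error rather than returning infinity;
ratios marginally above one (possible only through user-supplied states)
are clipped with a warning. Zero-emission windows give zero totals; a
zero all-region total makes shares undefined and errors. Empty
extrapolation windows, proxies missing their base-year value, non-positive
incomes, and negative exposure changes all error early with messages
naming the offending input. The acceptance workflow runs the 20-country,
43-year configuration end-to-end in a few seconds on one core.

## Limitations

The cycle model is global-mean only: it cannot produce the near-source
deposition hot spots a 3D transport model resolves, and its absolute 2012
ASGM deposition flux overshoots a 3D estimate by ~17% even though the
attribution ratios match. Food MeHg is scaled linearly with environmental
mercury (a conservative upper bound). Health coefficients are point
estimates; no uncertainty intervals are propagated. The booked IQ losses
are the cohort's lifelong loss assigned to one year, and re-emission
means the true damage trail of any emission year extends beyond the
accounting window — the totals are indicative lower-end estimates.
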