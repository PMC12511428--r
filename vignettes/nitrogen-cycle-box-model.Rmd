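---
title: "A three-box nitrogen-phosphorus-oxygen isotope model and its proxy companions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-box nitrogen-phosphorus-oxygen isotope model and its proxy companions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

nitrobox asks a focused question: how does the nitrogen-isotope
composition of the ocean respond to coastal upwelling, and how does the
answer change depending on whether phosphorus is recycled within the
water column or buried in sediments? The package couples a small
mechanistic model of that question to the proxy arithmetic needed to
read the answer out of sediment cores: carbon-isotope fractionation,
composite delta-15N records, accumulation rates, and a wind-stress-based
coastal upwelling diagnostic.

## The box model

Three boxes: a regional **surface** box (`V_surf = 1e15` m3), the
**OMZ** box beneath it where the oxygen minimum develops
(`V_omz = 1e16` m3), and a **rest-of-ocean** box lumping the remaining
surface and deep ocean (`V_rest = 1.3e18` m3). A single circulation
loop, rest -> OMZ -> surface -> rest, carries all tracers at the
upwelling transport `U` (0-0.25 Sv, the range typical of one upwelling
region) plus a background overturning `U_base` (0.05 Sv) that keeps the
ocean connected when the wind-driven part vanishes. Weak mixing
exchanges (`mix_surf_omz` 0.01 Sv, `mix_omz_rest` 0.03 Sv) represent
diffusive and eddy ventilation that does not scale with the wind.
Because the rest box contains its own surface limb, its oxygen is
relaxed toward solubility at an overturning-scale exchange
(`vent_rest`, 20 Sv); surface-box oxygen is clamped to the solubility
value `O2_surf` (0.22 mol/m3, a warm-surface value).

State variables are phosphate, the two nitrogen isotopologues (14N,
15N) and oxygen in each box. Carrying isotopologues rather than deltas
makes mass balance exact; delta-15N, defined as
`(R/R_AIR - 1) * 1000` with `R_AIR = 0.0036765`, is computed only for
reporting, and collapsed nitrogen pools report `NA` rather than NaN.

The biological cycle:

* **Uptake/export.** Production consumes the limiting nutrient (Liebig
  minimum of P and N/16) with a fast rate constant (`k_up`, 1e-6 1/s),
  so the limiting nutrient is drawn down nearly completely and export
  tracks nutrient supply. Organic matter has fixed N:P = 16. Exported N
  is instantaneously depleted by `eps_assim` = 5 permil relative to
  surface DIN - implemented as an exact delta-space shift, so
  delta-15N(surface) - delta-15N(export) = 5 holds identically.
* **Remineralization.** A fraction `remin_frac_omz` = 0.8 of export
  exerts its remineralization demand in the OMZ, the rest at the deep
  seafloor. Aerobic remineralization consumes `rO2P` = 150 mol O2 per
  mol P and shuts off along a narrow linear ramp just below the
  denitrification threshold `O2_thresh` = 5e-3 mol/m3 (at or above the
  threshold, denitrification is exactly zero). Where oxygen is short,
  water-column denitrification consumes nitrate at `rNO3P` = 104 mol N
  per mol P remineralized, limited by a canonical micromolar nitrate
  half-saturation (`K_N` = 8e-3 mol/m3), and leaves the residual pool
  enriched (`eps_wc` = 25 permil, a literature-typical value). Of the
  organic flux reaching the deep seafloor only `benthic_eff` = 0.84 is
  degradable at all; the refractory remainder (about 3% of total
  export, the canonical open-ocean burial efficiency) can only be
  buried or returned.
* **Burial (open setup).** The burial fraction `alpha` = 0.25 applies
  to exported organic P *not remineralized either aerobically or
  through denitrification* - the refractory flux plus whatever anoxia
  preserved. Buried N follows at `rNP_burial` without fractionation.
  The closed setup buries nothing and eventually remineralizes
  everything, conserving total P exactly.
* **Sedimentary denitrification.** A first-order, non-fractionating
  sink on deep nitrate (`k_sed` = 5e-14 1/s): pore-water nitrate
  consumption is near-complete, so no fractionation is expressed. It is
  present in both setups and sized so that the sediments carry the
  majority of total denitrification, as in the modern budget. Without
  a non-fractionating sink the steady-state delta-15N would sit pinned
  at `eps_wc` whatever the upwelling - the upwelling response lives in
  the *share* of water-column denitrification among the sinks.
* **N2-fixation.** Coupled linearly to the surface deficit,
  `k_fix * max(0, 16 P_surf - N_surf) * V_surf`, with `k_fix` = 5e-11
  1/s (fixation near 10% of export N at observed deficits) and newly
  fixed N at `eps_fix` = 0 permil.

### Why the defaults sit where they do

The open base case (`U` = 0.1 Sv, `W` = 2 mol/s) lands exactly at the
OMZ anoxia edge under these defaults, and the closed base case
(inventory 2.42 Pmol) sits just beyond its denitrification onset; that
placement organizes all four headline experiments:

* Closed setup, sweeping `U`: at the lowest transports the OMZ stays
  oxic and delta-15N is near zero; beyond the onset, oxygen demand
  outruns supply, water-column denitrification deepens, and deep
  delta-15N rises monotonically (to ~13 permil at 0.25 Sv).
* Open setup, sweeping `U`: export is pinned by the burial requirement
  (burial must balance `W`), so rising transport oxygenates the OMZ,
  denitrification wanes and delta-15N falls monotonically - burial
  reverses the sign of the upwelling response.
* Closed setup, sweeping the inventory at fixed `U`: export first rises
  with P availability, then flattens onto an oxygen-supply-limited,
  nitrogen-limited branch; delta-15N peaks at intermediate inventories.
* Open setup, sweeping `W`: beyond the anoxia edge additional input is
  absorbed by anoxia-enhanced burial, so export grows much more slowly
  than the input.

### Honest limits of the formulation

Two behaviours of the original figure set are *not* reproduced, for
structural reasons we consider informative rather than incidental:

* **No interior export maximum in the closed inventory sweep.** With
  the strictly linear deficit-coupled fixation closure, the
  nitrogen-limited branch has export `(U*N_m + F)/16` where the
  fixation flux F grows linearly with the surface P surplus; we find
  (numerically out to 7 Pmol, and by inspection of the budget) that
  export is monotone non-decreasing in the inventory. A genuine
  decline requires fixation to saturate - iron limitation of
  nitrogenase is the natural candidate - which the linear closure
  cannot express. The delta-15N maximum at intermediate inventory does
  occur.
* **Export in the open setup is flat only to ~35%, not ~10%, across a
  10-fold input range.** Steady state forces burial = `W`, and burial
  rides the organic leftover stream, so export must grow by roughly
  `dW/alpha` across the span. A flatter response would need a P sink
  fully decoupled from export (authigenic shelf burial is exposed as
  the `k_scav` variant, but with it the burial-denitrification
  structure of the open setup collapses, so it is off by default).

One robustness variant also has a regime boundary worth knowing: with
the burial fraction cut to `alpha = 0.1`, the burial-required export
exceeds the OMZ oxygen capacity everywhere in 0-0.25 Sv, the system
stays anoxia-pinned, and the surface N supply shifts from fixation
(0 permil) to recycled enriched nitrate as transport rises - deep
delta-15N then *rises* with `U` even as OMZ delta-15N falls. For
`alpha` of 0.25 or 0.5, both `rNP_burial` variants and the
oxygen-dependent burial-efficiency variant, the decreasing trend
stands.

### Numerics

Steady states are found by stiff time integration (`deSolve::lsoda`)
over geometrically growing chunks, interleaved with a damped-Newton
polish on the 11-dimensional tendency system; in the closed setup the
redundant deep-P equation is replaced by the inventory constraint,
which also removes the conservation null-space from the Jacobian. A
Newton root is accepted only if it is locally attracting (eigenvalue
check), so the solver cannot land on an unstable branch. The residual
is the largest tracer tendency expressed as a flux, relative to the
largest gross flux of the state; the default tolerance is 1e-10.
Sweeps use continuation (each converged state seeds the next) to stay
on one branch; non-converged points are flagged, never raised as
errors. The hard denitrification switch is regularized by a linear ramp
*below* the threshold (width 4e-3 mol/m3): a strict step has no steady
state when aerobic demand pins oxygen at the threshold, while the ramp
yields the same partial-denitrification state smoothly and `width -> 0`
recovers the step.

## Carbon-isotope systematics

`epsilon_toc()` uses the exact ratio form
`1000 * ((1000 + d13c_carb)/(1000 + d13c_org) - 1)`, which reduces to
the familiar difference to first order but stays correct at large
separations. `delta_carb()` derives the delta-13C of dissolved CO2 from
the atmospheric value (-5 permil, pre-industrial, held constant) via
the temperature-dependent gas/aqueous equilibrium fractionation and
returns the enrichment of carbonate over dissolved CO2, about +8 to
+10 permil at marine temperatures. The equilibrium coefficients live in
one named block (`mook_coefficients()`) so another edition can be
swapped without touching logic. `ep_minus_delta2()` composes the two;
the secondary-biology offset Delta_2 = 1.5 permil is attached as
metadata, not subtracted, because the quantity of interest is
epsilon_P - Delta_2 itself. Temperatures come from a user-supplied
age -> temperature table, linearly interpolated.

A note on sign conventions: the difference is computed carbonate minus
dissolved CO2. With the opposite sign the proxy would exceed the
maximum photosynthetic fractionation by construction, which is how one
can check any implementation of this arithmetic.

## Record statistics

`splice_records()` concatenates per-site dated series from one
environment class and reports (never corrects) the mean offset between
each temporally overlapping site pair. `delta15N_gap()` computes
Delta-15N = distal minus deep on a common age grid, masking grid points
that fall in data gaps wider than 10 Myr rather than bridging them.
`bin_series()` bins in fixed increments anchored at age zero, emitting
empty bins and marking undefined standard deviations.
`windowed_correlation()` pairs two series by nearest age within a
tolerance (2.5 Myr default) and reports Pearson r per age window, with
the default partition at 28 Ma; windows with fewer than four pairs are
marked insufficient. `corg_accumulation()` is plain unit arithmetic,
`(TOC/100) * density * rate`; outputs computed with the default dry
bulk density of 1 g/cm3 should be treated as order-of-magnitude.

## The upwelling diagnostic

`coastal_upwelling_flux()` finds ocean cells with land 4-neighbours,
builds each cell's offshore normal (the normalized mean of
land-to-ocean directions) and coastline length from spherical grid
metrics, and evaluates the offshore Ekman mass transport per metre of
coast, `(tau_y * nx - tau_x * ny)/f`, with `f = 2 * omega * sin(lat)`.
Cells within 5 degrees of the equator are skipped; only
upwelling-favourable (positive) cell fluxes enter the global integral,
with downwelling tallied separately. The integral is reported in kg/s
and as a Sverdrup equivalent (divided by the seawater density). These
conventions - 4-connectivity, the 5-degree cutoff, positive-part
integration, per-cell along-shore projection - are configurable
assumptions; the diagnostic is linear in the stress and exactly
invariant under the hemispheric mirror, and both properties are tested.

## What the synthetic data do and do not emulate

`make_records()` draws per-site records from a shared piecewise-linear
baseline with AR(1) noise in age order plus independent
within-timepoint scatter (2 permil full spread by default, the scatter
seen when several samples share an age), overlapping site windows, and
a TOC regime with an optional signed coupling between delta-15N and
organic-carbon accumulation per age window. The default baselines
sketch the qualitative shape of the published composites (deep margin
stable near 3-4 permil; distal elevated through the Paleogene,
converging by the middle Miocene) and are illustrative study
conditions only - no test treats them as ground truth for the real
records. The generators do not attempt diagenesis, bioturbation,
foraminiferal binding, or age-model error, so green tests say the
*arithmetic* is right, not that the real data would pass.
`make_windfield()` provides two analytic continent/wind templates - a
modern-like meridional coast under equatorward trades and a Tethys-like
zonal coastline in the easterly band - guaranteed non-degenerate, for
exercising the Ekman diagnostic. `make_boxmodel_observations()` plus
`recover_upwelling()` close the loop: transport used to generate noisy
steady-state observations is recovered by grid search within one grid
step.

## Problem sizes

The shipped tests and the acceptance script use 6-13 point sweeps,
20x20 to 45x90 wind grids, a few hundred synthetic record rows, and
trajectories to 1e12 s; a full run of everything takes a few minutes on
one core. All interfaces accept larger grids unchanged.

## Interfaces

The package is function-first: tibbles in, tibbles out, `autoplot()`
and `plot_composite()` for figures, `tidy()`/`glance()` on fitted
steady states, and CSV readers/writers (`read_record_table()`,
`write_results()`, `write_windfield_csv()`) with a stable schema and
fixed float formatting for repeatable diffs. Gridded fields travel as
long-format CSV. A deterministic run manifest (`run_manifest()`)
records package version, seeds and input digests.
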