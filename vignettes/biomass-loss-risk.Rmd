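---
title: "Fuzzy-logic decision support for climate-driven biomass loss risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy-logic decision support for climate-driven biomass loss risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzyrisk)
```

## The model

`fuzzyrisk` post-processes gridded dynamic global vegetation model (DGVM)
ensembles into a management-facing risk surface using an EEMS-style fuzzy
logic tree. Every node of the tree is a spatial layer; leaves are raw model
outputs normalized to *fuzzy truth* (0 = fully false, 1 = fully true) and
internal nodes combine their children cell-by-cell with three operators:

* **And** — per-cell minimum; the result at a cell comes from exactly one
  input (up to ties), so it can be *attributed* to its source,
* **Or** — per-cell maximum, attributed the same way,
* **Union** — per-cell mean, with no single source.

Normalization is linear between two thresholds: a value at or below the
fully-false threshold maps to 0, at or above the fully-true threshold to 1,
and in between to

$$\mathrm{fuzzyval} = \frac{\mathrm{inputval} - \mathrm{minthresh}}
                           {\mathrm{maxthresh} - \mathrm{minthresh}}.$$

Both boundary values are assigned by the interpolation branch, so
`convert(minthresh)` is exactly 0 and `convert(maxthresh)` exactly 1. The
engine also accepts `minthresh > maxthresh` as a decreasing ramp; the default
model only uses increasing specs, but the generalization costs nothing and
lets "is Low" statements be expressed.

### The default tree

The shipped configuration (`inst/extdata/biomass_loss_risk_tree.json`) has
eleven nodes — six normalized inputs and five operators:

* *MC2 Fire Threat* = Union(*Biomass Burned is High*, *Fire Frequency is High*)
* *MC2 Fire Loss Risk* = And(*Fire Threat*, *MC2 Biomass is High*)
* *MC2 Mortality Risk* = And(*Vegetation Stress is High*, *Live Biomass is High*)
* *MC2 Biomass Loss Risk* = Or(*Fire Loss Risk*, *Mortality Risk*)
* *Biomass Loss Risk* = And(*MC2 Biomass Loss Risk*, *Observed Biomass is High*)

Only the Or at *MC2 Biomass Loss Risk* is fixed by the method's published
description; the remaining wiring is this package's documented
reconstruction, chosen so that (a) risk requires both a threat and high
modeled biomass, (b) the observation-based biomass layer can only adjust
risk *down* (an And with it takes the minimum), and (c) risk and uncertainty
are exactly 0 wherever observed biomass is 0. The tree is plain JSON, so an
alternative wiring is one edit away and everything downstream is unchanged.

### Thresholds

Input thresholds come from one of two profiles:

* **derived** (default): the 10th and 90th percentiles of each variable's
  baseline-period distribution over the study area, using the
  linear-interpolation percentile definition (R's type-7 quantile; the
  method's source names no definition, so the choice is recorded here and
  checked against a brute-force sort-and-interpolate oracle). Vegetation
  departure keeps its fixed (0, 3) conversion, because its scale is defined
  by the lookup table rather than by a distribution.
* **paper**: the frozen published pairs — biomass burned (0, 110), fire
  frequency (0, 1), total biomass (31572, 73148), live biomass
  (5839, 29387), observed biomass (4053, 21844) g C m⁻², departure (0, 3) —
  for use when the original calibration should be reproduced exactly; the
  real baseline rasters behind them are not deposited anywhere.

### Vegetation departure

Vegetation stress compares the cell's **modal** vegetation type over a
future period with its modal type over the baseline period, then scores the
ordered pair through an expert lookup table with values in [0, 3]
(0 on the diagonal; symmetry is *not* assumed, since expert tables often
score A→B differently from B→A). Ties in the mode go to the lowest code —
deterministic and invariant to year order. Summarizing the baseline period
by its mode as well is a package choice; the method's description does not
say how the baseline type is summarized, and the mode is the symmetric
option. The actual expert table is not published, so the package ships a
clearly-labelled synthetic stand-in (bin distance capped at 3).

### Ensembles and uncertainty

Each scenario is driven by the same set of climate futures; the tree is
evaluated independently per member and only then reduced: per-cell minimum,
mean, and maximum bracket the risk, and *High Variability* converts the
per-cell standard deviation across members to fuzzy truth with thresholds
(0, 0.5). The **population** (divide-by-N) standard deviation is the
default because it is the only variant that attains the stated maximum 0.5
exactly (half the members at 0, half at 1); a sample-sd flag exists for
sensitivity. Regional numbers are area-weighted means over valid cells;
weights default to uniform and can be supplied per cell.

Between-scenario uncertainty for a matched pair (same climate futures under
two scenarios) is, per member pair and cell, the two-value population sd
(`|a−b|/2`) fuzzified with (0, 0.5) — i.e. `|a−b|` — averaged over pairs and
then over area. The published tables do not describe their construction;
this member-matched form is the default because both scenarios share their
20 climate futures, and a pooled 2N-member variant is available by flag.

### Driver attribution

Fire-versus-mortality attribution works on the two inputs of the Or node:
difference maps use the ensemble mean of each input before differencing;
dominance fractions split the valid area into zero-risk (risk exactly 0 —
exact zeros are common because any fully-false input upstream of an And
forces 0), fire-dominated, and mortality-dominated, with cell-level ties
split half-and-half so the three fractions always sum to 1. A member-level
tie (measure-zero on continuous data) counts as fire-dominated with a
warning. Member extremes credit every member attaining the per-cell
max/min, so each cell credits at least one member per extremum. Fractions
are plain cell counts by default with an area-weighted option, since the
published tables do not state which was used.

## The synthetic world

No data accompany the original study, so the generator builds an
MC2-like world with the statistical structure the analysis assumes:

* smooth latent fields (kernel-smoothed Gaussian noise; scale 5 cells) for
  coastal proximity, elevation, productivity, and dryness, on a default
  100×100 grid with a masked "ocean" corner;
* baseline biomass lognormal in productivity (median 50 000 g C m⁻²,
  log-sd 0.35, giving a 10th–90th range near the published thresholds);
  live biomass a noisy 35 % fraction;
* 20 climate futures whose warming is `forcing × 3.5 °C` scaled by a
  member-specific factor, and mixed-sign precipitation changes; the same
  member draws are reused across scenarios and periods (fixed per-member
  seed offsets), so a "climate future" is the same entity everywhere, as in
  a real ensemble;
* fire frequency a logistic function increasing in member warming and
  dryness, decreasing with coastal proximity; biomass burned proportional
  to frequency and live biomass; the no-fire-suppression analog multiplies
  both by 1.25;
* vegetation types as fixed-width bins of a climate index that shifts by
  0.45 bins per °C of member warming, over 7-year series with annual noise
  (sd 0.35 index units), so warming produces nonzero departures;
* observed biomass = baseline biomass under lognormal noise with **exactly**
  `⌈0.11 × n_valid⌉` lowest-productivity cells set to 0 — the exact count
  (rather than Bernoulli thinning) makes the 11 % zero-area analog testable
  exactly;
* scenario forcing multipliers 0.6 (moderate pathway) and 1.0 (high), and
  period multipliers 0 / 0.35 / 0.65 / 1.0 for baseline / early / mid /
  late century.

The generator also returns its latent fields and member draws, clearly
flagged as test-only ground truth, so monotonicity tests need not peek at
pipeline internals.

**What a green test establishes — and what it does not.** The synthetic
world reproduces the *qualitative* structure: regional mean risk increases
with period and forcing and under no-suppression, risk and uncertainty are 0
where observed biomass is 0, and injected member spread raises the
uncertainty layer monotonically (checked over spread multipliers 0.25–4 on a
40×40, 12-member configuration — a size chosen once for runtime and not
revisited). It does **not** reproduce the published regional numbers, which
derive from 80 undeposited DGVM runs, and it diverges in one known respect:
in the synthetic world regional uncertainty *decreases* through time,
because fire frequency saturates toward its logistic ceiling at high
forcing and compresses between-member spread, whereas the real ensemble's
uncertainty grows. Nothing in the tests asserts the uncertainty trend.

## Numerical choices

* Fuzzy range fixed to [0, 1]; no signed fuzzy space.
* Attribution ties record the lowest attaining input index plus a tie flag.
* Exact zero (not "below epsilon") defines zero risk.
* Layers travel as plain-text ASCII grids written at full double precision,
  so read/write round trips are bit-exact; ensemble stacks and year series
  are one grid per member/year plus a JSON manifest. (No GeoTIFF/NetCDF
  bindings are assumed; inputs must be co-registered upstream — the package
  checks shape and mask equality only and never interprets projection
  metadata.)
* Each run writes a provenance record (full config, threshold profile,
  package and R versions) beside its outputs.

## Worked example

```{r, eval = FALSE}
library(fuzzyrisk)
cfg <- synthetic_config(n_rows = 40, n_cols = 40, n_members = 6, seed = 7)
bundle <- generate_bundle(cfg)
rc <- run_config(bundle = bundle)
res <- run_scenario(rc, "rcp85_nfs", "late")
res$summary
res$dominance_counts
```

The same pipeline is scriptable end-to-end from the command line via
`fuzzyrisk_cli()` (subcommands `gen-data`, `derive-thresholds`, `run`,
`compare`); a launcher ships at `system.file("cli", "fuzzyrisk",
package = "fuzzyrisk")`.

## Limitations

* The internal wiring of the fire branch (Union vs Or; which biomass joins
  which branch) is a reconstruction, config-editable but not published fact.
* The expert departure table is synthetic; only its contract (total on the
  type set, diagonal 0, range [0, 3]) matches the original.
* No reprojection, resampling, or polygon reporting units; grid cells only.
* The DGVM itself, climate-data preparation, and the biomass-observation
  method are all upstream of this package and out of scope.
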