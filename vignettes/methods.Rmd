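---
title: "Models and methods behind aquarisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aquarisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquarisk)
```

# Scope and data model

`aquarisk` assesses drinking-water quality from per-station chemistry
tables: sixteen parameters (pH, alkalinity, free CO₂, EC, ORP, salinity,
TDS, total hardness TH, turbidity, NaCl, Ca²⁺, Cl⁻ and the heavy metals Cd,
Cu, Ni, Pb), one row per station, with longitude/latitude for the spatial
stage. All solutes are held internally in mg/L (EC in µS/cm, salinity in
ppt, turbidity in FTU, ORP in mV); declared units such as µg/L are converted
once, at load time. A station whose four metal cells are all missing is
flagged `metals_measured = FALSE` and excluded from the metal-based stages —
survey campaigns often analyse metals on a subset of stations only, and the
package treats that as a first-class situation rather than an error.

Missing values are excluded, never imputed, at this layer. Negative
concentrations and out-of-range pH are rejected at construction with the
offending row identified.

## Guideline registries

Four authorities are transcribed as defaults (WHO, USEPA, Indian ISDW,
Bangladeshi BDWS), each entry either a scalar upper limit or a two-sided
interval (pH 6.5–8.5, WHO alkalinity 200–600 mg/L, …). ORP carries no
standard in any registry: it is negative-valued and measures redox state,
not a contaminant load, so it is excluded from contamination factors and the
WQI. A `custom` authority and per-entry overrides cover everything else.

Compliance accounting counts a value as compliant iff it is at or below a
scalar limit or inside an interval; the per-parameter mean is the unweighted
mean over the authorities that declare a standard for that parameter.
Tightening a scalar limit can therefore never raise a compliance
percentage, a property the tests exercise directly.

# Contamination indices

The contamination factor $CF_i = M_i/S_i$ uses one scalar reference per
parameter. The default reference set is the BDWS upper bounds with one
substitution: free CO₂ has no Bangladeshi limit, so the WHO value
(10 mg/L) fills the slot. This keeps the divisor of the modified
contamination index at $n = 15$ (all parameters except ORP), which is the
count the published index tables imply ($TCI = 15 \cdot MCI$ on every row).
Interval standards contribute their upper bound.

Design points worth stating explicitly:

* **PLI at zero.** The geometric mean degenerates when any $CF$ is zero;
  zero terms are replaced by a configurable floor (default $10^{-6}$) with a
  warning. Concentrations of exactly zero are rare in practice (censored
  values are usually reported at a detection limit), so the floor is a
  guard, not a modelling choice.
* **Class boundaries.** All rubrics are contiguous half-open intervals,
  closed below: a value exactly on a printed boundary takes the upper
  class. Published rubric tables sometimes leave gaps (the MCI table jumps
  from "4–8" to ">16"); gaps are closed at the lower printed edge, so
  $[8, \infty)$ is "very high" for MCI.
* **MPI.** Computed over the four metals against BDWS limits by default
  (overridable). Stations without metal data report the conventional
  printed form: value 0, class "very low", weight 0. Published MPI columns
  are not reproducible from any single authority's limits — the reference
  set actually used there is unknowable — so MPI values are checked
  against first principles, not against the printed column.
* **WCI.** The weighted contamination index aggregates the five arbitrary
  weights. The exact published aggregation is under-determined: no linear
  weighting of the printed $A_w$ values reproduces the printed column
  (identical weight sums map to different printed WCIs). The default
  aggregator is $\sum A_w / (5 \times \text{active indices})$, which is
  bounded in $[0,1]$, handles unassessed indices gracefully, and is
  documented as *not* reproducing the printed WCI column; the aggregator is
  a function argument for users who prefer another convention.

# Ecological risk

$ERI = TRF \times M/S$ with toxic response factors Cd 30 and Cu/Ni/Pb 5,
summed to $PER$. The reference standards $S$ are a mixed-authority set
(Cd 0.003, Pb 0.01, Ni 0.02, Cu 0.05 mg/L) chosen so that the index scale is
internally consistent with the published per-metal risk table; copper's
0.05 mg/L matches no single authority and the registry's provenance note
says so. Both tables are overridable per metal. Classification bounds:
ERI low <40, moderate 40–80, considerable 80–160, high 160–320, very high
≥320; PER low <150, medium 150–300, considerable 300–600, extreme ≥600.

# Health risk

The exposure chain follows the USEPA drinking-water framework with three
cohorts:

| cohort | IR (L/d) | EF (d/yr) | EP (yr) | BW (kg) | SA (cm²) | ET (h/d) |
|---|---|---|---|---|---|---|
| child | 1.0 | 350 | 6 | 16 | 6800 | 1.0 |
| adult male | 2.0 | 350 | 30 | 70 | 19000 | 0.5 |
| adult female | 1.6 | 350 | 30 | 55 | 16000 | 0.75 |

with $AT = EP \times 365$ days for both the noncarcinogenic and the
carcinogenic pathway (no separate 70-year carcinogenic averaging — the
convention required to reproduce the published carcinogenic-risk table) and
dermal conversion factor $CF_{conv} = 10^{-4}$ L/cm³ as published (common
practice elsewhere is $10^{-3}$; the value is a cohort field and can be
overridden). The child daily dose coefficient
$IR \cdot EF \cdot EP/(BW \cdot AT) = 0.0599$ d⁻¹ exceeds the female
(0.0279) and male (0.0274) coefficients, so child risks strictly dominate on
identical water — the cohort ordering the tests assert.

Unit conventions: ADIs are computed in mg/kg-day; reference doses are kept
in µg/kg-day as tabulated (ingestion Pb 1.4, Cd 0.5, Cu 40, Ni 20; dermal
Pb 0.42, Cd 0.005, Cu 12, Ni 5.4), and the single mg→µg conversion happens
inside the hazard quotient. Slope factors: Cd 6.1, Ni 0.84,
Pb $8.5 \times 10^{-3}$ kg·day/mg. The nominal Pb value of "8.5" in
circulation is treated as a units slip — only the $10^{-3}$ scaling
reproduces published lead risks of order $10^{-4}$ — and is overridable.
Copper has no slope factor and is excluded from carcinogenic risk.

Two published inconsistencies are documented rather than chased: hazard
index tables of order $10^{-3}$ are not reproducible from these equations
under any consistent unit reading (the formulas as stated give child HQs of
order 1 for Cd at 0.02 mg/L), and published nickel carcinogenic risks imply
a slope factor near 1.7 rather than the stated 0.84. The package implements
the stated equations literally and keeps the stated constants; the packaged
fixtures carry the printed values, but only quantities that are actually
reproducible (cadmium and lead carcinogenic risks, the ecological-risk
table, the index identities, the WQI grading) are asserted numerically.

# Water quality index

$Q_i = 100\,|V_m - V_i|/|V_s - V_i|$ with ideal values $V_i = 0$ everywhere
except pH ($V_i = 7$); the absolute-value form keeps sub-ideal pH from going
negative, the standard convention for the weighted-arithmetic WQI. $V_s$
defaults to the WHO registry; interval standards use the bound farther from
the ideal (pH → 8.5, alkalinity → 600). Weights are $W_i = 1/V_s$, so
trace-metal standards dominate: cadmium at $V_s = 0.003$ mg/L carries a
weight five orders of magnitude above TDS. That is exactly why stations with
elevated metals produce WQIs in the hundreds-to-thousands while metal-free
stations of otherwise similar chemistry score below 1 — the bimodal pattern
visible in published grade tables. Grades are Excellent $[0,25]$, Good
$(25,50]$, Poor $(50,75]$, Very poor $(75,100]$, Unsuitable $(>100)$,
closing the printed "0–25 / 26–50" gaps as contiguous half-open intervals.
Where published grade labels contradict these stated bounds (e.g. a WQI of
2247 labelled "Very poor"), the package follows the stated bounds.

# Multivariate and spatial stages

Correlation is pairwise-complete Pearson; zero-variance columns flag `NA`
entries with a warning. PCA standardizes columns by default (units differ by
orders of magnitude, so the decomposition is of the correlation matrix) and
applies a deterministic sign convention — each component's largest-magnitude
loading is positive. Clustering is Ward (`ward.D2`) on Euclidean distances
after column standardization, for stations or parameters. Published PCA
percentages (PC1 65.55 %) are properties of raw data that were never
deposited; the tests assert structural properties instead, e.g. that the
high-correlation salinity block produces a PC1 fraction in the band implied
by block-equicorrelation eigenvalue theory ($1 + (b-1)\rho$ for a $b$-wide
block).

IDW interpolation uses all stations (no neighbour cutoff) with power
$p = 2$ by default, planar decimal-degree coordinates (adequate at
sub-degree extents; no projection machinery), and a station-coincidence
tolerance of $10^{-9}$ degrees within which a cell takes the station value
exactly. Outputs are convex combinations of station values — bounded by the
station extrema everywhere — and are written as plain-text ESRI ASCII grids.

# The synthetic generator

`generate_samples()` emulates the features of brackish coastal groundwater
that drive every downstream stage:

* **Right-skewed marginals.** All solutes are lognormal, moment-matched to
  per-parameter mean/SD targets (defaults transcribe a 20-station coastal
  survey's descriptive table, e.g. EC 1522 ± 947 µS/cm, Cd
  0.026 ± 0.038 mg/L). Lognormality keeps values positive and reproduces
  the mean ≪ max behaviour of the observed distributions.
* **The salinity block.** EC, salinity, TH, turbidity, NaCl, Ca²⁺ and Cl⁻
  share a log-scale equicorrelation ρ = 0.95 (sampled via the Cholesky
  factor of the equicorrelation matrix); TDS is a fixed fraction of EC
  (0.6386, the observed mean ratio) times a small lognormal noise term,
  giving the near-unit EC–TDS correlation that dominates real correlograms.
* **Everything else.** pH uniform on the observed range [7.24, 8.2]; ORP
  normal (−42.13, 10.62) clamped below zero; metals lognormal and mutually
  independent — observed metal inter-correlations are weak — with a
  per-metal exceedance spike (probability 0.05, factor calibrated per metal
  toward observed maxima) emulating the single-hotspot pattern that drives
  extreme ecological and carcinogenic risk at one station in twenty.

What the generator does *not* emulate: spatial autocorrelation (coordinates
are uniform, values are not geostatistically simulated), temporal
structure, censoring at detection limits, and any pH–metal solubility
coupling. Tests passing on synthetic data therefore validate the
computational chain and its invariances, not field realism.

Parameter recovery is tested by pooling 100 seeds at n = 20 (2 000 draws per
parameter) and requiring each pooled mean within 3 standard errors of its
target, with metals tested spike-free since the configured marginal targets
are pre-spike.

# Numerical choices and problem sizes

Half-open interval classification throughout (boundary value → upper
class); deterministic PCA signs and clustering tie-breaks (input order);
PLI zero floor $10^{-6}$; IDW coincidence tolerance $10^{-9}$ degrees;
seeds control all randomness and the pipeline is byte-deterministic for a
fixed configuration and seed. Test problem sizes were chosen to keep the
full suite in tens of seconds: 20–400 synthetic stations depending on what
a test needs to resolve, 100-seed ensembles for distributional claims, and
closed-form or loop-oracle cross-checks at ≤ 6 parameters where exhaustive
verification is feasible.

# Known limitations

* The WCI aggregation and the MPI reference set are declared conventions,
  not reconstructions of any published column (see above).
* Guideline registries cover four authorities plus `custom`; there is no
  database of national standards.
* No kriging/variograms, no Monte-Carlo exposure uncertainty, no
  inhalation pathway, no sediment indices (geoaccumulation, enrichment
  factor).
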