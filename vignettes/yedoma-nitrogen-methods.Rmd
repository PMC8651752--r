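---
title: "Methods: from chamber headspace to an N2O emission factor for thawing Yedoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from chamber headspace to an N2O emission factor for thawing Yedoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yedomaflux)
```

# The problem

Yedoma is ice-rich, organic-bearing late-Pleistocene permafrost, tens of
metres thick, with a low C/N ratio that makes its nitrogen stock large and,
once thawed, readily mineralizable. Along Arctic rivers, retrogressive thaw
exposes steep retreating cliffs whose stabilizing, revegetating slopes can
develop high nitrous oxide (N2O) emissions within a few years of thaw. This
package implements the full quantitative chain such a study needs: chamber
flux computation, soil physics, nitrogen transformation rates, incubation
analysis, an erosion-driven nitrogen mobilization budget, functional gene
summaries, and the nonparametric statistics layer — together with
synthetic-data generators that emulate each measurement type so the whole
chain is testable without field data.

# Chamber fluxes

A static chamber of effective height $h$ (volume/area, m) encloses the soil
surface; five headspace samples over a 50-minute enclosure give mixing
ratios $C(t)$ (ppm). The flux is computed from the OLS slope $b$
(ppm min$^{-1}$):

$$F = b \cdot 10^{-6}\,\frac{P}{RT}\,h\,M \cdot 1440$$

with $P$ pressure (Pa), $T$ air temperature (K), $R = 8.314$ J mol$^{-1}$
K$^{-1}$, and $M$ the mass basis per mole of gas (28.0134 g N per mol N2O;
12.011 g C per mol CH4 or CO2). N2O fluxes are reported in
µg N m$^{-2}$ d$^{-1}$, CH4/CO2 in mg C m$^{-2}$ d$^{-1}$; positive values
are emissions.

Quality control follows the RMSE rule: a series is rejected when the
regression RMSE (ppm) exceeds $3\times$ the analytical SD of standard-gas
mixtures in the same concentration range. The boundary itself is accepted
(rejection is strictly greater-than). We fit all samples with no
point-dropping: automated outlier deletion would be irreproducible, and the
$r^2$/RMSE report carries the same information the traditional visual
inspection did. Chamber height is a required input with no default, since
geometry varies between deployments.

```{r chamber}
s <- sim_chamber_series(true_flux = 548, chamber_height = 0.15,
                        air_temp = 278, noise_sd = 0)
compute_flux(s)
```

For surfaces where chambers cannot be deployed but pore-gas N2O was
measured, `pore_gradient_flux()` provides a Fick's-law estimate using the
Millington–Quirk effective diffusivity
$D_s = D_0\,\theta_a^{10/3}/\phi^2$ with
$D_0 = 1.43\times10^{-5}$ m$^2$ s$^{-1}$ at 293 K scaled by
$(T/293)^{1.75}$. Millington–Quirk is the standard soil-gas tortuosity
model; we chose it as the package's own design decision for the
gradient-based estimate, and it should be read as a diffusion-model
estimate, not a calibration against paired chambers.

# Soil physics

Water-filled pore space is WFPS $= \theta_v / \phi$ with porosity
$\phi = 1 - \rho_b/\rho_p$. Field VWC error can push WFPS above 1; we
report such values unclipped with a warning, because silently clipping
would hide exactly the samples a reviewer should look at. Particle density
defaults to 2.65 g cm$^{-3}$ (mineral soil) when unmeasured. Mineral N in
salt extracts converts to a dry-weight basis through the gravimetric water
content; C/N is the plain mass ratio.

# Net and gross N transformation rates

Net mineralization is the change in total mineral N (NH4$^+$ + NO3$^-$)
between two extractions divided by the incubation time; ammonification and
nitrification use the single pools, so net mineralization =
ammonification + nitrification by construction. The label addition used in
the field protocol (2.1–2.6 mg N kg$^{-1}$ DW) is part of the measured
pools and needs no arithmetic correction.

Gross rates use $^{15}$N pool dilution: labeling the product pool (NH4$^+$
for mineralization, NO3$^-$ for nitrification) and tracking pool size $M$
and atom-% excess APE at two times. Under constant gross production $p$ and
consumption $c$,

$$\frac{dM}{dt} = p - c, \qquad \frac{dH}{dt} = -c\,\frac{H}{M}$$

($H$ = excess $^{15}$N mass, APE $= H/M$), which integrates to the
logarithmic Kirkham–Bartholomew estimators implemented in
`gross_rates_kb()`:

$$p = \frac{M_t - M_0}{\Delta t}\,
      \frac{\ln(\mathrm{APE}_0/\mathrm{APE}_t)}{\ln(M_t/M_0)},
  \qquad c = p - \frac{M_t - M_0}{\Delta t},$$

switching to the limit $p = (M_0/\Delta t)\ln(\mathrm{APE}_0/\mathrm{APE}_t)$
when $|\ln(M_t/M_0)| < 10^{-9}$. The estimators are exact under the
constant-rate model, which the test suite verifies against an independent
fine-step Euler integration of the ODE system. Several variants of the
two-point estimator circulate; we implement the logarithmic pair because it
is the one consistent with the ODE model at any pool change, not only small
ones. The first extraction (4 h) is treated as $(M_0, \mathrm{APE}_0)$
rather than the labeling time, avoiding any assumption of instantaneous
label mixing; both times are configurable.

When the label is *not* diluted (APE$_t \ge$ APE$_0$) the gross rate is not
determinable — the situation in strongly immobilizing soils, where only net
rates can be reported — and `gross_rates_kb()` returns a reason code
instead of a number.

```{r kb}
pair <- sim_pool_dilution(gross_production = 2, gross_consumption = 1,
                          M0 = 5, APE0 = 8, dt = 1)
unlist(gross_rates_kb(pair)[c("production", "consumption")])
```

# Incubation rates and denitrification partitioning

Flasks are incubated at 10 °C under oxic, anoxic, and anoxic + 10 vol-%
acetylene headspaces, sampled at days 0, 1, 2, 3 and 6. The oxic rate is
the OLS slope over the **first four** points (production is constant early
but can saturate by day 6). Anoxic series often show net N2O consumption
(without acetylene) or a plateau (with acetylene, which blocks N2O
reductase) after initial production, so the anoxic rate is the **maximum
consecutive-interval** rate; a whole-series fit would systematically
underestimate it, which the tests demonstrate on simulated series. Negative
maximum rates (monotone decline) are retained and flagged — they are
information about net N2O uptake, not missing data.

Because acetylene makes N2O the terminal denitrification product, the
acetylene:anoxic rate ratio measures how much denitrified N escapes as N2,
and the difference (floored at 0) estimates the N2 production rate.
Amendment responses are plain fold changes against the control flasks.

Amounts are headspace-only: no dissolved-N2O (Bunsen solubility)
correction is applied, since treatments are compared internally at a single
temperature; absolute rates in wet soils are accordingly conservative. The
ppm-to-mass conversion (`headspace_n2o_ug()`) requires the flask free
volume, which varies with soil packing and must be supplied.

# Erosion, N mobilization, and the emission factor

`transect_retreat()` casts transects perpendicular to a shoreline baseline
at fixed spacing, intersects them with dated cliff-boundary polylines, and
reports per-transect retreat rates with median and quartiles — the standard
baseline-and-transect procedure of shoreline-change analysis. When a
transect crosses a sinuous cliff line more than once, the intersection
nearest the baseline is used; transects missing an intersection on either
date are dropped and counted. Coordinates are planar metric; DEMs are
consumed as ESRI ASCII grids and must be co-registered upstream.

`dem_volume()` is positive-only differencing (old − new, clipped at zero)
times cell area: positive differences mean subsidence due to thaw and
erosion, and deposition is excluded by that sign convention.

The budget chain then runs:

1. `annual_volume_per_area()` = (volume / epoch) / (median retreat ×
   section length). The normalizing area is the *annually eroded
   footprint*; of the plausible choices it is the one that makes the
   volume, retreat rate and section length mutually consistent in the
   downstream budget, and the DEM-difference footprint remains available to
   callers by passing their own denominator.
2. `n_mobilization()`: remove the ground-ice fraction (default 0.82,
   typical of ice-rich Yedoma), multiply by dry bulk density
   (1220 kg m$^{-3}$) and by the total-N (0.16 %) and mineral-N
   (35.3 mg kg$^{-1}$) contents of freshly thawed material.
3. `emission_budget()`: the median daily flux of the high-emitting
   revegetated surfaces times a 100-day snow-free season gives the seasonal
   N2O-N loss; dividing by the mineral N release gives the emission factor,
   compared against the IPCC factor for N inputs to managed mineral soils
   (1 %).

```{r budget}
avpa <- annual_volume_per_area(223502, epoch_years = 7,
                               retreat_rate = 3.7, section_length = 1700)
b <- n_mobilization(avpa)
emission_budget(548, 100, b$mineral_n_release)
```

The total-N and mineral-N outputs of this chain are not independently
roundable to each other (39.35 g of mineral N corresponds to 1.784 kg of
total N at these contents, while the two quantities round to 39 and 1.7);
the package reports full precision and leaves rounding to the caller.

# Functional gene summaries

Captured-metagenome counts are summarised as percentages of all functional
gene sequences captured, with `other` absorbing non-listed families, so
per-sample percentages sum to 100. amoA aggregates bacterial + archaeal;
nir aggregates nirK + nirS. The (nirK+nirS)/nosZ ratio — nitrite reduction
(N2O source) over N2O reduction (the only sink) — is the indicator of N2O
production potential, computed per sample and summarised as mean ± SE over
the n = 3 replicates. No compositional (log-ratio) transformation is
applied: plain proportions are what the indicator is defined on. Read
length/copy-number corrections belong to the upstream capture pipeline and
are out of scope. qPCR copy numbers scale by elution/template volume per g
of dry soil extracted.

# Statistics

Field variables here are typically non-normal and heavily right-skewed, so
the bespoke layer is nonparametric: tie-corrected Kruskal–Wallis omnibus,
Dunn's pairwise z tests on mean ranks with the pooled tie-corrected
variance, p adjustment (Holm default; Bonferroni and none available, since
unadjusted pairwise p values are sometimes reported for small-n molecular
data), and a compact letter display. `compact_letters()` uses
insert-and-absorb: groups sharing a letter are pairwise non-significant and
significant pairs share no letter; minimal letter count is not guaranteed,
but absorption removes redundant columns, and both display axioms are
property-tested on randomized significance matrices. Paired treatment
contrasts use the exact Wilcoxon signed-rank test (n ≤ 25, no ties) and
correlations use Spearman's rank method. Welch ANOVA + Games–Howell — the
normal-data branch of such analyses — is deliberately not re-implemented:
base R and standard packages provide it, and only the nonparametric path is
bespoke here. All-tied inputs give an undefined H; we return p = 1 with a
degenerate flag rather than an error.

# The synthetic-data generators

Each generator inverts exactly the arithmetic its analysis counterpart
applies, so zero-noise output round-trips to the generating parameters —
the backbone of the test suite.

* `sim_chamber_series()` — linear accumulation from a 0.33 ppm ambient N2O
  baseline, with i.i.d. Gaussian noise on the mixing ratios (the GC's
  analytical error model), not on the slope. Default schedule: 5 samples at
  0/12.5/25/37.5/50 min.
* `sim_pool_dilution()` — exact closed form of the constant-rate model:
  $M_t = M_0 + (p-c)\Delta t$ and
  $\mathrm{APE}_t = \mathrm{APE}_0 (M_0/M_t)^{p/(p-c)}$
  ($\mathrm{APE}_0 e^{-p\Delta t/M_0}$ when $p = c$).
* `sim_incubation_series()` — linear production to an onset day, then
  decline (anoxic behaviour) or plateau (acetylene behaviour); schedule
  days 0, 1, 2, 3, 6.
* `sim_dem_pair()` — plateau–cliff–shore scene with the cliff foot on a
  cell edge, moved inland by a known retreat; the true eroded volume
  (retreat × length × height) and dated boundary polylines are attached for
  recovery tests.
* `sim_gene_counts()` — multinomial reads over a profile of relative
  abundances, remainder to `other`.
* `sim_surface_table()` — per-surface WFPS/mineral-N drawn uniformly within
  the profile ranges and fluxes from a *median-anchored* draw: half the
  probability mass log-uniform below the profile median, half above (linear
  halves when a range spans zero). A plain log-uniform over a range like
  133–6286 would have median ≈ 914, not the profile's 548; anchoring makes
  the generating median equal the profile median, which is the quantity the
  downstream budget consumes.

The packaged per-surface profiles (`surface_profiles()`,
`default_gene_profiles()`) carry the observed values where available and
field-realistic assumptions elsewhere, each marked in an `assumed_fields`
column. Replicate counts default to n = 5 (n = 3 for molecular data),
matching typical field designs; within-surface variance components are not
observed quantities, so the uniform/log-uniform ranges stand in for them.

What the generators do **not** emulate — and therefore what passing tests
cannot show about real data: spatial autocorrelation between plots, weather
and seasonal dynamics, non-constant gross rates over the pool-dilution
window (remineralization of the label), chamber-induced nonlinearity near
saturation, DEM co-registration error, and capture-probe bias in the gene
counts. Recovery results here validate the arithmetic and estimators, not
the field design.

# Numerical choices and problem sizes

Degenerate inputs are flagged, not guessed at: undetermined gross rates,
undefined fold changes and gene ratios, degenerate paired tests and
all-tied group comparisons each carry an explicit flag or reason. The KB
singular case switches formulas below $10^{-9}$ on $|\ln(M_t/M_0)|$;
the QC boundary accepts ties. Test and acceptance problem sizes (1,000
Monte-Carlo chamber series and null simulations, a 27-point
pool-dilution grid, 1000×850-cell synthetic DEMs at 2 m resolution,
$10^5$-read gene tables) are chosen so every recovery check has
sampling error well below its tolerance while the full suite runs in
seconds.
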