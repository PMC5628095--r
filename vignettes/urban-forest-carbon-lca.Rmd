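---
title: "Methods: simulating urban forest carbon over decades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating urban forest carbon over decades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbancarbon)
```

`urbancarbon` simulates the above-ground carbon balance of an urban tree
population over a multi-decade horizon. This vignette explains the model,
its assumptions and parameters, the numerical choices behind the
implementation, and what the synthetic-data generator does and does not
emulate.

## Growth model

Each of ten dominant species classes has a nonlinear DBH–age curve fitted
from street-tree data (the coefficients ship with the package and are taken
as given — the package does no curve fitting). Seven classes follow the
Chapman–Richards saturating form

$$\mathrm{DBH}(a) = A\,(1 - e^{-k a})^{p},$$

which passes through zero at age 0, and three (Pinus, Quercus, Robinia) the
Gompertz form

$$\mathrm{DBH}(a) = A\,e^{-b\,e^{-k a}},$$

which starts at the small positive diameter $A e^{-b}$ (4–6 cm). Both
families are strictly increasing and approach the asymptote $A$ from below,
reflecting the slowing diameter increment of mature trees. Both invert in
closed form:

$$a = -\ln\!\big(1 - (\mathrm{DBH}/A)^{1/p}\big)/k
\qquad\text{and}\qquad
a = -\ln\!\big(-\ln(\mathrm{DBH}/A)/b\big)/k,$$

which is how a measured inventory diameter becomes an age estimate that the
annual simulation can then advance.

The eleventh class, "mix" (26.5 % of the canopy; species the classifier
could not separate), is the unweighted arithmetic mean of the ten curve
*outputs*. Averaging outputs, rather than averaging coefficients or picking
a representative species, is the natural reading of an "average of the
equations" rule and keeps the mix curve pointwise between the member
curves; a canopy-fraction-weighted mean is available as an option
(`weighted = TRUE`). The averaged curve has no closed-form inverse, so
`mix_age_from_dbh()` uses bracketed root finding (age tolerance 1e-10,
diameter residual checked against 1e-6 cm); tests verify it against a dense
0.01-year grid scan.

### Out-of-range diameters

Some asymptotes sit below plausible urban diameters (Tilia's is 56.5 cm), so
a policy for $\mathrm{DBH} \ge A$ is unavoidable. The default caps the age
at the age reaching $(1-\varepsilon)A$ with $\varepsilon = 10^{-3}$ and
warns — large real trees stay usable and the distortion stays visible — and
a strict mode errors instead. Gompertz diameters below the age-0 value clamp
to age 0 with a warning. The curves' printed residual errors (4–11 cm) are
*not* applied as per-year noise, which would break monotonicity; an optional
generator flag adds one mean-zero draw with that SD to the DBH at inventory
construction only.

## Biomass and carbon

Above-ground dry biomass comes from allometric power laws
$b = a\,\mathrm{DBH}^{c}$ (kg, cm). Species-specific urban allometries
differ substantially between studies and sites, so the table is pluggable
and keyed from the species registry. The packaged defaults are two generic
temperate parameterisations — broadleaf ($a = 0.12$, $c = 2.40$) and conifer
($a = 0.10$, $c = 2.35$), valid 5–80 cm — chosen as package defaults so the
pipeline is self-contained; they are not the species-specific equations of
any particular assessment, and absolute carbon magnitudes therefore depend
on the table supplied. Out-of-range diameters are evaluated and warned
about rather than clamped, so pool totals stay smooth. Mix-class trees take
the mean of the ten class biomasses at the same DBH (average of biomasses,
not biomass at an average DBH — consistent with how the mix growth curve
averages outputs). Carbon is a fixed fraction of dry biomass, 0.5 by
default, the standard factor for woody tissue; no urban correction factor
is applied.

## Mortality

Annual mortality is static and stratified by land use: street trees 3.5 %/y
(pollution, sealed surfaces, traffic damage), mixed
residential/commercial 2 %/y, parks 1 %/y. Stratification is by land use
only (an optional flag is not provided for species stratification because
the demographic contract is per land-use class; species enter only through
growth and biomass). Two selection modes:

* **stochastic** — every alive tree dies independently with its class rate
  (Bernoulli thinning), the realistic annual stratified random selection;
* **expected_value** — a deterministic companion for analysis and testing.
  Record-level updates kill exactly `round(rate × alive)` trees by seeded
  draw; the simulation engines instead carry continuous per-tree survival
  weights multiplied by $(1-m)$ each year, so class populations equal
  $n(1-m)^t$ *exactly* and pool arithmetic is reproducible to machine
  precision.

The population half-life — years until half a cohort is dead — is the
smallest integer $t$ with $(1-m)^t \le 0.5$, i.e.
$\lceil \ln 0.5 / \ln(1-m) \rceil$ (computed with a $10^{-9}$ slack so
exact solutions such as $m = 0.5 \Rightarrow t = 1$ are not pushed up a
year): 20, 35 and 69 years at the three rates. There is no maximum-age kill
switch; instead any class whose average age exceeds 80 years is flagged as
highly uncertain (strictly greater — 80.0 exactly is not flagged), since
such average ages are unlikely for urban populations. Flagged trees keep
growing on their curves.

## The accounting year and the pools

`run_lca()` advances the whole inventory annually over the horizon (default
60 years from 2008). Within a year, in order:

1. ages increment and DBH is re-evaluated on each tree's curve (the engine
   is age-driven: a tree's state is its age, and DBH/biomass/carbon are
   functions of it);
2. on pruning years — if enabled — every alive tree loses the pruning
   fraction of its above-ground carbon to the dead/residual pool. Pruning
   (10 % every 10 years is the common practice figure) is **off by
   default**, matching a reference computation that discusses but does not
   apply it. A tree's pruning reduction persists multiplicatively;
3. mortality is applied; dying trees move their **current-year** carbon
   into the accumulated dead pool.

Grow-then-die ordering means a tree killed in year $t$ contributes its
year-$t$ biomass — the natural reading of pools "accumulated" at reporting
time. The dead pool never decays (no decomposition is modelled; a decay
hook would be the extension point), so alive + dead carbon is monotone
non-decreasing, a property the tests assert. Reports are emitted at year 0
and every interval (default 10 years, with a trailing partial interval if
the horizon is not a multiple); densities divide pool carbon by a single
land-cover area (default 70,000 ha = 700 km²) for alive *and* dead pools
alike. Per-class densities use the same total area, so they read as
contributions to the citywide density rather than within-class densities.

## Planting scenarios

`run_planting_scenario()` follows one cohort of identical mix-class trees
(reference case 100,000 trees, 70 years) from a start age of 0 — the
Gompertz members make the age-0 mix DBH small but nonzero (≈1.5 cm), which
is accepted as-is absent any sapling-size specification. Because the cohort
is homogeneous, stochastic thinning is drawn as a population-level binomial
each year, distributionally identical to per-tree Bernoulli draws and far
cheaper for replicate analyses. `compensation_analysis()` then divides each
land-use class's alive-carbon decline (from simulation start to the class
rate's half-life year, clamped to the horizon) by the scenario's alive
carbon at that half-life year: a ratio above 1 reads as "how many times
larger the initiative would need to be to compensate the loss".

## Synthetic inventory generator

The generator emulates the summary statistics of a remotely sensed city
inventory of roughly 1.4 million trees: species classes drawn from the
published canopy fractions, land-use labels from a street/mixed/park split,
ages from per-class truncated normals (means 49/52/56 y, SDs 15/17/15 y,
truncated below at 1 year), and DBH derived from age through the growth
curves. Choices made where the source statistics underdetermine the
design:

* **Age family.** Only means and SDs are published; a truncated normal is
  the simplest family with controllable moments and no negative ages.
* **Land-use split.** No numerals are published; the shipped
  0.20/0.45/0.35 street/mixed/park default is a package value chosen to
  put a plausible plurality in mixed residential/commercial use, and it is
  a plain config field.
* **DBH is implied, not forced.** Forcing both the age moments and the
  36 cm mean DBH would break the growth-curve relationship the simulation
  depends on; the curves at these age distributions imply a mean DBH of
  ≈35.4 cm, within the ±15 % calibration band the tests check.
* **Heights** come from a monotone saturating height–DBH rule and are
  cosmetic; the carbon path is DBH-only.

What passing tests therefore show: the demographic machinery (sampling,
survival, half-lives, conservation, ordering of trajectories) behaves
exactly as specified on populations with realistic moments. What they do
not show: absolute carbon magnitudes for any real city, which hinge on the
allometry table and the real (spatially clustered, measurement-noisy,
understory-truncated) inventory — neither of which the generator emulates.

## Numerical choices and degenerate inputs

* Closed-form inverses are used wherever they exist; tests cross-check them
  against an independent bisection oracle to < 1e-4 years.
* Expected-value pool arithmetic is continuous precisely so that survival
  invariants hold exactly rather than "within rounding".
* Empty inventories yield all-zero report series and an explicit empty
  summary, not errors; empty populations have `NA` average age and an
  absent uncertainty flag.
* Unresolvable species or allometry keys fail before the simulation starts;
  CSV readers validate row invariants and report 1-based file line numbers.
* One seed governs a run (`--seed` on the CLI, `seed` fields in configs);
  replicate draws derive per-replicate seeds by offset, and every CLI output
  is accompanied by a JSON manifest (config snapshot, seed, package
  version, input digests) sufficient to re-run it bit-identically.

Problem sizes used by the test suite and the acceptance script — 50,000-tree
inventories for trajectory-shape checks, 100,000 for moment recovery and
cohort survival, 200 replicate seeds for the stochastic half-life bracket —
are the package's chosen verification scales: large enough that 3-standard-
error bands are tight, small enough to run anywhere.

## Known limitations

Static mortality rates ignore age-, size- and climate-dependent risk;
growth curves come from one temperate street-tree dataset and carry no
site or climate modifiers; the dead pool neither decomposes nor is
harvested, so late-horizon dead-carbon figures are upper bounds; emissions
from maintenance, planting, irrigation, removal and processing are out of
scope; and the default allometry is generic, so absolute pool magnitudes
should only be interpreted with a user-supplied, site-appropriate table.
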