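---
title: "Root cortical phenes and nitrogen capture: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Root cortical phenes and nitrogen capture: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootcortex)
```

# The question and the modelling strategy

Maize roots spend a large share of daily photosynthate on maintaining their
own cortex. Cortical anatomy therefore sets the metabolic price of soil
exploration: fewer cortical cell files (CCFN) and larger cortical cells
(CCS) both mean less respiring cytoplasm and less structural nitrogen per
gram of root, while aerenchyma (RCA) replaces living cortex with air. But
anatomy also moves root diameter — fewer files make thinner roots, larger
cells make thicker ones — and diameter sets the carbon cost of every
centimetre of new root. Whether a cortical phene state pays off under
nitrogen scarcity is thus a whole-plant budgeting question, which this
package answers with a simulation model in two layers: an empirical
**phene-cost model** and a mechanistic **root/soil simulator**.

# The phene-cost model

Four independent ordinary-least-squares regressions predict, from CCFN
(files) and CCS (µm²):

* root respiration (g CO₂ g⁻¹ DW d⁻¹),
* optimum tissue nitrogen concentration (µmol g⁻¹),
* minimum tissue nitrogen concentration (µmol g⁻¹),
* root diameter (mm).

`fit_cost_models()` fits them from plant-level anatomy records. The two
nitrogen responses are identified by treatment: tissue N measured under
high-nitrogen supply estimates the optimum (the concentration a
well-supplied plant maintains) and tissue N under low supply estimates the
minimum (the concentration below which growth stops). Responses are fitted
untransformed; predictions must be positive and satisfy
`minimum_n < optimum_n`, and predictions outside the observed anatomical
domain (CCFN 6–18, CCS 170–450 µm²) warn, because the linear surface has no
support there.

The package ships canonical predictions for the four contrast states
(`canonical_phene_states()`): reduced CCFN (6 files) and increased CCFN
(18 files) at CCS 360 µm², and large (450 µm²) and small (200 µm²) CCS at
10 files. These four rows are numerically planar per response, so a plane
fitted through them (`canonical_cost_coefficients()`) reproduces them to
about one percent; that plane is the cost surface used for arbitrary
(CCFN, CCS) combinations in grids and factorials.

# The synthetic parameterization generator

Because fitting needs raw plant-level data, `generate_anatomy_dataset()`
emulates the parameterization study's design: 4 anatomical categories × 3
genotypes × 3 plants × 2 nitrogen levels = 72 records. Genotype-level
anatomy is drawn uniformly inside category windows (reduced CCFN 6–9,
increased CCFN 14–18, small CCS 170–260 µm², large CCS 360–445 µm²; the
non-focal phene from the mid-range); all categories share one generating
plane per response, and responses add independent Gaussian noise
(defaults: 0.003 for respiration, 35/30 µmol g⁻¹ for the nitrogen
responses, 0.05 mm for diameter — roughly 5–10 % coefficients of variation,
typical of greenhouse physiology). An optional `n_level_effect` shrinks
low-nitrogen respiration and tissue N; it defaults to 0 so that pooled
fitting is exactly unbiased, since how the original regressions pooled
treatments is not documented. The generator emulates the *tabular*
structure only: it has no genotype-level random effects, no response
correlations and no measurement heteroscedasticity, so coefficient recovery
on synthetic data demonstrates the estimator's correctness, not robustness
to real anatomical data pathologies.

# The root/soil simulator

`run_simulation()` advances a single plant in daily steps (default 40 days;
the model is not intended beyond 42) in a 60 × 26 cm stand over a 150 cm
soil profile in 3 cm layers. Each day, in fixed order:

1. **Light interception** by the stand shading function
   `1 − exp(−k·LAI)` (`k = 0.6`), LAI over the plant's ground area.
2. **Gross assimilation** = irradiance (12 MJ m⁻² d⁻¹) × ground area ×
   intercepted fraction × light-use efficiency (3 g MJ⁻¹) × stress factor.
3. **Maintenance respiration**, paid first from assimilate plus the carbon
   reserve: shoot at 0.01 g C g⁻¹ d⁻¹, and each root segment at the
   phenotype's respiration rate (CO₂ converted to C by 12/44), discounted
   by aerenchyma (below).
4. **Shoot allocation**: the potential leaf-area sink (22 % relative
   expansion, capped at 350 cm² d⁻¹, times the stress factor) is served
   from at most 70 % of the remaining pool; at least 30 %
   (`root_share_min`) is held back for roots, so the shoot sink cannot
   starve the root system outright.
5. **Root growth** (`grow_roots()`): axial tips (1 primary, 3 seminal,
   crown whorls on a phytomer schedule from day 8) elongate at potential
   class rates with multiplicative lognormal jitter; construction cost per
   cm is cross-section area × tissue density (0.12 g cm⁻³), so cost scales
   with diameter². Axial tips are served before laterals: carbon scarcity
   curtails branching before it curtails the depth race, mirroring the
   sink-strength hierarchy of real root systems. Laterals initiate behind
   each axial tip at the phenotype's branching density (4–8 cm⁻¹), begin
   elongating 3 days later (the branching zone sits behind the elongation
   zone), run at 0.3 × the axial diameter, and are determinate at 4 cm.
   Unspent carbon banks to the reserve.
6. **Nitrate uptake and transport** (`uptake_and_transport()`): each
   segment takes up nitrate from its layer by Michaelis–Menten kinetics
   *per unit root surface* (Imax 12 µmol cm⁻² d⁻¹, Km 0.05 µmol cm⁻³
   solution), capped by whole-plant demand (the gap between the optimum
   nitrogen pool and the current pool) and by a per-layer extraction limit
   of 40 % of the layer stock per day. Then nitrate advects one layer
   down at the texture's leaching velocity times the day's drainage
   (silt loam 1.2, loamy sand 3.4 cm per cm drainage; drainage 0.35 cm d⁻¹
   plus 1.5 cm rain events every 5 days); nitrate leaving the bottom layer
   is lost.
7. **Stress update**: the nitrogen stress factor is 1 when the plant
   nitrogen concentration (pool / aerenchyma-discounted living dry weight)
   meets the phenotype's optimum, 0 at the minimum, linear between; it
   multiplies both light-use efficiency and leaf expansion the next day.
   Through the leaf-expansion term, stress shrinks the shoot sink and
   thereby shifts carbon toward roots — an emergent, not prescribed,
   stress response.

**Aerenchyma** develops per segment from age 1 day, linearly to the
phenotype's maximum at 20 days (maximum allowed 0.39 of the cross-section).
It discounts segment respiration and the segment's contribution to the
nitrogen requirement by `0.5 × rca/0.39` each (both effects halve costs at
the reference maximum). The nitrogen side is implemented as a demand-side
discount — aerenchymatous tissue simply requires less nitrogen — rather
than as a one-time credit to the nitrogen pool: the two are functionally
equivalent (both raise the effective nitrogen concentration), but the
demand-side form keeps the nitrogen ledger exactly `Δ(plant N) = uptake`.

**Conservation.** Every day, assimilated carbon equals biomass gain (shoot
+ root + reserve, times the 0.45 carbon fraction) plus respired carbon, and
soil nitrogen loss equals uptake plus bottom-boundary leaching; the test
suite asserts both to 1 part in 10⁸ daily over full runs.

**Stochasticity and determinism.** The only randomness is 5 % lognormal
jitter on daily elongation and lateral initiation, seeded once per
replicate; identical seed and inputs give bit-identical daily tables.
Experiments use 4 replicates with seeds `base_seed + 0:3`.

## Why these mechanisms, and not simpler ones

Three design choices carry the phene biology and were genuinely open:

* **Surface-based uptake.** If uptake scaled with root *length*, thin
  roots would dominate every comparison: halving diameter would double
  both length per unit carbon and uptake capacity. With kinetics per unit
  *surface*, a thicker root takes up more per centimetre, so diameter
  trades length against per-length capture (capacity ∝ carbon/diameter,
  not carbon/diameter²). This keeps the diameter penalty of large
  cortical cells at the modest size the anatomy warrants, instead of
  letting it swamp the respiration and nitrogen savings.
* **The per-layer extraction cap.** Mass flow and diffusion limit how fast
  roots can mine a soil volume regardless of root length density. The 40 %
  per day cap is a deliberately simple proxy: where roots are dense (the
  silt-loam topsoil) capture is cap-limited and extra laterals add only
  carbon cost, while where roots are sparse (deep layers through which the
  loamy-sand nitrate plume transits) capture is kinetics-limited and extra
  lateral surface genuinely adds capture. The branching-density × texture
  crossover — low branching best in silt loam, high branching best in
  loamy sand among cheap-cortex phenotypes — emerges from exactly this
  asymmetry.
* **Axial-priority carbon allocation.** Without it, dense or thick
  branching drains the axial depth race whenever carbon is scarce, and
  expensive phenotypes spiral: shallow roots miss the descending nitrate,
  stress cuts assimilation, roots stall further. Serving axial tips first
  bounds that feedback at the biologically defensible point.

# Experiments

* `calibrate_stress_levels()` bisects the nitrogen supply scalar until the
  reference phenotype's mean shoot dry weight is reduced by 25/50/75 %
  relative to its unstressed run (internal tolerance 1.5 points, at most
  14 iterations per target; the supply scalar multiplies the profile's
  initial nitrate of 90 mmol per plant area).
* `transphenic_decomposition()` isolates component contributions by
  swapping respiration, the nitrogen-requirement pair, or diameter
  individually from a variant phene state into the reference; `combined`
  swaps all three and `transphenic` all but diameter. Benefits are percent
  changes of replicate-mean shoot dry weight and root length; the additive
  expectation is the exact component sum and synergy the exact residual.
  Decompositions are reported at the medium (50 % reduction) calibration
  point of their reference phenotype.
* `sensitivity_grid()` crosses CCFN × CCS × stress scalars;
  `factorial_experiment()` crosses the extreme CCFN/CCS states with either
  an aerenchyma contrast (10 % vs 30 %) or a branching-density contrast
  (4 vs 8 cm⁻¹) in each soil, reporting relative increase over the worst
  performer (ties, vanishingly unlikely under jitter, would be broken by
  label order).

# Numerical choices and degenerate inputs

Layers are half-open intervals, depth positive downward; a segment belongs
to the layer of its midpoint at creation. The advection fraction
`velocity × drainage / thickness` is capped at 1 (at most one full layer
displacement per day; rain events in loamy sand reach this cap, which adds
numerical dispersion of the plume — acceptable since only the
texture *contrast* is interpreted). Uptake is rationed proportionally when
demand scaling or layer caps bind. Zero nitrogen supply, zero irradiance
(full starvation) and zero-carbon root growth are all exact special cases
with conserved ledgers; respiration unpayable from assimilate plus reserve
is truncated at the available pool (carbon starvation) rather than driving
pools negative. A singular anatomy design (constant CCFN *and* CCS, or
collinear predictors in a response subset) is an explicit error, as are
cost predictions that are non-positive or have crossed nitrogen
requirements.

# Problem sizes

Default experiments use 40-day runs (roughly 0.4 s each), 4 replicates per
scenario, the 2×2×2 factorials, and 50 synthetic datasets for the
coefficient-recovery check; a full calibration is about 100 runs. These
sizes put every analysis in the minutes range on a single core while
keeping replicate standard errors a few percent of the means — sufficient
for the ordering-level claims the package makes.

# Limitations

The simulator is a desk-scale re-implementation of the functional-
structural modelling idea, not a port of any existing simulator: absolute
outputs (e.g. the sizes of relative benefits) are not comparable to
published magnitudes, and only signs, orderings and interaction structure
should be interpreted. Water limitation, temperature, oxygen, soil
penetration resistance, phytohormones, microbial turnover and
mineralization are not modelled; soil texture acts solely through nitrate
mobility; root placement is one-dimensional (depth) with no explicit
horizontal geometry, so root competition within a layer is represented
only by the extraction cap; and the cost surface is linear in CCFN and CCS
by construction, so any anatomical cost nonlinearity is outside the model
family.
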