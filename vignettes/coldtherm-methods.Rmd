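---
title: "Modelling human heat transfer in cold, still air with coldtherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling human heat transfer in cold, still air with coldtherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldtherm)
```

## The model

`coldtherm` is a lumped-parameter (multi-node) model of human thermal
physiology for still, cold air in the 0–14 °C range. The body is divided
into twelve anatomical segments — head, shoulder, chest, abdomen, upper arm,
lower arm, hand, left/right thigh, left/right calf and feet — with a total
skin area of 1.92 m², the anthropometry of a healthy adult male. Each
segment is a radial stack of four lumped layers: a **core**, an
**equivalent layer** that merges muscle and fat, a **skin** layer and,
where the segment is dressed, a **clothing** layer. A single well-mixed
central blood pool exchanges heat convectively with every tissue node.

### Passive system

Each tissue node `(i, j)` obeys a heat balance

$$C_{p}(i,j)\,\frac{dT(i,j)}{dt} = Q(i,j) - Q_b(i,j) + Q_{c,\mathrm{in}} -
Q_{c,\mathrm{out}} - RES(i,j) - E(i,j),$$

with metabolic production `Q`, blood exchange `Q_b`, conduction to adjacent
layers `Q_c`, respiratory loss `RES` (chest core only) and skin evaporation
`E` (identically zero in the low-temperature mode: at these ambients sweat
evaporation is negligible next to metabolic and conductive flows). The
central blood pool integrates the sum of all node exchanges,
$C_{p,b}\,dT_b/dt = \sum_{i,j} Q_b(i,j)$.

The innermost core surface is a Dirichlet boundary held at 37 °C — the deep
body acts as a thermostat-regulated reservoir — so each core node also
conducts to a 37 °C virtual wall through its inner half-thickness. The net
wall flow is reported in the energy bookkeeping so that first-law closure
(production + wall input = convection + respiration) can be asserted at
every steady state; it closes to machine precision.

Individual terms:

* **Cold metabolic boost.** $Q^*(i,j) = Q_0\,(2 - 2^{0.1\,(T - T_0)})$,
  clamped at zero: at the set point $Q^* = Q_0$, ten degrees below it
  $Q^* = 1.5\,Q_0$. Applied to every node with nonzero basal rate.
* **External work.** $W(i,2) = \max(0,\ 58.2\,\mathrm{met}\,A - Q_{0,\mathrm{tot}})\,\mathrm{Metf}(i)$,
  equivalent layer only. The default activity level (0.7 met) sits just
  below the whole-body basal rate, so a resting subject does no external
  work.
* **Shivering.** $Ch(i,2) = g\,\mathrm{Cld}(1,1)\,\mathrm{Clds}\,\mathrm{Metf}(i)$
  with gain $g = 24.36$ W/°C² — the classic bilinear central-times-skin
  form, distributed over the musculature like work.
* **Blood exchange.** $Q_b = a\,\rho_b\,B_f\,(T - T_b)$ with countercurrent
  ratio $a = 1$ and $\rho_b = 1.067$ W·h/(L·°C). Flows are carried in L/h,
  which makes this product come out directly in watts; internally all other
  quantities are SI.
* **Cold vasoconstriction (core/equivalent beds).**
  $B_f^* = B_b\,2^{(T-37)/10}$: a Q10 down-scaling that halves perfusion for
  every 10 °C of tissue cooling. A `"literal"` mode applying the change term
  with the opposite sign — which would *increase* perfusion in the cold — is
  retained behind a flag for comparison, but the physiological form is the
  default because vasoconstriction, not vasodilation, is the observed cold
  response.
* **Respiration.** $RES = 0.0014\,Q_{tot}(34 - T_a) + 0.017\,Q_{tot}(5.867 - P_a)$
  applied to the chest core. The ambient vapor pressure $P_a$ is derived
  from relative humidity with the Magnus saturation correlation
  ($P_{sat} = 0.61094\,e^{17.625\,T/(T+243.04)}$ kPa), which matches steam
  tables to better than 1% over the range of interest.

### Active system

Thermoreception is the signed deviation from the node set point,
$Err = T - T_{set}$, split into exclusive warm/cold receptor signals
($\mathrm{Warm} = \max(Err, 0)$, $\mathrm{Cld} = \max(-Err, 0)$). Skin
signals integrate through the sensor weights `SKINR` (summing to one) into
`Warms`/`Clds`. The effector signals combine central command (head core)
with the integrated skin state:

$$DL = C_{dl}\,Err(1,1) + S_{dl}(\mathrm{Warms}-\mathrm{Clds}) + P_{dl}\,\mathrm{Warm}(1,1)\,\mathrm{Warms},$$
$$ST = -C_{st}\,Err(1,1) - S_{st}(\mathrm{Warms}-\mathrm{Clds}) + P_{st}\,\mathrm{Cld}(1,1)\,\mathrm{Clds},$$

both clamped at zero before entering the skin blood-flow law

$$BF(i,3) = \frac{B_b(i,3) + \mathrm{SKINV}(i)\,DL}{1 + \mathrm{SKINC}(i)\,ST}\; k_m(i), \qquad k_m = 2^{Err(i,3)/RT},$$

with the local sensitivity scale `RT` = 10 °C. Defaults for the gains
(`Cdl` 117, `Sdl` 7.5, `Cst` 5, `Sst` 0.5, product terms off) follow the
multi-node modelling lineage; all are scenario-configurable. No sweating
controller is implemented: evaporation is disabled in this temperature
range.

### Clothing and environment

Clothing is a pure thermal resistance in ideal contact with the skin (no
air gap): per covered segment the skin–garment conductance is
$A / (\tfrac{1}{2} d_{skin}/\lambda_{skin} + d_{cl}/\lambda_{cl})$, and the
garment node carries the fabric's thermal mass for transients. Two
ensembles ship with the package, transcribed from hot-wire measurements of
worn garments: a winter suit (upper body λ = 0.062 W/(m·K), 5.5 mm; lower
0.037, 5.1 mm) covering all but head and hands, and a summer
short-sleeves-and-shorts set (0.034/0.4 mm upper, 0.031/0.9 mm lower)
leaving lower arms, hands, calves and feet bare. The clothing area factor
defaults to `fcl = 1.35`.

The environment is still air with radiation off — the validation
measurements behind this model family were taken at night precisely so that
radiative flux was negligible, and wind is deferred. The outer surface
(garment, or bare skin) exchanges heat through a natural-convection power
law

$$h_c(i) = s\; C_i\; \max(T_{surf} - T_a,\ 0)^{1/4},$$

the classic quarter-power buoyancy scaling. $C_i$ is a per-segment shape
constant (slender limbs ~1.2–1.4, trunk ~0.9, head 1.1); the single global
scale $s$ was calibrated once, by one-dimensional root finding
(`calibrate_convection_scale()`), so that the steady 18 °C indoor,
short-sleeves scenario reproduces the reference whole-body area-weighted
coefficient of 3.27 W/(m²·K); the frozen value is $s = 1.5226$. This
correlation stands in for the boundary-layer CFD that a full spatial model
would solve; it reproduces area-weighted aggregates, not local flow fields.

From a converged state the package decomposes insulation as
$R_t = A(\bar T_s - T_a)/q$, $R_a = A(\bar T_c - T_a)/q$ and
$R_i = (R_t - R_a)/f_{cl}$, with $q$ the steady surface heat flow; the
identity $R_i f_{cl} + R_a = R_t$ holds algebraically.

## Parameter provenance

The layer conductivities and specific heats of the equivalent layer are
taken from the published per-segment table of this model family (e.g. head
0.1 W/(m·K) and 2318.4 J/(kg·K)); hands and feet, absent from that table,
reuse the lower-arm and calf properties as the closest printed analogue.
Per-segment areas, basal metabolic rates, set points, basal blood flows and
the SKINR/SKINV/SKINC/Metf distributions are not published for this exact
12-segment division, so the packaged defaults were chosen once from the
65-node modelling lineage the family descends from, anchored to three
published basal heat flows (head 17.17 W, upper-arm equivalent layer
0.639 W, abdomen 22.29 W) and to the 1.92 m² total area, and are shipped as
an editable TSV (`extdata/body_default.tsv`) so that any entry can be
overridden from a scenario file.

## Numerical choices

* **Integrator.** `deSolve::lsoda` with absolute tolerance 10⁻⁶ K and
  relative 10⁻⁸, over the ~49 coupled states (36 tissue nodes, up to 12
  garment nodes, one blood pool).
* **Steady state.** Integration proceeds in two-hour blocks until the
  largest derivative falls below 10⁻⁶ K/s, then a damped Newton iteration
  with a finite-difference Jacobian polishes the state to ~10⁻¹² K/s. The
  polish makes steady states reproducible to machine precision, which the
  calibration root-finds rely on; two runs started from the set points and
  from a uniform 20 °C agree to ~10⁻¹⁴ °C.
* **Heat-source calibration.** `calibrate_equivalent_heat_sources()` does a
  per-segment scalar root find (Brent) on the equivalent-layer source so
  the steady skin temperature matches a target within 0.05 °C; trial
  sources large enough to push the state out of the physical range are
  treated as "above target", which is safe because steady skin temperature
  is monotone in the source. Self-consistency (recovering the model's own
  realized sources from its own skin temperatures) holds to ≲0.1% on all
  twelve segments.
* **Degenerate inputs.** A 37 °C environment with zero metabolism is an
  exact fixed point; zero surface gradient gives zero convection (no
  buoyancy); negative work, shivering, dilation and constriction are all
  clamped at zero; states outside (−50, 50) °C are rejected with the node
  named.
* **Problem sizes.** The shipped analyses use single steady runs (seconds
  each), a six-temperature sweep, and 1000-replicate synthetic measurement
  batches — sizes chosen so a full reproduction runs on a laptop in well
  under a minute apart from the twelve-segment calibration check (~1 min).

## The synthetic measurement generator

No public button-logger dataset accompanies this model, so
`generate_synthetic_measurements()` fabricates one from a converged
simulation following the field protocol: twelve sites (bilateral chest,
abdomen, thigh and calf; head, upper and lower arm, back), one-minute
cadence, 60 samples. Each series is the simulated steady skin temperature
plus i.i.d. Gaussian sensor noise (sd 0.05 °C, the loggers' stated
accuracy) plus, on the bilateral pairs, a per-side constant offset
(Gaussian, sd 0.6 °C) standing in for left–right physiological asymmetry.
With these defaults the mean absolute left–right difference is ≈0.67 °C,
comfortably inside the ≤2 °C field observation, and the sd was chosen for
that realism before any validation statistic was computed. The generator
emulates sensor noise and bilateral asymmetry only: it does not emulate
slow drift, imperfect sensor contact, posture changes or
ambient fluctuation, so validation statistics computed against it
demonstrate the pipeline's correctness, not field accuracy. The "back"
site has no segment of its own and is compared against the shoulder skin
node; that mapping is the largest single source of site error in real
comparisons.

`relative_errors()` follows the field convention: the measured value is the
mean of the final 30 stable samples, and errors are percentages of the
Celsius reading (a few-degree discrepancy on a ~30 °C skin reading is a
few percent — the convention under which published error grids of this
model family, with entries up to ~16%, are interpretable). The report
surfaces the per-site errors, their maximum, the error of the site-mean
temperature and the mean bilateral difference without collapsing them into
a single figure of merit.

## Design choices that were genuinely open

* **Equivalent-source semantics.** The calibrated "equivalent-layer heat
  source" *replaces* the layer's metabolic + work + shivering input rather
  than adding to it, so a calibrated value is directly comparable to the
  realized physiological source and self-recovery is exact.
* **q in the resistance formulas.** The decomposition multiplies by body
  area and divides by the *total* surface heat flow (W); only this reading
  gives resistances in m²·K/W. Respiratory loss bypasses the clothing and
  is excluded from that flow; the air-layer share is a temperature ratio
  and is unaffected.
* **Thirteenth sensor site.** The sensor-weight sum runs over the twelve
  modelled segments with ΣSKINR = 1; no thirteenth site exists in this
  segmentation.
* **Hands and feet** are ordinary four-layer segments (with thin layers)
  rather than geometric simplifications, since only lumped balances are
  solved.

## Known limitations

* **No radiation, no wind, no moisture.** All three are outside this model
  version's scope; adding a radiative pathway would roughly halve the
  outer film resistance at these temperatures.
* **The air-layer share of insulation is large.** With radiation off and
  the film coefficient calibrated to ~3.3 W/(m²·K), the outer air film
  contributes ≈0.2 m²·K/W — more than the winter fabric itself
  (≈0.09 m²·K/W) — so this model attributes ~65% of total insulation to
  the air layer across the 0–14 °C sweep. Published CFD-based
  decompositions of the same scenario report a much smaller share
  (23–41%), but the absolute resistances printed alongside them imply film
  coefficients of order 10²  W/(m²·K), dimensionally inconsistent with the
  same studies' own whole-body convective coefficients. We report our
  decomposition as computed and flag the disagreement rather than adjust
  either quantity; users comparing against manikin standards (where
  still-air film resistance ≈0.1 m²·K/W *with* radiation) should enable
  nothing — just be aware the no-radiation film is necessarily larger.
* **Steady states are assumed** for all reported aggregates; transient
  trajectories are available but uncalibrated against wearable data.
* **One subject.** The defaults describe one 1.92 m² adult male; population
  variation enters only through the editable parameter table.

## A worked cold-exposure run

```{r example, eval = FALSE}
model <- build_body()
winter <- clothing_ensemble("winter")
res <- simulate_body(model, winter, environment_spec(0, RH = 0.85))
res
summarize_result(res)$segments

# six-temperature sweep and the resistance picture
sweep <- ambient_sweep(model, winter, c(0, 3, 5, 8, 12, 14), RH = 0.85)
sapply(sweep, function(r) r$clothing_surface_T$overall_mean)

# synthetic loggers and validation statistics
ms <- generate_synthetic_measurements(res, seed = 1)
relative_errors(res, ms)
```
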