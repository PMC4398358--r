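---
title: "Random-walk noise mapping: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-walk noise mapping: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noisewalk)
```

## The model

`noisewalk` treats a workplace as a two-dimensional plane (metres, origin
at the south-west corner; all levels are implicitly on the 1.5 m
measurement plane, so no vertical coordinate exists anywhere in the
model). Three kinds of agents live on it:

* **Stationary machines** at fixed positions, each described by an
  A-weighted sound power level $L_{WA}$ (dB re 1 pW) and duty-cycle
  probabilities $(p_{on}, p_{off}, p_{idle})$.
* **Moving machines** (excavators, piling rigs, narrow-gauge carts)
  confined to a rectangular working subarea, with the same emission
  description plus random-walk parameters.
* **Worker groups**, each a set of walkers confined to a subarea, who
  emit nothing and record their exposure.

Per simulation step, every machine independently samples a duty state
(full, idle, or off), every moving machine and worker takes one random
step, and the instantaneous sound-pressure field is evaluated at every
grid node. A source of power $W = 10^{L_{WA}/10}\,\mathrm{pW}$ radiating
hemispherically over a hard, non-absorbing surface produces intensity

$$I(r) = \frac{W}{2\pi r^2},$$

and the received per-source level is corrected in the level domain for
obstacles before contributions are summed energetically with the
background intensity $I_{BG} = 10^{L_{BG}/10}\cdot 10^{-12}$ W/m²:

$$L_i = 10\log_{10}\!\Bigl(\tfrac{I_{BG}}{I_0} + R_i \sum_k
        10^{A_{ik}/10}\,\tfrac{I_{ik}}{I_0}\Bigr), \qquad I_0 = 10^{-12}.$$

$A_{ik}$ is the screening correction of the straight path from source $k$
to node $i$ (0, −5 or −10 dB) and $R_i$ the facade-reflection factor of
the receiver (0 or +3 dB). Air absorption, wind and temperature
gradients, ground absorption and source directivity are deliberately
outside the model: barrier effects are the dominant propagation
correction at workplace scale, and this simple approximation keeps the
per-step field evaluation cheap enough to run thousands of steps.

Movement is a Pearson random walk: step $j$ displaces a walker by
$a_j(\cos\theta_j, \sin\theta_j)$ with $\theta_j \sim U[0, 2\pi)$. Each
new position depends only on the previous position, never on the
previous heading — there is no drift, persistence or path planning, which
is a fair description of a machine shuttling unpredictably inside a
work zone but not of one following a haul road.

After $N$ steps, each node's map value is the equivalent continuous level
$L_{Aeq} = 10\log_{10}\bigl(\frac{1}{N}\sum_s 10^{L_s/10}\bigr)$ — every
step is an equal time slice — and each worker's recorded series feeds the
dose, TWA, and exceedance-index calculations.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `grid_spacing` | 1 | m | Node spacing of the receiver mesh. 1 m resolves workplace-scale contours; halve it for small areas. |
| `max_step` | 5 | m/step | Upper bound on walk step length; with 1500 steps this lets a walker sweep a typical subarea many times over. |
| `n_steps` | 1500 | steps | Mostly-stationary layouts converge in a few hundred steps; moving-machine layouts keep improving up to about 1500, after which repeat-to-repeat differences plateau. |
| `lwa_idle` | `lwa_full` − 10 | dBA | Idle emission is not a published machine property; a 10 dB drop is a conservative engineering default and is always overridable per machine. |
| `exchange_rate` (Q) | 3 | dB | Dose-halving rate. The 3-dB (equal-energy) convention reproduces the bundled dosimeter reference values; a 5-dB option covers OSHA-style assessments. |
| `criterion_level` (CL) | 90 | dBA | Level giving 100% dose over the criterion duration. |
| `criterion_duration` | 480 | min | The 8-hour reference shift. |

## Numerical choices

* **Distance clamp.** A node can coincide with a source, where $1/r^2$
  diverges; source–receiver distances are clamped below at the grid
  spacing (1 m by default), consistent with treating sources as 1-m
  point-source cells.
* **Screening in 2-D.** With no heights there is no geometric way to
  decide whether a receiver can see over a barrier, so the screening
  class (full = −10 dB, partial = −5 dB) is declared per barrier; full
  dominates partial when several barriers cross one path. Walkers are not
  obstructed by barrier footprints, and receivers inside a footprint are
  still computed — buildings are obstacles, not exclusion zones.
* **Reflection is a receiver property.** The +3 dB facade correction is
  decided once per receiver (within 1 m of any reflective facade,
  outside the footprint) and applied to every source path at that
  receiver, not to the background term. It therefore shifts a
  single-source prediction by exactly +3 dB.
* **Region boundaries are closed**, so a walker clipped to a subarea edge
  is still inside; grazing contact of a path with a barrier footprint
  counts as an intersection.
* **Boundary policy.** Out-of-area step proposals are redrawn (heading
  and length) up to 1000 times, which preserves isotropy away from the
  walls, then clamped as a last resort; a `clip` policy is available
  when cheap biased steps are acceptable.
* **Step-length density.** Only the existence of a step-length density is
  inherent to the walk model; the uniform density on $(0, a_{max}]$ is
  the simplest choice and is the default. The fixed-length mode exists
  because it admits the closed form $E|R_n - R_0|^2 = n a^2$, used in the
  tests.
* **Duty states have no memory.** States are sampled independently per
  machine per step; a persistence (Markov) model would need dwell-time
  data that machine inventories do not carry.
* **Risk-band boundaries.** The published risk banding overlaps at every
  breakpoint (66–71, 71–76, …); bands are resolved as left-closed,
  right-open, with ≥ 86 dBA as the top class, so classification is
  monotone and total.
* **Percentiles.** L10/L50/L90 use linear interpolation between order
  statistics (type-7 quantiles), stated here because exceedance indices
  are convention-sensitive.
* **Draw order** (one seeded stream per run): initial positions of moving
  machines, then workers; per step, duty states (stationary machines
  first), moving-machine steps, then worker steps after the field is
  computed, so workers read the current step's field. Sweeps derive the
  seed of each (setting, repeat) pair deterministically from the base
  seed, so a 32-bit base seed reproduces an entire campaign.

## The dose convention

The bundled dosimeter reference table records, for three worker groups,
measured 30-minute LAeq and dose pairs alongside simulation predictions.
The measured columns are mutually consistent under exactly one
convention — Q = 3 dB, CL = 90 dBA, 8-hour criterion — which is why that
is the default: a constant 85.9 dBA for 30 min gives
`r round(dose_percent(85.9, 30), 1)`% and 88.5 dBA gives
`r round(dose_percent(88.5, 30), 1)`%, matching the dosimeter readouts to
one decimal. The *predicted* dose column of that table is not exactly
reproducible from its own predicted LAeq column under any single (Q, CL)
pair; `noisewalk` computes doses from the simulated exposure series under
the explicit convention in `exposure_config()` and leaves the convention
user-switchable rather than guessing a mixture.

## What the synthetic generator emulates — and what it does not

`generate_synthetic_scenario()` draws sound power levels uniformly on
95–120 dBA (the span of the surveyed machinery), random duty
distributions, and random positions, subareas and barriers inside the
area. It emulates the *structure* of real scenarios — counts, geometry
containment, probability simplexes — so round-trip, validation and
field-oracle properties can be tested across many layouts. It does not
emulate spatial organisation of real sites (machines cluster along
process lines, barriers are walls of buildings, duty cycles correlate
across a process). Passing tests on synthetic scenarios therefore
demonstrate the simulator's internal correctness, not the fidelity of
any particular site model; fidelity to a real site rests on surveyed
emission levels and a measured layout.

The bundled case-study scenarios carry surveyed emission data but
approximate, synthetic coordinates (the survey publishes its layouts only
as drawings), so their maps illustrate the workflow; no quantitative
check in the package depends on those coordinates.

## Problem sizes used in the checks

The test suite exercises the full 144 × 87-node mill grid for the
convergence sweep (seven step settings from 100 to 1500, three repeats,
42 ringed receivers — 882 predictions), and smaller 30 × 20-node grids
for the brute-force field-oracle comparisons; walk-statistics checks use
3000–10000 replicate walks of 20–50 steps. These sizes give Monte-Carlo
standard errors comfortably inside the asserted tolerances while keeping
a full suite run around a minute.

## Known limitations

* Strictly 2-D: no barrier heights, diffraction path lengths, or terrain.
* Single-number A-weighted emission levels: no octave-band spectra, so
  frequency-dependent screening cannot be represented.
* No temporal correlation in duty cycles, and no worker schedules — a
  worker "stays" in the subarea for the whole assessment horizon, so
  predicted doses are for continuous occupancy of that area.
* Walkers ignore barriers; a walker may cross a building footprint.
* Background noise is spatially uniform and unscreened.
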