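---
title: "A multiscale model of Wnt/Hippo cross-talk in the intestinal crypt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiscale model of Wnt/Hippo cross-talk in the intestinal crypt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cryptdyn)
```

# The model

`cryptdyn` simulates a population of epithelial cells lining an intestinal
crypt. The crypt cylinder is unrolled to a planar band (default 16 cell
diameters of circumference, 20 of height), periodic in `x`. Each cell is an
agent carrying three coupled layers of state:

1. **Signalling** — a ten-species Wnt/β-catenin network extended with a
   Hippo-dependent sequestration of cytoplasmic β-catenin by phosphorylated
   YAP;
2. **Cell cycle** — a five-variable restriction-point module whose mitogenic
   input is the transcriptional β-catenin level, with G1 exit when E2F1
   exceeds 1 and fixed S/G2/M durations;
3. **Mechanics** — an overdamped cell-centre model: Delaunay neighbours
   connected by linear springs, Voronoi areas as cell "volumes".

The layers close a loop: crowding shrinks Voronoi volumes, sustained
compression activates Hippo, Hippo sequesters cytoplasmic β-catenin away
from the nucleus, transcriptional β-catenin falls, G1 slows or arrests.
Conversely Wnt destabilises the destruction complex, raising β-catenin and
shortening G1.

## Signalling network

Species (nM): free Axin `X`, active destruction complex `D`, free adhesive
molecules `A`, free transcription molecules `T`, and β-catenin pools —
junction-bound `CA`, cytoplasmic `CC`, transcriptional `CT`, degradation-
marked `CU`, YAP-P-sequestered `CH` — plus a Wnt target protein `Y`.
`T + CT` is conserved, so nine ODEs are integrated and `T` recovered
algebraically (the conservation is verified to 1e-9 nM in the tests).

Kinetics are mass-action except two saturable fluxes:

* destruction-complex marking, `pU·D·CC/(KC + CC)`, which routes cytoplasmic
  β-catenin to the degradation-marked pool;
* Hippo sequestration, `J_H = pH_hat·CC/(KH + CC)`, which moves cytoplasmic
  β-catenin into the YAP-P/β-catenin complex; the complex decays at first
  order (`dH·CH`). Only the binding term couples `CC` and `CH`, and it enters
  both equations with opposite sign (flux matching — a test asserts the
  identity exactly).

Three rates respond to Wnt — Axin turnover `dX`, destruction-complex
disassembly `dDX` and degradation `dD` — interpolated linearly between
Wnt-off and Wnt-on values by `wnt_modulated_rates()`. High Wnt removes the
destruction complex, β-catenin accumulates, `CT` rises.

**Units of the sequestration rate.** The field quotes the YAP-P/β-catenin
binding rate as `pH = 26,000 h⁻¹` with `KH = 20 nM`. A literal first-order
rate of 26,000 h⁻¹ on `CC` would deplete the cytoplasmic pool within a
fraction of a second and arrest every cell at any Wnt level. `cryptdyn`
therefore implements `pH` as the *maximal sequestration flux* in nM/h (the
YAP-P abundance is absorbed into the constant): `J_H ≤ pH`, with
half-saturation at `CC = KH`. With the default β-catenin turnover this
places the single-cell arrest boundary slightly above the working point
`(W = 1, pH_hat = 26,000)`, which is exactly the regime described for the
reference values: they "do not arrest the fully stimulated cell" while lower
Wnt levels do arrest under full Hippo activation.

**Calibration.** The full rate-constant tables of the kinetic models this
network descends from were not available, so the network was parameterised
from scratch against four anchors:

1. Wnt-on / Wnt-off contrast: steady-state `CT` ≈ 10.3 nM at `W = 1` versus
   0.77 nM at `W = 0` (active destruction complex 20-fold lower when Wnt is
   on);
2. a proliferation boundary near `W ≈ 0.22` with Hippo off (cycles lengthen
   from 19 h at `W = 1` through 31 h at `W = 0.3` and 58 h at `W = 0.25` to
   arrest at `W = 0.2`), anchoring the spatial extent of the proliferative
   niche;
3. the cell at `W = 1` under full Hippo activation (`pH_hat = 26,000`,
   `KH = 20 nM`) cycles, but about twice as slowly (40.2 h vs 19.2 h
   uninhibited), while `W <= 0.9` under full activation arrests — the
   reference constants are described as chosen not to arrest the fully
   stimulated cell;
4. wild-type cycle length ≈ 19 h at full Wnt (G1 ≈ 9 h plus fixed S = 5,
   G2 = 4, M = 1 h), giving whole-crypt renewal on the scale of one to two
   days.

All constants are documented in `signalling_params()`.

## Cell-cycle module

The G1/S switch is a bistable five-ODE restriction-point model (pRb, E2F1,
inactive/active cyclin D:cdk4/6, phosphorylated pRb). Its mitogenic input is
`mu_ct · CT`. Two constants are the package's own calibration: the gain
`mu_ct = 0.104` (placing the saddle-node of the switch at the `W ≈ 0.22`
steady state, anchor 2 above) and a time-scale factor `tau = 10` that
rescales the switch dynamics so that G1 lasts hours rather than days; `tau`
multiplies the whole right-hand side and does not move the bifurcation
structure. G1 exit requires E2F1 > 1 (strict); cells whose input stays below
the saddle never fire — that is the model's notion of arrest, declared after
`T_max = 100 h` in `cycle_duration()`.

The active cyclin D equation has an invariant manifold at zero, so the
post-mitotic reset (`cycle_initial_conditions()`) seeds it with a small
positive value; both daughters receive the same reset.

## Mechanics

Delaunay adjacency (periodic in `x` by ghost replication; mirror images
below the base plane and above the top of the band bound every Voronoi
polygon), linear springs on edges shorter than 1.5 diameters, overdamped
updates `dr = F/η · dt`. Voronoi polygons are clipped to `y ∈ [0, H + 0.5]`;
cells whose polygon touches the *base* plane are flagged and excluded from
contact inhibition, because an area truncated at the crypt wall is a
boundary artefact rather than a crowding signal (the top plane merely caps
the open orifice and leaves areas meaningful). The clipped areas partition
the band exactly (tested to 1e-9).

Two choices deserve comment:

* **Spring stiffness μ = 60** (η = 1, dt = 1/240 h at the stability bound
  η/(4μ)). In a streaming column the compression at the base scales like
  η·(cell flux)·(rows above)/μ. With the conventional μ = 15 the homeostatic
  base volume fell below 0.52·V_eq, i.e. below *both* standard CI
  thresholds (60% and 90% of V_eq), and the two settings became
  indistinguishable — contradicting the reported insensitivity of the 60%
  threshold (and of 30%, which the reference experiments found equivalent
  to 60%). μ = 60 puts the homeostatic base volume at ≈ 0.60–0.75·V_eq:
  above the 60% threshold, below the 90% one.
* **Filtered volume for contact inhibition** (`tau_V = 2 h`). At every
  division both daughters' instantaneous Voronoi areas collapse to half a
  cell for about an hour. Feeding the raw area into the Hippo switch made
  every newly born cell contact-inhibited at *any* threshold, again erasing
  the contrast between thresholds. The CI check therefore uses an
  exponential moving average of the volume (daughters inherit the mother's
  filtered value), which models mechanosensing of sustained compression on
  the time scale of YAP phosphorylation rather than of tessellation noise.

`V_eq = √3/2` is the area per cell of hexagonal packing at the one-diameter
rest length.

## Wnt models

* `ME1` (static imposed gradient): `W = W_max·max(0, 1 − h/θ_W)` read once
  at the cell's birth position (each division re-reads it for both
  daughters).
* `ME2` (dynamic): the same gradient re-evaluated continuously.
* `MI` (internal, division-based): Wnt is cellular cargo. Cells in the basal
  reservoir (bottom fraction ρ of the crypt) are refreshed to `W_max` once
  per step, after the mechanics update; outside it, a division hands
  fraction `f = 0.5 + ξ` to one daughter and `1 − f` to the other, with
  `ξ ~ N(0, σ²)` *resampled* until `f ∈ [0, 1]` (rejection preserves the
  zero mean; at σ ≤ 0.2 truncation is negligible, verified by Monte Carlo).
  The split conserves Wnt exactly, so with σ = 0 every cell's level is
  `W_max·2⁻ᵏ` with `k` its division depth since leaving the reservoir — a
  property the tests check on lineage records.

## Engine loop and numerics

Per time step (dt = 1/180 h): spring forces and overdamped motion (x
wrapped, y clamped at the base) → tessellation volumes → reservoir refresh
(`MI`) → per-cell Hippo rate from the filtered volume (step activation:
`pH` below `θ_CI·V_eq`, 0 above; mutants and boundary-flagged cells exempt)
→ ODE advance → phase transitions → divisions (daughter at 0.1 diameters in
a uniform random direction; sister spring rest length ramps 0.1 → 1 over
1 h) → sloughing of cells above `y = H`. Runs are bit-reproducible given the
seed; ensembles derive one seed per run from the base seed.

The per-cell ODEs are advanced with fixed-step RK4: the stiff signalling
block at 8 substeps per mechanics step (the destruction-complex flux has a
local Lipschitz constant ≈ 2.5·10³ h⁻¹; 8 substeps keep λ·h ≈ 1.3, inside
the RK4 stability region), and the non-stiff cycle block at 2 substeps with
`CT` interpolated across the step (the coupling is one-way). The batched
integrator is cross-checked in the tests against `deSolve` (adaptive RK45,
rtol 1e-6/atol 1e-9 — the single-cell API) and against an independent
fixed-step RK4 oracle to 1e-5 nM over 10 h. The tessellation is rebuilt
every 5 steps (1/48 h; cells move ≲ 0.01 diameters between rebuilds) and
immediately re-used after removals via index remapping.

Single-cell operations (`cycle_duration()`, `steady_state_signalling()`,
`sensitivity_scan()`) use `deSolve` (`lsodar` root-finding for the E2F1
crossing; steady states accepted when the RHS max-norm falls below 1e-8
nM/h).

## Initial condition and burn-in

Cells start on a jittered hexagonal lattice filling the domain, signalling
at the per-cell Wnt steady state (Hippo off), cycle phases drawn at random
with duration-weighted probabilities so the population is desynchronised.
The population overshoots during the first ~30 h while the division/slough
balance establishes; all reported statistics exclude a 30 h burn-in (the
observable functions default to 10 h, which is appropriate for runs
continued from an already relaxed state).

## Mutants and washout

An APC double mutant has its destruction-complex marking flux set to zero at
any Wnt level, is never contact-inhibited, and progresses through the cycle
at the maximal-proliferation setting (G1 fixed at the wild-type `W = 1`,
Hippo-off value of about 9 h — the mutation specifies independence from
Wnt and volume, not a new rate). A washout experiment relaxes a wild-type crypt, mutates one
cell in the bottom 5%, and classifies each run as `WASHOUT` (mutant lineage
eliminated), `TAKEOVER` (monoclonal conversion) or `TIMEOUT`; timeouts are
excluded from the washout-probability denominator and reported separately.
The 95% interval uses the normal approximation
`p ± 1.959964·√(p(1−p)/n)`, clipped to `[0, 1]` (the tests compare it
against the exact binomial interval).

# What the simulations do and do not capture

The synthetic crypt reproduces: homeostatic turnover by division and
sloughing; a proliferative niche set by Wnt with contact inhibition
modulating it; emergent Wnt gradients by division-based dilution from a
basal reservoir; and clonal competition after a mutation. It does not
model: explicit Paneth cells or telocytes (the reservoir is a region, not a
cell type), Wnt secretion/diffusion, the Hippo kinase cascade (MST/LATS),
Notch-mediated fate decisions, altered adhesion of mutant cells, live-cell
extrusion near the orifice, or 3-D tubular geometry. Passing tests therefore
validate the model's internal logic and its qualitative agreement with the
reference in-silico experiments — not quantitative agreement with tissue
data.

# Problem sizes used by the tests and the acceptance script

The reference crypt is 16×20 cell diameters (~440 cells at homeostasis).
The acceptance script runs it for 110 h per condition (30 h burn-in, two
matched seeds per condition; 160 h for the internal-Wnt gradient run). The
test-suite crypts are a reduced 12×16 (~330 cells, 100 h), and the washout
mini-ensembles use a 6×8 crypt with five runs per condition and a 300 h
timeout. These sizes were chosen as the smallest at which the homeostatic
volume regime and the height-resolved profiles are stable; relative effects
between matched conditions are robust to them, while small-ensemble washout
statistics carry the wide binomial uncertainty stated with them. Clonal
competition resolves slowly (a monoclonal takeover needs six or more cell
doublings), so reduced-scale washout ensembles leave many runs unresolved;
the tests therefore use finite-horizon washout fractions for ordering
checks.

# Known limitations

* The Hippo activation is a step in the (filtered) volume — the simplest
  form consistent with a threshold description of contact inhibition.
  `effective_hippo_rate()` isolates it, so smooth alternatives are one-line
  swaps.
* With static birth-Wnt (`ME1`) and fast streaming, mitoses smear above the
  imposed Wnt extent by roughly one cycle's transit distance; the drop-off
  location is robust but its sharpness depends on the crypt's turnover
  rate.
* The binomial intervals of small washout ensembles are wide; the reduced
  test ensembles check ordering trends and bracket the reference
  probabilities only within those wide intervals.
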