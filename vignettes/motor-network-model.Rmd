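---
title: "An agent-based model of microtubule networks organized by motile cross-linkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of microtubule networks organized by motile cross-linkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtnetsim)
```

## The model

`mtnetsim` simulates the self-organization of stabilized microtubules by two
archetypes of motile cross-linker in a thin, quasi-two-dimensional volume:

* a **symmetric, plus-end-directed cross-linker** (kinesin-5/KIF11-like): two
  identical processive motor units joined by a Hookean spring. It slides
  antiparallel microtubules apart and organizes dense systems into extensile
  nematic bundles.
* an **asymmetric, minus-end-directed cross-linker** (kinesin-14/HSET-like):
  one nonprocessive minus-directed motor unit and one diffusive
  (lattice-hopping) tail unit. It focuses microtubule minus ends into asters.

The simulation volume is a thin box (default thickness 0.2 µm), periodic in X
and Y and reflective in Z. Coordinates are continuous and never wrapped:
all pairwise interactions use the minimum-image displacement, which leaves
trajectories naturally unwrapped for displacement analysis.

### Microtubules

Microtubules are polar, inextensible, bendable lines discretized as vertex
chains (segment length 0.5 µm by default), with vertex 1 the minus end.
They nucleate from a fixed set of randomly placed seeds at a rate chosen so
that most filaments appear in the first tens of seconds, and their plus ends
then elongate at

\[ v_g(t) = \alpha \left( 1 - \frac{\sum_i L_i(t)}{\Omega} \right), \]

where \(\Omega\) is a finite tubulin pool (µm of polymer) shared by all
filaments. Each filament draws its own maximum speed
\(\alpha = \alpha_0 \lvert 1 + 0.25\,\mathcal{N}(0,1) \rvert\), hard-clipped
to [0, 2] µm/s, which broadens the length distribution. There is no
catastrophe: lengths are non-decreasing, and the population converges to
mean length \(\Omega / n\) (2.5 µm in the network scenarios) regardless of
the speed heterogeneity. Growth stops globally at a configurable time
(default 600 s), after which lengths are fixed — the growth phase is a
kinetic property of the preparation and is deliberately *not* scaled with
box size.

Bending follows the linearized worm-like-chain energy
\(E = \kappa/(2 l^3) \sum_i \lvert r_{i-1} - 2 r_i + r_{i+1} \rvert^2\)
with rigidity \(\kappa = 20\) pN µm² (a standard microtubule value).
Inextensibility is enforced after every step by a Newton iteration on the
bond-length constraints (tridiagonal Lagrange-multiplier system, relative
tolerance \(10^{-6}\)), with a Gauss–Seidel fallback for degenerate
geometries.

### Cross-linkers

A cross-linker complex is two microtubule-binding units joined by a Hookean
spring with non-zero rest length,
\(\vec f = k (1 - e/\lvert \vec u \rvert)\, \vec u\); the joint rotates
freely. Units bind 8-nm lattice sites within a capture radius at a constant
rate, never with both units on the same filament, and unbind at the Bell
rate \(k_\mathrm{off} = k_\mathrm{off}^0 e^{f/f_\mathrm{unb}}\).

Motor units step stochastically by 8 nm toward their directional end with a
linear force–velocity law \(v = v_m (1 + f_\parallel / f_s)\), clipped to
\([0, 2 v_m]\): antagonistic load stalls the motor at \(-f_s\); assisting
load can at most double the speed; super-stall load gives zero rather than
backward stepping. Diffusive units hop to neighboring sites at the
detailed-balance-consistent rates
\(r_\pm = (D/a^2)\, e^{\pm f_\parallel a / 2 k_B T}\), so a loaded tail
drifts at the Einstein velocity \(D f_\parallel / k_B T\) for small forces
and relaxes to the Boltzmann distribution in a static potential.

At a filament end a unit either **releases** instantly or **holds** (motor
stepping past the end is suppressed; hops off the end are rejected). End
policies are central to the phenomenology: the symmetric plus-directed
complex releases at plus ends, which keeps its steady-state profile along
the filament uniform and permits nematic organization with short filaments;
both units of the asymmetric complex hold at ends, which lets it cluster
minus ends into asters.

The catalog (`linker_catalog()`) also provides the hypothetical variants
used in the mixed-motor experiments: a plus-end-directed version of the
asymmetric complex, a version with a non-hopping tail of matched dwell,
symmetric double-motor and double-tail constructs (the latter with either
end-holding or end-releasing tails), and a symmetric, mildly processive
minus-end-directed motor.

### Dynamics and integration

Vertices obey first-order (overdamped) Langevin dynamics with isotropic
slender-body drag \(\gamma = 3 \pi \eta l / \ln(l / 2 r_\mathrm{mt})\) per
vertex. One step of duration `dt` (default 0.005 s) proceeds in a fixed
order — nucleation/growth, force assembly (cross-link springs, then steric),
vertex update, constraint projection, Z reflection, linker kinetics
(unbind, move, bind; rates evaluated on pre-update loads), free-linker
diffusion — which guarantees bitwise reproducibility for a fixed seed.

Three numerical choices deserve explanation:

* **Exact Ornstein–Uhlenbeck treatment of bending.** At
  \(\kappa = 20\) pN µm², \(l = 0.5\) µm and slender-body drag, the
  stiffest bending mode relaxes in \(\sim 10^{-4}\) s, far below the 0.005-s
  step: any explicit update is unstable, and a backward-Euler update would
  distort thermal bending amplitudes by large factors. Because the
  discretized bending energy is an exact quadratic form, the bending term
  plus thermal noise is instead integrated *exactly* as an
  Ornstein–Uhlenbeck process in per-filament bending-mode space
  (eigendecomposition cached per vertex count). Free filaments therefore
  sample exact equilibrium statistics at any `dt`; the suite verifies
  equipartition of the transverse bending modes to within 10%.
* **Diagonally implicit soft forces.** Cross-link springs and steric
  contacts are explicit, but a vertex carrying total attached stiffness
  \(K\) (sum of spring constants of its anchors and contacts) uses the
  mobility \(dt / (\gamma + K\,dt)\). This is consistent as
  \(dt \to 0\) and unconditionally stable no matter how many cross-linkers
  load one vertex — the situation in aster cores, where dozens of anchors
  would otherwise make an explicit update explode. A per-vertex drift cap
  of a quarter segment length per step guards against rare force spikes;
  it does not engage in normal operation.
* **Exact event-count sampling.** Binding and unbinding fire with
  probability \(1 - e^{-r\,dt}\); motor steps are Poisson; diffusive hops
  use the exact net-hop (Skellam) distribution over the step, with a
  Gaussian limit at very high bias, so strongly loaded tails remain correct
  and cheap.

Steric repulsion is a soft core: segment pairs of distinct filaments closer
than \(d = 0.05\) µm feel \(k_s (d - r)\) along the closest-approach
direction with the components parallel to both filament axes projected out,
so contact does not resist sliding. The projected force is deliberately
non-conservative; the force–energy consistency test therefore covers the
bending and spring terms (exact gradients), and the steric term is checked
by its own invariants (perpendicularity, action–reaction, range).

### Quantification

Two readouts mirror the reference experiments:

* **Signed sliding speed** (`signed_mt_speed()`): per filament and disjoint
  window \(\Delta t\), the unwrapped minus-end displacement is projected on
  the filament axis at the window start, oriented plus→minus; positive =
  minus-end-leading. For unlinked, freely rotating filaments the estimator
  has a small *negative* bias of order \(-(L/2)(1 - e^{-D_r \Delta t})/\Delta t\)
  (the projection of a rotating end shrinks), which is why a large
  \(\Delta t\) is used and why the network speed approaches the motor speed
  only once most filaments are cross-linked.
* **Bundle/aster size** (`crosslink_clusters()`): connected components of
  the graph whose edges are doubly bound cross-linkers of one type; the
  largest component size normalized by the filament count is reported as
  bundle size (symmetric linker) or aster size (asymmetric linker).

## Parameters

Printed, non-negotiable constraints: time step 0.005 s; 8-nm lattice;
growth law and speed rule with the 0.25 spread factor and [0, 2] µm/s clip;
steady-state mean length 2.5 µm; microtubule density 0.8/µm²; unloaded
speeds 0.03 µm/s (symmetric complex) and 0.08 µm/s (asymmetric motor unit);
the asymmetric motor takes on average two steps per engagement
(\(k_\mathrm{off}^0 = 5\)/s); its tail dwells 500× longer
(\(k_\mathrm{off}^0 = 0.01\)/s); thin-box geometry with the figure-caption
box sizes.

Everything else is a reconstruction, chosen once, exposed in the scenario
config, and calibrated — the standard practice for such models — so that the
*network-level* behavior matches the described regimes (asters from the
asymmetric linker, extensile activity from the symmetric one):

| parameter | default | rationale |
|---|---|---|
| `kBT` | 4.23e-3 pN µm | 306 K (experiments at 33 °C) |
| `eta` | 0.1 pN s/µm² | crowded buffer, ~100× water |
| `kappa` | 20 pN µm² | literature microtubule rigidity |
| `k_spring` | 10 pN/µm | force transmission at sub-100-nm extensions under pN loads |
| `rest_length` | 0.05 µm | complex dimension |
| `binding_range` | 0.1 µm | reach of the extended complex; exceeds the steric gap so cross-linking across touching filaments stays possible |
| `k_on` | 2.5 /s | calibrated at network level: at 10 /s nearly every motor is doubly bound within ~100 s and crossing filaments are welded into static clusters before any remodeling can occur; at 2.5 /s cross-links keep turning over and the network stays motile |
| `f_unb` | 6 pN (motors), 1000 pN (tail) | Bell sensitivity of motor domains; tail unbinding treated as force-insensitive |
| `fs` | 5 pN | kinesin-scale stall force |
| `D` (tail) | 2e-4 µm²/s | set by the network-level force balance the mixed-motor regimes require: a few tails per filament must only mildly resist sliding driven by the plus-directed linker, while tens of tails per filament must collectively stall it; protein friction per tail is `kBT/D` ≈ 21 pN s/µm |
| `k_steric`, `d_steric` | 20 pN/µm, 0.05 µm | soft core preventing overlap in the 0.2-µm slab |
| `k_off0` (symmetric unit) | 0.1 /s | processive, ~10 s engagements |

## Scenario presets and scaling

`build_scenario()` reproduces the reference configurations: a
60 × 60 × 0.2 µm box with 2,880 filaments and 46,080 symmetric linkers
(16 per filament); a 40 × 40 × 0.2 µm box with 1,280 filaments and 40,960
asymmetric linkers (32 per filament); mixed-motor boxes with 2 symmetric
linkers per filament plus 2:1 or 16:1 asymmetric:symmetric mixtures; the
variant catalog in 20 × 20 µm boxes; and a motor-free control. The `scale`
argument multiplies the lateral box dimensions (thickness fixed), the
duration and the default analysis window, while preserving all intensive
quantities (density, linkers per filament, pool per filament).

The full-scale scenarios (thousands of filaments, 8,000 s) are
cluster-scale computations. The package's tests exercise the emergent
regimes at scale 0.25 with run lengths of 280-520 s — long enough for the
pool to empty (by ~250 s), for cross-linking to reach steady turnover and
for one or two speed-analysis windows of 240 s. The window is deliberately
*not* scaled down with the box: the rotational-diffusion bias of the speed
estimator depends on filament length and rotational diffusivity, which are
scale-independent, so a linearly scaled window would drown the sliding
signal in bias.

What those scaled-down checks do show: aster-like clustering with
immobilized filaments under the asymmetric linker (against the motor-free
control's 1/N baseline); positive (minus-end-leading) population sliding
under the dense symmetric linker; enhanced bundling with positive sliding
when the asymmetric linker is added 2:1 to sparse symmetric linker; and
cluster dominance of the asymmetric linker at 16:1. What they cannot show:
the slow coarsening, system-spanning network formation and sustained
extensile steady state of the full-scale runs, which develop over
thousands of seconds in boxes many filament lengths wide. Two specific
finite-size effects matter. First, small boxes polarity-sort and fragment
within a few hundred seconds, so the population speed peaks during
assembly and then decays instead of rising monotonically; the positive
association between bundling and speed survives in most but not all seeds.
Second, contraction of minus-end clusters itself registers as
minus-end-leading (positive) displacement, and a heavily cross-linked
population carries less of the estimator's negative rotational bias than a
sparsely linked one, so speed *comparisons between conditions of very
different connectivity* (e.g., the 16:1 versus 2:1 mixtures) are
systematically confounded at this scale even when each condition's own
phenotype is clear.

## Limitations

* No hydrodynamic coupling between filaments; isotropic vertex drag.
* No dynamic instability, severing or minus-end growth.
* Lattice sites have no exclusion: multiple units may occupy one site.
* The diagonally implicit treatment of soft forces slightly underdamps
  thermal fluctuations of heavily cross-linked vertices (free filaments are
  exact); this is a stabilization, not a statement about protein friction.
* The Z confinement applies mirror reflection to all mobile positions.

## Reproducing the numbers

`scripts/acceptance.R` recomputes, from a fresh seed: the steady-state mean
filament length of a growth-only population at one tenth of the large
scenario's filament count; the configuration arithmetic of the scenario
builders; and the kinetic Monte Carlo recoveries (dwell-time ratio,
steps per engagement). The `analysis/` scripts run the same computations as
narrative drivers and write their tables under `results/`.
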