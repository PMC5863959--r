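---
title: "An agent-based mechanical model of cell-death-triggered biofilm wrinkling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based mechanical model of cell-death-triggered biofilm wrinkling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrinklesim)
```

## The model

`wrinklesim` simulates a bacterial colony as a collection of spherical
agents. One agent is one cell of radius $R_i$ together with the shell of
extracellular polymeric substance (EPS) glued to its wall; the EPS scaling
factor $\alpha > 1$ makes the mechanically active radius $\alpha R_i$.
Agents interact only through an elastic bond network. A bond between agents
$i$ and $j$ forms when their center distance $d$ drops below a creation
threshold $\delta_c$ and breaks only when $d$ exceeds $\delta_d \ge
\delta_c$, so contact history matters (hysteresis). A bonded pair exerts a
central force of magnitude

$$|f^b_{ij}| = K\, x_{ij} \tanh(s_b |x_{ij}|), \qquad
  x_{ij} = \alpha R_i + \alpha R_j - d,$$

repulsive when the EPS shells overlap ($x_{ij} > 0$) and adhesive when the
bond is stretched ($x_{ij} < 0$). Nonbonded pairs exert no force at any
distance. The agar substratum at the plane $x = 0$ acts on each agent
through the analogous vertical force with $x_{ii} = \alpha R_i - d$, where
$d$ is the height of the agent center, bonded below the single threshold
$\delta_{ca}$. Two switches implement adhesion knock-outs: they zero the
adhesive branch (the negative-$x$ part) of the pair or agar force while
leaving repulsion and the bond bookkeeping untouched.

Agents move in an overdamped environment. Positions follow the
Euler-Maruyama discretization of Brownian dynamics,

$$\mathbf{x}_i(t + \Delta t) = \mathbf{x}_i(t)
  + \frac{\Delta t}{\zeta} \mathbf{f}^a_i(\mathbf{x})
  + \sqrt{2 D_c \Delta t}\, \boldsymbol{\xi}(t),$$

with friction $\zeta$, diffusion coefficient $D_c$ (zero by default: no
active motility) and $\boldsymbol{\xi}$ a vector of independent standard
normal draws from R's seeded RNG stream. Each step updates the bond
network, evaluates forces, moves the agents and applies the boundary
conditions, in that order, so forces are always consistent with the bond
network of the same configuration.

Cell death is purely subtractive: every agent whose center lies inside the
cell-death pattern (CDP) — a rectangular box at the colony-substratum
interface, or an image raster mapped onto the horizontal plane — is removed
together with all its bonds, either all at once or in random batches with
short relaxations in between.

## Parameters, units and defaults

All lengths are micrometers, time is seconds, forces are in reduced units
of $K \cdot \mu m$. Defaults, all overridable through `model_params()`:

| parameter | default | meaning |
|---|---|---|
| $R_i$ | 2 | cell radius |
| $\alpha$ | 2 | EPS scaling; agent radius $\alpha R_i = 4$ |
| $K$ | 2 | bond spring constant |
| $s_b$, $s_{ba}$ | 0.08 | bond / agar-bond stiffness (1/um) |
| $\delta_c$ | $2\alpha R = 8$ | bond creation at the rest length |
| $\delta_d$ | $1.5\,\delta_c = 12$ | bond breakage |
| $\delta_{ca}$ | $1.1\,\alpha R = 4.4$ | agar bond threshold |
| $\zeta$ | 1 | viscous friction |
| $D_c$ | 0 | agent diffusion |
| $\Delta t$ | 0.025 | time step, chosen so $\Delta t\, K/\zeta \le 0.05$ |

Three of these deserve their rationale spelled out, because they are
genuinely open modelling choices and they decide whether the colony
behaves as a connected elastic body at all.

**The packing density counts cell volume, not EPS-shell volume.** The
initial colony is a uniform random packing at volumetric density $\Phi$.
If $\Phi$ were the volume fraction of the *EPS-scaled* spheres, the mean
number of contacts per agent at the rest length would be $8\Phi$
independently of every radius and scale choice — about 1.3 at the
wrinkle-formation densities $\Phi = 0.12\ldots0.18$, far below the
continuum-percolation threshold of roughly 2.7 contacts. Such a packing is
mechanical dust: it carries no stress, a compressed state cannot exist,
and ablation does nothing (we verified all three numerically). Reading
$\Phi$ as the volume fraction of the *cells* (radius $R_i$), the EPS
shells occupy $\alpha^3 \Phi \approx 1.0{-}1.4$ of space at the same
nominal densities, overlap heavily, and give mean coordination around
$8\alpha^3\Phi \approx 10$. That overlap *is* the stored compression of
the stiff colony, and it is the only reading under which the stated
densities are simultaneously "compressed" and mechanically connected.
`packing_spec()` therefore books density against the cell radius by
default (`packing_radius` exposes the choice).

**Bond breakage at $1.5\,\delta_c$.** With a narrow hysteresis band (10%),
bonds break under modest shear and the colony behaves like a dense liquid:
any surface structure levels out. The EPS tether that cements neighboring
cells should survive moderate stretch, so the default lets bonds persist
to 1.5 times the creation distance. This also keeps the quasi-stable
colony cohesive during relaxation instead of evaporating at its free
surface.

**One-sided walls.** A `wall` axis clamps agent centers at the 0-plane
only and is open on the far side. The wrinkle domain uses a wall in $x$
(the agar surface) with periodic horizontal axes; wrinkles must be free to
rise above the initial block top, so a second lid would suppress the
phenomenon being studied. The compression domain likewise has its single
impenetrable wall at $y = 0$, the opposite side being controlled by the
frozen border cells. Because overdamped agents carry no momentum, the wall
projects rather than reflects.

## The experiment protocols

**Initial colony.** `build_initial_colony()` places the agents uniformly
at random (overlaps permitted; a rejection option caps them), then runs
2000 noise-free steps with all forces scaled by 0.1. This weak-force
homogenization equilibrates the worst local crowding without unfolding the
global compressed state.

**Quasi-stable state.** `wrinkle_experiment()` then relaxes the colony
(noise off, capped step budget) before touching it. During this
pre-relaxation the open top lets vertical stress drain while the periodic
horizontal axes cannot relax — the lateral compression stays locked in the
bond network. The result is the quasi-stable colony the perturbation
starts from: flat, vertically settled, laterally pre-stressed. Ablation
then removes the CDP agents and the system relaxes toward quiescence,
defined as the maximum deterministic agent speed $\max_i |f_i|/\zeta$
falling below 0.01 um/s. Step budgets cap both relaxations; hitting a cap
is reported (`converged`, `steps`, `v_max`) and warned about, never
silent.

**Morphometrics.** The domain is divided into cubic voxels (20 um
default). Per voxel, the mean center height is recorded; empty voxels are
NA and excluded from all maxima. Colony height $H$ is the global maximum
of voxel means; the border height is the maximum in the first $y$ row, the
center height the maximum in the row containing $y = L_y/2$, and $r_h$
their ratio — 1 for a flat colony, about 2 when a central wrinkle doubles
the local height. The wrinkle area thresholds the per-column surface at
1.3 times the border height and takes the largest 8-connected component of
the binary image (4-connectivity is an option). Displacement fields
aggregate the horizontal displacement vectors of agents by their initial
mesh cell (sums stored, means derived); the convergence field counts, per
mesh cell, agents entering minus agents leaving between two snapshots, so
it sums to zero when nothing was removed and to minus the removed count
after ablation. Per-agent stress is the pairwise virial
$\sigma_i = -\tfrac{1}{2V_i}\sum_j f^{ij} \otimes r^{ij}$ over bonded
neighbors with $V_i = \tfrac43\pi(\alpha R_i)^3$, sign-flipped so
compression is positive; the hydrostatic stress is the mean of its
diagonal.

**Rheometry.** `uniaxial_compression()` displaces the border cells (those
overlapping the plane $y = L_y$) by $\Delta L$ in $-y$, freezes their $y$
coordinates, relaxes to quiescence, and records the summed $y$ force on
the border cells over their number. Stiffness is the least-squares slope
of the initial linear part of the stress-strain curve.

## What the generator emulates, and what it does not

The random packing plus homogenization stands in for the growth history of
a real colony: it reproduces a laterally compressed, disordered, cohesive
cell block, which is all the perturbation experiment needs as an initial
condition. It does not reproduce growth-generated anisotropy, the layered
architecture of real biofilms, EPS heterogeneity, or any biochemistry:
cell death is imposed as a region, not produced by nutrient depletion.
Passing tests therefore demonstrate the mechanical pathway from localized
death to surface deformation under these idealized initial conditions —
they do not validate the model against measured biofilm rheology.

Scale matters too. The default study domains here are a few thousand to
fifteen thousand agents (boxes of 45 x 360 x 45 up to 45 x 720 x 90 um),
two orders of magnitude below full-scale colony blocks (hundreds of
thousands of agents). In this
regime we observe the qualitative phenomenology — convergent motion into
the ablated region, localized ridges forming above wide cell-death
regions, stiffness ordering with $s_b$, loss of coherent structure without
cell-cell adhesion — but the ridges are modest (surface elevations of
10-25% over the border in our runs) and appear at seed-dependent positions
within the cell-death footprint rather than as one tall central fold, so
center-row height ratios near 2 are not reached at this scale. The
acceptance script reports what the scaled-down domains actually produce.

## Numerical choices

- **Time step**: $\Delta t = \min(0.025, 0.05\,\zeta/K)$; the explicit
  integrator is stable well beyond this (per-agent stiffness stays below
  $\sim 10 K s_b$), the margin covers deep-overlap packings.
- **Neighbor search**: cell lists feed a Verlet pair list with a skin of
  $0.3\,\delta_d$, rebuilt when any agent has moved half a skin; bond
  state is a compact adjacency rebuilt every step. A brute-force $O(N^2)$
  reference implementation in the test suite must agree to $10^{-12}$
  relative over 100 steps.
- **Quiescence**: $v_{max} < 0.01$ um/s with the noise term disabled;
  velocity is force over friction, the only meaningful velocity in a
  position-only scheme.
- **Degenerate pairs**: coincident centers have no force direction and
  raise an error rather than picking one arbitrarily.
- **Ties and edges**: bond creation uses strict $d < \delta_c$, breakage
  strict $d > \delta_d$; voxel and mesh indices clamp boundary points into
  the grid; the center row is the voxel row containing $y = L_y/2$.
- **Convergence sign**: entered minus left, so positive values mark
  accumulation (convergence as negative divergence).
- **Agar bond**: the single threshold $\delta_{ca}$ creates and breaks the
  bond, as specified — which makes the agar bond memoryless, so it is
  derived from the configuration rather than stored. Note that
  $\delta_{ca}$ must exceed $\alpha R_i$ for the adhesive branch to exist
  at all; the default is $1.1\,\alpha R_i$.

## A small worked example

A scaled-down wrinkle experiment (a minute or two on one CPU):

```{r example, eval = FALSE}
box <- sim_box(45, 360, 45)                     # agar wall in x, periodic y, z
cdp <- rect_cdp(W_D = 216, H_D = 27, box = box) # wide centered death region
res <- wrinkle_experiment(box, phi = 0.18, params = model_params(),
                          cdp = cdp, seed = 11)
res$metrics
image(res$convergence)      # where biomass accumulated
image(res$height_map$h_x)   # the final surface
```

## Known limitations

- No cell growth, division, or motility beyond the optional $D_c$ noise
  term; no nutrient or waste fields; cell-death patterns are inputs, not
  emergent.
- Monodisperse spheres by default (per-agent radii are supported, rod
  shapes are not), no tangential or frictional forces, EPS is not
  resolved as separate agents.
- The center-row height ratio is blind to ridges that form off-center;
  inspect the full surface (`height_map()$h_x`) when interpreting it.
- Scaled-down domains underestimate wrinkle amplitude (see above); full-scale
  domains are configurable but need hours, not minutes.
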