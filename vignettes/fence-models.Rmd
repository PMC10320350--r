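---
title: "Modelling membrane-skeleton fences in particle-based simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling membrane-skeleton fences in particle-based simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memfence)
```

## The model

The lateral mobility of lipids and proteins in the plasma membrane is not
free: the actin-based membrane skeleton partitions the membrane into
compartments of tens to hundreds of nanometres, and transmembrane proteins
anchored to that skeleton ("pickets") line the compartment boundaries.
A molecule diffuses quickly inside a compartment and only occasionally
"hops" across a fence — the picket-fence picture of hop diffusion.

`memfence` simulates this with two-dimensional Brownian dynamics. Particle
positions evolve by the overdamped Langevin propagator

$$
\Delta x_i \;=\; \delta_{\mathrm{crossing}}
\left( \sqrt{2 D_0\, \mathrm{d}t}\; \xi
\;+\; \frac{\mathrm{d}t}{\gamma}\Big(
\sum_{j \ne i} F_{ij}\,\hat r_{ij}
\;+\; \sum_k F^{\mathrm{fence}}_{ik}
\;+\; \gamma\, v_{\mathrm{drift}} \Big)\right),
$$

with $\xi$ a pair of standard normal draws, $\gamma = k_B T / D_0$ the drag,
$F_{ij} = k_{\mathrm{pair}}\,(r_i + r_j - |\Delta x_{ij}|)$ a linear
repulsion acting only while discs overlap, and
$\delta_{\mathrm{crossing}} \in \{0, 1\}$ the outcome of the probabilistic
crossing test (below). Momentum is assumed to relax within one timestep, so
there is no velocity state. Forces are evaluated from the configuration at
the start of the step (explicit Euler–Maruyama), and $\delta$ applies to the
*entire* proposed displacement, drift and forces included.

Internally everything is expressed in nanometres, nanoseconds, attojoules
and kelvin. In these units the default membrane diffusion coefficient
$D_0 = 0.8\,\mu\mathrm{m}^2/\mathrm{s}$ is $8\times10^{-4}$ nm²/ns, a drift
of $1\,\mu\mathrm{m}/\mathrm{s}$ is $10^{-6}$ nm/ns, and
$\gamma \approx 5.177$ aJ·ns/nm² at 300 K. One coherent unit system avoids
silent factor-of-$10^n$ errors; the YAML configuration layer accepts
unit-suffixed strings (`"0.8 um^2/s"`, `"20 us"`) and converts.

## The fence mesh

The skeleton is a periodic Voronoi tessellation. `generate_periodic_voronoi()`
places $w\,h/L^2$ uniform seeds in the box, copies them into the eight
surrounding images (Moore neighbourhood) so the diagram is periodic, and
computes each central seed's cell by half-plane clipping against the
perpendicular bisectors of its neighbours, nearest first, with an early exit
once no remaining seed can cut the cell. The characteristic length is the
mean of $\sqrt{A_c}$ over compartments. If it misses the requested $L$ by
more than 2%, seeds are redrawn with one point more or one point less —
in the direction that corrects the error, so the count oscillates around the
analytic value $w\,h/L^2$ (a schedule that only walks away from that count
cannot converge, because counts far from it can never satisfy the 2% band).
The retry cap is 500; in practice a handful of attempts suffice.

Because the mean of square roots is at most the square root of the mean,
$L_{\mathrm{mesh}} \le \sqrt{wh/n}$ with equality only for equal-area cells:
random meshes sit a few percent *below* the naive estimate, which is exactly
why the retry rule exists. The 2% check uses the compartments of the central
box copy.

## The three fence models

* **Probabilistic fences** are infinitely thin barriers on the Voronoi
  edges. When a proposed displacement crosses fences, one uniform draw is
  made per crossed fence (in path order) and the step is accepted only if
  every draw falls below $P_{\mathrm{hop}}$; otherwise the particle stays
  exactly where it was. The per-step probability depends on the timestep:
  halving $\mathrm{d}t$ doubles the crossing attempts but shrinks the
  displacement by $\sqrt 2$, and the net effect is square-root scaling. The
  scaled parameterization $\tilde P_{\mathrm{hop}}$ (fraction per
  $\sqrt{\mathrm{ns}}$) makes results timestep independent:
  `scale_hop_probability(0.001677, 2000)` = 0.075. Above
  $\mathrm{d}t \approx 2000$ ns a step can cross more than one fence; the
  simulator tests each crossed fence independently and counts such steps in
  a warning counter so that regime is visible.
* **Potential fences** surround each edge with a triangular potential of
  width $x_0$ and height $k_{\mathrm{fence}}$, i.e. a constant repulsive
  force $k_{\mathrm{fence}}/x_0$ within $x_0$ of the line, symmetric on both
  sides. Where several fences are in range (corners), the force direction is
  the vector sum of the per-fence candidates but the magnitude is capped at
  the strongest single candidate, so corners never produce forces beyond
  $k_{\mathrm{fence}}/x_0$. A particle exactly on a fence line contributes
  no force for that fence (a measure-zero tie, resolved deterministically).
  Crossing the full half-width costs exactly $k_{\mathrm{fence}}$ of work
  per side.
* **Picket fences** place immobile discs of radius $R$ on the fence lines,
  spaced as close as possible to $2R + l_{\mathrm{free}}$ centre-to-centre
  by deterministic equal subdivision of each segment, with pickets at both
  endpoints and duplicates at shared vertices merged (tolerance
  $10^{-9}$ nm). Pickets repel mobile particles through the same linear
  pair force. Random Voronoi meshes always contain a few edges shorter than
  a picket diameter; by the strict contract that is a configuration error,
  and `short_segments = "endpoints"` opts into placing only the endpoint
  pickets there, which the drift scenario uses.

## Numerical choices

* **Randomness.** All draws come from R's RNG (also inside the compiled
  kernel), so `set.seed()` governs everything. The draw order per step is
  fixed — all $\xi$ pairs in particle order, then crossing draws in particle
  order — which makes the brute-force and voxel-indexed neighbour paths
  consume the stream identically; the two paths are bitwise equivalent and
  tested as such. Each replication derives a child seed from the master
  seed, so replications are independent and a run is reproducible from its
  manifest.
* **Neighbour search.** Below 16 particles an all-pairs scan is fastest;
  from 16 on, a cell list over the box with cells at least as large as the
  interaction range is rebuilt every step. Fences and pickets live in a
  static lookup grid built once per run from their Moore-tiled images, so
  minimum-image geometry reduces to plain geometry. Pair forces are
  accumulated in ascending particle index so floating-point sums do not
  depend on the search path.
* **Boundaries.** Periodic axes wrap with image counters (trajectories are
  recorded unwrapped — squared displacements across images would otherwise
  be meaningless); repulsive axes reflect the offending displacement
  component specularly, preserving step-length statistics near walls. A
  displacement longer than half a periodic axis raises an error, since the
  minimum image would be ambiguous.
* **Degenerate inputs.** Coincident particle centres (undefined force
  direction) are an error, as are paths that a segment cannot classify
  (collinear paths do not count as crossings); a path *ending* exactly on a
  fence counts as one crossing, ties between fences break toward the lower
  segment index. Initial positions are drawn uniformly and redrawn on
  overlap, up to 10⁴ attempts per particle.

## Observables

The ensemble mean squared displacement is
$\mathrm{MSD}(\tau) = \langle |r(\tau) - r(0)|^2 \rangle$ over particles and
replications (a sliding-origin time average is available but off by
default), with standard errors from the between-replication spread, and
$D(t) = \mathrm{MSD}(t) / (2 n t)$, $n = 2$ dimensions. Short lags probe the
free microscopic coefficient, long lags the fence-restricted macroscopic
one.

The radial distribution function
$g(\mathrm{dist}) = \rho^{-1} \langle C_i / A_i \rangle$ counts neighbours
in annuli of width $\mathrm{d}r$ (default 0.5 nm, bins centred on multiples
of $\mathrm{d}r$) around each reference particle and normalizes by the
in-box annulus area and the global density $\rho = N/A$. At repulsive
boundaries the annulus area is clipped by the analytic circular-segment
formula (and an exact chord-length integral when both axes are walls) — no
Monte Carlo, so the estimator is deterministic given the frames. Note
$g \to (N-1)/N$ for an ideal gas of $N$ particles under this normalization.
Occupancy profiles histogram final positions across replications, with
barrier positions on bin edges.

## The 1D barrier oracle

For a single particle between equally spaced, partially permeable barriers
in an effectively infinite domain, the density profile from a delta start
solves the diffusion equation with the interface condition that the flux
through a barrier is continuous and equals $P\,(c^- - c^+)$. The oracle is
a finite-volume scheme whose faces coincide with the barrier positions;
barrier faces get the composite conductance $1/(\Delta x/D + 1/P)$ (two
half-cell diffusive resistances in series with the membrane resistance),
interior faces $D/\Delta x$. Time stepping is Crank–Nicolson after four
backward-Euler start-up steps that damp the rough initial profile
(a Gaussian one cell wide approximates the delta). The scheme is
unconditionally stable, conserves mass to solver precision, is symmetric for
a centred start, and converges: halving the grid changes the profile by
less than 0.5% in L1. Default resolution is $\Delta x = L/50$ and 400 time
steps over the evaluation time.

`fit_permeability()` scans $P$ log-spaced over $[0, 10^3 D/L]$ — beyond the
upper bound barriers are indistinguishable from transparent — and refines
with bounded scalar minimization, tie-breaking toward smaller $P$. Recovery
of a known $P$ is accurate to well under 2%. The simulated occupancy at
$t = 1.58$ ms with probabilistic fences every 50 nm matches the fitted
oracle's compartment integrals within binomial error at 10⁴ replications;
the mapping from $P_{\mathrm{hop}}$ to $P$ is reported as fitted, not
asserted in closed form.

## Scenarios and problem sizes

`run_scenario()` packages the standard study designs: `free` (diffusion
recovery), `validate1d` (the barrier benchmark above), `timestep_sweep`
(scaled $\tilde P_{\mathrm{hop}}$ across $\mathrm{d}t$), `crowding_sweep`
($D_\mathrm{eff}$ versus particle count — potential fences show the
crowding bias, where fence-potential energy released in collisions raises
macroscopic $D_\mathrm{eff}$ with density, while free, probabilistic and
picket systems slow down), `drift` (directed motion toward a repulsive wall
with $g(\mathrm{dist})$ per region) and `relate_fences_export` (the
$(P_{\mathrm{hop}}, D_\mathrm{eff})$ and $(k_{\mathrm{fence}},
D_\mathrm{eff})$ curves a parameter-matching fit would consume).

Defaults are desk scale, chosen to finish in roughly a minute while keeping
the statistical conclusions at wider tolerances: 128 instead of 512
replications for diffusion recovery, 10⁴ instead of 10⁵ replications for
the 1D validation, 0.05 s instead of 0.5 s drift runs, crowding checked at
{1, 500, 2000} particles over 0.2 ms. `full_scale = TRUE` restores the
full-scale conditions. Every scenario writes its effective configuration,
seed and config hash to a manifest, and re-running from the same seed
reproduces trajectories bitwise.

## What the generator does and does not emulate

The synthetic systems capture compartmentalized diffusion of disc-shaped
molecules in a flat, homogeneous membrane: fence geometry statistics via the
periodic Voronoi mesh, excluded volume via linear pair repulsion, skeleton
interaction via the three fence models, and electric-field-like transport
via a constant drift. They do not emulate membrane curvature, lipid
microdomains with distinct viscosity, hydrodynamic coupling, reactions,
transient picket binding, per-fence heterogeneity of hop probabilities, or
anomalous-diffusion analysis — passing tests say nothing about those.
The drift calibration deserves a caveat in the other direction: at
$1\,\mu\mathrm{m}/\mathrm{s}$ over 0.01 s the deterministic displacement
(10 nm) is smaller than the diffusive spread (~16 nm se at 64
replications), so the desk-scale drift estimate is intrinsically noisy; it
is a consistency check against its own standard error, not a precision
measurement.

## Known limitations

* The propagator is first order; the potential-fence model needs
  $\mathrm{d}t \lesssim 200$ ns and pickets $\mathrm{d}t \approx 2$ ns at
  the default parameters, otherwise the steep particle–picket interaction
  is under-sampled and restriction is overestimated. Timesteps must be
  re-checked whenever $D_0$, $L$ or the force constants change.
* Probabilistic fences above $\mathrm{d}t \approx 2000$ ns enter the
  multi-fence-crossing regime (watch the `multi_cross` counter).
* The pair-force constant is interpreted as a linear spring in aJ/nm²
  (default 0.1), making force = constant × overlap length.
* `radial_distribution()` treats distances beyond a quarter of the smaller
  box extent as unreliable (periodic aliasing) and defaults `r_max`
  accordingly.
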