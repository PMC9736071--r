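---
title: "Automated path searching: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated path searching: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapsr)
```

## The problem

Conformational transitions of biomolecules — such as the interconversion
between a ground and an excited state of an enzyme — proceed along
minimum free-energy paths (MFEPs): the most probable channels connecting
two metastable states on a high-dimensional free-energy landscape.
`tapsr` implements travelling-salesman automated path searching (TAPS),
an iterative refinement scheme that starts from any rough guess path
(typically one generated by targeted dynamics) and relaxes it onto the
MFEP, then quantifies the free-energy profile along the result by
umbrella sampling and WHAM and reads off transition states (TS) and
intermediate states (IS).

The package is organised so that the same core operates on two kinds of
configuration: points in $\mathbb{R}^d$ on analytic model potentials
(where every result can be checked against an independent reference) and
molecular coordinate sets compared by RMSD after Kabsch superposition.

## Path collective variables

A path is an ordered set of $N$ nodes with fixed endpoints.  Progress
along and departure from the path are measured by the path collective
variables

$$
s(x) = \frac{\sum_{i=1}^{N} i\, e^{-\lambda d_{x,i}^2}}
            {\sum_{i=1}^{N} e^{-\lambda d_{x,i}^2}},
\qquad
z(x) = -\frac{1}{\lambda}\ln \sum_{i=1}^{N} e^{-\lambda d_{x,i}^2},
$$

where $d_{x,i}$ is the metric distance between configuration $x$ and
node $i$, and the smoothing constant is set from the inter-node spacing,
$\lambda = 2.3\,(N-1) / \sum_i d_{i,i+1}^2$.  Conventions that differ
across the PCV literature and are fixed here:

* both sums run over $i = 1..N$ (an index-0 node does not exist);
* $s$ is reported in node-index units $1..N$, not rescaled to $[0,1]$,
  so an umbrella spacing of 0.5 means half an inter-node gap;
* $z$ carries *squared*-distance units, because the exponent uses
  $d^2$; for large $\lambda$, $z \to \min_i d_{x,i}^2$;
* $\lambda$ is recomputed whenever a path is constructed or modified —
  a stale $\lambda$ cannot occur by construction.

Two numerical points matter.  The exponential sums are always stabilised
by subtracting the smallest exponent, so projections of configurations
far from the path cannot underflow to 0/0.  And for a finite discrete
path the identity $s(\text{node } k) = k$ is exact only where the
Gaussian tails are symmetric about the query (the central node); near
the path ends the truncated tail contributes at the
$e^{-4\lambda\,\mathrm{gap}^2} \approx 10^{-4}$ level.  Profiles along
$s$ also inherit a periodic "staircase" ripple at the node period,
because $|ds/dx|$ oscillates between nodes with amplitude fixed by the
constant 2.3; bin free-energy profiles at or above the node scale, or
use a plain coordinate umbrella when the system is one-dimensional.

The mean projection of one path's nodes onto a reference path,
$\bar z = \frac1N \sum_i z(\text{node}_i;\ \text{ref})$, is the
convergence monitor.  Note that $\bar z$ of two *coinciding* discrete
paths is slightly negative (the log of several overlapping node kernels
exceeds the single-node value), which is why the optimizer compares the
signed $\bar z$ against its tolerance rather than $|\bar z|$.

## The sampler

Node sampling uses overdamped (Brownian) dynamics with the
Euler–Maruyama scheme,
$x_{t+1} = x_t - D\beta\,\nabla(U + U_\text{bias})\,\Delta t
+ \sqrt{2 D \Delta t}\,\xi$.  This replaces a full MD engine: TAPS only
needs equilibrium samples in restrained ensembles, and overdamped
dynamics is the simplest sampler with the right stationary distribution.
Defaults put $\beta = 1$ so all energies are in units of $k_BT$.
`simulate()` refuses step sizes with
$D\beta\,\Delta t\,k_\text{max} \ge 2$ against each potential's
stiffness estimate (the Euler stability bound for the stiffest harmonic
mode, including the restraint's own curvature $\sim k_s/\text{gap}^2$).
Identical seeds give bit-identical trajectories: the compiled integrator
draws from R's own RNG stream.

Nanosecond budgets of all-atom studies map onto step counts; the
package's convention is $1\,\mathrm{ns} \equiv 10^5$ steps, so the
common "2 ns per umbrella window" corresponds to the
$2 \times 10^5$-step windows used throughout the validation suite.  The
mapping is bookkeeping, not physics: only the product
$D\,\Delta t \times \text{steps}$ matters to the sampler.

Bundled landscapes: the Müller–Brown surface (standard coefficients), a
quartic double well / $n$-dimensional two-basin landscape, a three-hole
potential, a harmonic well and a flat potential for null tests.  In the
two-basin family the configured well offset enters through a
$\tfrac{\text{offset}}{2}(1 + \tanh 4x)$ step that is flat at both
wells: curvatures and anharmonic corrections are then identical in the
two basins and the Boltzmann free-energy difference equals the
configured offset up to barrier-shoulder contributions (about 2% at a
3 $k_BT$ barrier and $\beta = 1$), which the bundled
Boltzmann-integration oracle quantifies exactly.

## The optimization loop

Each iteration: (1) sample every interior node under a harmonic
restraint $\tfrac{k_s}{2}(s - i)^2$, with the analytic chain-rule
gradient of $s$; (2) pool the samples and pick candidate nodes; (3)
reorder the candidates as a shortest open tour between the fixed
endpoints; (4) reparametrize to the target geometric resolution.
Per-node seeds derive deterministically from (master seed, iteration,
node), so node order never affects reproducibility, and a node whose
sampling diverges is kept at its old position rather than aborting the
iteration.

**Candidate selection** is greedy density-peak picking: repeatedly take
the sample with the most neighbours within `density_radius` (default:
half the target resolution), then suppress everything inside that
radius.  Density peaks of the restrained ensembles approximate the
free-energy minima of the perpendicular hyperplanes — exactly where MFEP
nodes belong, because paths other than the MFEP are unstable in the
directions orthogonal to themselves.  Selection stops early when the
best remaining neighbour count falls below 10% of the first pick's:
without this floor, sparse excursion tails get promoted to nodes, the
tour lengthens, the reparametrizer inserts more nodes, the candidate
budget (which follows the current node count) grows, and the node count
runs away.  With the floor the node count self-limits near
(path length)/(target resolution).

**Tube wall on z.**  Only $s$ is restrained in the classic description;
$z$ motion is what lets the path relax.  On strongly curved paths,
however, the constant-$s$ slabs fan out on the outside of a bend, the
restrained ensemble pools in that wedge, and the selected nodes bulge
off the MFEP (on the Müller–Brown hairpin this effect alone holds the
recovered path several node-spacings away from the reference).  The
package therefore adds a half-harmonic wall
$\tfrac{k_z}{2}(z - z_\text{max})^2$ for $z > z_\text{max}$, active only
during node sampling, never during umbrella runs.  The default tube
radius is half an inter-node gap laterally
($z_\text{max} = (\text{resolution}/2)^2$) — the regime in which
adjacent constant-$s$ slabs remain well separated even at bends — with
$k_z = 8/(\beta z_\text{max}^2)$ so the wall reaches several $k_BT$ one
tube radius beyond the boundary.  The path still migrates freely toward
the MFEP (the tube moves with the path every iteration); it only stops
individual walkers from out-running the current path's resolution.
Setting `z_max = Inf` restores fully unrestrained z.

**Reordering** solves the open travelling-salesman problem from the
first endpoint to the last: exact Held–Karp dynamic programming up to 12
interior nodes, nearest-neighbour seeding plus full 2-opt refinement
beyond, with lexicographic tie-breaking for determinism.

**Reparametrization** inserts metric midpoints into gaps wider than
`d_max_factor` × resolution and deletes the cheapest interior node
flanking gaps narrower than `d_min_factor` × resolution (endpoints are
never deleted), re-entering the insertion pass if a deletion reopens an
oversized gap, for at most 10 rounds.

**Convergence** is declared when $\bar z(\text{current}, \text{previous})$
stays below `convergence_tol` (default: 1% of the initial mean squared
gap) for `convergence_window` (default 5) consecutive iterations.
Reaching `max_iterations` returns an honest `converged = FALSE` result.
Classical MDS of pooled path nodes (`mds_project`, Torgerson
double-centering via the top eigenpairs) gives the complementary visual
diagnostic of how iterates move.

## Reference MFEPs for validation

Validation needs an independently computed MFEP.  A zero-temperature
string relaxation (steepest descent plus equal-arclength redistribution,
`string_mfep`) finds the right topology quickly but stalls at the
tangent-discretization level — at a hairpin with curvature radius
$\approx 0.18$ and gradient norms $\approx 150$, the discrete
perpendicular-gradient residual plateaus orders of magnitude above a
$10^{-3}$ target no matter how long it runs.  The shipped oracle
(`mep_flowline_oracle`) therefore uses the string result only for saddle
guesses, refines each saddle by minimizing $|\nabla U|^2$, and then
integrates the two steepest-descent flowlines
$x' = -\nabla U/|\nabla U|$ out of every saddle with RK4 at arclength
step $5\times10^{-5}$.  Every point of such a flowline lies on the MFEP
by definition; chaining the segments through the intermediate minima and
resampling to 12001 equal-arclength nodes yields a reference whose
maximum discrete perpendicular gradient is below $10^{-3}$.

## Free-energy profiles

Umbrella windows are scheduled along $s$ from 1 to $N$ at an average gap
of 0.5 (the last window sits exactly at $N$), sampled under
$\tfrac{k}{2}(s - s_c)^2$, and combined by the standard self-consistent
WHAM iteration on binned probabilities, run in log-space until the
window constants change by less than $10^{-7}$ (cap $10^5$ iterations;
non-convergence is an error carrying the last residual).  Defaults that
the literature leaves open, all exposed in the interface: 10 bins per
unit of $s$; the first 10% of each window discarded as equilibration;
zero-count bins masked, never imputed, with a run of three or more empty
interior bins treated as a disconnected histogram error; adjacent-window
overlap measured as shared normalized-histogram mass with a 0.05
pass threshold and midpoint centers proposed for failing pairs.

States are read off the profile by topographic prominence (default
0.5 $k_BT$): interior maxima are transition states, interior minima
intermediate states; the two profile endpoints are the designated end
states and always appear in the minima list; alternation is enforced
among interior extrema by discarding the lower-prominence violator.
`delta_g` then returns $f(s_B) - f(s_A)$ between identified minima —
negative when the destination state is the more stable one.

## Study conditions of the validation suite

The test suite and the acceptance script run fixed desk-scale studies;
their sizes are choices of this package, made once:

* **Müller–Brown MFEP recovery**: straight 15-node initial path between
  the two deep minima; $\beta = 4$, $D = 0.01$, $\Delta t = 10^{-3}$
  (stability margin ≥ 4 against the stiffest mode), $k_s = 150$
  (restraint fluctuation ≈ 0.04 node units), 500 recorded samples per
  node spaced 20 steps (several perpendicular relaxation times), at most
  40 iterations.  $\beta = 4$ keeps the perpendicular spread of the
  softest valley segment below about half a node gap so density peaks
  localize the valley floor; runs at $\beta \le 2$ are visibly noisier
  and $\beta = 8$ under-explores.
* **Umbrella/WHAM validation**: $2\times10^5$ steps per window (the
  "2 ns" analogue), $k = 60$ at spacing 0.25 for the double well
  (window spread ≈ 0.13, overlap ≈ 0.3) and $k = 16$ at spacing 0.5
  for the flat null.
* **Sampler physics**: free diffusion over 8000 independent
  coordinates for $10^5$ steps; equipartition over 400 harmonic
  coordinates; well occupancy from an $8\times10^6$-step double-well
  run with a 1 $k_BT$ offset (thousands of barrier crossings).

## What the toy studies do and do not show

The generator emulates the *geometry* of activated transitions — two
basins, an intermediate, saddles, a curved MFEP — with exact oracles.
Passing these studies demonstrates that the path search, the collective
variables, the reorder/reparametrize machinery and the WHAM estimator
are implemented correctly and fit together.  It does not demonstrate
anything about force fields, solvent, sampling convergence at molecular
dimensionality, kinetics, or the existence of multiple parallel paths
(the search follows one channel; enumerating alternatives is out of
scope).  Molecular-mode support (XYZ/PDB input, align-set/compute-set
RMSD metrics, contact and RMSD trajectory statistics) is exercised on
synthetic structures only; no external structure is required or
downloaded.

## Known limitations

* Perpendicular sampling and the biased integrator require the
  euclidean metric; RMSD metrics are available for projection and
  analysis but not for on-the-fly restrained dynamics.
* The PCV staircase ripple makes sub-node-scale structure on
  $f(s)$ partially an artifact of the mapping $x \mapsto s$; interpret
  TS/IS calls at the node scale.
* The tube wall biases the *sampling* of each hyperplane, not the final
  profile (umbrella runs are wall-free); still, with `z_max` far below
  the default the path can take more iterations to migrate.
* `select_candidates` is $O(n^2)$ in pooled sample count; pools above
  20000 samples are thinned by striding before selection.
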