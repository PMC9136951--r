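---
title: "Water-network thermodynamics with waternet: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-network thermodynamics with waternet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(waternet)
```

## The problem

Buried protein binding sites often hold small, ordered networks of water
molecules that exchange very slowly with bulk solvent. Two families of
methods estimate the thermodynamics of such networks from molecular
simulations: grand-canonical Monte Carlo (GCMC), which inserts and deletes
waters in a region of interest (ROI) under a controlled chemical potential,
and grid-based inhomogeneous solvation theory (GIST), which resolves
solvation energy and entropy onto a grid of voxels from an equilibrium
ensemble. `waternet` implements both routes at desk scale, together with the
statistics used to compare hydration structure across simulation protocols,
and ships synthetic systems with exactly known answers so that every
estimator can be validated against an oracle rather than against another
simulation.

## Grand-canonical sampling

The sampler works in the Adams formulation: the dimensionless parameter $B$
plays the role of the chemical potential. A proposed insertion of a water
into the ROI (uniform position, uniform orientation) is accepted with
probability

$$P_\mathrm{ins} = \min\left[1,\ \frac{e^{B - \beta\,\Delta U}}{N+1}\right],
\qquad
P_\mathrm{del} = \min\left[1,\ N\,e^{-B - \beta\,\Delta U}\right],$$

where $N$ is the number of waters before the move, $\Delta U$ the potential
energy change and $\beta = 1/k_BT$. Equilibrium with bulk water corresponds
to

$$B_\mathrm{equil} = \beta\,\mu'_\mathrm{sol} + \ln\!\frac{V_\mathrm{ROI}}{V^\circ},$$

with $\mu'_\mathrm{sol}$ the excess chemical potential of water and
$V^\circ$ its standard-state volume. The defaults
($\mu'_\mathrm{sol} = -25.9$ kJ/mol, $V^\circ = 30$ Å$^3$, $T = 300$ K) are
calibrated values for rigid three-site water under plain-cutoff Monte Carlo
conditions; both are plain arguments of `adams_parameters()`.

```{r}
params <- adams_parameters(T = 300, mu_ex = -25.9, V_std = 30)
roi <- roi_sphere(c(15, 15, 15), 3)
equilibrium_adams(params, roi)
```

Energetics are rigid-water Lennard-Jones (Lorentz–Berthelot combining) plus
Coulomb, with plain truncation at the box cutoff: no shifting, switching or
long-range electrostatic treatment. That choice mirrors cutoff-based Monte
Carlo practice for these systems and keeps every energy exactly
recomputable by brute force in the tests; PME-level comparisons are out of
scope. Units are fixed package-wide (Å, kJ/mol, K, elementary charge;
Coulomb constant 138.935458 kJ mol$^{-1}$ Å e$^{-2}$). Site separations
below $10^{-6}$ Å short-circuit to an infinite-energy sentinel so hard-core
overlaps auto-reject instead of overflowing.

Two deliberate simplifications of the sampler, documented here because they
differ from protein simulations: the toy systems are **closed over the
ROI** — there is no explicit bulk phase, so exchange with bulk is
represented entirely by the chemical-potential term (exactly what the
acceptance rules encode); and a translation that would carry a water out of
the ROI is rejected, so the number of waters in the ROI always equals the
number in the system. Insertion orientations use Shoemake's uniform
quaternion method; translations propose uniform displacements in a cube of
half-width 0.3 Å by default. Insert and delete proposal weights must be
equal so the $B$ terms in the acceptance ratios need no proposal-asymmetry
correction. Every run takes one RNG seed and reproduces bit for bit.

### The lattice oracle

`lattice_gc_system()` defines a model with $M \le 20$ binding sites, site
energies $\epsilon_m$ and optional pair couplings, whose grand partition
function

$$\Xi(B) = \sum_{s \in \{0,1\}^M} e^{B N(s) - \beta U(s)}$$

is summed exactly by `enumerate_lattice()`. The same Adams acceptance
functions drive `run_gcmc_lattice()`; because its insertion proposal is
uniform over the $M$ cells rather than over a continuous volume, the
acceptance rules are applied with $B_\mathrm{cell} = B + \ln M$, exactly as
the continuum Adams parameter absorbs $\ln V_\mathrm{ROI}$. The stationary
law is then exactly the enumerated weight, which makes the lattice the
single source of truth for the sampler and for free-energy integration.

```{r}
sys <- lattice_gc_system(c(-12, -9, -7), T = 300)
enumerate_lattice(sys, B = -3)$mean_N
tr <- run_gcmc_lattice(sys, B = -3, n_moves = 2e4, seed = 1)
mean(tr$records$N[-(1:4000)])
```

## Titration and grand-canonical integration

`titrate_gcmc()` runs the sampler over a grid of Adams values;
`build_titration_curve()` aggregates the post-burn-in occupancies (default
burn-in fraction 0.2) into points $(B_k, \langle N\rangle_k, \mathrm{SE}_k)$.
Repeats at one $B$ are pooled with a between-repeat standard error; a single
trace gets a 20-block standard error to absorb autocorrelation.

The binding free energy of growing the network from $N_i$ to $N_f$ waters
follows from integrating the titration curve:

$$\Delta G(N_i \to N_f) = k_BT\left[B_f N_f - B_i N_i -
\int_{B_i}^{B_f} \langle N\rangle\, dB - (N_f - N_i)\,B_\mathrm{equil}\right],$$

where $B_i, B_f$ are the Adams values at which the smoothed curve passes
through $N_i, N_f$, and the last term references the transfer to bulk at
$B_\mathrm{equil}$. Numerical choices, in order of application:

* **Monotone smoothing.** Isotonic regression (`stats::isoreg`) restores
  monotonicity of the sampled means, then a monotone piecewise-cubic
  (Fritsch–Carlson) interpolant makes $B(N)$ inversion well defined;
  quadrature is trapezoidal on a 1000-point refined grid. At eleven knots
  the interpolant contributes a partial-integral bias of order 0.04 kJ/mol
  on lattice-like curves — the tests budget for it explicitly.
* **Ties.** If the smoothed curve is flat at the requested $N$, $B(N)$ is
  the midpoint of the flat interval.
* **End clamping.** Integer occupancies at the ends of the curve
  ($N = 0$, $N = M$) are approached only asymptotically by
  $\langle N\rangle(B)$. A requested $N$ within `clamp_tol` (default 0.05
  waters) of the attained range is clamped to the range end; anything
  further out raises an error rather than extrapolating. With Adams grids
  extending about five units beyond the outer transitions the clamping
  error is of order $10^{-3}$ kJ/mol. The exact lattice reference
  (`lattice_transfer_free_energy()`, the Legendre transform
  $k_BT[B\langle N\rangle - \ln\Xi]$ of the enumerated grand potential,
  with the same $B_\mathrm{equil}$ reference) applies the same clamping
  rule so the comparison is well posed.
* **Errors.** The standard error of $\Delta G$ propagates the per-point
  standard errors through the trapezoid weights; antisymmetry
  ($\Delta G(N_i \to N_f) = -\Delta G(N_f \to N_i)$) and path additivity
  over intermediate integers hold by construction.

`free_energy_profile()` tabulates $\Delta G(0 \to N)$ for every attainable
integer, reports the global minimum and the interpolated
$\langle N\rangle(B_\mathrm{equil})$, and flags the minimum as *shallow*
when a neighbouring integer lies within $k_BT$ — a situation in which the
reported optimal network size should not be over-interpreted.

## GIST

`gist_analysis()` bins water oxygens onto cubic voxels (0.5 Å spacing by
default, half-open intervals, boundary observations to the higher-index
voxel) and computes per voxel $k$, always as per-frame averages so ROI sums
are directly comparable between runs:

* $E_{sw}(k)$: mean solute–water interaction energy of the waters observed
  in the voxel; summed over voxels this equals the direct total exactly.
* $E_{ww}(k)$: water–water energy with half-weight attribution — each pair
  energy is split equally between the two partner voxels, so the ROI sum
  counts every pair once.
* $T\Delta S_\mathrm{trans}(k) = -k_BT\,(N_k/N_\mathrm{frame})
  \ln(\rho_k/\rho^\circ)$ with $\rho_k = N_k/(V_k N_\mathrm{frame})$,
  the uniform-within-voxel approximation; zero for empty voxels
  ($x\ln x \to 0$) and at bulk density. $\rho^\circ$ comes from the water
  model (0.0329 Å$^{-3}$ for the three-site model, 0.0332 for the
  four-site one).
* $T\Delta S_\mathrm{orient}(k)$: a first-nearest-neighbour
  (Kozachenko–Leonenko) estimate over the orientations pooled in the
  voxel. Distances are rotation angles $d = 2\arccos|q_i\cdot q_j|$ (the
  absolute dot product folds the quaternion double cover), the geodesic
  ball volume is $V(d) = \pi(d - \sin d)$ with total orientation-space
  volume $\pi^2$, and the estimator carries the Euler–Mascheroni additive
  correction. "Euler's constant" is read as the Euler–Mascheroni constant
  $\gamma \approx 0.5772$, the constant that makes the NN estimator
  asymptotically unbiased; the tests arbitrate the normalisation against a
  histogram-based entropy oracle rather than trusting any copied constant.
  Voxels with fewer than two observations contribute zero with a flag;
  duplicate orientations are floored at $10^{-6}$ rad and counted.
* $\Delta G(k) = E_{sw} + E_{ww} - T\Delta S_\mathrm{trans}
  - T\Delta S_\mathrm{orient}$, with ROI totals over the voxel mask and
  standard errors from a frame-block bootstrap (10 blocks by default).

Per-water energies are computed by the package's own energetics at binning
time (`gist_frames_from_trace()`), which decouples the GIST arithmetic from
any simulation engine. Density maps ($\rho_k/\rho^\circ$) export to OpenDX
via `write_dx()`.

Two estimator caveats worth knowing. First, $N\ln N$ averaging gives the
translational term a small positive bias in sparsely occupied voxels
(about $k_BT/2$ per occupied voxel per $N_\mathrm{frame}$); at the bulk
fixture's scale (64 voxels, 500 frames) this amounts to $\sim$0.1–0.2
kJ/mol on the ROI total, which is why the bulk-limit tests use a tolerance
of 0.5 kJ/mol rather than zero. Second, the NN orientational estimator is
noisy below a handful of observations per voxel; it is exact in
distribution only asymptotically, and the tests check it at $10^4$
pooled observations against the histogram oracle (agreement within 10%).

## Hydration-comparison statistics

* **Equilibration fits.** $N(t) = a + b(1 - e^{-kt})$ by bounded nonlinear
  least squares (all parameters $\ge 0$): $a$ waters at $t=0$, plateau
  $a+b$. The equilibration time is $t_\mathrm{eq} = (1/k)\ln[b/(0.05(a+b))]$
  — the 95%-of-plateau crossing — defined as 0 when
  $b \le 0.05(a+b)$ (a trace that starts equilibrated, the "wet start"
  case); $N_\mathrm{eq}$ averages the observed trace over
  $t \ge t_\mathrm{eq}$. A trace with no time trend leaves $b$ and $k$
  jointly unidentifiable, so the fit falls back to the constant model
  rather than failing.
* **Water-site clustering.** Average-linkage hierarchical clustering of
  oxygen positions pooled over frames, cut at 2.4 Å, with the distance
  between same-frame waters set to $10^6$ Å so simultaneous waters never
  merge; clusters below 30% occupancy are dropped. Centroids are
  unweighted member means. The small-instance tests compare against an
  independent brute-force agglomeration.
* **Tanimoto similarity.** $T = c/(a + b - c)$ with $c$ the number of
  centroids that agree within 1.4 Å. Matching — here and everywhere else in
  the package — is greedy one-to-one in ascending distance: deterministic,
  symmetric, and equal to optimal bipartite matching whenever sites are
  well separated. Two empty sets compare as 1 (flagged); one empty set as 0.
* **Crystal-water recovery.** Fraction of crystal waters with a matched
  centroid within each threshold of a 0–2 Å sweep; because greedy matching
  is nested in the threshold, the curve is monotone by construction.
* **Occupancy-distribution comparison.** Pairwise two-sample
  Kruskal–Wallis rank tests (tie-corrected chi-square via
  `stats::kruskal.test`) on subsampled post-equilibration $N$ series, with
  a permutation reference when either series has fewer than ten values.
  The pairwise two-sample form matches the heat-map structure such
  comparisons are reported in; significance stars follow the
  0.1/0.05/0.01/0.001 convention.
* **Site pairing.** Sites from two runs paired greedily within 1 Å and
  scored by Pearson $R$, mean absolute deviation, maximum deviation and
  mean relative deviation (absolute difference over the larger absolute
  value, averaged).

## What the synthetic generators emulate — and what they do not

`make_toy_host()` builds a spherical shell of weak Lennard-Jones wall sites
around a cavity with a small number of attractive "hotspot" sites, plus an
optional blocker that sterically occludes part of the network (the
apo/holo toggle). Hotspot depths default to 18 kJ/mol so that, combined
with water–water attraction, per-water binding lands a few $k_BT$ below
the bulk reference — titration curves are then non-trivial but resolvable
with $\sim10^4$ moves per Adams value. Waters bind on a shell around each
attractor (a Lennard-Jones well has its minimum at finite separation), so
hotspot positions mark network sites, not exact oxygen coordinates.

`make_gist_frames()` plants Poisson-sampled waters as a uniform bulk level
plus Gaussian density peaks with optionally concentrated orientations, and
assigns solute–water energies from an analytic Gaussian well so that every
conservation identity is checkable exactly. `make_occupancy_trace()`
generates the exponential relaxation traces with Gaussian noise floored at
zero (noise model chosen as Gaussian on $N$; the flooring matters only for
near-empty traces).

These generators reproduce the *statistical structure* the analyses need —
titration curves monotone in $B$, localized density peaks, ordered versus
disordered orientation populations, noisy relaxation traces — not protein
physics. Passing tests therefore demonstrate estimator correctness, not
force-field accuracy: there is no protein flexibility (so no structural
alignment is implemented, and trajectories with drifting host coordinates
are rejected rather than aligned), no explicit bulk phase, no long-range
electrostatics, and net-neutral toy hosts sidestep the question of how a
charged system should be treated without a long-range correction.

## Problem sizes used in the checks

The validation suite runs the lattice study at $10^5$ moves per Adams value
on an 11-point grid for sampler checks, and pools four repeats of
$4\times10^5$ moves per value for free-energy integration (where the
0.1 kJ/mol agreement with the exact Legendre-transform reference needs
point standard errors of a few thousandths of a water). The bulk GIST
fixture uses a $4^3$-voxel grid at 500 frames; orientational-estimator
agreement is checked at $10^4$ pooled observations; equilibration-fit
recovery runs 100 noisy traces and is assessed as mean relative error
(the per-seed worst case at that noise level is a $\sim$3$\sigma$ draw of
the rate constant, around 8%); the apo/holo comparison titrates both
toggles over $B = -20\ldots-4$ at 12 000 moves per value. These sizes were
chosen so each property is resolved with a comfortable statistical margin.

## Known limitations

* Plain-cutoff electrostatics only; quantitative comparison with
  Ewald-based engines is out of scope by design.
* The titration integrator refuses to extrapolate beyond the sampled
  occupancy range; widen the Adams grid instead.
* The orientational entropy estimator is a pooled first-NN estimate; at
  voxel occupancies of a few observations its per-voxel values are noisy
  (ROI totals are the robust quantity).
* Replica exchange between Adams values, hybrid GCMC/MD and alchemical
  decoupling are not implemented.
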