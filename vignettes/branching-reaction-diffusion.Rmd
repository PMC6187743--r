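---
title: "Modelling 3D branching morphogenesis with a four-field reaction-diffusion system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling 3D branching morphogenesis with a four-field reaction-diffusion system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`branchrd` simulates the self-organization of branched, lung-airway-like
tissue structures from the interplay of four concentration fields on a
regular 3D grid:

* an **activator** $A$ (biologically, a BMP4-like morphogen) that amplifies
  itself autocatalytically,
* an **inhibitor** $H$ (an MGP-like BMP antagonist) produced alongside the
  activator and diffusing faster, which suppresses activation laterally,
* a **substrate** $S$ (an FGF10-like growth factor) that fuels
  activator/inhibitor production and is consumed by differentiated cells,
* a non-diffusing **differentiation marker** $Y$ that commits voxels to
  "tissue" irreversibly once the local activator is high enough.

$$
\begin{aligned}
\partial_t A &= c\,A^2 S/H - \mu A + D_A \nabla^2 A + \rho_A Y\\
\partial_t H &= c\,A^2 S - \nu H + D_H \nabla^2 H + \rho_H Y\\
\partial_t S &= c_0 - \gamma S - \varepsilon Y S + D_S \nabla^2 S\\
\partial_t Y &= d A - e Y + \frac{Y^2}{1 + f Y^2}
\end{aligned}
$$

All quantities are dimensionless. $\mu, \nu, \gamma, e$ are first-order
degradation rates; $\rho_A, \rho_H$ are secretion rates of the morphogens
by differentiated cells; $c_0, \varepsilon$ are substrate production and
consumption rates; $D_A < D_H$ encodes the short-range-activation /
long-range-inhibition requirement.

The $Y$ kinetics are bistable: with $A$ clamped at zero the nonzero fixed
points of $dY/dt = -eY + Y^2/(1+fY^2)$ solve $feY^2 - Y + e = 0$, giving
(for the canonical $e = 0.1$, $f = 10$) a repeller at
$(1-\sqrt{0.6})/2 \approx 0.113$ and an attractor at
$(1+\sqrt{0.6})/2 \approx 0.887$. A voxel whose $Y$ is pushed past the
repeller by activator exposure ($+dA$) therefore switches irreversibly to
the differentiated state; the tissue is read out as $\{Y \ge Y_a\}$ with
$Y_a = 0.5$, which sits cleanly between the repeller and the attractor.

## What actually drives patterning here

A point worth stating explicitly, because it shapes the whole package: at
the homogeneous steady state $A^* = \nu/\mu$, $H^* = c\nu S^*/\mu^2$,
$S^* = c_0/\gamma$, $Y^* = 0$, the trace of the $A$–$H$ Jacobian block is
$\mu - \nu$, which is **positive** for every parameter set the scenarios
use. The background state is therefore unstable already at wavenumber
zero, and the textbook Turing condition — stable to uniform perturbations,
destabilized only by diffusion at finite wavenumber — does not hold at
this fixed point. `dispersion()` computes the full relation
$\mathrm{Re}\,\lambda_{\max}(q)$ of $J - q^2\,\mathrm{diag}(D_A, D_H, D_S, 0)$
and reports the strict flag honestly (`turing_unstable = FALSE` for these
sets), rather than assuming the label the mechanism is usually given.

What the dynamics actually do is excitable, front-driven patterning with
lateral inhibition. The local $A$–$H$ subsystem is a relaxation
oscillator: activator pulses grow autocatalytically, the slower-degrading
inhibitor catches up and quenches them, and the medium is refractory until
$H$ decays. A differentiated region secretes activator ($\rho_A Y$),
re-igniting pulses at its rim; each pulse pushes the $Y$-front outward
into substrate-rich territory while depleted substrate and exported
inhibitor suppress re-activation behind and beside the front. Elongation,
side-branching and tip-splitting all emerge from this pulse-by-pulse
competition, biased by where $S$ is plentiful. The linearized dispersion
relation remains meaningful for small perturbations around the fixed
point — the package verifies measured Fourier-mode growth rates against
$\mathrm{Re}\,\lambda(q)$ on periodic domains to within 5% — but the
structures themselves live far from that linear regime.

## Numerical scheme and resolution

The solver is a plain explicit Euler scheme with a 7-point Laplacian,
zero-flux (mirror) boundaries by default, and no implicit or adaptive
machinery. Three numerical choices matter:

* **Grid spacing.** The activator core width is
  $\sqrt{D_A/\mu} \approx 0.35$–$0.58$ length units across the scenario
  parameter sets, and the inhibition range is
  $\sqrt{D_H/\nu} \approx 1.8$–$2.9$. The default spacing `h = 0.25`
  resolves the core with ~2 voxels and the inhibition range with ~12. At
  `h = 1` the core is sub-voxel: discrete spikes then either nucleate
  spurious tissue spots over the whole domain or fail to ignite the seeded
  bud at all, so coarse grids change the phenomenology qualitatively, not
  just quantitatively.
* **Time step.** `dt = 0.04` sits at the explicit-Euler diffusion bound
  $h^2/(6\max D) = 0.0401$ for the default spacing. The stepper refuses a
  larger `dt` unless explicitly overridden, and negative or non-finite
  concentrations abort the run with a diagnostic naming the step, voxel
  and field; negativity is treated as a symptom of a too-large step, never
  silently clamped. The one clamp in the scheme is the `H_floor`
  ($10^{-8}$) applied to the denominator of the autocatalysis term; clamp
  events are counted and reported in the run log.
* **Run length.** A "step" count for an explicit scheme is only
  meaningful together with the time increment behind it, which differs
  between implementations of this model family. In this package's units the seeded bud ignites within $t \sim 100$ and grows by
  discrete activator pulses, each inhibitor-refractory cycle adding a
  shell of differentiated tissue; the measured front speed at the
  canonical parameter sets is of order $10^{-3}$ length units per time
  unit. Structures the size of the lateral-inhibition range — the point
  where elongation and branch competition begin — therefore need
  $t \gtrsim 10^3$, and multi-generation trees substantially more.
  Scenario run lengths in `builtin_scenario()` ($t = 4000$–$6000$ on the
  64 × 64 × 32 default domain) were fixed once from this staging and are
  recorded in every run's metadata; longer horizons are a configuration
  choice.

## Initial conditions

The default background is the homogeneous $Y=0$ fixed point with a
multiplicative fluctuation of amplitude 0.05 (5%) applied independently to
$A$ and $H$ per voxel from a seeded RNG — the only stochastic element in
the pipeline; everything downstream is deterministic given the seed. The
background transient decays to the excitable rest state (the zero-activator
point $A = 0$, $H \to 0$, $S = c_0/\gamma$) without nucleating tissue,
while the seeded bud — a sphere of radius 2 voxels with $Y = 1$ at the
domain center — ignites and grows. The initial fluctuations are what
breaks the bud's spherical symmetry; with `fluctuation = 0` and a centered
seed the entire trajectory stays mirror-symmetric to rounding error,
which the test suite asserts.

The gradient-fabrication scenario instead starts with no differentiated
cells anywhere and an affine activator ramp (defaults 0.001 to 2.9, the
two uniform-control levels) along one axis; its uniform controls use the
same low/high values without the ramp. Fluctuations are applied on top of
the ramp — without them the dynamics would remain exactly plane-uniform,
transverse structure could never arise in exact arithmetic, and branching
from a gradient would be unobservable.

## Morphometrics

`extract_tissue()` thresholds $Y$ at $Y_a$ and measures the largest
26-connected component: volume fraction, principal-axis ratio (from
second moments), and sphericity with exposed-face surface-area counting
corrected by the stereological factor 2/3 so a digitized ball scores
near 1. `skeletonize_region()` thins the component to a curve skeleton by
sequential removal of simple points (Bertrand–Malandain characterization,
six directional subiterations, endpoints preserved), fuses touching
junction voxels into branch-point nodes, and traces edges with the
26-connected arc metric ($1, \sqrt2, \sqrt3$ step weights). Sequential
directional thinning is topology-preserving but places junctions with up
to one voxel of axis-dependent jitter; tests compare arc lengths at that
tolerance.

The five-regime classifier operationalizes pattern reading as a fixed
metric cascade (volume fraction > 0.5 → spillover; sphericity > 0.85 and
axis ratio < 1.5 → no-branch; no branch points → parent-only; branch
points predominantly in the distal 25% of the arc-length extent with
daughter-arm length ratio ≥ 0.25 → tip-splitting; otherwise
side-branching). The distal-fraction and arm-symmetry thresholds are this
package's choices where the original classification was visual; all are
exposed as arguments. Transverse activator/inhibitor profiles are sampled
by trilinear interpolation along the widest tissue chord through the
distal tip (probing a few voxels of setback behind the rounded apex), and
peaks are counted by relative prominence (default 0.1 of the profile
range), with plateaus counting once and profile ends excluded.

"Spatial separation of bifurcation events" is the centerline arc distance
from each branch point to its nearest ancestor branch point; the
root-to-first-branch-point distance is reported separately, matching the
definition used for the substrate-consumption ($\varepsilon$) contrast:
high consumption exhausts substrate right ahead of the tip and forces
early splitting (short separations), low consumption lets the stalk run
(long separations).

## What the synthetic fixtures do and do not show

The morphometric pipeline is validated on analytic voxelized shapes —
balls, capsule cylinders, single and double Y-tubes with constructed arm
lengths and angles — whose topology and moments are known exactly. These
fixtures exercise thresholding, component labeling, thinning, graph
tracing, classification and separation measurement, but they are smooth,
noise-free solids: they do not probe threshold sensitivity on the rough,
pulse-layered surfaces real runs produce, nor anything about the PDE
dynamics. Conversely, passing the simulation-level checks says the model
reproduces the qualitative regime structure of this idealized chemical
system — it says nothing about real lung development, where mechanics,
multiple cell types and lumen formation (all deliberately outside this
model) matter.

## Numerical edge cases and conventions

* Degenerate parameters: `c0 = 0` gives the $H^* = 0$ steady state, which
  is flagged `degenerate` and refused by the Jacobian/dispersion path.
* The full (four-equation) steady state is found by damped Newton with
  the analytic Jacobian from the clamped-Y0 state, keeping iterates
  non-negative; non-convergence is an error carrying the last iterate.
* Empty tissue regions are valid results (`n_components = 0`,
  `UNDETERMINED` label), not errors; a mask thinner than one voxel
  yields an empty skeleton.
* Checkpoints are ASCII VTK snapshots plus a JSON sidecar; since the
  fluctuation RNG is consumed entirely at initialization, resuming a
  checkpoint reproduces the uninterrupted trajectory bit for bit.
* All randomness flows through the single `rng_seed` of the
  initial-condition specification.

## Problem sizes used in the shipped checks

The package's own test suite and the acceptance script run the scenarios
on a 32 × 32 × 16 grid (8 × 8 × 4 length units at the default spacing)
for $t \le 2000$, with one to three fluctuation seeds per claim, which
keeps the full suite within tens of minutes on one CPU; the
parameter-plane sweep covers the $\mu$–$\nu$ rectangle
$[0, 0.8] \times [0, 0.1]$ on a coarse grid. At these sizes the checks
exercise the full pipeline — ignition, bud growth, thresholding,
skeletonization, classification, separations, profiles — but the
structures reached are early-stage: a bud at or below the
lateral-inhibition scale, not a multi-generation tree. Given the measured
front speed (previous section), the branching stages lie at horizons and
box sizes well beyond these shipped checks; the scenario-level claims
about side-branching, tip-splitting, separation ordering and the
five-regime map are therefore exactly that — claims the shipped reduced
runs measure and report, not guarantees they reproduce. Larger domains
(the printed 64 × 64 × 32) and longer horizons are a matter of
configuration, not code.

## Known limitations

* The chemistry-only model: no mechanics, no hollow tubes, no cell
  migration or chemotaxis of the differentiation marker.
* Explicit Euler only; stiff parameter corners pay for it in step count.
* The strict Turing flag is `FALSE` at the canonical sets (see above);
  consumers expecting a classical Turing diagnosis should read
  `q_peak`/`lambda_peak` and the front-driven interpretation instead.
* Sequential thinning's voxel-level jitter bounds the precision of arc
  length comparisons to about one voxel.
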