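---
title: "Weighted-ensemble design of conformational-switch kinetics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted-ensemble design of conformational-switch kinetics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`switchWE` implements a complete computational pipeline for studying — and
rationally accelerating — protein conformational switches built by
alternate frame folding (AFF): a protein fused to a circular permutant of
itself so that two overlapping "frames" (N, the original fold, and N', the
permutant fold) share a sequence segment and therefore fold mutually
exclusively. Ligand binding to one frame drives switching, and the
response time of the switch is set by the rate constants of the N to N'
and N' to N conformational changes. This vignette explains the models,
the sampling strategy, the estimators, the numerical choices, and the
synthetic systems on which the package validates itself.

## 1. The energy model

The package uses a residue-level, native-centric (Go-type) representation:
one bead per residue at the C-alpha position, with attractive interactions
only between residue pairs in contact in a native structure.

For a structure with native contact set $\{(i,j)\}$ (C-alpha distance
$\le$ 8 Å by default, sequence separation $\ge 3$; both config-exposed),
the potential is

$$
V = \sum_{\text{bonds}} \tfrac12 k_b (r - r_0)^2
  + \sum_{\text{angles}} \tfrac12 k_a (\theta - \theta_0)^2
  + \sum_{\text{dihedrals}} \big[k_d^{(1)}(1-\cos\Delta\phi)
        + k_d^{(3)}(1-\cos 3\Delta\phi)\big]
$$
$$
  + \sum_{\text{contacts}} \varepsilon_{ij}
      \Big[5\big(\tfrac{r_{0,ij}}{r}\big)^{12}
         - 6\big(\tfrac{r_{0,ij}}{r}\big)^{10}\Big]
  + \sum_{\text{non-native}} \varepsilon_{\mathrm{ev}}
      \big(\tfrac{\sigma}{r}\big)^{12},
$$

the canonical functional form for C-alpha structure-based folding models.
All reference values ($r_0$, $\theta_0$, $\phi_0$) are taken from the
native geometry, so the native structure is a stationary point of the
bonded terms and every contact well sits at its minimum there. Excluded
volume ($\sigma = 4$ Å, between all non-native pairs with separation
$\ge 3$) is what makes the two frames of an AFF construct *mutually
exclusive*: both frames cannot simultaneously occupy the shared segment's
docking interface.

Defaults (config-exposed through `buildAFFModel()`): $k_b = 20$,
$k_a = 10$, $k_d^{(1)} = 0.5$, $k_d^{(3)} = 0.25$,
$\varepsilon_{\mathrm{ev}} = 1$ in the model's energy unit (kcal/mol in
real units, $k_BT$ in reduced units). The single well depth
$\varepsilon$ is uniform across contacts and is the one calibration
scalar (Section 5).

### Dual-frame assembly

`buildAFFModel()` builds the construct *duplicated segment + linker +
full parent chain* and maps the parent's contacts onto both frames: the N
frame uses the original copy of the duplicated residues, the N' frame the
N-terminal copy; contacts lying entirely inside the shared segment are
tagged `shared` and counted once. Linker residues receive bonds only (no
angles, dihedrals or contacts involving a linker bead), keeping the
linker flexible. Both frames carry identical shared-segment parameters,
and a remapping-closure invariant (tested) guarantees the two frames'
$(r_0, \varepsilon)$ multisets are identical before any perturbation.

### Mutations and ligand bias

An "underpacking" mutation (e.g. Phe to Ala) is modelled as the idealized
maximum-underpacking scenario: *all attractive native interactions of the
parent residue are removed*. Numerically this is a WCA-style split of the
12-10 well: a mutated pair keeps the repulsive core (the well shifted up
by $\varepsilon$ and truncated at $r_0$) and loses the attraction. We
deliberately did not substitute the generic $\sigma = 4$ Å excluded
volume for mutated pairs: at compressed geometries the generic wall is
*softer* than the 12-10 core it replaces, so that substitution can lower
the energy of a configuration — violating the defining property of a
delete-attractive mutation. With the WCA split, `applyMutation()` never
decreases the energy of any configuration and raises the native-state
energy by exactly the summed deleted well depths (both properties are
tested).

Ligand (Ca²⁺) binding is represented minimally as a uniform
multiplicative scaling ($\ge 1$) of the binding-competent frame's contact
well depths, optionally restricted to contacts touching a user-supplied
binding-loop residue set; scale 1 reproduces the apo model exactly. The
binding-dead frame is simply left unscaled.

## 2. Dynamics

Conformations evolve by overdamped (inertialess) Brownian dynamics,

$$x \leftarrow x + \frac{D\,\Delta t}{k_BT} F + \xi, \qquad
  \xi \sim \mathcal N(0,\, 2D\,\Delta t),$$

with a single diffusion coefficient for every bead. All noise is drawn
from R's RNG, so a fixed `set.seed()` makes every trajectory — and every
weighted-ensemble archive built on top — bitwise reproducible.

Numerical choices worth knowing about:

* **Timesteps.** Rather than claiming stability a priori, every step is
  guarded by a per-coordinate displacement bound (default 2 Å; exceeding
  it raises a timestep-too-large error). The fixtures use
  $\Delta t = 0.002$ (real-unit hairpin) and $0.004$ (reduced-unit AFF
  construct), values at which multi-million-step runs stay clear of the
  guard and the mean potential energy agrees with finer-step runs to
  about 2%.
* **Angle regularization.** The exact angle force diverges as
  $1/\sin\theta$ at collinearity; the kernel floors $\sin\theta$ at 0.1,
  softening the restoring force only for $\theta \gtrsim 174^\circ$.
* **Torsion switch-off.** The torsion angle is undefined when three
  consecutive beads are collinear; the whole term (energy and force
  together, so they stay consistent) is switched off when either plane
  normal falls below $\sin = 0.1$ of its flanking bond angle.
* **Hard floor.** Pair distances below 0.05 Å overflow the $r^{-12}$
  terms; the energy is reported non-finite and propagation stops with an
  error rather than producing NaNs.

Force-gradient consistency is verified against central differences on
randomly perturbed configurations (away from the regularized regions),
and the minimized-RMSD progress coordinate (Kabsch superposition via SVD)
is verified against an independent quaternion implementation and against
`bio3d::fit.xyz`.

## 3. Weighted-ensemble sampling

The weighted-ensemble (WE) strategy maintains many weighted trajectory
replicas, partitioned into bins along a progress coordinate. Every
$\tau$ of dynamics, each occupied bin is resampled to a target count
(default 4): the highest-weight walker is split (clones share the
parent's weight equally) until the count is reached, or the two
lowest-weight walkers are merged, the survivor drawn with probability
proportional to weight and absorbing both weights. Splitting and merging
preserve the expectation of every weight-linear observable, so no bias is
introduced into the dynamics; total weight is conserved to floating-point
accumulation error (the suite asserts $|\sum w - 1| \le 10^{-12}$ after
every iteration of every run).

Conventions: bins are half-open $[{\rm low}, {\rm high})$ with the
outermost bins absorbing over/underflow, so every finite coordinate maps
to exactly one bin; walkers with non-finite coordinates are quarantined
with an error record. For AFF constructs the progress coordinate is the
pair of frame RMSDs $(\mathrm{rmsd}_N, \mathrm{rmsd}_{N'})$ from the two
folded references; 1-D fixtures use the position itself.

Two modes:

* **Steady state**: walkers reaching the target state are *recycled* —
  terminated and reinitiated in the initial state with identical weight;
  the recycled weight per unit time is the target flux.
* **Equilibrium**: no recycling.

Steady-state runs are best started from a pre-equilibrated ensemble;
`weConfig(initialWalkers = )` accepts a previous archive's stored final
walker set for exactly this purpose, and the toy-switch rate protocol
(`toySwitchRates()`) warm-starts all replicate runs from one equilibrium
archive. Every walker carries a *history label* (the state it visited
last, inherited through splits and merges, recycled walkers relabelled to
the initial state); runs report the unset-label fraction so users can
confirm it decays.

## 4. Estimators

**Rates.** The macroscopic rate constant is $k_{ij} = f_{ij} / p_i$:
recycled flux into $j$ per unit time divided by the probability-weighted
fraction of trajectories more recently in $i$ than in $j$ (unset labels
excluded from numerator and denominator). Analyses discard a burn-in
fraction (default 10%, config-exposed); the short fixture runs in the
tests use 40-50% because their startup transient occupies a larger share
of the run — an explicit, documented choice, checked by a stationarity
test (doubling the burn-in moves fixture rates by less than the s.e.m.).
With $n \ge 2$ independent archives the s.e.m. of $k$ across archives is
reported. The WE rate on the 1-D double well agrees with a brute-force
mean-first-passage oracle within statistical error (and within a few
percent at default settings).

**States.** Following the mode rule, state boundaries are placed at the
maxima of the equilibrium probability distribution along the progress
coordinate; boundary ties resolve toward the basin, the absorbing
outermost bins are excluded from mode detection, and two usable modes
must be separated by a genuine dip (valley below 0.6 of the lower mode) —
otherwise (flat or freely diffusing distributions) state definition fails
with an explicit error.

**Stabilities.** $\Delta G_{\rm fold} = -k_BT\,
\ln(P_{\rm folded}/P_{\rm unfolded})$, with populations read either from
the state regions of an equilibrium archive or from history-labelled
weight (`method = "label"`); opposing steady-state simulations can be
combined instead through the rate ratio
(`stabilityFromRates()`), whose labelled-population interpretation makes
it exactly comparable to the `"label"` equilibrium estimate. A practical
warning encoded in the fixtures: the rate-ratio route is only faithful
when each directional run reinserts walkers from the state's own
(pre-equilibrated) ensemble — reinsertion from a single atypical
configuration (e.g. a fully extended chain) biased the folding rate by an
order of magnitude in our validation, so the hairpin's `stabilityFun`
harvests state pools from an equilibrium run first. Both estimator
routes were validated against long brute-force occupancy measurements at
marginal stability.

**Efficiency.** $S = (\mathrm{MFPT} \times n_{\rm events}) /
T_{\rm WE}$: the expected brute-force cost of harvesting the same number
of independent switching events divided by the aggregate WE simulated
time. On the double-well family, $S$ grows with barrier height as
expected for a rare-event method.

## 5. Calibration

`calibrateContactStrength()` finds the uniform $\varepsilon$ reproducing
a target folding free energy by monotone bracketing: the next trial
interpolates the bracketing pair (false position) with a bisection
fallback. We chose false position over plain bisection because the
$\Delta G(\varepsilon)$ response of a cooperative folder is steep and
smooth (tens of $k_BT$ per unit $\varepsilon$ on the fixtures), so
interpolation converges in about five stability evaluations where
bisection from a safe bracket needs ten or more. The search trace is
returned, and an unbracketable target raises a `calibrationFailure`
condition carrying the trace.

## 6. The synthetic systems — and what they do and do not show

All validation inputs are generated in code, seed-deterministically.

**1-D diffusive wells** (`makeDoubleWell()`): a Brownian particle in
$V(x) = h\,[(x/a)^2 - 1]^2$, or the sextic
$6.75\,h\,(x/a)^2[(x/a)^2-1]^2$ with a central metastable well standing
in for an on-pathway switching intermediate. Rates, stationary
histograms and first-passage times have closed-form or cheap brute-force
oracles that share no code with the WE engine, so WE-vs-oracle agreement
is a genuine cross-check.

**Beta-hairpin folder** (`makeToyHairpin()`): a two-stranded antiparallel
hairpin in real units (kcal/mol), the two-state component on which
stability estimation and calibration are exercised against
experimental-scale targets. The default is 16 beads; the calibration
checks run the 12-bead variant, whose equilibrium-occupancy stability
estimator is both quicker and tighter (fresh-seed spread of a few tenths
of a kcal/mol near a −5.6 kcal/mol target) — the validation suite's
re-check tolerance (0.3 target tolerance plus 0.5 estimator spread)
states exactly this.

**Miniature AFF switch** (`makeToyAFF()`): a 20-bead parent — scaffold
hairpin (residues 1-10) forming the outer strands of a three-stranded
sheet plus a docking hairpin (residues 11-20) whose bottom strand
occupies the sheet's *central* slot — duplicated (11-20) and prepended
through a 2-residue linker into a 32-bead construct. The central slot is
sterically singular, which is what enforces mutually exclusive folding;
an earlier planar-hairpin design failed exactly this requirement (the
duplicate could dock on the mirror face) and was rejected. The default
contact strength (0.80 kT) was fixed once, when the fixture was defined,
at the value giving each construct frame a clear two-state character
(80-90% folded from its own reference; roughly $-2\,k_BT$ frame
stability — the stability-floor regime of the design criteria);
`calibrate = TRUE` instead re-derives a strength from the isolated
parent's stability, mirroring the component-wise calibration a real
design study performs. Test problem sizes (WE iterations in the low
hundreds, three replicates per rate, bin widths of 1.5 Å on the RMSD
plane) are the fixture's own scale, chosen so the full design screen runs
on a desk machine.

**The switching-rate protocol.** Transit times of the miniature switch
are strongly asymmetric: the N' to N docking search completes in tens of
segment lengths, while N to N' takes hundreds (the incoming copy's
docking strand hangs at its free terminus, and partially-docked decoy
poses on the scaffold's outer faces act as kinetic traps — realistic
frustration, but slow). Fully converged forward fluxes are therefore out
of reach at desk scale, and `toySwitchRates()` instead fixes a *matched
protocol*: every construct (wild type, mutant, control) runs with
identical warm starts, seeds, run lengths (350 forward / 250 reverse
iterations by default) and binning, so all comparisons share their
convergence transient and fold-changes are meaningful as matched-stage
comparisons even where absolute rates are still relaxing. Further
choices that matter: each direction warm-starts from an equilibrium
archive begun in its *own* initial fold (warm weight near the target
state would otherwise contaminate the flux); bins are fine (1 Å) along
the incoming frame's RMSD — the slow docking coordinate — with three
coarse bins (folded / intermediate / far) along the other frame's RMSD,
which keeps basin and plateau populations separated at a quarter of the
walker cost of a full 2-D grid; the forward direction runs a leaner
ensemble (three walkers per bin versus four) since its comparisons rest
on order-of-magnitude fold changes rather than tight error bands. Short
fixture runs use 40-50% burn-in because the warm-start transient
occupies a large share of the run.

What passing on these systems shows: weight management, recycling,
lineage bookkeeping, Eq.-1 estimation, TPE segmentation, contact scoring
and the screen's selection logic are correct, and the physics of
preferential ground-state destabilization plays out as designed. What it
does not show: that a residue-level model parameterized this way is
quantitatively predictive for any *particular* protein — transferring the
pipeline to a real switch requires real structures, an experimental
stability to calibrate against, and the paper-scale simulation effort.

## 7. The design screen

Transition path ensembles are reconstructed from the stored lineage: for
every recycling event, the path runs from the frame after the lineage's
last visit to the initial state through the first frame inside the
target, so unproductive excursions are excluded by construction. A
native contact counts as formed when its pair distance is at most
$1.2\,r_0$ (config-exposed); a residue's *contact score* is the
ensemble-weighted mean number of formed native contacts it participates
in, computed per independent simulation to give cross-simulation s.e.m.s.
TPE probability fields weight each path's frames uniformly by the path's
weight.

A sampling caveat that matters at fixture scale: recycled path weights
span many orders of magnitude, so a transition path ensemble of a few
dozen paths has an *effective* sample size of only a handful — and for
the slow forward direction the sampled pathway ensemble itself still
varies qualitatively between independent runs. Reverse-direction scores
(built on hundreds of paths) are reproducible across seeds; forward-
direction and combined rankings are reproducible only under a fixed seed
at this scale, which is what the validation suite pins down. The paper-
scale remedy is simply more independent simulations (the reference
protocol pools ten). `tpeFrames(weighting = "uniform")` exposes the
pathway-diversity weighting (each path counts equally) as an alternative
to the default steady-state path weighting.

`rankCandidates()` orders residues by the ground-state-minus-TPE score
difference, combined across the two switching directions as the sum of
the max-normalized differences (the screen seeks mutations that
accelerate both directions); residues in or adjacent to the
ligand-binding site are flagged and excluded, as are residues whose
mutant stability violates the floor (default $-2$, the minimum stability
margin retained). The negative control — the mutation expected to leave
rates unchanged — is the buried interface residue (contact degree at
least the interface median) with the *smallest* combined score change,
ties broken by residue index.

## 8. Known limitations

* Uniform $\varepsilon$ only (no per-pair heterogeneity); ligand bias is
  a uniform scaling, not a structural ion model.
* The equilibrium-occupancy stability estimator becomes noisy for very
  stable folders (rare unfolded excursions carry bursty weight); the
  pool-based opposing-steady-state route is provided for that regime.
* Discretization: at the fixtures' timesteps, stationary averages carry
  a percent-level integrator bias; all comparisons are internally
  consistent (same integrator everywhere), and the WE-vs-brute-force
  checks share the same timestep by construction.
* Archives store end-of-segment configurations only (intra-segment
  samples are available from `runSegment()` but are not kept by the WE
  loop); TPE frames therefore have $\tau$ resolution.
* Model archives are R serializations (RDS) plus TSV exports for every
  tabular product; no HDF5 container is written.
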