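---
title: "Coupled 3D chromatin and 1D epigenetic dynamics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled 3D chromatin and 1D epigenetic dynamics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epichrom)
```

## The model

`epichrom` simulates a reconstituted chromatin fibre held by two macroscopic
beads (a tweezer force clamp) in a solution of implicitly modelled
reader and writer proteins.  The fibre is a bead-spring polymer of $L$ beads
of size $\sigma$ (about 3 kb, or 30 nm), each carrying a *colour*
$q \in \{\text{grey}, \text{red}, \text{blue}\}$ that represents its dominant
epigenetic mark (e.g. unmarked, H3K27me3, H3K9me3).  Two dynamics are
coupled:

* **3D conformation.**  Each bead obeys the Langevin equation
  $m\ddot r = -\gamma \dot r - \nabla U + \xi$ with unit mass, friction
  $\gamma = 1$, and thermal noise obeying fluctuation–dissipation at the
  solution temperature $T_L$.  The potential $U$ sums harmonic bonds
  ($\kappa = 100\,k_BT_L/\sigma^2$, $x_0 = 1.1\sigma$), a Kratky–Porod
  stiffness with persistence length $l_p = 3\sigma$, and a
  truncated-and-shifted Lennard-Jones pair interaction whose cutoff depends
  on the colours: $1.8\sigma$ (attractive, depth exactly $-\varepsilon$)
  for equal non-grey colours, $2^{1/6}\sigma$ (purely repulsive WCA)
  otherwise.  Like-colour attraction is the implicit action of bridging
  readers; $\varepsilon$ is their binding affinity.  A constant force $\pm f$
  along the stretching axis acts on the two terminal macro-beads (diameter
  $5\sigma$; they interact through the repulsive channel with
  additive-radius shifts, never carry marks and are never recoloured).

* **1D epigenetic state.**  Writers are modelled as a Metropolis process:
  every recolouring interval $\tau_R$ each polymer bead is attempted once on
  average (a batch of $L$ uniformly random single-bead attempts); the
  proposal switches to one of the two other colours with probability $1/2$
  each and is accepted with probability $\min(1, e^{-\Delta U/k_BT_R})$,
  where $\Delta U$ involves only the colour-dependent pair terms of that
  bead.  With $T_R = T_L$ (the default) the coupled dynamics obeys detailed
  balance.

The positive feedback — spatial proximity promotes equal colours, and equal
colours promote spatial proximity — makes the system a *magnetic polymer*:
under a stretching force $f$ and affinity $\varepsilon$ it switches abruptly
between a stretched, epigenetically disordered state (SD) and a compact,
coherently coloured one (CO), separated by a critical line
$f_c(\varepsilon)$.

### Units

Lengths are in $\sigma$, energies in $k_BT_L$, and times in the Brownian
time $\tau_{Br} = \sigma^2\gamma/k_BT_L$ (one LJ time unit at the default
$\gamma = T_L = 1$).  `map_units()` converts to physical units through
$\tau_{Br} = 3\pi\eta\sigma^3/k_BT$; at $\sigma = 30$ nm, $\eta = 150$ cP
and 300 K this gives about 9 ms, so the reference recolouring interval
$\tau_R = 10^3\,\tau_{Br}$ is roughly 10 s.

```{r units}
map_units(30, 150, 300)
```

### Normalisation of the pair potential

The attractive channel is normalised so that its minimum equals
$-\varepsilon$ exactly: the shifted bracket is divided by
$4\,|\text{bracket minimum}|$.  For the WCA channel the bracket minimum is
zero, so the conventional WCA normalisation (prefactor
$4\,\epsilon_{ab}$ with $\epsilon_{ab} = 1\,k_BT_L$) is used; its value at
contact ($x = \sigma$) is then $1\,k_BT_L$.  This makes $\varepsilon$ the
literal bond energy of a like-colour contact, which is the convention in
which the phase behaviour of this model family is usually quoted.

### Bending convention

The Kratky–Porod term is implemented as $l_p(1 - \cos\theta)/\sigma$ with
$\theta$ the angle between consecutive tangent vectors, so that a straight
chain costs nothing and a hairpin costs $2l_p/\sigma$.  (Taken literally,
the $(1 + \cos\theta)$ form sometimes printed for this term would make the
straight chain the energy *maximum*, which contradicts the role of $l_p$ as
a persistence length; the package fixes the sign so the straight chain is
the minimum and verifies this property in its tests.)

### Integration

The Langevin equation is integrated with the BAOAB splitting of velocity
Verlet: deterministic half-kicks and half-drifts around an exact
Ornstein–Uhlenbeck step for the friction + noise.  The default timestep
$dt = 0.01$ is stable for the stiffest force-field term ($\kappa = 100$)
and reproduces the target temperature and the free-bead Einstein relation
$D = k_BT_L/\gamma$ to within the statistical accuracy asserted in the test
suite.  The engine RNG is a counter-seeded xoshiro256++; the thermal and
recolouring streams are decorrelated substreams of the replica seed, so a
run is bit-reproducible from its config and seed.

## Simulation protocol

`run_simulation()` follows the flooding protocol: the chain (straight,
compact, or with knots tied in) is first equilibrated under the stretching
force with *all* pair cutoffs lowered to $2^{1/6}\sigma$ (no proteins in
solution: purely repulsive, colour-blind interactions, no recolouring).  At
$t = 0$ the system is flooded: colour attractions and recolouring switch
on, and the production phase records frames of positions and colours.  All
colours start unmarked by default (a naive fibre); grey beads lack any
attraction, so the first sweeps colour the fibre almost freely and the
competition between red and blue then unfolds under the 3D feedback.

## Tying knots

`tie_knot()` splices a parametric knotted curve — $(2,3)$ and $(2,5)$ torus
curves for $3_1$ and $5_1$, the standard figure-eight space curve for
$4_1$ — into the interior of a straight chain.  The closed curve is opened
on its outer equator; short straight tails are grown *radially outward*
from the opening before the chord is aligned with the stretching axis, so
the flanks approach the knot from outside its body (plain linear ramps can
thread a loop of the figure-eight and silently change the topology — the
radial tails make the splice topology-safe).  The open curve is
arc-length-resampled so consecutive beads sit about one bond length apart,
and the builder verifies bond lengths and the absence of overlaps below
$0.8\sigma$.  Composite chains (e.g. $5_1$ at one third, $3_1$ at two
thirds) are built by applying `tie_knot()` twice on disjoint extents.

## Analysis suite

* **Order parameters.** `magnetisation()` ($m = |n_{red} - n_{blue}|/L$),
  `radius_of_gyration()`, per-frame series and steady-state averages
  ($\langle R_g \rangle \equiv \langle R_g^2\rangle^{1/2}$, time-averaged
  over the final window — 20% of frames by default — then replica-averaged).
* **Kymographs.**  The frames × beads colour matrix, written as TSV.
* **Domains and boundaries.**  A domain is the union of all windows of at
  least `w_min` = 50 beads in which one colour exceeds $\theta$ = 90%;
  overlapping claims by different colours are cut where the combined purity
  is maximal, so clean blocks split exactly at their interface.  A boundary
  requires adjacent red/blue domains with signed magnetisations differing
  by more than $2\theta$ and sits at the interface midpoint (half-integer
  positions).  Boundaries are linked frame-to-frame by nearest-neighbour
  matching with a 10-bead jump gate; tracks closer than `w_min/2` terminate
  (merge events).  The time-averaged MSD
  $\delta^2x(t)$ and the diffusion coefficient
  $D = \lim_{t\to\infty}\delta^2x/2t$ (half the least-squares slope over
  lags in 10–50% of the track duration) quantify boundary motion.
* **Knot localisation.**  A sub-arc is closed into a ring by one of two
  deterministic schemes: prolonging both ends along the arc's end-to-end
  axis and reconnecting far outside (robust for stretched chains), or
  through a single point far along the outward bisector (for compact arcs).
  Rings are simplified by triangle elimination before the Alexander
  determinants $|\Delta(-1)|$, $|\Delta(-2)|$ are computed from a generic
  projection's crossing matrix (degenerate projections are retried under a
  deterministic rotation sequence).  The odd part of $|\Delta(-2)|$ removes
  the power-of-$t$ normalisation ambiguity and separates $4_1$ (11) from
  $5_1$ (31).  `minimal_knotted_arc()` shrinks the arc from both ends by
  bisection — always against the already-tightened opposite end, and
  demanding *consensus of both closure schemes*, because a closure path can
  spuriously re-complete a cut knot when the opposite tail is long — and
  finishes with single-bead tightening.
* **Solitons.**  `soliton_profile()` computes the time-averaged local
  coherence $\bar m(x)$ at offset $x$ from the arc centre $c_K$: the signed
  magnetisation in an 11-bead sliding window is averaged within each
  inter-switch time window, its magnitude taken afterwards so that red and
  blue epochs do not cancel, and windows are combined with frame-count
  weights.  Switches are sign flips of the knot-arc signed magnetisation
  through a $\mp 0.5$ hysteresis band.  `soliton_dynamics()` applies the
  boundary-MSD machinery to $c_K(t)$, after two tracking-noise corrections:
  frames whose detected arc exceeds 60 beads (transient delocalisation,
  roughly three times the tight-arc length — the centre of a momentarily
  inflated arc does not track the soliton) have $c_K$ linearly
  interpolated from flanking frames, and a 5-frame median filter removes
  isolated detection jumps.  Neither correction biases the long-time MSD
  slope; MSD fits weight each lag by its number of averaged start-time
  pairs.

## Scaled-down study conditions

The reference conditions of the model ($L = 1000$, runtime
$5\times10^6\,\tau_{Br}$, $\tau_R = 10^3\,\tau_{Br}$) are far beyond a
desktop test budget, so the package's own studies (tests and the
acceptance script) use scaled-down conditions chosen once:

* *Phase transition*: $L = 100$, $\varepsilon = 2$, four replicas of
  $3\times10^5$ steps ($3\times10^3\,\tau_{Br}$) per force, force grid
  $f \in \{0.25, 1, 4, 8\}\,k_BT_L/\sigma$ bracketing the expected critical
  force, $\tau_R = 10\,\tau_{Br}$ (the fast-writer limit: recolouring still
  much slower than the timestep and slower than bead-scale diffusion, but
  fast enough that ordering completes within the run).
* *Homopolymer scaling*: frozen all-red chains, $L \in \{50, 100, 200\}$,
  $\varepsilon = 2$, $f = 0$ from compact initial conditions (globule
  branch) and $f = 10$ from straight ones (stretched branch).
* *Boundary diffusion*: $L = 200$, $f = 1$, $\varepsilon \in \{3, 4, 5\}$,
  random initial colours, $\tau_R = 10\,\tau_{Br}$ — the regime where this
  scaled system shows long-lived multi-domain states.  (At large forces and
  affinities the scaled system collapses into a single mixed globule
  instead of the quasi-one-dimensional pearl chain, so boundaries are
  studied at moderate force.)
* *Knotted solitons*: $L = 200$, $4_1$ knot, $f = 1.25$, $\varepsilon = 1$,
  $\tau_R = 200\,\tau_{Br}$, runtime $1.2\times10^4\,\tau_{Br}$, two seeds.  Local
  coherence inside the knot strengthens with the recolouring/diffusion
  time-scale separation, so the soliton study uses the largest $\tau_R$
  that keeps two seeds within the test budget.

What passing tests under these conditions do show: the machinery of the
model (potentials, integrator, recolouring, detection algorithms) is
correct against independent oracles, the scaled system crosses an abrupt
ordering transition, boundaries diffuse with an $\varepsilon$-suppressed
mobility, and a knotted arc localises epigenetic order and diffuses with an
$\varepsilon$-insensitive mobility.  What they do not show: quantitative
phase boundaries or diffusion constants of the reference-scale system
($L = 1000$, $\tau_R = 10^3$), finite-size scaling, or any property of real
chromatin beyond the model's assumptions (implicit, saturating proteins;
three colours; no explicit nucleosome structure, insulators or
out-of-equilibrium writing).

## Numerical choices and degenerate inputs

* Pair overlaps below $0.3\sigma$ are clamped in the engine so a
  pathological initial condition produces a large finite force rather than
  an overflow; the integrator aborts with a diagnostic if positions become
  non-finite.
* Verlet neighbour lists use a $0.4\sigma$ skin and rebuild when the two
  largest displacements could reach it; results are identical to the
  brute-force double loop (asserted in tests).
* Knot invariants: projections are declared degenerate on near-tangencies,
  near-parallel overlaps or coincident crossing heights and retried under
  golden-angle rotations (up to 40); collinear *disjoint* projected
  segments (ubiquitous in stretched chains) are accepted.  Rings with two
  or fewer crossings are unknots by construction.  $|\Delta(-2)|$ values
  too large to round exactly in doubles fall back to classification by
  $|\Delta(-1)|$ alone.
* Domain detection on strings shorter than `w_min` errors; empty domain
  lists and frames without boundaries are legitimate outputs
  (`link_boundaries` simply opens no tracks).
* `diffusion_coefficient()` refuses fewer than 10 lags in its fit window
  and flags non-diffusive MSDs (log-log slope outside $[0.8, 1.2]$)
  while still reporting D.

## Known limitations

* The minimal-arc search assumes the knot type is stable until the arc is
  cut into the core; on marginal frames the two closure schemes can
  disagree and the search then reports a conservative (larger) arc or none.
* The detected minimal arc is the topological core of the knot; the
  epigenetically ordered region around a knotted soliton is systematically
  broader (roughly twice the core length under the scaled conditions), so
  per-frame overlap measures between the two are bounded well below 1.
* Multi-domain ("pearl necklace") conformations at strong force and strong
  affinity, as well as the $T_R \neq T_L$ out-of-equilibrium regime, are
  outside the scaled studies; the $T_R$ parameter exists but no
  out-of-equilibrium phenomenology is asserted.
* Replica parallelism is not built in; sweeps run serially.
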