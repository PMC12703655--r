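---
title: "Selectivity-filter occupancy and permeation analysis with PoreFlux"
author: "PoreFlux authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selectivity-filter occupancy and permeation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PoreFlux)
```

## Scope

PoreFlux post-processes simulation trajectories of tetrameric K⁺-channel
pores of the MthK type: a TVGYG selectivity filter (SF, residues T59–G63),
a water-filled cavity below it, and, further toward the intracellular
side, a phenylalanine ring (F87), two glutamate rings (E92, E96) and the
lower gate (F97). The questions it answers are the ones asked of
voltage-biased simulations of such channels: which SF sites are occupied
and by what; how occupancy statistics change when a divalent cation is
bound below the filter; how many complete permeation events occurred and
what single-channel current they correspond to; and how ion densities,
gate distances and per-residue flexibility behave along the trajectory.

Because production molecular dynamics is upstream of this package, it
also ships a kinetic Monte Carlo generator that produces desk-scale
trajectories with the same statistical structure — single-file
voltage-biased hopping, a voltage-dependent Ca²⁺ block below the SF —
together with exact ground truth, so every stage of the analysis can be
validated against known answers.

## Pore geometry and site conventions

All geometry is recomputed independently on every frame; nothing is
smoothed across frames.

* **Axis.** The instantaneous pore axis is the principal axis (leading
  eigenvector of the coordinate covariance) of the twenty SF backbone
  carbonyl oxygens, signed so that the Y62 ring lies extracellular of the
  T59 ring. This is robust to rigid-body tilt and needs no global
  alignment.
* **Reference zero.** The centroid of the four T59 carbonyl oxygens. All
  axial coordinates, site boundaries and density profiles are reported
  relative to it.
* **Site boundaries.** Each oxygen ring contributes one boundary plane at
  the mean axial position of its four symmetry-equivalent oxygens. The
  canonical eight-fold coordination cages then are
  S1 = [G61-O, Y62-O], S2 = [V60-O, G61-O], S3 = [T59-O, V60-O],
  S4 = [T59-OG1, T59-O], with the cavity site
  Scav = [F87 plane, T59-OG1]. The S4 lower bound uses the threonine
  side-chain hydroxyl ring, the standard K-channel convention. The S0
  cage above S1 is not scored. If a frame's planes are out of order the
  condition is reported (warning plus a refused geometry object), never
  silently reordered.
* **F87 site.** The Ca²⁺ region below the cavity: the Scav axial slab
  with a wider radial cutoff (5.0 Å from the axis, against 3.5 Å for SF
  sites). The F87 plane itself is the mean axial position of the
  per-chain F87 ring centroids.
* **E92 site.** A contact criterion — any position within 4.5 Å of an E92
  carboxylate oxygen — rather than an axial slab, because density at a
  glutamate ring is broad and conformationally heterogeneous.

All cutoffs are configuration keys; the defaults above were chosen so
that coordinated ions are accepted and cavity bystanders rejected.

## Site assignment and state strings

A particle occupies an SF site when its axial coordinate falls inside
the site interval and its radial distance from the axis is below the
cutoff; water is represented by its oxygen, ammonium by its nitrogen.
Assignment is geometric and memoryless — hysteresis belongs to event
detection, not to occupancy statistics. Two deterministic tie-breaks:
an axial coordinate exactly on a boundary plane belongs to the site
above (extracellular side), and when two particles satisfy one site the
one nearer the interval midpoint is the occupant while the rest are
recorded as extra occupants (on single-file generator data the extras
list is provably always empty, and the tests assert that).

The SF state string is the 4-letter code over S1..S4 with K = K⁺,
N = NH₄⁺, W = water, O = empty (an unexpected species renders as X);
Scav is reported separately and excluded from the code. Frames are
conditioned on *Ca²⁺ bound below the SF* using the F87-site flag only: a
Ca²⁺ ion at the E92 ring does not block the pore and does not set the
label. No dwell-time filter is applied to the flag; transient visits
count for exactly the frames they span.

## Permeation events and currents

Event detection uses three compartments along the axis: INTRA below the
F87 plane, FILTER between the F87 and G63 planes, EXTRA above the G63
plane. An outward event is the ordered visit INTRA → FILTER → EXTRA by
one ion without returning to INTRA in between; inward is the mirror;
incomplete excursions count nothing. The compartment boundaries span the
whole pore (not merely the SF) so that counted events are full transits,
insensitive to intra-filter shuttling.

Periodic boundaries are handled by flagging any per-frame axial
displacement larger than half the box as a wrap: the ion moved through
the bulk across the box boundary, so a transit in progress is abandoned
and, if the ion lands inside the filter compartment, its origin is
unknown and nothing is credited until it next reaches a bulk
compartment. This prevents phantom events without resetting compartments
spuriously. No minimum dwell time is imposed in the bulk compartments;
the hysteresis that keeps rattling from being counted comes entirely
from requiring a full three-compartment traversal.

The current is `I = (n_out − n_in)·e / T`, reported in pA with positive
sign for net outward flow, and the applied-field voltage convention is
`V = E_z · L_z` with positive voltage driving cations outward. The
rectification ratio is `|I(−V)| / |I(+V)|`; a perfect inward rectifier
(zero outward current) is flagged as infinite rather than silently
dropped.

## Profiles, gate and flexibility

Axial density profiles histogram, per frame, the particles of each
species inside a cylinder around the instantaneous axis (default radius
8 Å, range −25 … +5 Å relative to T59 — wide enough to cover Scav, F87
and E92; bin width 0.5 Å resolves a sharp F87 peak against a broad E92
peak). Since the bar-plot normalisation of such figures is not uniquely
defined, both raw counts and per-frame means are emitted. Gate opening
is measured as the two cross-pore diagonals between opposing F97 Cα
atoms (chains 1–3 and 2–4) plus their mean. RMSD/RMSF use rigid-body
superposition (via bio3d's Kabsch fit) onto a fit selection, RMSD over a
measurement selection, and RMSF as the per-atom RMS deviation from the
time-averaged fitted structure, aggregated per residue; the identity
RMSD is exactly zero and both metrics are invariant to global rigid-body
motion, which the test suite asserts.

## The kinetic generator

`simulateTrajectory()` runs a continuous-time Markov chain (exact
stochastic simulation, direct method, with the per-pattern move sets
memoised for speed) on a single-file ladder:

```
bulk_in — [E92] — [F87] — Scav — S4 — S3 — S2 — S1 — bulk_out
```

K⁺ and NH₄⁺ hop along bulk_in–Scav–S4–S3–S2–S1–bulk_out under
at-most-one-ion-per-site exclusion, plus a slow bulk_in ↔ bulk_out
exchange representing diffusion around the periodic box. Ca²⁺ binds two
sites in parallel from the intracellular bulk: E92 (voltage-independent)
and F87, whose on-rate carries the voltage factor
`exp(q·V·δ_Ca / 2kT)` with q = 2 (the off-rate can optionally carry the
inverse factor; by default the voltage dependence is assigned entirely
to binding, since the two are not separable from occupancy data alone).
kT corresponds to 310 K.

Rates follow a symmetric Arrhenius split,
`k = ν · exp(−ΔU/2) · exp(±q·V·δ/2kT)`, where `U` sums per-site free
energies of occupied sites, a nearest-neighbour pair penalty W inside
the SF, and the interaction between an F87-bound Ca²⁺ and pore ions.
Each of the four intra-filter hops carries the same fractional
electrical distance δ (default 1/6); the two boundary hops split the
remainder so the total transmembrane drop is always 1. The bulk
exchange is electrically silent, which closes the thermodynamic cycle
at `q·V` per transit — the applied-field convention.

Two ingredients implement the check-valve:

* **Block.** While a Ca²⁺ ion is seated at F87, the bulk_in ↔ Scav
  passage is closed in both directions: the ball sits in the permeation
  pathway below the cavity. Outward conduction requires that passage, so
  it stops when the ball is seated; at negative voltage the ball is
  essentially never seated, so inward conduction is untouched.
* **Coupling.** The F87-bound Ca²⁺ interacts with pore ions
  (`caCoupling`, kT per site), and the same energies feed back into the
  Ca²⁺ on/off rates, so an ion arriving in the cavity on the inward path
  actively unseats the ball — the check-valve opens under inward flow
  without any ad hoc rule.

### Calibration of the defaults

The defaults are the study conditions, fixed once against the exact
stationary solution (`stationaryOccupancy()`, below) to reproduce the
qualitative occupancy phenomenology reported for voltage-biased
simulations of this channel: KOKO as the dominant Ca-free state at
negative and zero voltage, S2 occupancy growing with positive voltage,
very little F87 Ca²⁺ binding at −300 mV rising monotonically to
near-certain binding at +300 mV, and — conditioning on Ca-bound frames
at 0 mV — the dominant state shifting from KOKO to KKOK.

Two calibration choices deserve a note. First, site energies make S1 and
S3 the deep wells (−3.2 kT) with shallower S2, S4 and Scav, which fixes
KOKO as the equilibrium ground state; the pair penalty W = 2 kT keeps
adjacent-ion states transport intermediates rather than resting states.
Second, the Ca–ion coupling is *not* a monotone function of distance: at
0 mV the chain satisfies detailed balance, so the conditional state
distribution on Ca-bound frames is exactly the Boltzmann reweighting of
the free one by the coupling energies — a monotone repulsion can then
only suppress S4-containing states and provably cannot move weight from
KOKO (S1·S3) to KKOK (S1·S2·S4). Reproducing the reported conditional
shift therefore requires an effective interaction that penalises the
cavity site strongly (+3 kT at Scav, which also powers the unseating
feedback) but mildly stabilises S4 and S2 while penalising S3. We treat
this as an empirical effective free-energy shift of the filter
configurations in the field of the bound ion — calibrated against the
reported conditional occupancies, not derived from Coulomb's law — and
it is exposed as an ordinary parameter vector for sensitivity analysis.

Particle counts default to 4 K⁺, 2 Ca²⁺, 2 Cl⁻ and 4 waters in a 60 Å
box — ion numbers typical of the small simulation boxes this emulates.
Water never enters S1–S4 by default; a `waterSfRate` parameter enables
transient visits to the outer sites (S1, S4) only, mirroring the
observation that water only transiently occupies the outer cages.

### Ground truth and its frame resolution

The generator logs per-frame true site occupants, state strings and
Ca-binding flags, and a permeation event log. The event log is
*frame-resolved*: it lists the complete transits observable at the
sampling interval, computed from the true (jitter-free) coordinates by
an independent compartment scan, so that a correct analysis of the
emitted coordinates must recover it exactly at zero jitter. Transits
faster than one frame interval cannot appear in any sampled trajectory;
they are counted separately in the exact continuous-time totals
(`nOutwardExact`, `nInwardExact`). At the default sampling interval
(0.2 ns) and hop rates the two differ by a few percent at most.

### The exact stationary oracle

`stationaryOccupancy()` enumerates the complete exclusion state space
(species-resolved site occupancy, pool splits, Ca flags — a few hundred
states at the defaults, with a hard cap), builds the generator matrix
from the same rate law, and solves the global balance equations
directly. It shares no sampling code with the simulator, so agreement
between long-run empirical occupancies and the exact solution (asserted
to within three standard errors, with autocorrelation handled by block
means over 500 ns blocks) validates both the simulator and the
assignment pipeline. It also yields the exact conditional state
distributions used for calibration.

## What the synthetic data do and do not emulate

The generator reproduces the statistical structure the analysis relies
on: single-file site occupancy with exclusion, voltage-biased hopping
with complete transits in both directions, a voltage-dependent blocker
below the filter, periodic-boundary recycling (bulk exchanges appear as
coordinate wraps larger than half the box), Gaussian positional jitter,
and a rigid protein scaffold whose rings define the same geometry the
analysis measures. It does **not** emulate conformational dynamics of
the protein (the scaffold is rigid apart from jitter), explicit water,
sub-site ion positions within a cage, correlated multi-ion "knock-on"
moves (ions hop one site at a time), or absolute molecular-dynamics
currents — generator currents are set by the chosen rates, so only
ratios and directional effects are meaningful. Passing tests therefore
demonstrate correctness of the measurement pipeline and qualitative
mechanism reproduction, not quantitative agreement with any particular
force field.

## Numerical choices

* Boundary ties in site assignment resolve extracellularly; midpoint
  ties between two candidates resolve by particle id — both are
  measure-zero but keep runs bit-reproducible.
* Normalisation invariants (site fractions and state frequencies sum to
  1) are enforced to 1e−9 by class validity; density mass conservation
  is tested to 1e−9; rigid-body invariance of site geometry to 1e−6 Å.
* Seeded generator runs are bit-reproducible; the pipeline embeds no
  timestamps, so identical configs and seeds give byte-identical
  reports.
* Test problem sizes: 1000 randomized frames for the assignment oracle,
  800 ns trajectories for ground-truth recovery, one 10⁵ ns run for
  stationary recovery (≈5·10⁵ frames), ten paired 1000 ns runs per
  voltage for the mechanism checks — sizes at which the assertions'
  statistical margins are comfortable on a laptop-class machine.
* An empty filter, an empty system and a zero-frame condition are all
  legal inputs with defined outputs; zero frames *overall* and a zero
  total rate with mobile particles are errors.

## Limitations

The analysis assumes an approximately four-fold channel whose SF oxygen
rings exist in at least three chains; heavily distorted filters will
trip the plane-ordering report rather than being scored. Gate diagonals
assume the chain order encodes opposition (1–3, 2–4). The kinetic model
is a coarse single-file ladder: it has no sub-site structure, no
concerted moves, and an effective (calibrated, non-monotone) Ca–ion
coupling; its currents are not predictions. Trajectory I/O is
multi-model PDB (mandatory) or DCD plus a PDB topology; very large
trajectories should be analysed in chunks as the coordinate array is
held in memory.
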