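---
title: "Models and estimators behind hairpinREX"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators behind hairpinREX}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hairpinREX)
```

`hairpinREX` studies how loop flexibility and native-contact strength set
the folding cooperativity of the GB1p-series β-hairpins.  This vignette is
the package's own account of the models it samples, the estimators it
applies, and the design decisions taken where more than one reasonable
choice existed.  Every number quoted here is computed by the test suite or
by `scripts/acceptance.R`; nothing is asserted that the code does not
itself produce.

## The bead-level hairpin

Each 16-residue hairpin is represented by one CA bead per residue plus
*surrogate* beads that are rigid functions of the local backbone: a
carbonyl-O and amide-HN bead for interior residues (2–15), placed 1.9 Å
along the in-plane bisector of the chain at each residue with a ±0.5 Å
offset along the chain tangent, and a single SC bead 2.0 Å along the local
chain normal for the four contact residues (positions 3, 14, 5, 12 — the
Trp43–Val54 and Tyr45–Phe52 homologs).  Because the zigzag of a CA trace
alternates the sign of the local normal, SC beads alternate sides of the
strand exactly as a β-pleat does.

The point of the surrogates is that the *literal* distance criteria of the
analysis apply unchanged to coarse-grained and atomistic input alike:

* a native backbone H-bond counts when the donor-HN to acceptor-O distance
  is ≤ 2.6 Å (inclusive), over the 7-pair registry shared by all three
  peptides;
* a sidechain contact counts when the minimum inter-group distance is
  ≤ 6.5 Å for the single-bead sidechains.  For atomistic input with
  multi-atom sidechain groups the corresponding heavy-atom criterion is
  4.2 Å, and `countSidechainContacts()` accepts any cutoff;
* helicity is the mean frequency of O(i)···HN(i+4) distances ≤ 2.6 Å over
  all eligible pairs.

The folded reference (`buildNativeFixture()`) is an idealized two-strand
construction refined by a deterministic penalty minimization until every
registry pair satisfies the 2.6 Å criterion and both sidechain pairs are
in contact, with 3.8 Å CA–CA bonds and no excluded-volume violations.  It
supplies the native bonded geometry of the energy function and the folded
reference for tests.

## The coarse-grained potential

The CG energy is Go-like, with five reported components
(`bonded`, `excluded_volume`, `hbond_contact`, `sidechain_contact`,
`screened_charge`; their sum is the total, exactly):

* **bonded** — stiff bonds (k = 50 kcal/mol/Å², r₀ = 3.8 Å); angle terms
  referenced to the native fixture (k = 1.2 kcal/mol/rad² in the shipped
  presets); a native-referenced dihedral across the loop.  The
  loop-stiffness multiplier λ_loop scales the angle and dihedral terms of
  the loop segment proper (residues 7–10): λ_loop ≪ 1 emulates the
  flexible `-DATK-` loop, λ_loop > 1 the proline-rigidified `-PATG-` turn,
  which is rigid *in the turn geometry* (the native reference), i.e.
  pre-organized.
* **excluded_volume** — a soft quadratic wall below σ = 3.4 Å for CA pairs
  separated by ≥ 3 residues; finite at zero distance, so overlapping beads
  yield a large but numeric energy, never NaN.
* **hbond_contact** — a well of depth ε_hb on each registry pair, flat up
  to the 2.6 Å counting cutoff and switched smoothly to zero over
  `hbWidth`.  On top of the per-bond wells sits a nearest-neighbour
  cooperativity term: each *consecutively formed* pair of registry bonds,
  in zipper order from the turn outward, contributes an extra −`hbCoop`.
  This pairwise coupling is the standard statistical-mechanics lever for
  two-state behaviour in hairpin models: without it the per-bond
  free-energy cost and gain are nearly uniform in N_HB, the profile
  F(N_HB) is zipper-linear, and no parameter choice produces a barrier.
  With it, stabilization concentrates in fully zipped states.  `hbCoop`
  defaults to 0; at ε_hb = ε_sc = 0 the total reduces to
  bonded + excluded volume.
* **sidechain_contact** — wells of depth ε_sc on the two native pairs,
  flat only out to `scPlateau` = 4.6 Å (just above the native 4.4 Å
  separation) and switched off over `scWidth`.  Keeping the energy plateau
  *inside* the 6.5 Å counting cutoff matters: if loosely collapsed states
  collect full contact energy, they pre-pay the loop-ordering entropy and
  the folding barrier disappears.
* **screened_charge** — an optional Debye-screened Coulomb term over the
  sidechain formal charges (K/R +1, D/E −1); disabled (prefactor 0) in all
  shipped presets.

Moves are single-bead displacements, crankshaft rotations of one interior
bead, and rigid pivots of everything on one side of a residue, each with
uniform symmetric amplitudes, so plain Metropolis acceptance is valid.
One sweep is 16 attempted moves with full energy re-evaluation in the
compiled kernel.

### Preset calibration

The three shipped presets were calibrated — as the package's own design
step, since no reference CG parameters exist for these peptides — against
the qualitative regime targets at 270 K under 270–450 K replica exchange,
and verified on four independent master seeds before being frozen into
`inst/extdata/presets.yaml`:

| preset | ε_hb | ε_sc | λ_loop | hbCoop | regime at 270 K |
|---|---|---|---|---|---|
| GB1p-like  | 0.35 | 2.0  | 0.05 | 0.78 | two-state, folded favoured (P_f ≈ 0.6), barrier ≈ 1.2–1.4 kT |
| HP5A-like  | 0.33 | 0.55 | 1.5  | 0.93 | two-state, marginally stable (P_f ≈ 0.4), barrier ≈ 1.1–1.3 kT |
| GB1m3-like | 0.50 | 2.4 | 2.5  | 0.80 | folded-dominated, downhill (P_f ≈ 0.85, no barrier) |

The folded-population order GB1m3-like > GB1p-like > HP5A-like mirrors
the experimental stability series of the peptides.  The reduced-unit
zipper presets encode the same physics analytically: the flexible-loop
preset carries much larger degeneracy at N = 0–1 (loop entropy), the
rigid-loop presets share one degeneracy profile and differ in ε.

## The zipper oracle

The zipper model is the package's exactly solvable stand-in: microstate
N ∈ {0..7} is the number of native H-bonds formed, level energy is −Nε,
level weight Ω(N)·exp(βNε).  `zipperExact()` returns Z, the populations,
and the *same estimators the ensemble analysis uses* (P_f = Σ_{N≥4},
P_u = Σ_{N≤1}, ΔG, ΔU, ΔS), which makes every stochastic claim of the
sampling and analysis machinery checkable against a closed form.  The
sampler proposes ±1 steps *within the ordered support of Ω* (levels with
Ω > 0), reflecting at the ends by proposal rejection, and accepts on the
level-energy difference and degeneracy ratio.  Restricting proposals to
the support is deliberate: the two-level model used for oracle tests
(Ω = [g, 0, …, 0, 1]) has zero-degeneracy interior levels that a literal
±1 walk could never cross, while the support walk reduces exactly to ±1
when all Ω > 0.  For that model T_m = E0/(kB ln g) in closed form.

## Replica exchange

Temperatures follow the exponential ladder
T_k = T_min (T_max/T_min)^{k/(n−1)} with exact endpoints.  Each
temperature slot runs an independent Metropolis chain; every
`exchangeInterval` sweeps, neighbouring slots attempt a temperature swap
with p = min(1, exp[(β_i − β_j)(U_i − U_j)]), and attempt blocks
alternate the even- and odd-indexed disjoint neighbour pairings so every
pair is tried in turn.  The replica→temperature assignment is a
permutation at every sweep (class validity enforces it), frames carry both
the replica id and the slot temperature, and the per-temperature streams
are therefore demultiplexed by construction.

Sweeps between exchange attempts play the role that fixed-length dynamics
segments play in a molecular-dynamics REX protocol; Monte Carlo was chosen
because its canonical statistics are exactly testable (harmonic ⟨x²⟩,
canonical-averaged exchange acceptance, zipper populations).

**Seeding.**  The master seed spawns one L'Ecuyer-CMRG stream per replica
plus one for exchange decisions.  Streams travel with the replica, not the
temperature slot, so results are independent of loop order and the whole
run — record, observables, snapshots — is bit-reproducible from the seed.
The caller's RNG state is saved and restored.

**Production window.**  Analyses use the trailing fraction of sweeps
(default 0.6), the Monte Carlo analogue of discarding the first part of a
long simulation as equilibration; it is configurable everywhere.

## Thermodynamic estimators

Frames are folded when N_HB ≥ 4, unfolded when N_HB ≤ 1; frames at
N_HB ∈ {2, 3} are intermediate and enter neither population (populations
are fractions of *all* production frames, so P_f + P_u ≤ 1).  Then

* ΔG = −kB·T·ln(P_f/P_u),
* ΔU = ⟨U⟩_folded − ⟨U⟩_unfolded, for the total and every component,
* ΔS = (ΔU − ΔG)/T, reported in cal/mol/K in physical mode (kB = R =
  1.987204×10⁻³ kcal/mol/K) and unscaled in reduced mode (kB = 1).

ΔS is constructed from ΔU and ΔG, so the identity ΔS·T = ΔU − ΔG holds
exactly in every result row.  When the unfolded state has fewer than
`unfoldedFloor` (default 10) production frames, the temperature switches
to *folded-dominated* mode: P_u is set to 1 − P_f, ΔG comes from the
folded fraction, and ΔU/ΔS are reported as NA rather than estimated from
a near-empty sub-ensemble.  The symmetric unfolded-dominated case is
handled the same way.

T_m is the temperature where P_f = P_u: an exact ladder hit returns that
temperature; otherwise ΔG(T) is interpolated linearly between the
bracketing ladder temperatures (falling back to P_f − P_u where ΔG is
undefined at a bracket end); with no crossing a bound (`"<Tmin"`,
`">Tmax"`) is reported, the honest answer when a peptide never folds or
never unfolds inside the ladder.  Multiple crossings return the lowest
with a warning.

Standard errors are half-split: each estimator is recomputed on the first
and second halves of the production stream (by sweep order) and
SE = |half₁ − half₂|/2.  This is the simplest reading of a
difference-of-halves error; when an estimator is undefined on a half the
SE is NA, never silently zero.

## Landscapes

Free-energy profiles are F = −kT ln p from histograms: unit bins centred
on integers for discrete coordinates (N_HB, N_SC), 0.5 Å bins for
distances, range/50 bins for PC scores.  The lowest *populated* bin is
shifted to exactly 0; empty bins are masked, never zero-filled, and never
enter the minimum; contour levels are integer multiples of kT.

Two barrier summaries exist: `profileBarrier()` (saddle between the two
deepest local minima) and `twoStateBarrier()`, which measures the highest
bin strictly between the unfolded-basin minimum (N_HB ≤ 1) and the
folded-basin minimum (N_HB ≥ 4) above the shallower of the two, clipped
at 0.  The latter is the cooperativity diagnostic used in the acceptance
checks, because it is robust to small intermediate dips (a rigid
pre-organized loop genuinely populates turn-formed states around
N_HB ≈ 3).

The minimal-energy path across a 2D surface is defined here as the
*bottleneck-optimal* path: over 8-connected moves through unmasked bins it
minimizes the maximum F encountered, with ties broken by the smaller
total F along the path and then lexicographically on the bin sequence, so
the result is deterministic.  This is one reasonable formalization of a
"minimal energy path" drawn through a folding surface; tests verify it
against exhaustive threshold enumeration and an independent shortest-path
implementation.

Joint PCA pools the CA traces of one or more peptides sampled at one
temperature, superposes every frame on the pooled mean (Kabsch, proper
rotations only; two align→re-mean iterations after an initial alignment to
the first frame — the reference structure is a free choice and the pooled
mean makes the two-peptide comparison symmetric), diagonalizes the
covariance of the flattened coordinates and keeps the top two components.
Component signs are canonicalized (positive third moment of the scores) so
rigidly transformed inputs give identical projections, and scores are
snapped to 10⁻⁹ before binning so round-off cannot flip edge samples
between bins.

## What the synthetic data do and do not show

The CG model emulates: the native contact topology and registry of the
three hairpins, the loop-flexibility contrast between `-DATK-` and
`-PATG-`, tunable contact strengths, two-state vs downhill regimes, and
ensemble demultiplexing across an exponential temperature ladder.  It does
not emulate: atomistic force-field energetics (the per-component ΔU
decomposition here reports the CG terms, not vdW/surface-area/explicit
electrostatic/solvation magnitudes), solvent effects on folding entropy,
or real kinetics.  Passing tests therefore demonstrate that the
*estimators and the sampling engine* are correct and that the regime
phenomenology is reproduced — not that the CG parameters are transferable
to real peptides.  Analyses of externally supplied ensembles (multi-model
PDB + energy sidecar) go through exactly the same metrics and estimators.

## Numerical choices and degenerate inputs

* Distance criteria are inclusive (≤), for the 2.6 Å criterion too.
* Collinear chain segments get a deterministic perpendicular fallback in
  the surrogate-bead framing; coincident bonded beads are an error.
* Exactly overlapping nonbonded beads produce a finite repulsion.
* Problem sizes: the packaged demos and checks use 8 replicas and
  2×10⁴–10⁵ sweeps (zipper), 4×10⁴ sweeps (CG), chosen so every stochastic
  assertion has ≥3σ headroom while a full run of the suite and the
  acceptance script stays in the minutes range on one core.
* Zipper partition sums use log-sum-exp, so low-temperature evaluations do
  not overflow.

## Known limitations

* The half-split SE is a two-sample spread estimate; it is noisy and can
  underestimate the error of slowly mixing observables.  Tests therefore
  floor it where they compare against closed forms.
* `twoStateBarrier()` assumes an integer N_HB axis and the 4/1 threshold
  convention; other reaction coordinates need `profileBarrier()` or an
  explicit basin definition.
* The CG presets are calibrated at the 270 K analysis temperature under
  the packaged ladder; they are regime emulators, not fitted force
  fields.
* Trajectory PDB output stores coordinates at PDB precision (10⁻³ Å);
  energies and metadata round-trip exactly through the sidecar, but
  coordinates only to that precision.
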