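# hairpinREX

Replica-exchange Monte Carlo sampling and two-state folding analysis for
GB1p-series β-hairpin peptides.

## The problem

The 16-residue C-terminal hairpin of the protein G B1 domain (GB1p,
`GEWTYDDATKTFTVTE`, residues 41–56) and two designed variants — HP5A
(`KKYTWNPATGKATVQE`) and GB1m3 (`KKWTYNPATGKFTVQE`), which replace the
flexible `-DATK-` loop with a proline-rigidified `-PATG-` turn and vary the
cross-strand hydrophobic pair strength — span three folding regimes:
marginally stable two-state (HP5A), cooperative two-state (GB1p) and
folded-dominated, essentially downhill (GB1m3).  Studying how loop
entropy and native-contact strength together set folding cooperativity
requires (i) an enhanced-sampling engine that equilibrates all three
systems across temperature, and (ii) a consistent analysis layer that
turns the sampled ensembles into populations, folding thermodynamics and
free-energy landscapes.

`hairpinREX` provides both, at desk scale, for computational biophysicists
who want a fully verifiable version of this workflow:

* **models** — a coarse-grained (CG) bead hairpin with the native 7-pair
  backbone H-bond registry (42NH–55CO, 42CO–55NH, 44NH–53CO, 44CO–53NH,
  46NH–51CO, 46CO–51NH, 47CO–50NH in literature numbering), the two
  native sidechain contacts (Trp43–Val54, Tyr45–Phe52 homologs), tunable
  loop stiffness and contact strengths; plus an exactly solvable zipper
  model used as an analytic oracle.
* **sampling** — single-temperature Metropolis Monte Carlo and temperature
  replica exchange (REX) with exponential ladders
  T_k = T_min (T_max/T_min)^(k/(n−1)) and the detailed-balance swap
  criterion p = min(1, exp[(β_i − β_j)(U_i − U_j)]).
* **metrics** — N_HB (native backbone H-bonds at the 2.6 Å criterion),
  native sidechain contacts, helicity (1–4 H-bond frequency), loop
  (Cα6–Cα11) and end-to-end distances.
* **thermo** — two-state classification (folded N_HB ≥ 4, unfolded
  N_HB ≤ 1), ΔG = −RT ln(P_f/P_u), ΔU from sub-ensemble mean potential
  energies (total and per component), ΔS = (ΔU − ΔG)/T, melting
  temperature T_m where P_f = P_u, all with half-split standard errors;
  a folded-dominated mode sets P_u = 1 − P_f when the unfolded minimum is
  absent.
* **landscapes** — F = −kT ln p profiles and 2D surfaces with kT contour
  levels, bottleneck-optimal minimal-energy paths, Kabsch superposition
  and joint PCA landscapes.
* **interface** — multi-model PDB + TSV-sidecar trajectory I/O, YAML-driven
  `simulate | analyze | report` pipeline stages with manifests
  (`inst/scripts/hairpinrex` is a thin CLI over `runPipeline()`).

## Worked example

Replica exchange on the GB1p-like zipper preset (reduced units, kB = 1),
followed by the full thermodynamic analysis:

```r
library(hairpinREX)

zm  <- zipperPreset("GB1p-like")
run <- runREX(zipperSamplerModel(zm), buildLadder(1.0, 2.5, 8),
              rexConfig(nSweeps = 20000, exchangeInterval = 10, seed = 7))
th  <- analyzeThermo(run)
thermoTable(th)[1, c("temperature", "Pf", "Pu", "dG", "dU", "dS")]
#>   temperature     Pf    Pu     dG    dU     dS
#> 1           1 0.5583 0.403 -0.325 -7.10 -6.777
meltingPoint(th)        # 1.0598  (exact crossing for this preset: 1.0765)
zipperExact(zm, 1)$dG   # -0.504  (closed form at T = 1)
```

The first ladder temperature is below the preset's melting point, so the
folded population leads (P_f = 0.56 vs P_u = 0.40, ΔG < 0); all
quantities agree with the zipper's closed-form values within their
half-split errors, and T_m is recovered to one ladder spacing.

The same machinery runs the structural model — here the cooperative
GB1p-like CG preset at 270–450 K, with the F(N_HB) folding profile at
270 K:

```r
kB  <- gasConstantKcal()
m   <- cgSamplerModel(buildHairpinTopology("GB1p"), cgPreset("GB1p-like"))
run <- runREX(m, buildLadder(270, 450, 8),
              rexConfig(40000, 10, seed = 11, kB = kB))
obs <- productionWindow(run)
sub <- obs[obs$temperature == 270, ]
mean(classifyState(sub$nhb) == "folded")     # 0.67  (folded population)
fe  <- feProfile1D(sub$nhb, kT = kB * 270)
twoStateBarrier(fe)$barrier / (kB * 270)     # 1.27  (barrier in kT)
```

A barrier of ~1.3 kT between the unfolded (N_HB ≤ 1) and folded
(N_HB ≥ 4) basins is the signature of two-state cooperative folding; the
GB1m3-like preset instead gives a downhill profile with no barrier and a
folded population above 0.8.

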