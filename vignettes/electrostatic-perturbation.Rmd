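---
title: "Measuring electrostatic perturbation between holo and apo protein structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring electrostatic perturbation between holo and apo protein structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Ligand or cofactor binding deforms a protein's structure, and with it the
electrostatic field its residues sit in. `eperturb` quantifies that change by
comparing two structures of the same protein — the bound (holo) form $P^h$
and the unbound (apo) form $P^a$ — through *electrostatic potential
differences* (EPDs) between residue pairs.

Each residue $R_i$ is represented by a single **reactive atom** (its
side-chain functional atom: OG for serine, NE2 for histidine, NZ for lysine,
and so on; CB or CA where no polar head exists). With $\mathrm{Pot}(P^x,
R_i)$ the electrostatic potential at that atom, in the dimensionless kT/e
units that continuum solvers emit, the EPD of a pair in one structure is

$$ \mathrm{PD}(P^x, R_i, R_j) \;=\; \mathrm{Pot}(P^x, R_i) - \mathrm{Pot}(P^x, R_j). $$

For each residue, the set $\Phi_i$ of neighbors within a radius $P_{rad}$
(default 6 Å, reactive atom to reactive atom) is computed **on the holo
structure only** and reused for the apo sums, so both sums always range over
the same residues even when binding rearranges the neighborhood. The
per-residue perturbation score is

$$ E_i^{perturb} \;=\; \sum_{j \in \Phi_i} \mathrm{PD}(P^h, R_i, R_j)
   \;-\; \sum_{j \in \Phi_i} \mathrm{PD}(P^a, R_i, R_j), $$

which is invariant under any global offset of either structure's potentials
— only relative, local changes register. A **polarity reversal** is a
residue pair whose EPD changes sign between the two forms,
$\mathrm{PD}_1 \cdot \mathrm{PD}_2 < 0$, with
$|\mathrm{PD}_1 - \mathrm{PD}_2| \ge P_{thresh}$ (default 150 kT/e). Such
pairs flag qualitative electrostatic rearrangements, e.g. the loss of a
metal-binding site. The same neighbor-sum construction applied to
reactive-atom distances gives a per-residue *spatial deviation*, so
electrostatic and conformational change can be contrasted residue by
residue.

## Inputs and the two potential backends

Structures come as PDB files; residues pair strictly by chain, author
number and insertion code. Point mutations are tolerated up to
`max_mutations` (default 5, enough for the typical single/double-mutant
comparison); insertions or deletions are an error, never silently
realigned — the method compares like with like.

Potentials come from one of two backends:

* **`dx`** — a scalar potential grid in APBS's OpenDX format, typically the
  output of a PDB2PQR + APBS run, queried by trilinear interpolation at the
  reactive atoms. This is the intended production route.
* **`coulomb`** — a built-in screened-Coulomb sum over PQR point charges,
  $\phi(\mathbf{r}) = \frac{k}{\varepsilon}\sum_i q_i e^{-\kappa r_i}/r_i$
  with $k = 561.0$ (the kT/e conversion of $e^2/4\pi\varepsilon_0$Å at
  298 K), uniform dielectric $\varepsilon = 80$ and $\kappa = 0$ by default,
  distances clamped at 0.5 Å. This keeps the pipeline runnable with no
  external solver, but it is emphatically *not* a Poisson–Boltzmann
  replacement: no dielectric boundary, no ionic atmosphere beyond the
  scalar screen.

Absolute EPD values from published Poisson–Boltzmann runs are therefore not
reproducible here without the original solver settings; what this package
can and does validate offline is the arithmetic downstream of the solver
(the bundled `reversal_reference()` pairs), and the full pipeline on
synthetic fields with known closed-form answers.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `radius` ($P_{rad}$) | 6 | Å | neighbor cutoff, holo-defined |
| `reversal_threshold` ($P_{thresh}$) | 150 | kT/e | minimum |PD1 − PD2| for a reversal |
| `viz_threshold` | 200 | kT/e | |E^perturb| above which PyMOL colors a residue |
| `dielectric`, `kappa` | 80, 0 | —, 1/Å | Coulomb backend screening |
| `max_mutations` | 5 | count | tolerated point mutations |

Boundary conventions, decided where the stated method leaves room:
thresholds are inclusive (`>=`), since the published reversal tables retain
pairs printed exactly at round values; the neighbor cutoff is likewise
`<=`. Polarity reversal is tested over **all** residue pairs by default
(published reversal pairs span distant sequence positions), with a
neighbor-pairs mode available. The polar-only mode restricts both centers
and neighbor members to {ASP, GLU, LYS, ARG, HIS, SER, THR, ASN, GLN, TYR,
CYS, TRP} — a choice, overridable, since no canonical list is mandated.
Mutated positions stay in the sums by default (their reactive atoms simply
differ); spatial deviation uses the signed sum-difference transliteration
of the electrostatic construction, with an absolute-value variant as an
option. Residues whose reactive atom falls outside a grid, or that lack a
potential, are dropped on *both* sides of every sum so holo and apo always
see the same neighbor count.

The reactive-atom map itself is a decision: the method's anchor-point idea
requires one atom per residue, but no standard table exists. The default
map takes each side chain's functional atom with a CB→CA fallback (glycine:
CA) and can be replaced wholesale from a plain-text file
(`read_reactive_atom_map()`).

## What the synthetic fixtures emulate — and what they don't

`fixture_spec()`/`make_fixture_pair()` build matched holo/apo inputs with
known geometry (linear chains by default: 10 residues, 5 Å spacing, so each
interior residue has exactly two neighbors at the default radius), PQR
charges on the reactive atoms, and an analytic potential field (constant,
affine, or the Coulomb model itself). An *injected* apo offset at residue
$k$ yields the closed-form expectation
$E_k^{perturb} = -|\Phi_k|\,\delta$ and $+\delta$ at each neighbor; the
generator realizes the offset exactly in both backends (a whole enclosing
grid cell is offset for the DX route; a calibrated extra point charge 1 Å
from the reactive atom for the Coulomb route) and reports per-backend
ground-truth tables. Coordinates are quantized to PDB text precision at
generation time so file round-trips are exact and recovery tests can assert
at 1e-9.

Fixtures exercise parsing, pairing, reactive-atom resolution,
interpolation and all the sums on realistic file formats — but they are
toy geometries with toy charges. A green recovery test establishes that
the machinery computes the stated quantities exactly; it says nothing
about whether a screened-Coulomb potential is an adequate physical model
for a given protein, nor about solver-dependent absolute magnitudes.

## Numerical choices

Trilinear interpolation reproduces affine fields exactly and stays within
the bounds of the eight surrounding nodes; points outside the grid are an
error (no extrapolation), with the upper boundary face counted as inside.
Grids are written at full double precision (`%.16e`), so write/read
round-trips are lossless. The Coulomb sum clamps distances below 0.5 Å,
making potentials total even at atom positions; a residue's own reactive
atom is excluded from the sum at its own position. Ties in altloc
occupancy resolve to the alphabetically first conformer; rank stability in
`radius_sweep()` is Spearman's correlation of $|E^{perturb}|$ between
consecutive radii, reported as `NA` when degenerate (e.g. all-zero
perturbations in a self-comparison).

## A worked example

```{r, eval = FALSE}
library(eperturb)

fix <- make_fixture_pair(fixture_spec(residue_types = "ALA",
                                      injection = c("5" = 300)))
paths <- write_fixture_pair(fix, "fx")

res <- run_pipeline(run_config(
  paths[["holo_pdb"]], paths[["apo_pdb"]], backend = "dx",
  holo_dx = paths[["holo_dx"]], apo_dx = paths[["apo_dx"]],
  out_dir = "fx/out"
))
res
subset(res$perturbation, abs(e_perturb) >= 200,
       select = c(label, e_perturb, neighbor_count))
```

The out directory then holds `perturbation.tsv`, `reversals.tsv` (columns
`residue_a`, `residue_b`, `PD1`, `PD2`, `deltaPD`, one decimal), a
deterministic `perturbation.pml` PyMOL script coloring residues with
$|E^{perturb}| \ge$ threshold red/blue by sign, and `parameters.log` with
every resolved setting.

## Known limitations

The method measures perturbation; it cannot assign mechanism or causality,
and it performs no structure superposition (it never needs a common frame —
only potentials and intra-structure distances). Multimeric entries are
analyzed over all chains unless filtered. The Coulomb backend's uniform
dielectric flattens exactly the solvation physics a Poisson–Boltzmann
solver supplies; treat its absolute numbers as qualitative. Sequence
realignment, homology mapping and nucleic-acid chains are out of scope.
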