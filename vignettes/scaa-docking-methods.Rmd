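---
title: "Simplified-alphabet antigen libraries and restrained rigid-body docking: methods"
author: "scaadock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simplified-alphabet antigen libraries and restrained rigid-body docking: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaadock)
```

This vignette is the package's own account of the models and numerical
choices behind each stage: what is computed, under which assumptions, which
parameters matter, and what the shipped synthetic fixtures can and cannot
demonstrate.

## The chemical model: a six-letter alphabet on a rigid scaffold

Antigen 9-mers bound to MHC-II adopt a conserved extended conformation, and
only the side chains at positions P3, P5 and P8 (counted from the N
terminus) face the TCR's CDR3 loops. The package therefore treats antigen
chemistry as a three-letter word over a reduced alphabet: each of the 20
natural residues is represented by one of six chemical-class exemplars ---
Asp (negative), Gln (polar amide), His (positive), Ser (polar hydroxyl),
Tyr (aromatic), Val (hydrophobic). Compact exemplars are deliberate: short
side chains minimise the rotamer bias a rigid construction would otherwise
bake in. Histidine is modelled doubly N-protonated (+1), consistent with
the mildly acidic extracellular milieu of many immune reactions; the
protonation is carried as metadata and as +0.5 formal charges on the ring
nitrogens.

The mapping is shipped as data (`inst/extdata/scaa_alphabet.csv`), not
code, so alternative alphabets can be substituted. Fourteen of the twenty
assignments are fixed by published reference translations; the remaining
six (C$\to$S, M$\to$V, W$\to$Y, I$\to$V, S$\to$S, H$\to$H, N$\to$Q) follow
the BLOSUM-style class logic of the alphabet and are validated only by
consistency (`validate_scaa_table()` enforces the 20-code domain, the
six-letter codomain and idempotence). Glycine belongs to the hydrophobic
class when it occupies a triad position, but is the inert spacer
everywhere else --- the template projection (`project_to_template()`)
applies the spacer first and translates only triad positions.

Positions are numbered P1..P9 from the N terminus. Because both numbering
conventions appear in the literature, `antigen_template(numbering = "C")`
re-interprets the triad positions from the C terminus.

## Peptide construction

`build_backbone()` performs internal-coordinate chain extension: each atom
is placed from a bond length, bond angle and torsion relative to three
previously placed atoms, with the first residue in a fixed frame (N at the
origin, CA on +x, C in the xy plane). The construction is exact --- bond
lengths equal the Engh--Huber-style constants to machine precision and the
measured $\phi/\psi$ of a built chain reproduce the inputs to $10^{-12}$
degrees --- and bit-deterministic, so every library member shares an
identical backbone scaffold.

The default dihedral table is an extended $\beta$-like scaffold
($\phi=-139^\circ$, $\psi=135^\circ$, $\omega=180^\circ$ at every
position). This is a stand-in: scaffold dihedrals measured from a real
peptide--MHC complex are the intended input (`dihedral_table(file=)`), and
the default is labelled as such in its provenance field.

Side chains are placed from ideal internal-coordinate templates with a
single most-common rotamer per residue ($\chi = 180^\circ$ where the small
built-in table has no entry). Aromatic six-rings use uniform 1.39 Å /
120° geometry, which closes the hexagon exactly and keeps it exactly
planar. No hydrogens are built; scoring uses heavy atoms only. No
energy minimisation of internal geometry is performed --- rigidity is the
premise, not an approximation to be relaxed.

## Restraints

Two ambiguous interaction restraints anchor the ligand to the receptor:
(P2 CA, P3 CB, P4 CA) against the CDR3$\alpha$ loop-center CA and
(P4 CA, P5 CB, P6 CA) against the CDR3$\beta$ center, each with
flat-bottom bounds 4--8 Å and force constant 50 kcal mol$^{-1}$ Å$^{-2}$.
The "central residue" of an annotated loop range is the lower median
index. Ambiguity is aggregated as
$d_\mathrm{eff} = (\sum_\mathrm{pairs} d^{-6})^{-1/6}$, a smooth
minimum-dominated effective distance: it never exceeds the closest pair
distance and adding a pair can only decrease it. The restraint energy is a
soft-square potential, zero on the closed interval $[4, 8]$ and harmonic
in the violation outside.

The same scheme can be counted as *four* restraints by splitting each
three-membered group differently; `make_default_airs(mode = "split")`
emits one single-pair restraint per listed atom for that reading. Neither
mode is asserted as the original intent. Where a CB slot falls on a
glycine spacer the pair degrades to CA with a warning. Restraints export
both as a native JSON schema and in the ambiguity-driven docking `assign`
dialect (bounds $[4,8]$ written as `6.0 2.0 2.0`), so an external engine
can be used instead of the built-in one; the package never shells out to
external software.

## Scoring and docking

The docking engine is a desk-scale stand-in for a full
molecular-mechanics docking suite, and no absolute energies from such
engines are claimed. Scoring is intermolecular-only:

* 12-6 Lennard-Jones with per-element-class parameters (C, N, O, S).
  The radii ($\sigma_C = 3.20$ Å, $\sigma_N = 3.05$, $\sigma_O = 2.85$,
  $\sigma_S = 3.35$) sit about 6% below common liquid-simulation values:
  rigid ideal-geometry bodies cannot relax out of mild overlap, and with
  full-size radii near-contact poses are dominated by hard-core repulsion
  rather than by the interactions being compared.
* Coulomb with a distance-dependent dielectric $\epsilon(r) = 4r$ (a cheap
  implicit solvent), over a coarse charge set: a backbone dipole
  (N $-0.40$, CA $+0.25$, C $+0.55$, O $-0.40$) plus formal charges
  spread over the terminal polar atoms of charged side chains and
  $\pm 0.25/0.5$ dipoles on polar groups.
* the summed flat-bottom AIR energies.

Cutoff 12 Å with no switching function; the resulting discontinuity
(~$10^{-3}$ kcal/mol per pair at the cutoff) is accepted at this scale.
Units are kcal/mol and Å throughout. Both molecules are fully rigid.

`dock_peptide()` generates the ensemble: initial placements draw a uniform
random rotation (quaternion method) and a translation putting the ligand's
restraint-anchor centroid in a 1.5 Å ball around the receptor-side
restraint atoms' mean position, so most starts already satisfy the AIR
window; grossly overlapping draws are resampled a bounded number of times.
Each start is refined by Metropolis Monte Carlo over rigid
rotations/translations with geometric cooling, preceded by a deterministic
"pull-out" that backs an interpenetrating start out along the
receptor-to-ligand axis, and followed by up to three re-anneals if the run
ends at positive total energy (a wedged pose). The refiner returns the
lowest-energy pose visited, never worse than its start.

The default schedule is 4000 steps with Gaussian step scales of 12° /
0.8 Å and cooling from 20 to 0.02 kcal/mol. A gentler schedule (hundreds
of steps, ~2° / 0.3 Å, T ~2) was evaluated first and rejected: with
uniformly random starting orientations it cannot rotate a 30 Å peptide
into the correct basin within the step budget, and a small fraction of
poses stays wedged in restraint-violating clashes, which inflates the
ensemble spread well past the few-percent standard-error regime the
method's statistics assume. All schedule parameters are user-settable.

Everything is a deterministic function of the seed: `dock_peptide(seed)`
reproduces bit-identical pose sets, and `run_pipeline()` docks peptide $i$
with seed $\texttt{seed} + i - 1$, so a library run equals independent
per-peptide runs.

## Ensemble statistics and library reduction

All `n_poses` poses enter the per-peptide statistics (no filtering): the
per-peptide coordinates are the ensemble means of energy ($E_i$) and
intermolecular contacts ($C_i$, heavy-atom pairs under 6.0 Å --- a
configurable default chosen to give counts of order $10^2$--$10^3$ for a
9-mer against a receptor). SDs use the sample convention (ddof = 1, 0 for
a single pose) and $\mathrm{SEM} = \mathrm{SD}/\sqrt{n}$.

The best-binder window is centred on the unweighted means of the
per-peptide $E_i$ and $C_i$ with half-widths equal to their standard
deviations *across the library* --- the spread of the energy--contact map.
A literal "standard error of the mean" reading of the window width is also
implemented (`sigma = "sem"`) but not the default: the SEM of 216 means is
tiny compared to the plotted spread of the map the window is meant to
capture, and would select almost nothing. Membership is the closed double
inequality in both coordinates. For independent standard-normal
coordinates the expected member fraction is
$(\Phi(1)-\Phi(-1))^2 \approx 0.466$, which the test suite verifies by
Monte Carlo.

The positional heatmap averages $E_i$ for each SCAA class at each triad
position over a subset of records --- by default the window members, the
reading most consistent with a best-binder analysis; `subset = NULL` uses
all records (a documented open choice). Empty cells are missing, not zero.
Exclusion proposals take each position's energetic *maximum*, with two
conservative guards: a maximum must lead the runner-up by more than a
margin (default 1 kcal/mol; exact ties and noise-level leads propose
nothing), and minima are never turned into positive selections --- an
energetically dominant residue is not necessarily the biological one.
Proposals are advisory: `run_pipeline()` reports them and the reduced
library size but never reduces on its own.

## Synthetic fixtures: what they show and what they do not

`make_mock_receptor()` builds two 7-residue poly-alanine loops (helical
dihedrals $\phi=-60^\circ$, $\psi=-45^\circ$) and places them as the walls
of a V-shaped groove around the shared library scaffold frame. Placement
is self-calibrating: each loop's central CA is positioned by root-finding
so that the default AIR effective distance from the scaffold anchors is
exactly 6.0 Å, and each loop is rolled about its axis to present its
least-clashing face to the groove. The $\beta$ loop is tilted 12° and
raised 0.8 Å so the groove has no mirror symmetry. `make_planted_complex()`
then settles a library peptide into the groove by deterministic
Nelder--Mead minimisation of the intermolecular energy under a strong
pinning term holding both effective distances at 6.0 Å, after a coarse
roll scan that seats the triad side chains. The stored pose satisfies both
restraints at the flat-bottom centre ($E_{air}=0$, $d_\mathrm{eff}=6.0\pm
0.1$) and is clash-free, making it a valid recovery target.

Docking recovery is measured as the *minimum* ligand-C$\alpha$ RMSD to the
plant over the 100 refined poses --- the standard sampling-success
criterion. Across ten seeds this minimum falls between 1.0 and 2.0 Å and
the ensemble $\mathrm{SEM}(E)/|\bar E|$ between 1.6% and 1.9%. The
lowest-energy pose usually lies 2--2.5 Å from the plant; occasionally a
competing basin at larger RMSD scores marginally lower, which is expected
for a symmetric-ish poly-alanine groove and a coarse force field, and is
why energy rank is not the recovery criterion.

These fixtures exercise every code path deterministically, but a
two-loop poly-alanine groove is not a TCR: it has no real CDR3 sequence
diversity, no MHC-II partner shaping the bound conformation, and its
energy scale is set by the simplified force field. Passing the fixture
suite demonstrates internal correctness (geometry, restraints,
reproducibility, recovery of a planted ground truth), not predictive
accuracy on real complexes. Likewise `make_synthetic_records()` plants
known per-class/per-position energy offsets under Gaussian noise so the
heatmap/exclusion stage can be tested against ground truth; it emulates
record-level statistics only, not docking physics.

## Problem sizes and degenerate inputs

The test suite and the acceptance script keep simulations at the scale the
statistics need and no larger: one 100-pose docking run on the fixture,
$10^4$ records for the window-fraction Monte Carlo, full 216-peptide
pipeline runs only with `n_poses = 1` and zero-step schedules (exercising
plumbing, not physics). A full-physics 216-peptide screen at the default
schedule is a production run of roughly an hour on one core.

Degenerate inputs are handled explicitly: empty effective alphabets
enumerate to an empty library with a warning; a single pose has SD 0 by
convention; windows require at least two records; empty heatmap cells are
`NA`; collinear torsion references are rejected; selectors that do not
resolve to exactly one atom are errors naming the selector; missing
backbone atoms in an annotated CDR3 range abort annotation with the
residue list.

## Known limitations

* The scoring function is a simplified stand-in; absolute energies and
  contact counts are not comparable to published molecular-mechanics
  values, and only relative/statistical behaviour is meaningful.
* Receptor side chains are rigid; induced fit and encounter-complex
  dynamics are out of scope, as is the MHC-II molecule itself (its
  geometric role is mimicked by the restraints).
* The default dihedral scaffold is generic; per-system scaffolds should be
  supplied from real complexes.
* The rotamer policy is a single fixed rotamer per residue; restraints on
  CA/CB atoms are used precisely so that this bias does not steer the
  docking, but sidechain-level contacts still inherit it.
* Library reduction arithmetic supports arbitrary per-position alphabets
  (e.g. decamer designs with restricted anchor positions), but no attempt
  is made to enumerate beyond the triad template.
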