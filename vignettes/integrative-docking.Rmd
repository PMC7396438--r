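---
title: "Integrative rigid-body docking constrained by in vivo cross-links"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative rigid-body docking constrained by in vivo cross-links}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlinkdock)
```

## The problem

Periplasmic chaperones such as SurA hand nascent outer-membrane proteins
to the BAM complex, but no experimental structure of the chaperone bound
to the machine exists. What does exist is sparse but precise residue-level
information: photo-cross-linking with the unnatural amino acid pBpa
identifies receptor residues in direct contact with the ligand protein,
and chemical cross-linkers constrain specific residue pairs to lie within
a known spacer-arm reach (12 Å for amine-to-amine reagents such as DSP,
6.8 Å for amine-to-sulfhydryl reagents such as SPDP). `xlinkdock`
implements the computational half of such a study: exhaustive rigid-body
docking of a ligand onto a receptor, followed by screening of the pose
ensemble against the cross-linking data, rescoring, and model-quality
validation — plus the small mass/band arithmetic used to argue about the
stoichiometry of cross-linked products.

## The pipeline

`runPipeline()` chains eight stages, each independently callable:

1. **simulate / load** — either generate a synthetic ground-truth system
   (`makeBlockComplex`) or read receptor/ligand PDB files with a
   restraint TSV and criteria YAML.
2. **dock** (`dockSearch`) — grid-based rigid docking.
3. **cluster / density** (`clusterPoses`, `poseDensity`).
4. **annotate** (`annotatePoses`) — interfaces, restraint distances,
   rescoring per pose.
5. **filter** (`filterPoses`) — experiment-derived interface criteria.
6. **restrain** — retained models must satisfy every spacer-arm
   restraint (the satisfied-count column is the filter key).
7. **select** (`selectModels`) — the density/score/rescore triple
   criterion over cluster representatives.
8. **validate** (`verifyScore`, `ramachandranClassify`) — model-quality
   grading of the ligand model.

All stage outputs are plain TSV/PDB/JSON, so any stage can be re-run in
isolation; the manifest records the seed and a configuration hash.

## Docking model

Structures are rasterised onto a cubic occupancy grid (default spacing
1.2 Å; a cell is occupied when its centre lies within 1.8 Å of a heavy
atom). Occupied cells with at least one empty 6-neighbour are *surface*;
the rest are *core*. The pairwise shape-complementarity score of a
translation is

$$S(t) = \sum_{\text{cells}} f(\text{receptor}, \text{ligand}),\qquad
f(\text{surface},\ \text{occupied}) = +1,\quad
f(\text{core},\ \text{occupied}) = -C,$$

with clash penalty $C = 9$ by default. For each sampled rotation the
score over *all* integer translations is computed at once by 3D FFT
cross-correlation; the implementation is required (and tested) to equal
the direct double-loop sum to 1 × 10⁻⁶. FFT round-off is rounded away at
the ninth decimal so that exact score ties remain exact and the
documented tie-break (score, then rotation index, then lexicographic
translation) is meaningful.

Rotations are sampled as seeded uniform random unit quaternions with the
identity rotation always included as the first element — a sampled set
therefore always contains the input orientation, and runs are
reproducible from the seed alone. Receptor residues marked *blocked*
(the membrane-embedded region in the motivating system) are removed
before rasterisation: cells owed solely to them contribute neither
contact nor clash.

A pose is a unit quaternion plus a translation, applied about the
reference ligand's heavy-atom centroid, so the transformed ligand
centroid is simply `centroid + t`. That position is what leader
clustering and pose density use.

## Screening the ensemble

**Clustering** is greedy leader clustering on the ligand position:
poses are visited in descending primary score and join the first cluster
whose representative lies within the cluster radius (default 10 Å), else
found a new one. **Density** counts poses whose ligand position falls
within a radius of a pose (inclusive of itself). The pipeline default
for the density radius is 5 Å rather than the 10 Å used for clustering:
on a toy complex only ~25 Å across, a 10 Å ball covers half the search
space and the count degenerates into "distance to the cloud centroid",
whereas 5 Å measures local consensus. Both radii are configuration.

**Filtering** encodes the experimental constraints: required receptor
interface residues (the photo-cross-link capture sites), a required
ligand docking domain that must carry at least `minDomainFraction`
(default 0.5 — the domain binds "mainly") of the ligand interface
residues, an orientation-required residue set with a minimum interface
count and an orientation-forbidden set with a maximum (to fix which face
of the ligand looks at the receptor). Every failure is recorded
per-criterion. Filtering is monotone: adding a required residue can only
shrink the passing set, a property the test suite checks over random
criteria.

**Restraints** are evaluated as minimum distances between anchor atoms:
NZ for lysine amines, SG for cysteine sulfhydryls (CB fallback with a
note when the modelled residue lacks the reactive group — e.g. a
wild-type position where the experiment used a cysteine mutant), CB with
CA fallback for residue-level photo-cross-links (default 10 Å reach when
used as a distance). Satisfaction is inclusive (`distance <= max`, with
a 1 × 10⁻⁹ Å tolerance for floating-point arithmetic) because a spacer
arm length is a maximum reach. A wildcard ligand anchor scans every
ligand lysine and reports all partners within reach, nearest first.

**Selection** follows the triple criterion — high density, high primary
score, low rescore. Records on the Pareto front of (density ↑, score ↑,
rescore ↓) rank before dominated records, then a lexicographic order
(density desc, score desc, rescore asc, pose id) decides. The pipeline
feeds this the cluster representatives (highest-scoring member per
cluster) of the restraint-satisfying passing set: representatives are
what one reports as models, and this suppresses low-scoring "crossroads"
poses that accumulate density where many mediocre placements overlap.

## Rescoring

The rescore is an ordinal re-ranking, not a calibrated energy. Heavy-atom
pairs within 9 Å contribute: a 6-12 Lennard-Jones split with the shifted
convention (outside the combined radius the attractive part is the full
LJ value and repulsion is zero; inside, attraction is held at the well
depth and repulsion is the excess — so repulsion is non-negative and
vanishes exactly at contact), screened Coulomb with a distance-dependent
dielectric over formal charges (+1 Lys NZ / Arg CZ, −1 Asp CG / Glu CD),
and a polar/apolar pairwise contact desolvation with a linear switch.
Pair distances are floored at half the combined radius so clashing
decoys stay finite. Weights are configuration (`rescoreWeights()`);
lower is better. No published weight set is reproduced — the score's
role is to separate packed from clashing placements, which the tests
check against the synthetic native and pushed-in decoys.

## Validation

`backboneDihedrals` computes standard φ/ψ torsions (right-handed sign
convention, degrees in (−180, 180]); missing atoms or collinear geometry
yield an undefined angle with a reason, never an error.
`ramachandranClassify` tests points against shipped favorable-region
polygons (favored + allowed combined: α basin, β/extended basin
continued across the ψ = 180° wrap, left-handed α) with ±360° shifts, so
classification is wrap-invariant.

`verifyScore` is a 3D-1D environment-profile assessment: per residue,
side-chain burial (sphere-point accessible area, 92 points by default,
probe 1.4 Å) and polar-contact fraction map to one of six
burial/polarity classes, φ/ψ bins give three secondary-structure
classes, and a 20 × 18 score table supplies the per-residue score. The
verify score is the per-residue sum, compared against an expected high
score calibrated on residue count — by default 0.45 per residue, a
constant consistent with published expected-high values for chaperone-
sized models — and an expected low score fixed at 45% of the high.
Grading uses three explicit bands: at or above the high bound
(`mostly_correct`), between the bounds (`intermediate`, still an
acceptably built model), and below the low bound (`grossly_misfolded`).
The boundary at the low bound joins the between band (inclusive lower
bound).

The shipped score table is a **synthetic calibration**
(`profile3d_scores_synthetic.tsv`), generated from hydropathy/burial
compatibility: no published profile table is reproduced, and the file
name says so. It orders good against bad environments correctly — which
is all the package claims — and is replaceable via
`profileScoreTable(path = ...)`.

## The synthetic ground-truth generator

`makeBlockComplex(seed, n_receptor = 120, n_ligand = 23,
interface_size = 9)` builds a five-layer receptor slab on a 3.5 Å
pseudo-residue lattice with a two-layer pocket carved into its top face,
and a ligand whose two bottom layers fill the pocket, continuing as a
stepped pyramid above. Residues are five-atom pseudo-residues (N, CA, C
plus two side-chain carbons) with a mirror-symmetric footprint, so shape
complementarity carries no directional bias; 0.2 Å Gaussian jitter
(seeded) keeps the lattice from producing degenerate ties. The pocket is
carved one lattice unit wider than the ligand footprint, which at the
default rasterisation radius leaves a contact band on every wall without
core clashes, and the ligand sits 0.6 Å low so its bottom face already
touches the floor contact band — pressing deeper immediately costs clash
penalty. The requested `interface_size` is realised as a p × p pocket
footprint with p = max(2, round(√interface_size)).

Planted ground truth: a cysteine (SG) and a lysine (NZ) on the pocket
walls pair with ligand lysines across the interface at ~5.5 Å — inside
the 6.8 Å amine-sulfhydryl and 12 Å amine-amine reaches with slack — and
a wildcard any-lysine restraint and a photo-cross-link site complete the
restraint set. The bottom slab layer (its own chain) is the blocked,
membrane-embedded analogue, kept ≥ 8 Å from the ligand. The bottom
ligand layer is the orientation-proximal set, layers above the pocket rim
the distal set, and the in-pocket layers the docking domain. Slab sites
are retained by priority — pocket walls, floor and the blocked column
first, then proximity to the pocket — and a receptor budget below the
structural minimum is a generation error rather than a silently broken
system. Generated systems are verified against their own invariants
(restraints satisfied with ≥ 0.5 Å margin, blocked distance, distal set
outside the native interface) with bounded retries.

What the generator does *not* emulate: real side-chain rotamers and
packing, sequence diversity, solvent, conformational flexibility, and
the size of a real receptor complex (a BAM-sized receptor has ~1500
residues, not 120). Passing the recovery tests therefore demonstrates
that the pipeline's machinery — grid scoring, clustering, filtering,
restraint evaluation, selection — is correct and self-consistent, not
that docking accuracy on real structures matches any published model
set.

## Parameters that matter

| parameter | default | units | where |
|---|---|---|---|
| grid spacing | 1.2 | Å | `dockSearch`, config |
| rasterisation radius | 1.8 | Å | `discretizeStructure` |
| clash penalty C | 9 | — | `correlateGrids` |
| rotations | 60 | count | pipeline config |
| retained poses (top_n) | 200 | count | pipeline config |
| interface cutoff | 5.0 | Å heavy-atom | `interfaceResidues` |
| cluster radius | 10 | Å | `clusterPoses` |
| density radius | 10 (op) / 5 (pipeline) | Å | see above |
| min domain fraction | 0.5 | — | `FilterCriteria` |
| spacer reaches | 6.8 / 12 | Å | restraint TSV |
| photo-site reach | 10 | Å | restraint TSV |
| energy cutoff | 9 | Å | `energyParams` |
| sphere points | 92 | count | `accessibleArea` |
| expected-high calibration | 0.45 | score/residue | `expectedScoreBounds` |

## Numerical choices and degenerate inputs

* Altloc: the first-listed location of each atom is kept.
* Insertion codes are part of residue identity; numbering is taken as-is
  from the file (no renumbering).
* Hydrogens are parsed but excluded from all distance, grid, surface and
  energy computations.
* FFT correlation output is rounded at 1 × 10⁻⁹ so exact ties stay exact.
* A ligand with no heavy atoms yields an empty pose list with a warning,
  so batch runs survive degenerate inputs; an empty rotation set is a
  configuration error.
* Grid dimensions are capped at 128³ cells (resource error above).
* Restraint satisfaction and Ramachandran region membership are
  boundary-inclusive.
* An empty structure has verify score 0; chain-terminal residues have
  the corresponding dihedral undefined.

## Problem sizes

The test suite and the acceptance script run the full pipeline on
synthetic systems of 120 receptor and 23 ligand residues with 60
rotations and 200 retained poses (a few seconds per run), brute-force
oracles on grids up to 12³ and random 30-residue toys, and decoy
ensembles of 200. These sizes were chosen so each ground-truth property
is exercised well inside interactive runtimes while keeping every oracle
comparison exhaustive.

## Known limitations

* Rigid-body only: no flexibility, refinement or side-chain repacking.
* The shape-complementarity score omits the desolvation/electrostatic
  grid terms some published docking functions add at the FFT stage;
  those physics live (simplified) in the rescoring step, which is used
  ordinally.
* The 3D-1D score table and the expected-high calibration are package
  calibrations, not reproductions of proprietary tables; absolute verify
  scores are comparable within this package only.
* Ramachandran regions are a generic two-level set; outlier counts will
  not match any specific commercial region definition.
* PDB input only (fixed-column); no mmCIF, assemblies or occupancy
  weighting.
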