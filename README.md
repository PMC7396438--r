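# xlinkdock

Integrative rigid-body docking of protein–protein complexes constrained
by in vivo cross-linking data.

Residue-level cross-linking experiments yield two kinds of spatial
information about a complex that has no experimental structure:
photo-cross-linking (pBpa) identifies receptor residues in direct
contact with the ligand protein, and chemical cross-linkers bound
specific residue pairs to a known spacer-arm reach (12 Å amine–amine,
6.8 Å amine–sulfhydryl). `xlinkdock` turns such data into structural
models: it docks the ligand exhaustively onto the receptor by
FFT-accelerated shape complementarity, clusters the pose ensemble by
ligand position, screens it against the experimentally required
interface residues, docking domain and orientation, checks every
spacer-arm restraint, re-ranks with a detailed-energy score, and selects
final models by the high-density / high-score / low-rescore triple
criterion. Model quality is graded with Ramachandran classification and
a 3D-1D environment-profile verify score with length-calibrated
expected high/low bounds (low = 45% of high). The package also carries
the stoichiometry arithmetic of cross-linked products: predicted adduct
masses and internal-control-normalised band quantification.

The docking score of a translation $t$ at a given rotation is the grid
sum

$$S(t)=\sum_{\text{cells}} f,\qquad f(\text{surface},\text{occ})=+1,\;
f(\text{core},\text{occ})=-C,$$

computed for all translations at once by 3D FFT cross-correlation and
guaranteed (and tested) to equal the direct sum to 1e-6. A built-in
synthetic-system generator plants a ground-truth complex — pocket,
native pose, cross-link anchor pairs inside the spacer reaches, blocked
membrane-analogue region — so every pipeline stage is testable without
any external input.

## Worked example

```r
library(xlinkdock)

sys <- makeBlockComplex(seed = 1)          # ground-truth toy complex
sys
#> SyntheticSystem (seed 1): receptor 120 residues / ligand 23 residues,
#>   4 planted restraints, 16 blocked residues

evaluateRestraints(sys@restraints, sys@receptor, sys@ligand)[,
  c("label", "kind", "distance", "satisfied", "partners")]
#>           label             kind distance satisfied partners
#> 1      SPDP_6.8 amine_sulfhydryl 5.612855      TRUE     S:10
#> 2        DSP_12      amine_amine 5.684131      TRUE     S:18
#> 3 DSP_12_anyLys      amine_amine 5.684131      TRUE     S:18
#> 4     pBpa_site       photo_pBpa 5.561095      TRUE     S:18

res <- runPipeline(defaultRunConfig(seed = 1), "run1")
#> [simulate] receptor 120 residues, ligand 23 residues
#> [dock] 200 poses generated
#> [annotate] 10 clusters
#> [filter] 4 of 200 poses pass
#> [select] 1 models selected
#> [validate] ligand model graded mostly_correct (verify 14.20)

res$selected[, c("id", "cluster", "density", "score", "rescore", "sat_count")]
#>    id cluster density score   rescore sat_count
#> 12 12       2       7    56 -210.6355         4
```

Every planted restraint is measured at ~5.6 Å — within both spacer-arm
reaches. Of 200 docking poses, 4 satisfy the interface criteria and all
four restraints; the selected model (pose 12, the representative of its
cluster) has the top shape-complementarity score (56) and sits at
translation (0.58, 0.54, −0.10) Å — within one 1.2 Å grid cell of the
planted native placement. The 23-residue ligand model grades
`mostly_correct` (verify score 14.2 against an expected high of 10.35
and an expected low of 4.66, i.e. 45% of the high).

The stoichiometry arithmetic is one call:

```r
predictedMass(c(BamA = 1, SurA = 2))   # 95 + 2*47
#> [1] 189
```

A thin command-line wrapper lives at `inst/scripts/xlinkdock.R`
(`simulate` and `run` subcommands over the same functions).

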