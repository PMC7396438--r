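Package: xlinkdock
Title: Integrative Rigid-Body Docking Constrained by In Vivo Cross-Links
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs and screens rigid-body models of protein-protein
    complexes under residue-level cross-linking restraints. Provides
    FFT-accelerated shape-complementarity docking on occupancy grids,
    pose clustering and density analysis, interface-based filtering
    against photo-cross-linking derived binding-site residues, chemical
    cross-link spacer-arm distance checks, energy-based rescoring,
    Ramachandran and 3D-1D profile model validation, and the band
    quantification and adduct-mass arithmetic used for stoichiometry
    analysis of cross-linked products. A synthetic two-body complex
    generator with planted cross-link anchors provides ground truth for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    bio3d,
    pracma
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'crosslink-products.R'
    'docking.R'
    'pipeline.R'
    'pose-analysis.R'
    'rescoring.R'
    'restraints.R'
    'structure-io.R'
    'synthetic.R'
    'utils-geometry.R'
    'validation.R'
    'xlinkdock-package.R'
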