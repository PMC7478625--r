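Package: corepan
Title: Core and Pan-Genome Analysis with Multi-Evidence Annotation,
    Pathway Profiling and Marker Phylogenomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative genomics toolkit for bacterial genera, built
    around the gut anaerobe genus Roseburia as the motivating system.
    Reconciles multi-evidence functional annotation (equivalog and
    domain profile-HMM hits filtered at trusted cutoffs, KEGG
    Orthology and protein-family assignments, and gene-neighbourhood
    context) into a confidence-tiered function call per gene; computes
    core-genome, pairwise-shared and Venn-exclusive orthologue
    co-occurrence statistics over genome rosters; evaluates boolean
    pathway-requirement trees to call pathway completeness and
    vitamin synthesis-versus-salvage strategies; and builds
    neighbor-joining trees with bootstrap supports from concatenated
    single-copy markers under Poisson-corrected amino-acid or
    Tamura-Nei nucleotide distances. A fully seeded synthetic-data
    generator emits pangenomes, evidence tables and marker alignments
    with known truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'rng.R'
    'tiers.R'
    'annotation-io.R'
    'evidence.R'
    'pangenome.R'
    'pathways.R'
    'phylo.R'
    'simulate.R'
    'pipeline.R'
    'corepan-package.R'
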