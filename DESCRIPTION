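Package: ClustConsrank
Title: Consensus Scoring of Protein-Protein Docking Models with
    Contact-Based Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ranks ensembles of protein-protein docking models by
    conservation of inter-residue contacts (CONSRANK consensus scoring)
    and implements Clust-CONSRANK, in which scoring is preceded by
    agglomerative hierarchical clustering of the models on their
    contact Hamming distances (single or complete linkage, distance or
    maxclust cuts), with one model selected per top-populated cluster.
    Includes a redundancy-removal baseline, CAPRI-style quality
    assessment (fraction of native contacts, ligand RMSD, quality
    classes), PDB ensemble input with residue-numbering harmonization,
    consensus contact maps, and a seeded rigid-body decoy simulator for
    desk-scale benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ClustConsrank-package.R'
    'utils.R'
    'contacts.R'
    'evaluation.R'
    'structio.R'
    'synthetic.R'
    'consrank.R'
    'clustering.R'
    'selection.R'
    'cli.R'
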