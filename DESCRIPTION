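Package: AntioxScreen
Title: Antioxidant Thermochemistry, Reactivity Descriptors and Druglikeness
    Screening for Phenolic Compounds
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-processing calculus for quantum-chemical studies of phenolic
    antioxidants such as the anthocyanidin petunidin. Computes conceptual-DFT
    global reactivity descriptors (hardness, softness, electronegativity,
    chemical potential, electrophilicity) from frontier-orbital or total
    energies, per-site thermochemical parameters of the radical-scavenging
    mechanisms (BDE for HAT, AIP/PDE for SET-PT, PA/ETE for SPLET) with exact
    thermodynamic-cycle closure, multi-criteria O-H site-reactivity ranking
    (bond orders, atomic charges, pKa, dissociation energies), molecular-graph
    property counting from SMILES (molecular weight, H-bond donors/acceptors,
    rotatable bonds, Ertl TPSA), and a druglikeness layer with Lipinski/Veber
    rule checks, bioactivity-score classification and the multiplicative
    sigmoid drug score. Ships an inverse-constructed synthetic species
    generator with known descriptor ground truth and a bundled petunidin
    fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Cheminformatics, Pharmacogenetics, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'AntioxScreen-package.R'
    'units.R'
    'descriptors.R'
    'druglikeness.R'
    'species.R'
    'mechanisms.R'
    'fixtures.R'
    'molgraph.R'
    'site_reactivity.R'
    'report.R'
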