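Package: darkog
Title: Discovery and Characterization of Conserved Dark Gene Families
    from Orthogroup Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies and characterizes conserved gene families of unknown
    function ("dark" orthogroups) from orthogroup membership tables and
    exhaustive homology-search results. Implements dark/light classification
    from hit descriptions, lowest-common-ancestor lineage assignment over a
    configurable taxonomic rank ladder, selection of lineage-conserved dark
    families, an exponential bitscore-decay model of homology detection
    failure with per-taxon detection probabilities, dark-versus-light
    expression-bias statistics for bulk, proteomic and single-cell data, and
    a filtered, deduplicated remote-homology network over gene families.
    Includes a seeded synthetic-data generator that emulates every input
    with planted ground truth so the full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    IRanges,
    ape,
    igraph,
    minpack.lm,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'darkog-package.R'
    'AllClasses.R'
    'darkness.R'
    'expression.R'
    'hdf.R'
    'intervals.R'
    'io.R'
    'lineage.R'
    'network.R'
    'pipeline.R'
    'simulate.R'
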