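Package: popcar
Title: Strain Prioritization and Unique-Metabolite Discovery by PCA Plane
    Search of LC-MS Bucket Tables
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the PoPCAR workflow for untargeted LC-MS
    metabolomics of bacterial strain collections. Per-sample feature lists
    are merged into a bucket table under retention-time and ppm mass
    tolerances, replicates are averaged, and the table is range-filtered,
    sum-normalized and Pareto-scaled before principal component analysis.
    For every strain the package automatically locates the PC plane in
    which that strain separates most from all others, extracts the mass
    features unique to the strain from the bucket table, ranks them by
    Euclidean loading distance in that plane, and optionally dereplicates
    the masses against a compound database under adduct rules, flagging
    non-matching masses as putatively novel. A synthetic-data generator
    with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Metabolomics, MassSpectrometry, PrincipalComponent, Software
RoxygenNote: 7.3.3
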