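Package: cgrid
Title: Cartesian Grid Normalization of Flattened Sensorimotor Cortex Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imposes an N x M Cartesian grid on an atlas-bounded region of a
    flattened cortical surface mesh, demonstrated on the sensorimotor cortex
    (precentral and postcentral gyri). Anatomical borders are extracted from
    per-vertex atlas labels, 10th-order polynomials are fitted through the
    three sulcal borders, intermediate curves are generated by coefficient
    interpolation, truncated at the dorsal and ventral borders, and resampled
    at equal arc length to form tiles. Per-vertex scalar maps (e.g. GLM beta
    values) are averaged per tile, yielding directly comparable activation
    grids across subjects and hemispheres. Includes Fisher z-transformed
    Pearson pattern-similarity evaluation (within-subject left-right and
    between-subject leave-one-out), surface smoothing, readers and writers for
    FreeSurfer, GIFTI and a plain-text mesh dialect, and a synthetic flat-map
    generator with planted somatotopic hotspots for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'dialect.R'
    'flatmesh.R'
    'io-fmesh.R'
    'io-freesurfer.R'
    'io-gifti.R'
    'io-flatmap.R'
    'neighbors.R'
    'borders.R'
    'polyfit.R'
    'curves.R'
    'cgrid-build.R'
    'cgrid-map.R'
    'smoothing.R'
    'similarity.R'
    'synthetic.R'
    'pipeline.R'
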