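Package: bulbmorph
Title: Quantitative Analysis of Olfactory Bulb Rewiring During Amphibian
    Metamorphosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the restructuring of the main olfactory bulb
    (MOB) during anuran metamorphosis from four kinds of raw data: projection
    field volumetry and bilateral innervation overlap from multi-channel 3D
    fluorescence stacks (maximum-entropy and Huang fuzzy thresholding,
    axis profiles, polynomial and RANSAC regression); odor-response tuning and
    spatial density mapping of glomerular regions from volumetric calcium
    recordings (difference maps, asymmetric least squares baseline correction,
    12.5 percent tuning threshold, forskolin classification, Scott's-rule
    kernel density estimates); tuft-level morphometry of reconstructed
    projection neurons from SWC files (density-based tuft clustering, convex
    hull volumes, path distances, branch classification); and two-area
    behavioral choice assays from trajectory tables (visit segmentation,
    time-per-visit statistics, paired signed-rank testing). A synthetic-data
    module generates every input with planted, recoverable ground truth so the
    whole pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    tools,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'thresholds.R'
    'filters.R'
    'volumetry.R'
    'regression.R'
    'asls.R'
    'kde.R'
    'calcium.R'
    'convhull.R'
    'swc.R'
    'neuron.R'
    'behavior.R'
    'synthetic.R'
    'io.R'
    'pipeline.R'
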