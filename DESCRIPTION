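Package: filatrace
Title: Filament Picking for Cryo-EM Micrographs by Oriented Line
    Enhancement, Ridge Detection and Directional Tracing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for selecting filamentous particles (e.g. F-actin,
    tobacco mosaic virus) in cryo-electron micrographs. Implements line
    enhancement with banks of oriented second-derivative Gaussian kernels,
    Steger-style subpixel ridge detection with hysteresis linking and
    junction splitting, an end-to-end picking pipeline with grid-search
    threshold optimization, directional-map tracing of candidate boxes
    into filaments, pixel-level precision/recall evaluation based on
    morphological opening, a synthetic micrograph generator with ground
    truth, and readers/writers for MRC, TIFF, EMAN helical box and STAR
    coordinate files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'filatrace-package.R'
    'utils.R'
    'formats.R'
    'linefilter.R'
    'metrics.R'
    'ridge.R'
    'pipeline.R'
    'synthgen.R'
    'tracer.R'
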