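Package: seqBabel
Title: Declarative Interpretation and Translation of Structured Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts information-bearing segments (cell identifiers, unique
    molecular identifiers, well barcodes, spatial barcodes, payloads) from
    arbitrarily structured high-throughput sequencing reads declared in a
    plain-text process configuration, error-corrects them by rank-count
    knee-point imputation, allowlist mapping or an external plugin, organizes
    the corrected values in a parental-local value tree, minimizes the number
    of value species per variable while preserving the tree topology, and
    re-emits the reads as FASTQ of any other declared structure so that tools
    built for one read layout can analyze another. Includes a structured-read
    simulator with ground truth, a spatial bead-to-spot conversion-table
    builder, clonal-well calling for row-column-plate PCR libraries, and a
    rank-difference statistic for comparing high-dimensional profiles before
    and after translation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'config.R'
    'config-io.R'
    'matcher.R'
    'segmentation.R'
    'correction.R'
    'value-space.R'
    'translate.R'
    'spatial.R'
    'eval.R'
    'simulate.R'
    'orchestrator.R'
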