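Package: genovizrec
Title: Knowledge-Based Recommendation of Interactive Genomics Visualizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A knowledge-based recommendation engine that maps abstract
    descriptions of genome-mapped datasets (file format, attribute types,
    feature extent and density, connectivity) and an analysis task
    (identify, compare, overview) to ranked interactive-visualization
    designs. Recommendation knowledge is stored as per-component decision
    matrices with binary (+1/-1) cells; output options are ranked by cosine
    similarity between a scenario-derived input vector and each matrix row.
    Six components are resolved in sequence (encoding, alignment, layout,
    partition, arrangement, interactivity), tied top options branch into
    design variations, and each complete candidate is serialized as a
    Gosling-grammar-subset JSON specification. Includes an exhaustive
    scoring mode for stimulus selection, a seeded scenario generator, and
    command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
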