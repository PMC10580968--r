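Package: microassembly
Title: Community Assembly, Co-Occurrence and Topological Analysis of Microbiome OTU Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for analysing prokaryotic community assembly from
    OTU count tables: rarefaction and abundance transforms; partitioning of
    taxa into abundant/rare and generalist/specialist groups by Levins niche
    breadth; distance-decay regression of community similarity against
    geographic distance; Sloan neutral community model fitting by non-linear
    least squares; canonical correspondence analysis with permutation tests
    and variation partitioning; SparCC compositional correlation networks
    with hub and keystone taxon identification; and Mapper topological
    networks of samples with SAFE enrichment scoring. Includes a synthetic
    OTU-table generator with planted neutral, spatial, specialist and
    correlation structure so that every stage has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    igraph,
    minpack.lm,
    geosphere,
    jsonlite,
    yaml
Suggests:
    biomformat,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
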