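Package: hdindex
Title: Human Disturbance Index Mapping on Gridded Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies anthropogenic pressure on gridded landscapes with the
    Human Disturbances Index (HDI), the cellwise sum of a land-use naturalness
    index (LNI), a resource-consumption index (RCI), and a pollutant-emission
    index (PEI). Builds consumption and emission surfaces from sectoral
    statistics, population rasters, and coarse emission fields (ordinary
    kriging or inverse-distance upsampling), standardizes each surface to 0-10
    scores with Fisher-Jenks natural breaks, classifies the 0-60 HDI into ten
    equal-interval disturbance levels, and analyzes spatiotemporal patterns
    through weighted centroid migration, global Moran's I with normal and
    permutation inference, and Getis-Ord Gi* hot- and cold-spot detection.
    Includes a seeded synthetic-landscape generator so every pipeline stage is
    testable without external data, plus ESRI ASCII grid I/O and GeoJSON zone
    rasterization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
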