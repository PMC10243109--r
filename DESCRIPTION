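Package: hdSpectra
Title: Hyperdimensional Binary Encoding and Clustering of Tandem Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Spectral clustering of MS/MS spectra via hyperdimensional
    computing. Spectra read from Mascot Generic Format files are filtered and
    quantized, encoded into bit-packed binary hypervectors by XOR-binding
    m/z-bin and intensity-level codebook vectors and majority bundling,
    divided into precursor-mass buckets, and clustered per bucket on
    normalized Hamming distance matrices with DBSCAN or complete-linkage
    hierarchical clustering. Ships clustering-quality metrics (clustered
    spectra ratio, incorrect clustering ratio, completeness) and a seeded
    generator of labeled synthetic datasets with planted cluster structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    parallel,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
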