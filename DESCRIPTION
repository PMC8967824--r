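Package: szdpd
Title: Stack-ZDPD Compression and a Mini-Aird Container for Mass Spectrometry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lossless-at-integer-level compression of centroided mass
    spectrometry m/z arrays with the Stack-ZDPD scheme: m/z values are
    quantized to a configurable decimal precision, the arrays of up to 2^n
    adjacent same-level spectra are merged into one sorted integer array,
    delta-encoded, compressed with a patched frame-of-reference (PFor)
    bit-packing codec and a zlib outer layer, and stored together with an
    n-bit-per-peak tag array that allows exact per-spectrum reconstruction.
    Includes a documented two-file container format (JSON index plus binary
    blocks) with random spectrum access and extracted ion chromatogram
    queries, a subset mzML reader and fixture writer, a seeded generator of
    TOF-like synthetic runs, layer-sweep benchmarking utilities, and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    xml2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mzR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
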