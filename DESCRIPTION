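Package: airdlite
Title: Computation-Oriented Mass Spectrometry Data Format with ZDPD m/z Compression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reader, writer, converter and query engine for a two-file mass
    spectrometry data container: a JSON metadata document plus a binary block
    file holding compressed spectra. The m/z dimension is compressed with the
    ZDPD pipeline (fixed-point quantization at a chosen number of decimal
    places, delta coding of the sorted integers, patched frame-of-reference
    bit packing, then DEFLATE), and intensities with either a 1-decimal-place
    fixed-point zlib codec or a near-lossless log10 codec. Spectra are
    reordered and indexed by acquisition mode (retention-time linear, DDA
    MS1/MS2 groups, or DIA/SWATH precursor-window groups) so that block reads,
    single-spectrum seeks and extracted ion chromatograms touch only the bytes
    they need. Includes an mzML converter and a deterministic synthetic-run
    generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    mzR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
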