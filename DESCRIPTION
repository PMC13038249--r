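Package: fastapack
Title: Fast Block-Based Lossless Compression of FASTA Files
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Lossless compressor and decompressor for FASTA files (and
    arbitrary byte streams) built around fixed-size block processing.
    Each block is partitioned into typed streams: DNA runs packed two
    bits per base, N-runs stored as lengths only, mixed/ambiguous
    content kept verbatim, and headers plus non-conforming line breaks
    copied raw. Regular line wrapping is modelled and removed, and
    letter case (soft-masking) is preserved as a bitmask. Streams are
    optionally compressed with zstd (level 1, long-distance matching);
    the dominant packed-DNA stream is only compressed when a one-time
    probe on the first block shows at least a 1.25-fold reduction, so
    redundant collections shrink multi-fold while low-redundancy
    genomes are processed at full speed. Includes a deterministic
    synthetic FASTA corpus generator for testing, a documented
    container format, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: libzstd (>= 1.4), zlib
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
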