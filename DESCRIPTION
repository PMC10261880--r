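Package: slow5pipe
Title: Streaming Access to Nanopore Signal Files and Batched Basecall Dispatch
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reader and writer for the SLOW5 (ASCII) and BLOW5 (compressed
    binary) nanopore raw-signal file formats, including appending, a byte-offset
    index for random access, a delta-zigzag-varint signal codec, and sequential
    batched streaming with multi-worker record decoding. On top of the format
    layer it provides a basecall-dispatch pipeline modelled on server/client
    basecalling wrappers: a bounded submission queue, pluggable basecaller
    backends (with a deterministic pore-level mock), FASTQ and unaligned-SAM
    emission, and pass/fail splitting by mean phred quality. A synthetic signal
    generator with known ground-truth sequences, multi-read FAST5 conversion,
    and instrumented sequential-versus-random access benchmarks make the whole
    stack testable without real sequencing data or a neural-network basecaller.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    parallel,
    rhdf5,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: zstd
Config/testthat/edition: 3
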