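Package: blatr
Title: BLAT-Style DNA Sequence Search with 2bit Archives, PSL Output,
    and an In-Memory Query Server
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A self-contained seed-and-extend DNA search toolkit in the
    style of BLAT and its gfServer/gfClient pair.  Provides a byte-exact
    encoder and decoder for the UCSC .2bit genome archive format
    (including N-blocks and soft-mask blocks), a k-mer tile index with
    overused-tile filtering, ungapped x-drop extension and block
    chaining into 21-column PSL alignment records, a
    QueryResult/Hit/HSP result object model, a TCP genome-search server
    with ergonomic lifecycle management (start, stop, status, wait,
    port retry, attach), and a deterministic synthetic-benchmark
    generator with planted-query truth tables.  All operations can run
    fully in memory; a command-line interface with shell completion
    mirrors the library surface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    parallel,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
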