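Package: zoneworm
Title: K-mer Graph Clustering and Greedy Contig Assembly via Map/Collate/Reduce
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Partitions the de Bruijn graph of an RNA-Seq read set into
    connected components ("zones") before assembly, then runs a greedy
    Inchworm-style contig builder independently within each component.
    Every graph stage (k-mer counting, overlap-edge extraction and
    filtering, connected components by zone-label propagation, regrouping
    of k-mers by zone) is expressed as map/collate/reduce cycles over
    hash-partitioned key/value stores with optional out-of-core paging,
    so the same code path scales from in-memory toy data to spilled
    on-disk processing. Includes a synthetic transcript and read
    simulator for fully reproducible end-to-end validation, and a
    command-line interface with inspectable TSV intermediates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    yaml,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
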