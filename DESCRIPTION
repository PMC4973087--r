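Package: ddradkit
Title: Design, Simulation and Analysis of Double-Digest RAD-Seq Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for planning and validating double-digest
    restriction-site associated DNA sequencing (ddRAD-seq) experiments. It
    digests genomes in silico with pairs of restriction enzymes (including
    degenerate IUPAC recognition sites), counts size-selectable fragments and
    models tag yield as a function of genome size; designs variable-length
    inline-barcode sets and shortened adapters; simulates paired-end reads
    with the protocol's read anatomy, depth dispersion and adapter
    read-through; demultiplexes and quality-filters such reads with
    restriction-remnant validation and pool-balance statistics; and clusters
    truncated reads into RAD tags, merges them into a catalog of loci and
    exports a SNP matrix in Phylip format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
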