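Package: wgdkit
Title: Paleopolyploidy Detection, Ks-Based WGD Dating and Karyotype Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and dating ancient whole-genome duplications
    from gene collinearity. Detects synteny blocks from homologous gene pairs
    under gap and family-size constraints, estimates Ka/Ks with the
    Nei-Gojobori (1986) counting method, fits Gaussian multi-peak models to
    Ks kernel densities, applies a two-step shared-event evolutionary-rate
    correction to date polyploidizations, builds reference-anchored homology
    tables to quantify post-polyploidy gene loss (loss rates, geometric
    deletion run-lengths, translocated best-hit fractions), classifies
    homoeolog expression bias, and replays ancestral-karyotype evolution
    through a chromosome event algebra. A forward simulator of polyploid
    genome evolution provides ground-truth datasets for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    igraph,
    jsonlite,
    minpack.lm,
    rtracklayer,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
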